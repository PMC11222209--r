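#' Connected metal components of a postoperative CT
#'
#' Thresholds the volume at `metal_threshold` and extracts 26-connected
#' components of supra-threshold voxels, discarding components smaller than
#' `min_volume_mm3` (beads, streak fragments). Components are returned
#' sorted by size, descending.
#'
#' @param postop A `ct_volume`.
#' @param metal_threshold Intensity above which voxels count as metal; the
#'   same threshold later excludes screws from the registration metric.
#' @param min_volume_mm3 Minimum component volume; the conventional default
#'   is half a screw-shaft volume, supplied by the caller (0 keeps all).
#' @return List of components, each a list with `idx` (1-based array
#'   indices), `world` (voxel world coordinates), `values` (intensities),
#'   `size_mm3`, and `centroid` (intensity-weighted, world mm). Empty list if
#'   nothing is above threshold.
#' @export
detect_metal_components <- function(postop, metal_threshold,
                                    min_volume_mm3 = 0) {
  stopifnot(metal_threshold >= min(postop$data))
  supra <- postop$data >= metal_threshold
  if (!any(supra)) return(list())
  labs <- cpp_label_components26(supra, dim(postop$data))
  tab <- tabulate(labs[labs > 0])
  voxvol <- prod(postop$spacing)
  keep <- which(tab * voxvol >= min_volume_mm3)
  keep <- keep[order(tab[keep], decreasing = TRUE)]
  lapply(keep, function(k) {
    idx <- which_indices(labs == k, dim(postop$data))
    w <- array_index_to_world(postop, idx)
    v <- postop$data[idx]
    list(idx = idx, world = w, values = v, size_mm3 = nrow(idx) * voxvol,
         centroid = colSums(w * v) / sum(v))
  })
}

#' Initialize a screw estimate from a metal component
#'
#' The shaft axis is taken as the principal eigenvector of the component's
#' voxel-coordinate covariance; the tip is anchored at the extreme projection
#' on that axis farthest from the volume's posterior face, and the tail
#' placed one nominal shaft length behind it (screws are of predetermined
#' length, which also disambiguates the tip from the tulip head).
#'
#' @param component One element of [detect_metal_components()]'s result.
#' @param radius,length Nominal shaft radius and length, mm.
#' @param level,side Carried through to the result.
#' @return A `detected_screw`: list with `tip`, `tail`, `axis`, `fit_score`
#'   (NA until fitted), `level`, `side`.
#' @export
init_screw_from_component <- function(component, radius, length,
                                      level = NA_character_,
                                      side = NA_character_) {
  w <- component$world
  if (nrow(w) < 8) stop("component too small to orient")
  cen <- sweep(w, 2, colMeans(w))
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  if (ev$values[1] < 4 * ev$values[2])
    stop("degenerate geometry: component is not elongated")
  axis <- ev$vectors[, 1]
  proj <- cen %*% axis
  # tip = end farther from the posterior (-y) face, i.e. larger world y
  if (axis[2] < 0) { axis <- -axis; proj <- -proj }
  tip <- colMeans(w) + max(proj) * axis
  tail <- tip - length * axis
  new_detected_screw(tip, tail, NA_real_, level, side)
}

new_detected_screw <- function(tip, tail, fit_score, level, side) {
  axis <- (tip - tail) / sqrt(sum((tip - tail)^2))
  structure(list(tip = tip, tail = tail, axis = axis, fit_score = fit_score,
                 level = level, side = side),
            class = "detected_screw")
}

#' Refine a screw pose by fitting the shaft model to the image
#'
#' Maximizes the contrast between the mean clipped intensity inside a
#' capsule of the nominal shaft radius and the mean clipped intensity in a
#' surrounding shell (radius to 2x radius), over five degrees of freedom
#' (tip position and two axis direction components; shaft length is fixed to
#' the plan). Intensities enter as a soft metal-occupancy (logistic squash
#' about the metal threshold), which clips streak-artifact brightness and
#' makes bone and soft tissue equivalent background so surrounding anatomy
#' cannot bias the fit. Shaft and shell membership use a smooth boundary so
#' the objective is differentiable; shell voxels within the tulip-head
#' region posterior of the tail are excluded so poly-axial head angulation
#' cannot bias the shaft axis.
#'
#' @param postop A `ct_volume`.
#' @param init A `detected_screw` initialization.
#' @param radius,length Nominal shaft radius and length, mm.
#' @param metal_threshold Clip level (and implicit metal definition).
#' @param maxit Iteration cap for the optimizer.
#' @return A fitted `detected_screw` with `fit_score` set. If the optimizer
#'   hits the iteration cap a warning carries the best iterate.
#' @export
fit_screw_model <- function(postop, init, radius, length, metal_threshold,
                            maxit = 300) {
  # candidate voxels: dilated bounding box around the initial capsule
  lo <- pmin(init$tip, init$tail) - 2 * radius - 2.5
  hi <- pmax(init$tip, init$tail) + 2 * radius + 2.5
  vlo <- floor(world_to_voxel(postop, lo))
  vhi <- ceiling(world_to_voxel(postop, hi))
  d <- dim(postop$data)
  rng <- lapply(1:3, function(a)
    max(1, vlo[a] + 1):min(d[a], vhi[a] + 1))
  idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  W <- array_index_to_world(postop, idx)
  # soft metal-occupancy: a logistic squash centred on the metal/background
  # interface midpoint saturates streak-artifact brightness (clipping) and
  # flattens bone-vs-soft-tissue contrast, so the shell term responds to
  # metal only, not to whichever anatomy happens to surround the shaft; the
  # midpoint is estimated from the data so the blurred metal boundary is
  # located without erosion
  raw <- postop$data[idx]
  metal_level <- stats::median(raw[raw >= metal_threshold])
  bg_level <- stats::median(raw[raw < metal_threshold])
  occ_mid <- (metal_level + bg_level) / 2
  occ_width <- 0.05 * (metal_level - bg_level)
  v <- plogis((raw - occ_mid) / occ_width)
  e1 <- orth_basis(init$axis)
  # boundary softness: follows voxel size so the objective stays smooth on
  # coarse grids
  soft <- max(0.25, 0.5 * mean(postop$spacing))
  norm_vox <- pi * radius^2 * length / prod(postop$spacing)
  guard <- 2 * radius + 1  # tulip-head down-weighting zone behind the tail
  objective <- function(par) {
    tip <- par[1:3]
    axis <- init$axis + par[4] * e1$u + par[5] * e1$v
    axis <- axis / sqrt(sum(axis^2))
    tail <- tip - length * axis
    # shaft model: cylinder capped by the hemispheric rounded tip whose
    # apex is the tip landmark, i.e. a capsule about the segment stopping
    # one radius short of the tip
    seg_tip <- tip - radius * axis
    dc <- dist_to_segment(W, tail, seg_tip) - radius
    t_ax <- sweep(W, 2, tail) %*% axis
    w_in <- plogis(-dc / soft) * plogis(t_ax / soft)
    # shell: one-radius-thick layer around the shaft surface, excluding the
    # tulip-head zone behind the tail; it wraps the tip apex, so metal past
    # the model tip is penalized and the axial position locks in
    w_sh <- plogis(dc / soft) * plogis((radius - dc) / soft) *
      plogis((t_ax - guard) / soft)
    # matched-filter form: total occupancy captured inside minus total
    # leaking into the shell (the model volume is fixed, so sums are
    # well-conditioned where per-region means would trade the fractional
    # apex taper against solid tulip metal and slide axially)
    (sum(w_in * v) - sum(w_sh * v)) / norm_vox
  }
  init_score <- objective(c(init$tip, 0, 0))
  # simplex first for capture range, quasi-Newton to finish
  pre_fit <- optim(c(init$tip, 0, 0), objective,
                   method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 400, reltol = 1e-8,
                                  parscale = c(0.5, 0.5, 0.5, 0.02, 0.02)))
  fit <- optim(pre_fit$par, objective,
               method = "BFGS",
               control = list(fnscale = -1, maxit = maxit, reltol = 1e-9,
                              parscale = c(0.5, 0.5, 0.5, 0.02, 0.02)))
  if (pre_fit$value > fit$value) fit <- pre_fit
  if (fit$convergence != 0)
    warning("screw fit did not converge within the iteration cap; returning best iterate")
  tip <- fit$par[1:3]
  axis <- init$axis + fit$par[4] * e1$u + fit$par[5] * e1$v
  axis <- axis / sqrt(sum(axis^2))
  # the capsule contrast localizes the axis and radial position precisely,
  # but the axial position only weakly (the shaft continues into the tulip,
  # so all axial information lives at the tip apex): finish with a 1-D
  # apex localization -- slide the model so its apex sits where the
  # occupancy profile along the fitted axis crosses one half
  shift <- apex_shift(postop, tip, axis, occ_mid, occ_width)
  tip <- tip + shift * axis
  out <- new_detected_screw(tip, tip - length * axis, fit$value, init$level,
                            init$side)
  out$init_score <- init_score
  out
}

# sub-voxel apex localization: sample metal occupancy along the fitted
# axis and interpolate the half-occupancy crossing
apex_shift <- function(postop, tip, axis, occ_mid, occ_width,
                       reach = 4, step = 0.05) {
  # a single on-axis ray: off-axis rays would cross the curved apex
  # surface earlier and bias the estimate tail-ward
  ts <- seq(-reach, reach, by = step)
  pts <- sweep(outer(ts, axis), 2, tip, "+")
  prof <- plogis((sample_volume(postop, pts) - occ_mid) / occ_width)
  below <- which(prof < 0.5)
  if (length(below) == 0 || below[1] == 1) return(0)
  i <- below[1]
  # linear interpolation between the bracketing samples
  t0 <- ts[i - 1]; t1 <- ts[i]
  p0 <- prof[i - 1]; p1 <- prof[i]
  t0 + (0.5 - p0) / (p1 - p0) * (t1 - t0)
}

orth_basis <- function(a) {
  a <- a / sqrt(sum(a^2))
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(a, h); u <- u / sqrt(sum(u^2))
  list(u = u, v = cross3(a, u))
}

#' Detect and fit all screws in a postoperative volume
#'
#' Convenience wrapper: extracts metal components (minimum size half a
#' screw-shaft volume), orients each, and refines each with the shaft-model
#' fit.
#'
#' @param postop A `ct_volume`.
#' @param plans Plan tibble (nominal radius and length are taken from it).
#' @param metal_threshold Metal intensity threshold.
#' @return List of fitted `detected_screw` objects.
#' @export
detect_screws <- function(postop, plans, metal_threshold) {
  radius <- plans$radius_mm[1]
  length <- plans$length_mm[1]
  min_vol <- 0.5 * pi * radius^2 * length
  comps <- detect_metal_components(postop, metal_threshold, min_vol)
  lapply(comps, function(cmp) {
    init <- init_screw_from_component(cmp, radius, length)
    fit_screw_model(postop, init, radius, length, metal_threshold)
  })
}

#' Match detected screws to planned trajectories
#'
#' One-to-one assignment minimizing the summed tip-to-tip distance after
#' mapping planned tips through a coarse per-level transform (identity for
#' phantoms, or a whole-volume pre-alignment for real data). The assignment
#' is solved exactly over all permutations (screw counts per scene are
#' small). Unmatched plans or detections are reported, never dropped
#' silently; near-ties (two assignments within 1 mm total cost) are flagged.
#'
#' @param detected List of `detected_screw` objects.
#' @param plans Plan tibble.
#' @param coarse_transforms Named list of [rigid_transform()] per level, or a
#'   single transform used for all levels (default identity).
#' @return List with `pairs` (tibble: plan index, detection index, distance,
#'   plus level/side from the plan), `unmatched_plans`, `unmatched_detections`
#'   (integer indices), and `ambiguous` (logical).
#' @export
match_screws_to_plans <- function(detected, plans,
                                  coarse_transforms = rigid_transform()) {
  np <- nrow(plans); nd <- length(detected)
  get_T <- function(level) {
    if (inherits(coarse_transforms, "rigid_transform")) return(coarse_transforms)
    coarse_transforms[[level]]
  }
  if (np == 0 || nd == 0) {
    return(list(pairs = tibble::tibble(plan = integer(), detection = integer(),
                                       distance_mm = numeric()),
                unmatched_plans = seq_len(np),
                unmatched_detections = seq_len(nd), ambiguous = FALSE))
  }
  cost <- matrix(0, np, nd)
  for (i in seq_len(np)) {
    tip_mapped <- apply_transform(get_T(plans$level[i]),
                                  plan_point(plans[i, ], "tip"))
    for (j in seq_len(nd))
      cost[i, j] <- sqrt(sum((tip_mapped - detected[[j]]$tip)^2))
  }
  k <- min(np, nd)
  if (k > 7) {
    # large scenes: greedy globally-closest pairing (screws at different
    # levels are far apart, so this is exact in practice)
    cm <- cost
    plan_idx <- integer(0); det_idx <- integer(0)
    for (s in seq_len(k)) {
      m <- arrayInd(which.min(cm), dim(cm))
      plan_idx <- c(plan_idx, m[1]); det_idx <- c(det_idx, m[2])
      cm[m[1], ] <- Inf; cm[, m[2]] <- Inf
    }
    o <- order(plan_idx)
    plan_idx <- plan_idx[o]; det_idx <- det_idx[o]
    pairs <- tibble::tibble(
      plan = plan_idx, detection = det_idx,
      level = plans$level[plan_idx], side = plans$side[plan_idx],
      distance_mm = cost[cbind(plan_idx, det_idx)])
    return(list(pairs = pairs,
                unmatched_plans = setdiff(seq_len(np), plan_idx),
                unmatched_detections = setdiff(seq_len(nd), det_idx),
                ambiguous = FALSE))
  }
  # exact assignment by permutation enumeration over the smaller side
  if (np <= nd) {
    perms <- permutations_of(seq_len(nd), k)
    costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(k), p)]), 0)
  } else {
    perms <- permutations_of(seq_len(np), k)
    costs <- vapply(perms, function(p) sum(cost[cbind(p, seq_len(k))]), 0)
  }
  best <- which.min(costs)
  ambiguous <- sum(costs <= costs[best] + 1) > 1
  if (np <= nd) {
    plan_idx <- seq_len(k); det_idx <- perms[[best]]
  } else {
    plan_idx <- perms[[best]]; det_idx <- seq_len(k)
  }
  pairs <- tibble::tibble(
    plan = plan_idx, detection = det_idx,
    level = plans$level[plan_idx], side = plans$side[plan_idx],
    distance_mm = cost[cbind(plan_idx, det_idx)])
  pairs <- dplyr::arrange(pairs, .data$plan)
  list(pairs = pairs,
       unmatched_plans = setdiff(seq_len(np), plan_idx),
       unmatched_detections = setdiff(seq_len(nd), det_idx),
       ambiguous = ambiguous)
}

permutations_of <- function(items, k) {
  if (k == 0) return(list(integer()))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1]] <<- chosen
      return(invisible(NULL))
    }
    for (i in seq_along(remaining))
      rec(c(chosen, remaining[i]), remaining[-i])
  }
  rec(integer(), items)
  out
}

#' @export
print.detected_screw <- function(x, ...) {
  cat("<detected_screw>", x$level, x$side, " tip [",
      paste(sprintf("%.2f", x$tip), collapse = ", "), "] tail [",
      paste(sprintf("%.2f", x$tail), collapse = ", "), "] score",
      sprintf("%.1f", x$fit_score), "\n")
  invisible(x)
}

#' Detected screws as a tibble
#' @param x List of `detected_screw` objects.
#' @return Tibble with one row per screw.
#' @export
screws_to_tibble <- function(x) {
  dplyr::bind_rows(lapply(x, function(s) tibble::tibble(
    level = s$level, side = s$side,
    tip_x = s$tip[1], tip_y = s$tip[2], tip_z = s$tip[3],
    tail_x = s$tail[1], tail_y = s$tail[2], tail_z = s$tail[3],
    fit_score = s$fit_score)))
}
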