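#' Least-squares rigid alignment of paired point sets
#'
#' Kabsch/Umeyama alignment: centroid subtraction, SVD of the cross
#' covariance, and determinant correction so the returned rotation is always
#' proper (no reflection, no scaling). Used to initialize each level's
#' registration from planned vs detected screw tip/tail landmarks.
#'
#' @param source n x 3 matrix of source world points (mm).
#' @param target n x 3 matrix of corresponding target points.
#' @return A [rigid_transform()] `T` minimizing `sum ||T(source) - target||^2`,
#'   with attribute `degenerate = TRUE` when the points are collinear (n >= 3)
#'   so rotation about the line is unconstrained.
#' @export
svd_point_align <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target)) stop("point lists must have equal length")
  if (nrow(source) < 2) stop("at least 2 point pairs are required")
  cs <- colMeans(source); ct <- colMeans(target)
  H <- crossprod(sweep(source, 2, cs), sweep(target, 2, ct))
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  out <- rigid_transform(R, ct - as.numeric(R %*% cs))
  # collinearity: second singular value of the centred source ~ 0
  s2 <- svd(sweep(source, 2, cs), nu = 0, nv = 0)$d
  attr(out, "degenerate") <- nrow(source) >= 3 && s2[2] < 1e-6 * max(s2[1], 1)
  out
}

#' Masked mutual information between two CT volumes under a rigid transform
#'
#' Mutual information (nats) of the 2D intensity histogram over voxels that
#' lie inside the fixed (preoperative) vertebra label and map under
#' `transform` to moving (postoperative) voxels below the metal-exclusion
#' threshold. Binning is over the masked intensity ranges with
#' partial-volume (linear) weighting of the moving-side histogram
#' contributions; samples whose interpolation support touches metal,
#' an exclusion region or the field edge are dropped.
#'
#' @param fixed,moving `ct_volume`s (fixed = preop, moving = postop).
#' @param transform A [rigid_transform()] mapping fixed world to moving world.
#' @param fixed_mask A `label_mask` on the fixed geometry.
#' @param label Level name or label value selecting the inclusive mask.
#' @param moving_exclusion_threshold Moving intensities at or above this are
#'   treated as metal and excluded (`Inf` disables).
#' @param n_bins Histogram bins per axis.
#' @param exclusion Optional integer/logical array on the moving grid;
#'   nonzero voxels are excluded (used to mask out fiducial beads).
#' @param fixed_exclude Optional logical vector/array on the fixed grid;
#'   `TRUE` fixed voxels are dropped from the sample set.
#' @return MI in nats, with attributes `n_used`, `h_fixed`, `h_moving`,
#'   `h_joint`.
#' @export
mutual_information <- function(fixed, moving, transform, fixed_mask, label,
                               moving_exclusion_threshold = Inf, n_bins = 32,
                               exclusion = NULL, fixed_exclude = NULL) {
  stopifnot(n_bins >= 2)
  samp <- mi_fixed_samples(fixed, fixed_mask, label, n_bins,
                           fixed_exclude = fixed_exclude)
  mi_eval(samp, moving, transform, moving_exclusion_threshold, n_bins,
          exclusion)
}

# precompute the fixed-side sample set: world points, bin indices.
# With jitter = TRUE each sample is displaced by a deterministic
# quasi-random sub-voxel offset (R3 low-discrepancy sequence) and the fixed
# intensity interpolated there: this breaks the voxel-grid alignment that
# otherwise imprints grid-periodic local optima on the partial-volume MI
# surface, which would trap restarted optimizations in neighbouring
# grid dimples.
mi_fixed_samples <- function(fixed, fixed_mask, label, n_bins, stride = 1,
                             fixed_exclude = NULL, jitter = FALSE) {
  lab <- resolve_label(fixed_mask, label)
  sel <- fixed_mask$labels == lab
  if (!is.null(fixed_exclude)) sel <- sel & !fixed_exclude
  idx <- which_indices(sel, dim(fixed_mask$labels))
  if (nrow(idx) == 0) stop("empty fixed mask for label ", label)
  if (stride > 1) idx <- idx[seq(1, nrow(idx), by = stride), , drop = FALSE]
  if (jitter) {
    i <- seq_len(nrow(idx))
    # R3 sequence: fractional parts of i * (1/phi3^k), phi3 the plastic number
    jit <- cbind(i * 0.8191725133961645, i * 0.6710436067037893,
                 i * 0.5497004779019703)
    jit <- jit - floor(jit) - 0.5
    vox <- idx - 1 + jit
    vals <- cpp_sample_trilinear(fixed$data, dim(fixed$data), vox,
                                 min(fixed$data))
    pts <- voxel_to_world(fixed, vox)
  } else {
    vals <- fixed$data[idx]
    pts <- array_index_to_world(fixed, idx)
  }
  lo <- min(vals); hi <- max(vals)
  bins <- bin_index(vals, lo, hi, n_bins)
  list(pts = pts, bins = bins, values = vals,
       lo = lo, hi = hi, n_bins = n_bins)
}

bin_index <- function(v, lo, hi, n_bins) {
  w <- (hi - lo) / n_bins
  if (w <= 0) return(rep(0L, length(v)))
  as.integer(pmin(pmax(floor((v - lo) / w), 0), n_bins - 1))
}

mi_eval <- function(samp, moving, transform, threshold, n_bins, exclusion,
                    mov_range = NULL, on_empty = c("error", "zero"),
                    mov_bin = NULL) {
  Tm <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  M <- (solve(moving$affine) %*% Tm)[1:3, , drop = FALSE]
  if (is.null(mov_bin))
    mov_bin <- moving_bins(moving, threshold, n_bins, exclusion, mov_range)
  res <- cpp_mi_binned(samp$bins, samp$pts, M, mov_bin, dim(moving$data),
                       samp$n_bins, n_bins)
  if (res$n_used == 0) {
    if (match.arg(on_empty) == "zero")
      return(structure(0, n_used = 0))
    stop("empty overlap after masking")
  }
  structure(res$mi, n_used = res$n_used, h_fixed = res$h_fixed,
            h_moving = res$h_moving, h_joint = res$h_joint)
}

# per-voxel moving-side histogram bin, with -1 marking metal-excluded,
# user-excluded or otherwise invalid voxels; precomputing this makes each
# metric evaluation touch one small integer per interpolation corner
moving_bins <- function(moving, threshold, n_bins, exclusion = NULL,
                        mov_range = NULL) {
  v <- moving$data
  rng <- if (is.null(mov_range)) moving_range(moving, threshold) else mov_range
  b <- bin_index(v, rng[1], rng[2], n_bins)
  b[v >= threshold] <- -1L
  if (!is.null(exclusion)) b[exclusion != 0] <- -1L
  stopifnot(is.integer(b))
  b
}

moving_range <- function(moving, threshold) {
  v <- moving$data
  if (is.finite(threshold)) {
    below <- v[v < threshold]
    if (length(below) == 0) stop("no moving voxels below the exclusion threshold")
    range(below)
  } else range(v)
}

#' Register one vertebral level across scans
#'
#' Per-level rigid alignment of the preoperative to the postoperative scan:
#' the transform is initialized by [svd_point_align()] on the planned vs
#' detected screw tip and tail landmarks of the level, then refined by
#' maximizing masked mutual information over 6 degrees of freedom with a
#' coarse-to-fine Gaussian smoothing pyramid and a quasi-Newton (BFGS)
#' optimizer. The preoperative vertebra label is the inclusive mask; metal
#' is excluded from the postoperative scan by the intensity threshold.
#' Single-screw levels (two landmarks, rotation about the screw axis
#' unconstrained) automatically gain the mask centroid vs metal-component
#' centroid as a third pseudo-landmark pair and carry a degeneracy flag.
#'
#' @param preop,postop `ct_volume`s.
#' @param mask Preoperative `label_mask`.
#' @param level Level name or label value.
#' @param plans Plan tibble (rows for this level are used).
#' @param detections List of `detected_screw` (matched to `plans` rows by
#'   [match_screws_to_plans()] internally, or pass `pairs`).
#' @param metal_threshold Metal exclusion threshold for the moving volume.
#' @param config Optional list overriding registration settings: `n_bins`
#'   (32), `pyramid_sigma_vox` (c(2, 0) voxels), `pyramid_stride` (c(8, 3)),
#'   `maxit` (c(60, 40)), `reltol` (1e-8), and the deterministic stencil
#'   polish stages: a safeguarded quadratic-stencil sweep (`polish_iter`,
#'   `polish_h`, `polish_shrink`), a NEWUOA trust-region finish
#'   (`newuoa_rhobeg`, `newuoa_rhoend`, `newuoa_maxfun`) and a
#'   deterministic rotational basin hop (`hop_rounds`, `hop_deg`).
#' @param exclusion Optional moving-grid exclusion array (e.g. dilated bead
#'   spheres, see [bead_exclusion_mask()]).
#' @param fixed_exclude Optional fixed-grid logical exclusion.
#' @param init Optional [rigid_transform()] overriding the landmark
#'   initialization (used by the perturbation analysis).
#' @param context Optional precomputed registration context (internal; lets
#'   the perturbation analysis reuse the smoothing pyramid across replicates).
#' @return A `registration_result`: list with `level`, `transform`,
#'   `init_transform`, `mi_final` (nats, finest level), `mi_init`,
#'   `converged`, `n_iterations`, `degenerate_init`, `centroid`.
#' @export
register_level <- function(preop, mask, level, postop, plans, detections,
                           metal_threshold, config = list(),
                           exclusion = NULL, fixed_exclude = NULL,
                           init = NULL, context = NULL) {
  cfg <- reg_config(config)
  lab <- resolve_label(mask, level)
  level_name <- if (is.character(level)) level else
    names(mask$level_ids)[match(lab, mask$level_ids)]
  degenerate <- FALSE
  if (is.null(init)) {
    lm <- level_landmarks(plans, detections, level_name, mask, postop,
                          metal_threshold)
    init <- svd_point_align(lm$source, lm$target)
    degenerate <- isTRUE(attr(init, "degenerate")) || lm$single_screw
  }
  centroid <- mask_centroid(mask, lab)
  if (is.null(context))
    context <- mi_context(preop, mask, lab, postop, metal_threshold, cfg,
                          exclusion, fixed_exclude)
  refined <- mi_refine(context, init, cfg, centroid)
  structure(list(level = level_name, transform = refined$transform,
                 init_transform = init, mi_final = refined$mi_final,
                 mi_init = refined$mi_init, converged = refined$converged,
                 n_iterations = refined$n_iterations,
                 degenerate_init = degenerate, centroid = centroid),
            class = "registration_result")
}

reg_config <- function(config) {
  cfg <- list(n_bins = 32, pyramid_sigma_vox = c(2, 0),
              pyramid_stride = c(8, 4), polish_stride = 1,
              maxit = c(40, 30),
              reltol = 1e-8, polish_iter = 6,
              polish_h = c(0.006, 0.25), polish_shrink = 0.55,
              newuoa_rhobeg = 0.5, newuoa_rhoend = 1e-5,
              newuoa_maxfun = 1500, newuoa_restarts = 3,
              max_passes = 2, pass_tol = 5e-4,
              hop_rounds = 1, hop_deg = c(-1, -0.5, 0.5, 1),
              fence_rot = 0.09, fence_mm = 5, fence_weight = 1)
  cfg[names(config)] <- config
  cfg
}

level_landmarks <- function(plans, detections, level_name, mask, postop,
                            metal_threshold) {
  rows <- which(plans$level == level_name)
  if (length(rows) == 0) stop("no plans at level ", level_name)
  det_tb <- screws_to_tibble(detections)
  src <- list(); tgt <- list()
  used <- 0
  for (i in rows) {
    j <- which(det_tb$level == level_name & det_tb$side == plans$side[i])
    if (length(j) != 1) next
    used <- used + 1
    src[[length(src) + 1]] <- rbind(plan_point(plans[i, ], "tip"),
                                    plan_point(plans[i, ], "tail"))
    tgt[[length(tgt) + 1]] <- rbind(detections[[j]]$tip, detections[[j]]$tail)
  }
  if (used == 0) stop("no matched screws at level ", level_name)
  single <- used == 1
  if (single) {
    # third pseudo-landmark: vertebra mask centroid <-> nearest metal
    # component centroid, to pin rotation about the screw axis
    cen_pre <- mask_centroid(mask, level_name)
    comps <- detect_metal_components(postop, metal_threshold)
    if (length(comps) > 0) {
      cents <- t(vapply(comps, function(cmp) cmp$centroid, numeric(3)))
      dists <- sqrt(rowSums(sweep(cents, 2, tgt[[1]][1, ])^2))
      src[[length(src) + 1]] <- matrix(cen_pre, 1)
      tgt[[length(tgt) + 1]] <- cents[which.min(dists), , drop = FALSE]
    }
  }
  list(source = do.call(rbind, src), target = do.call(rbind, tgt),
       single_screw = single)
}

# precomputed per-level registration context: smoothed pyramid volumes,
# fixed-side sample sets and moving intensity ranges, shared across
# optimizer iterations and perturbation replicates
mi_context <- function(preop, mask, lab, postop, threshold, cfg,
                       exclusion, fixed_exclude) {
  if (!is.null(exclusion) && !is.integer(exclusion))
    exclusion <- as.integer(exclusion)
  mean_sp <- mean(preop$spacing)
  levels <- lapply(seq_along(cfg$pyramid_sigma_vox), function(l) {
    sig_mm <- cfg$pyramid_sigma_vox[l] * mean_sp
    f <- smooth_volume(preop, sig_mm)
    m <- smooth_volume(postop, sig_mm)
    list(samp = mi_fixed_samples(f, mask, lab, cfg$n_bins,
                                 stride = cfg$pyramid_stride[l],
                                 fixed_exclude = fixed_exclude,
                                 jitter = TRUE),
         moving = m,
         mov_bin = moving_bins(m, threshold, cfg$n_bins, exclusion))
  })
  list(levels = levels,
       samp_full = mi_fixed_samples(preop, mask, lab, cfg$n_bins,
                                    fixed_exclude = fixed_exclude),
       samp_polish = mi_fixed_samples(preop, mask, lab, cfg$n_bins,
                                      stride = cfg$polish_stride,
                                      fixed_exclude = fixed_exclude,
                                      jitter = TRUE),
       moving_full = postop,
       mov_bin_full = moving_bins(postop, threshold, cfg$n_bins, exclusion),
       threshold = threshold, exclusion = exclusion)
}

# multi-resolution MI refinement; rotation parameterized about the mask
# centroid so rotation and translation are decorrelated
mi_refine <- function(ctx, init, cfg, centroid) {
  par0 <- transform_to_par(init, centroid)
  par <- par0
  total_it <- 0
  conv <- TRUE
  last_val <- -Inf
  # soft trust region about the landmark initialization: the SVD landmark
  # fit is accurate to a few millimetres, so excursions far beyond it are
  # never genuine -- they chase the spuriously high MI of small-overlap
  # configurations -- and are pushed back by a quadratic penalty
  fence <- function(p) {
    dr <- pmax(abs(p[1:3] - par0[1:3]) - cfg$fence_rot, 0)
    dt <- pmax(abs(p[4:6] - par0[4:6]) - cfg$fence_mm, 0)
    cfg$fence_weight * (sum((dr / cfg$fence_rot)^2) +
                          sum((dt / cfg$fence_mm)^2))
  }
  for (pass in seq_len(cfg$max_passes)) {
  for (l in seq_along(ctx$levels)) {
    lev <- ctx$levels[[l]]
    negmi <- function(p) {
      tr <- par_to_transform(p, centroid)
      fence(p) - as.numeric(mi_eval(lev$samp, lev$moving, tr, ctx$threshold,
                                    cfg$n_bins, NULL, on_empty = "zero",
                                    mov_bin = lev$mov_bin))
    }
    f_start <- negmi(par)
    fit <- optim(par, negmi, method = "BFGS",
                 control = list(maxit = cfg$maxit[l], reltol = cfg$reltol,
                                parscale = c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5)))
    total_it <- total_it + fit$counts[1]
    if (!is.finite(fit$value) || fit$value > f_start) {
      # quasi-Newton diverged at this stage (e.g. onto a lost-overlap
      # plateau); redo the stage with the slower but safe simplex search
      fit <- optim(par, negmi, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10,
                                  parscale = c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5)))
      total_it <- total_it + fit$counts[1]
    }
    if (is.finite(fit$value) && fit$value <= f_start) par <- fit$par
  }
  # the BFGS stages run on a deliberately small iteration budget; the
  # stencil polish below always finishes with per-axis movements bounded by
  # its final (sub-tolerance) step size, so convergence is judged by the
  # polished objective never falling below the initialization's
  pol <- stencil_polish(par, ctx, cfg, centroid)
  par <- pol$par
  total_it <- total_it + pol$n_eval
  # final trust-region polish (NEWUOA): its quadratic model tracks the MI
  # surface even along nearly flat rotational ridges, so restarts from
  # perturbed initializations settle onto the same optimum
  sc <- c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5)
  negmi_pol <- function(q) {
    trq <- par_to_transform(q * sc, centroid)
    -as.numeric(mi_eval(ctx$samp_polish, ctx$moving_full, trq, ctx$threshold,
                        cfg$n_bins, NULL, on_empty = "zero",
                        mov_bin = ctx$mov_bin_full))
  }
  val <- pol$value
  for (restart in seq_len(cfg$newuoa_restarts)) {
    # each restart re-expands the trust region; on the nearly flat
    # rotational ridges of the metric a fresh quadratic model walks further
    # than a single shrunken one
    nu <- minqa::newuoa(par / sc, negmi_pol,
                        control = list(rhobeg = cfg$newuoa_rhobeg,
                                       rhoend = cfg$newuoa_rhoend,
                                       maxfun = cfg$newuoa_maxfun))
    total_it <- total_it + nu$feval
    if (is.finite(nu$fval) && -nu$fval >= val) {
      improved <- -nu$fval - val > 1e-6
      par <- nu$par * sc
      val <- -nu$fval
      if (!improved) break
    } else break
  }
  # deterministic rotational basin hop: the MI surface can hold subsidiary
  # optima about a degree away in rotation; probe small rotations about
  # each axis and re-finish from any that genuinely improves the objective
  for (round in seq_len(cfg$hop_rounds)) {
    cand <- NULL; cand_val <- val
    for (ax in 1:3) for (mag in cfg$hop_deg * pi / 180) {
      p2 <- par
      p2[ax] <- p2[ax] + mag
      v2 <- -negmi_pol(p2 / sc)
      total_it <- total_it + 1
      if (v2 > cand_val + 1e-5) { cand_val <- v2; cand <- p2 }
    }
    if (is.null(cand)) break
    nu2 <- minqa::newuoa(cand / sc, negmi_pol,
                         control = list(rhobeg = cfg$newuoa_rhobeg,
                                        rhoend = cfg$newuoa_rhoend,
                                        maxfun = cfg$newuoa_maxfun))
    total_it <- total_it + nu2$feval
    if (is.finite(nu2$fval) && -nu2$fval > val) {
      par <- nu2$par * sc
      val <- -nu2$fval
    } else break
  }
  # a restart of the whole schedule can escape a subsidiary basin the first
  # descent settled into; stop once a pass no longer improves the objective
  if (val - last_val < cfg$pass_tol) break
  last_val <- val
  }
  # final objective at full resolution, and the guarantee that refinement
  # never reports a worse objective than its initialization
  tr <- par_to_transform(par, centroid)
  mi_fin <- as.numeric(mi_eval(ctx$samp_full, ctx$moving_full, tr,
                               ctx$threshold, cfg$n_bins, NULL,
                               mov_bin = ctx$mov_bin_full))
  mi_ini <- as.numeric(mi_eval(ctx$samp_full, ctx$moving_full, init,
                               ctx$threshold, cfg$n_bins, NULL,
                               mov_bin = ctx$mov_bin_full))
  if (mi_fin < mi_ini) {
    # the quasi-Newton stage can diverge from a poor start (e.g. a trial
    # step that loses overlap leaves it on a flat zero-MI plateau); rescue
    # with a derivative-free restart from the initialization
    lev1 <- ctx$levels[[1]]
    negmi1 <- function(p) {
      trp <- par_to_transform(p, centroid)
      fence(p) - as.numeric(mi_eval(lev1$samp, lev1$moving, trp,
                                    ctx$threshold, cfg$n_bins, NULL,
                                    on_empty = "zero",
                                    mov_bin = lev1$mov_bin))
    }
    fit <- optim(transform_to_par(init, centroid), negmi1,
                 method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10,
                                parscale = c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5)))
    pol <- stencil_polish(fit$par, ctx, cfg, centroid)
    total_it <- total_it + fit$counts[1] + pol$n_eval
    tr2 <- par_to_transform(pol$par, centroid)
    mi2 <- as.numeric(mi_eval(ctx$samp_full, ctx$moving_full, tr2,
                              ctx$threshold, cfg$n_bins, NULL,
                              mov_bin = ctx$mov_bin_full))
    if (mi2 >= mi_ini) {
      tr <- tr2
      mi_fin <- mi2
    } else {
      tr <- init
      mi_fin <- mi_ini
      conv <- FALSE
    }
  }
  list(transform = tr, mi_final = mi_fin, mi_init = mi_ini, converged = conv,
       n_iterations = as.integer(total_it))
}

# deterministic quadratic-stencil polish on the finest pyramid level's
# sample set: per parameter axis, sample MI at +/- h, take the (damped)
# 1D quadratic argmin step, shrinking h each sweep. The stencil spacing is
# large relative to the metric's sample-set micro-structure, so restarts
# from different initializations settle onto the same point -- this is what
# makes the perturbation consistency of the registration tight.
stencil_polish <- function(par, ctx, cfg, centroid) {
  f <- function(p) {
    tr <- par_to_transform(p, centroid)
    as.numeric(mi_eval(ctx$samp_polish, ctx$moving_full, tr, ctx$threshold,
                       cfg$n_bins, NULL, on_empty = "zero",
                       mov_bin = ctx$mov_bin_full))
  }
  h <- rep(cfg$polish_h, each = 3)
  n_eval <- 1
  f0 <- f(par)
  for (it in seq_len(cfg$polish_iter)) {
    for (a in 1:6) {
      step <- numeric(6); step[a] <- h[a]
      fp <- f(par + step); fm <- f(par - step)
      denom <- fp - 2 * f0 + fm
      delta <- if (denom < 0) 0.5 * h[a] * (fm - fp) / denom else
        h[a] * sign(fp - fm)
      cand <- par
      cand[a] <- cand[a] + max(min(delta, h[a]), -h[a])
      fc <- f(cand)
      best <- which.max(c(f0, fp, fm, fc))
      if (best == 2) { par[a] <- par[a] + h[a]; f0 <- fp }
      else if (best == 3) { par[a] <- par[a] - h[a]; f0 <- fm }
      else if (best == 4) { par <- cand; f0 <- fc }
      n_eval <- n_eval + 3
    }
    h <- h * cfg$polish_shrink
  }
  list(par = par, n_eval = n_eval, value = f0)
}

transform_to_par <- function(tr, centroid) {
  w <- matrix_to_rotvec(tr$rotation)
  t_c <- as.numeric(tr$rotation %*% centroid) + tr$translation - centroid
  c(w, t_c)
}

par_to_transform <- function(p, centroid) {
  R <- rotvec_to_matrix(p[1:3])
  rigid_transform(R, centroid + p[4:6] - as.numeric(R %*% centroid))
}

#' Moving-grid exclusion mask for fiducial beads
#'
#' Marks a sphere of the bead radius dilated by `dilate_vox` voxels around
#' each bead position, for masking beads out during registration.
#'
#' @param volume The moving `ct_volume`.
#' @param beads n x 3 world bead positions (mm).
#' @param bead_diameter Bead diameter, mm.
#' @param dilate_vox Dilation in voxels (default 2).
#' @return Integer array on `volume`'s grid (1 = excluded).
#' @export
bead_exclusion_mask <- function(volume, beads, bead_diameter = 1,
                                dilate_vox = 2) {
  d <- dim(volume$data)
  out <- array(0L, d)
  if (is.null(dim(beads))) beads <- matrix(beads, ncol = 3)
  if (nrow(beads) == 0) return(out)
  r <- bead_diameter / 2 + dilate_vox * max(volume$spacing)
  for (i in seq_len(nrow(beads))) {
    b <- beads[i, ]
    vlo <- pmax(floor(world_to_voxel(volume, b - r)) + 1, 1)
    vhi <- pmin(ceiling(world_to_voxel(volume, b + r)) + 1, d)
    rng <- lapply(1:3, function(a) vlo[a]:vhi[a])
    idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    w <- array_index_to_world(volume, idx)
    hit <- rowSums(sweep(w, 2, b)^2) <= r^2
    out[idx[hit, , drop = FALSE]] <- 1L
  }
  out
}

#' Fixed-grid logical exclusion for fiducial beads
#' @inheritParams bead_exclusion_mask
#' @return Logical array on `volume`'s grid (`TRUE` = excluded).
#' @export
bead_exclusion_logical <- function(volume, beads, bead_diameter = 1,
                                   dilate_vox = 2) {
  bead_exclusion_mask(volume, beads, bead_diameter, dilate_vox) > 0
}

#' Registration convergence-basin (perturbation) analysis
#'
#' Re-runs the refinement from randomly perturbed initializations and
#' compares each result to the unperturbed baseline: each replicate composes
#' a rotation of exactly `rot_deg` about a uniformly random axis through the
#' vertebra centroid and a translation of exactly `trans_mm` in a uniformly
#' random direction with the baseline initialization, refines from there,
#' and reports the translation (at the vertebra centroid) and rotation
#' discrepancy versus the baseline transform.
#'
#' @param preop,mask,postop,plans,detections,metal_threshold,config,exclusion,fixed_exclude
#'   As in [register_level()].
#' @param baseline A converged `registration_result` for the level.
#' @param n Number of perturbation replicates.
#' @param rot_deg,trans_mm Perturbation magnitudes (degrees, mm).
#' @param seed Integer seed for the random perturbations.
#' @return A `perturbation_report`: list with `level`, `n_perturbations`,
#'   `rot_magnitude_deg`, `trans_magnitude_mm`, `replicates` (tibble:
#'   translation/rotation discrepancy and convergence per replicate), and
#'   means/SDs.
#' @export
perturbation_analysis <- function(preop, mask, postop, plans, detections,
                                  metal_threshold, baseline, n = 10,
                                  rot_deg = 2, trans_mm = 2, seed = 1,
                                  config = list(), exclusion = NULL,
                                  fixed_exclude = NULL) {
  if (!isTRUE(baseline$converged)) stop("baseline registration did not converge")
  cfg <- reg_config(config)
  lab <- resolve_label(mask, baseline$level)
  ctx <- mi_context(preop, mask, lab, postop, metal_threshold, cfg,
                    exclusion, fixed_exclude)
  set.seed(seed)
  reps <- list()
  for (r in seq_len(n)) {
    pert <- random_rigid_transform(rot_deg, trans_mm,
                                   center = baseline$centroid)
    init_r <- compose_transform(pert, baseline$init_transform)
    res <- tryCatch(
      register_level(preop, mask, baseline$level, postop, plans, detections,
                     metal_threshold, config = config, exclusion = exclusion,
                     fixed_exclude = fixed_exclude, init = init_r,
                     context = ctx),
      error = function(e) NULL)
    if (is.null(res)) {
      reps[[r]] <- tibble::tibble(replicate = r, translation_mm = NA_real_,
                                  rotation_deg = NA_real_, converged = FALSE)
    } else {
      d <- transform_discrepancy(res$transform, baseline$transform,
                                 baseline$centroid)
      reps[[r]] <- tibble::tibble(replicate = r,
                                  translation_mm = d[["translation_mm"]],
                                  rotation_deg = d[["rotation_deg"]],
                                  converged = res$converged)
    }
  }
  reps <- if (n > 0) dplyr::bind_rows(reps) else
    tibble::tibble(replicate = integer(), translation_mm = numeric(),
                   rotation_deg = numeric(), converged = logical())
  structure(list(
    level = baseline$level, n_perturbations = n,
    rot_magnitude_deg = rot_deg, trans_magnitude_mm = trans_mm,
    replicates = reps,
    mean_translation_mm = mean(reps$translation_mm, na.rm = TRUE),
    sd_translation_mm = sd(reps$translation_mm, na.rm = TRUE),
    mean_rotation_deg = mean(reps$rotation_deg, na.rm = TRUE),
    sd_rotation_deg = sd(reps$rotation_deg, na.rm = TRUE)
  ), class = "perturbation_report")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>", x$level,
      sprintf("MI %.4f (init %.4f), %s, %d iterations\n", x$mi_final,
              x$mi_init, if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(x$transform)
  invisible(x)
}

#' @export
tidy.registration_result <- function(x, ...) {
  dplyr::mutate(tidy(x$transform), level = x$level, .before = 1)
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(level = x$level, mi_final = x$mi_final, mi_init = x$mi_init,
                 converged = x$converged, n_iterations = x$n_iterations,
                 degenerate_init = x$degenerate_init)
}

#' @export
tidy.perturbation_report <- function(x, ...) x$replicates

#' @export
glance.perturbation_report <- function(x, ...) {
  tibble::tibble(level = x$level, n_perturbations = x$n_perturbations,
                 rot_magnitude_deg = x$rot_magnitude_deg,
                 trans_magnitude_mm = x$trans_magnitude_mm,
                 mean_translation_mm = x$mean_translation_mm,
                 sd_translation_mm = x$sd_translation_mm,
                 mean_rotation_deg = x$mean_rotation_deg,
                 sd_rotation_deg = x$sd_rotation_deg)
}
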