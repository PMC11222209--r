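#' Screw-aligned anatomical reference frame
#'
#' Accuracy is reported in a frame anchored to each planned trajectory:
#' the AP (anterior-posterior) axis lies along the planned shaft (tail to
#' tip), the SI (superior-inferior) axis is the component of the inferior
#' endplate normal perpendicular to AP, and the ML (medial-lateral) axis
#' completes the frame with its positive direction pointing medially (toward
#' the sagittal midplane) for the plan's side. Mirroring right-sided screws
#' into the same medial-positive convention lets both sides pool directly.
#'
#' Sign conventions: ML medial(+)/lateral(-), AP anterior(+)/posterior(-),
#' SI superior(+)/inferior(-).
#'
#' @param plan A single screw plan (one row of a plan tibble, or a list) with
#'   fields `tip_x..z`, `tail_x..z`, `side` ("L" or "R").
#' @param endplate An endplate plane from [fit_endplate_plane()] (fields
#'   `point`, `normal`).
#' @param midline_x World x coordinate of the sagittal midplane (default 0).
#' @return A `screw_frame`: list with `origin` (planned tail), unit vectors
#'   `e_ML`, `e_AP`, `e_SI`, and `side`.
#' @export
build_screw_frame <- function(plan, endplate, midline_x = 0) {
  tip <- plan_point(plan, "tip")
  tail <- plan_point(plan, "tail")
  e_AP <- tip - tail
  e_AP <- e_AP / sqrt(sum(e_AP^2))
  n <- endplate$normal / sqrt(sum(endplate$normal^2))
  si <- n - sum(n * e_AP) * e_AP
  nsi <- sqrt(sum(si^2))
  if (nsi < sin(5 * pi / 180))
    stop("degenerate frame: endplate normal within 5 degrees of the planned shaft")
  e_SI <- si / nsi
  e_ML <- cross3(e_SI, e_AP)
  medial <- if (identical(plan$side, "R")) c(-1, 0, 0) else c(1, 0, 0)
  if (sum(e_ML * medial) < 0) e_ML <- -e_ML
  structure(list(origin = tail, e_ML = e_ML, e_AP = e_AP, e_SI = e_SI,
                 side = plan$side),
            class = "screw_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

plan_point <- function(plan, which) {
  as.numeric(c(plan[[paste0(which, "_x")]], plan[[paste0(which, "_y")]],
               plan[[paste0(which, "_z")]]))
}

#' Fit a plane to the inferior vertebral endplate
#'
#' Selects exterior surface voxels of the level's label whose estimated
#' outward direction is within 45 degrees of inferior, that lie in the
#' inferior 30% of the label's superior-inferior extent, and that sit in the
#' anterior half of the label (so posterior-element under-surfaces do not
#' contaminate the fit), then fits a total-least-squares plane through their
#' world coordinates. The normal is oriented superiorly.
#'
#' @param mask A `label_mask`.
#' @param level Level name or label value.
#' @param body_axis_hint Approximate superior direction in world coordinates
#'   (unit vector; default +z).
#' @param anterior_hint Approximate anterior direction (default +y).
#' @return An `endplate_plane`: list with `point` (on-plane world point) and
#'   `normal` (unit, superior-oriented).
#' @export
fit_endplate_plane <- function(mask, level, body_axis_hint = c(0, 0, 1),
                               anterior_hint = c(0, 1, 0)) {
  lab <- resolve_label(mask, level)
  sv <- surface_voxels(mask, lab)
  if (nrow(sv$idx) == 0) stop("insufficient endplate surface (no surface voxels)")
  hint <- body_axis_hint / sqrt(sum(body_axis_hint^2))
  # outward direction within 45 degrees of inferior (-hint)
  ow <- sv$outward / pmax(sqrt(rowSums(sv$outward^2)), 1e-12)
  keep <- (ow %*% (-hint)) > cos(45 * pi / 180)
  pts <- sv$world[keep, , drop = FALSE]
  if (nrow(pts) >= 1) {
    # inferior 30% of the label's SI extent
    s_all <- sv$world %*% hint
    s <- pts %*% hint
    lo <- min(s_all)
    keep2 <- s <= lo + 0.3 * (max(s_all) - lo)
    pts <- pts[keep2, , drop = FALSE]
  }
  if (nrow(pts) >= 1) {
    a <- pts %*% anterior_hint
    ctr_a <- mean(sv$world %*% anterior_hint)
    pts <- pts[a >= ctr_a, , drop = FALSE]
  }
  if (nrow(pts) < 20) stop("insufficient endplate surface (", nrow(pts),
                           " candidate voxels)")
  # surface voxels sit half a voxel inside the physical surface; shift the
  # candidates to the half-voxel crossing along the inferior direction
  half_step <- 0.5 * max(abs(as.numeric(hint %*% mask$affine[1:3, 1:3])))
  pts <- sweep(pts, 2, hint * half_step)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  if (sum(normal * hint) < 0) normal <- -normal
  structure(list(point = ctr, normal = normal), class = "endplate_plane")
}

# surface voxels of a label (6-connectivity), with crude outward direction
# estimated from which face neighbours are background; returns 1-based array
# indices, world coords and outward vectors (world space)
surface_voxels <- function(mask, lab) {
  L <- mask$labels == lab
  d <- dim(L)
  pad <- function(shift_axis, shift) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    n <- d[shift_axis]
    if (shift == 1) { dst[[shift_axis]] <- 2:n; src[[shift_axis]] <- 1:(n - 1) }
    else { dst[[shift_axis]] <- 1:(n - 1); src[[shift_axis]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- L[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb_bg <- list()
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  any_bg <- array(FALSE, d)
  for (m in 1:6) {
    ax <- which(dirs[m, ] != 0)
    sh <- dirs[m, ax]
    # neighbour in +dir is background <=> shifted-by--dir copy of L is FALSE
    nb <- !pad(ax, -sh)
    nb_bg[[m]] <- nb & L
    any_bg <- any_bg | nb_bg[[m]]
  }
  surf <- any_bg & L
  idx <- which_indices(surf, d)
  if (nrow(idx) == 0)
    return(list(idx = idx, world = matrix(0, 0, 3), outward = matrix(0, 0, 3)))
  Alin <- mask$affine[1:3, 1:3]
  outward <- matrix(0, nrow(idx), 3)
  lin <- (idx[, 1]) + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
  for (m in 1:6) {
    hit <- nb_bg[[m]][lin]
    if (any(hit)) {
      wdir <- as.numeric(Alin %*% dirs[m, ])
      wdir <- wdir / sqrt(sum(wdir^2))
      outward[hit, ] <- outward[hit, , drop = FALSE] +
        matrix(wdir, sum(hit), 3, byrow = TRUE)
    }
  }
  list(idx = idx, world = array_index_to_world(mask, idx), outward = outward)
}

#' Locate the mid-pedicle point of a planned trajectory
#'
#' The mid-pedicle point is the point along the planned trajectory where the
#' screw comes closest to (or maximally breaches) the medial pedicle wall --
#' the clinically critical proximity to the spinal canal. The medial wall is
#' represented by canal-facing boundary voxels of the level's label (surface
#' crossings at half-voxel offsets); the planned axis is sampled at `step` mm
#' arc increments and the signed distance to the wall evaluated at each
#' sample, negative when the sample lies outside the label (breach). Ties are
#' broken toward the smaller arc length from the tail.
#'
#' @param plan A single screw plan row (see [build_screw_frame()]).
#' @param mask A `label_mask`.
#' @param level Level name or label value (defaults to `plan$level`).
#' @param step Arc sampling step, mm.
#' @param wall_capture_mm Wall voxels farther than this from the planned axis
#'   are ignored (restricts the wall to the pedicle's extent).
#' @return A `mid_pedicle_locus`: list with `point` (world, on the planned
#'   axis), `arc_param` (mm from tail), `wall_distance` (signed mm, negative
#'   = breach), `side`, `level`.
#' @export
locate_mid_pedicle <- function(plan, mask, level = plan$level, step = 0.1,
                               wall_capture_mm = 8) {
  lab <- resolve_label(mask, level)
  tail <- plan_point(plan, "tail")
  tip <- plan_point(plan, "tip")
  len <- sqrt(sum((tip - tail)^2))
  axis <- (tip - tail) / len
  wall <- medial_wall_points(mask, lab, plan$side)
  if (nrow(wall) == 0) stop("no medial pedicle wall found for level ", level)
  # restrict wall to the pedicle's extent around the planned axis
  rel <- sweep(wall, 2, tail)
  t_ax <- rel %*% axis
  perp <- rel - t_ax %*% t(axis)
  keep <- sqrt(rowSums(perp^2)) <= wall_capture_mm & t_ax >= 0 & t_ax <= len
  wall <- wall[keep, , drop = FALSE]
  if (nrow(wall) == 0) stop("planned trajectory does not pass the pedicle wall at level ", level)
  ts <- seq(0, len, by = step)
  samples <- outer(ts, axis) + matrix(tail, length(ts), 3, byrow = TRUE)
  # unsigned distance to the wall point set
  d2 <- outer(rowSums(samples^2), rowSums(wall^2), "+") -
    2 * samples %*% t(wall)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  inside <- sample_label_nn(mask, samples) == lab
  if (!any(inside)) stop("planned trajectory entirely outside label ", level)
  signed <- ifelse(inside, dmin, -dmin)
  i <- which.min(signed)  # which.min returns the first (smallest arc) tie
  structure(list(point = samples[i, ], arc_param = ts[i],
                 wall_distance = signed[i], side = plan$side, level = plan$level),
            class = "mid_pedicle_locus")
}

# canal-facing (medial) wall surface points: label voxels whose medial
# x-neighbour is background, refined to the half-voxel surface crossing
medial_wall_points <- function(mask, lab, side) {
  L <- mask$labels == lab
  d <- dim(L)
  idx <- which_indices(L, d)
  w <- array_index_to_world(mask, idx)
  # medial = toward decreasing |x|: for a left-side (x<0) screw the canal is
  # at larger x, for right-side at smaller x
  step_ijk <- if (identical(side, "R")) -1L else 1L
  # which voxel axis moves world x: the axis with the largest |x| direction
  ax <- which.max(abs(mask$affine[1, 1:3]))
  sgn <- sign(mask$affine[1, ax])
  di <- as.integer(step_ijk * sgn)
  nb <- idx
  nb[, ax] <- nb[, ax] + di
  ok <- nb[, ax] >= 1 & nb[, ax] <= d[ax]
  lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
  bg <- ok & !L[lin]
  if (!any(bg)) return(matrix(0, 0, 3))
  pts <- w[bg, , drop = FALSE]
  off <- numeric(3)
  off[ax] <- di / 2
  shift <- as.numeric(mask$affine[1:3, 1:3] %*% off)
  sweep(pts, 2, -shift)
}

# nearest-neighbour label lookup at world points
sample_label_nn <- function(mask, world) {
  vox <- round(world_to_voxel(mask, world)) + 1
  d <- dim(mask$labels)
  out <- integer(nrow(vox))
  ok <- vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
    vox[, 1] <= d[1] & vox[, 2] <= d[2] & vox[, 3] <= d[3]
  lin <- vox[ok, 1] + d[1] * (vox[ok, 2] - 1) + d[1] * d[2] * (vox[ok, 3] - 1)
  out[ok] <- mask$labels[lin]
  out
}
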