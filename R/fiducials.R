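#' Detect spherical fiducial beads in a CT volume
#'
#' Finds supra-threshold connected components whose volume is within +/-50%
#' of a sphere of the expected diameter and which are disjoint from the
#' (much larger) screw components, and reduces each to its
#' intensity-weighted centroid. Beads overlapping a screw component merge
#' into it and are therefore excluded, mirroring manual practice of
#' discarding beads obscured by screws.
#'
#' @param volume A `ct_volume`.
#' @param threshold Detection threshold, above the bone plateau.
#' @param expected_diameter Bead diameter, mm.
#' @param exclusion Optional list of screw components
#'   ([detect_metal_components()]); their voxels are removed before bead
#'   labeling, and candidate beads closer than `exclusion_margin_mm` to any
#'   screw voxel are dropped (blurred screw rims can shed bead-sized
#'   fragments).
#' @param exclusion_margin_mm Minimum clearance from screw components, mm.
#' @param min_prominence Optional minimum excess of the candidate's peak
#'   intensity over its local background ring; rejects blur ridges at
#'   concave bone corners that can mimic bead-sized blobs (a sensible value
#'   is ~25% of the bone-to-metal contrast).
#' @return n x 3 matrix of bead centroids (world mm); zero rows if none.
#' @export
detect_beads <- function(volume, threshold, expected_diameter = 1,
                         exclusion = NULL, exclusion_margin_mm = 2,
                         min_prominence = NULL) {
  supra <- volume$data >= threshold
  if (!is.null(exclusion))
    for (cmp in exclusion) supra[cmp$idx] <- FALSE
  if (!any(supra)) return(matrix(0, 0, 3))
  labs <- cpp_label_components26(supra, dim(volume$data))
  tab <- tabulate(labs[labs > 0])
  voxvol <- prod(volume$spacing)
  target <- 4 / 3 * pi * (expected_diameter / 2)^3
  # a supra-threshold bead blob may be smaller than the nominal sphere
  # (partial volume eats the rim) or a little larger (blur spreads it);
  # accept a window of half to 1.5x the sphere plus a few voxels of slack
  # at 0.6 mm slices a 1 mm bead can alias to a single supra-threshold
  # voxel, while a favourably placed one spreads over 2-3 slices after
  # blur; accept from one voxel up to a few times the nominal sphere
  keep <- which(tab * voxvol >= voxvol &
                  tab * voxvol <= 3 * target + 6 * voxvol)
  if (length(keep) == 0) return(matrix(0, 0, 3))
  res <- lapply(keep, function(k) {
    idx <- which_indices(labs == k, dim(volume$data))
    peak <- idx[which.max(volume$data[idx]), ]
    bead_centroid(volume, peak, expected_diameter,
                  peak_value = max(volume$data[idx]))
  })
  if (!is.null(min_prominence))
    res <- Filter(function(r) r$prominence >= min_prominence, res)
  if (length(res) == 0) return(matrix(0, 0, 3))
  cents <- do.call(rbind, lapply(res, function(r) r$centroid))
  if (!is.null(exclusion) && length(exclusion) > 0) {
    clear <- vapply(seq_len(nrow(cents)), function(i) {
      min(vapply(exclusion, function(cmp) {
        min(sqrt(rowSums(sweep(cmp$world, 2, cents[i, ])^2)))
      }, 0))
    }, 0)
    cents <- cents[clear >= exclusion_margin_mm, , drop = FALSE]
  }
  if (nrow(cents) == 0) return(cents)
  cents[order(cents[, 3], cents[, 2], cents[, 1]), , drop = FALSE]
}

# sub-voxel bead centroid: background-subtracted intensity weighting over a
# small neighbourhood of the peak voxel, so partial-volume intensities in
# adjacent slices recover the bead's position between slices
bead_centroid <- function(volume, peak_idx, expected_diameter,
                          peak_value = NULL) {
  d <- dim(volume$data)
  core_r <- expected_diameter / 2 + 1.1   # weighting sphere, mm
  ring_r <- core_r + 1.0                  # background-estimation ring, mm
  half <- ceiling(ring_r / volume$spacing)
  rng <- lapply(1:3, function(a)
    max(1, peak_idx[a] - half[a]):min(d[a], peak_idx[a] + half[a]))
  idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  v <- volume$data[idx]
  w <- array_index_to_world(volume, idx)
  ctr <- array_index_to_world(volume, matrix(peak_idx, 1))
  r <- sqrt(rowSums(sweep(w, 2, as.numeric(ctr))^2))
  bg <- stats::median(v[r > core_r & r <= ring_r])
  core <- r <= core_r
  wt <- pmax(v[core] - bg, 0)
  list(centroid = colSums(w[core, , drop = FALSE] * wt) / sum(wt),
       prominence = (if (is.null(peak_value)) max(v[core]) else peak_value) - bg)
}

#' Partial-volume-aware bead detection threshold
#'
#' A 1 mm bead blurred by the scanner point-spread function never reaches
#' the full metal plateau: the central attenuation is roughly the Gaussian
#' kernel mass inside the bead. This helper places the detection threshold
#' at 30% of the background-to-metal contrast: below the attenuated peak of
#' even an unfavourably voxel-aligned bead, while bulk bone that also
#' exceeds it is rejected by the component size window.
#'
#' @param background Background plateau intensity (e.g. trabecular bone).
#' @param metal Metal plateau intensity.
#' @return Threshold intensity.
#' @export
bead_detection_threshold <- function(background, metal) {
  background + 0.3 * (metal - background)
}

#' Build a matched fiducial set from pre/post bead lists
#'
#' Pairs beads by nearest neighbour after mapping the preoperative beads
#' through a coarse transform (identity by default); unpaired beads are
#' marked unusable. Manual bead coordinates (the original protocol) can be
#' supplied directly as matrices.
#'
#' @param beads_pre,beads_post n x 3 world coordinates (mm).
#' @param coarse_transform Optional [rigid_transform()] for pairing only.
#' @param max_pair_mm Pairs farther apart than this are unusable.
#' @return A `fiducial_set`: list with `pre`, `post` (matched n x 3) and
#'   `usable` (logical).
#' @export
fiducial_set <- function(beads_pre, beads_post,
                         coarse_transform = rigid_transform(),
                         max_pair_mm = 15) {
  pre <- as.matrix(beads_pre); post <- as.matrix(beads_post)
  if (nrow(pre) == 0)
    return(structure(list(pre = pre, post = post[0, , drop = FALSE],
                          usable = logical(0)), class = "fiducial_set"))
  mapped <- apply_transform(coarse_transform, pre)
  used_post <- rep(FALSE, nrow(post))
  match_idx <- rep(NA_integer_, nrow(pre))
  for (i in seq_len(nrow(pre))) {
    if (nrow(post) == 0) break
    d <- sqrt(rowSums(sweep(post, 2, mapped[i, ])^2))
    d[used_post] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= max_pair_mm) {
      match_idx[i] <- j
      used_post[j] <- TRUE
    }
  }
  usable <- !is.na(match_idx)
  post_m <- matrix(NA_real_, nrow(pre), 3)
  post_m[usable, ] <- post[match_idx[usable], , drop = FALSE]
  structure(list(pre = pre, post = post_m, usable = usable),
            class = "fiducial_set")
}

#' Fiducial registration error
#'
#' Per-bead error `||T(pre_i) - post_i||` over usable beads, with the mean
#' absolute error and sample standard deviation -- the bead-based measure of
#' registration accuracy (beads having been masked out of the registration
#' itself).
#'
#' @param beads A `fiducial_set`.
#' @param transform The level (or scene) [rigid_transform()], preop to
#'   postop world.
#' @return List with `per_bead` (tibble: bead, error_mm, usable), `mae_mm`,
#'   `sd_mm`, `n_usable`.
#' @export
fiducial_registration_error <- function(beads, transform) {
  if (sum(beads$usable) == 0) stop("no usable fiducial beads")
  mapped <- apply_transform(transform, beads$pre)
  err <- sqrt(rowSums((mapped - beads$post)^2))
  err[!beads$usable] <- NA_real_
  ok <- err[beads$usable]
  list(per_bead = tibble::tibble(bead = seq_along(err), error_mm = err,
                                 usable = beads$usable),
       mae_mm = mean(ok),
       sd_mm = if (length(ok) >= 2) sd(ok) else NA_real_,
       n_usable = length(ok))
}
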