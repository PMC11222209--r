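#' CT volumes and label masks
#'
#' A `ct_volume` is a 3D scalar grid (HU-like units) together with a 4x4
#' affine mapping 0-based voxel indices to world millimetres (RAS: +x right,
#' +y anterior, +z superior, the radiographic convention). A `label_mask` is
#' an integer grid on the identical geometry whose nonzero labels name
#' vertebral levels (label 0 is background).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @return `ct_volume()` returns a `ct_volume`; `label_mask()` a `label_mask`.
#' @export
ct_volume <- function(data, affine) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, affine = unname(affine), spacing = spacing),
            class = "ct_volume")
}

#' @param labels 3D integer array (0 = background).
#' @param level_ids Named integer vector mapping level names (e.g. "T7") to
#'   label values; defaults to `L<k>` names for the labels present.
#' @rdname ct_volume
#' @export
label_mask <- function(labels, affine, level_ids = NULL) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3)
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  if (is.null(level_ids)) {
    level_ids <- stats::setNames(present, paste0("V", present))
  }
  if (!all(level_ids %in% present))
    stop("every level_id must appear in the label grid")
  v <- ct_volume(labels, affine)
  structure(list(labels = labels, affine = v$affine, spacing = v$spacing,
                 level_ids = level_ids),
            class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume>", paste(dim(x$data), collapse = " x "), "voxels, spacing",
      paste(sprintf("%.3f", x$spacing), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask>", paste(dim(x$labels), collapse = " x "), "voxels, levels:",
      paste(names(x$level_ids), collapse = ", "), "\n")
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based (the NIfTI convention); world coordinates are in
#' millimetres.
#'
#' @param volume A `ct_volume` or `label_mask`.
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (or vice versa).
#' @export
voxel_to_world <- function(volume, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, 1)
  p <- cbind(as.matrix(idx), 1) %*% t(volume$affine[1:3, , drop = FALSE])
  unname(p)
}

#' @param world n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, world) {
  if (is.null(dim(world))) world <- matrix(world, 1)
  inv <- solve(volume$affine)
  p <- cbind(as.matrix(world), 1) %*% t(inv[1:3, , drop = FALSE])
  unname(p)
}

# world coordinates of every voxel with array index in `which_idx`
# (n x 3, 1-based R indices)
array_index_to_world <- function(volume, which_idx) {
  voxel_to_world(volume, which_idx - 1)
}

# n x 3 matrix of 1-based array indices for a logical array condition
which_indices <- function(cond, dims) {
  w <- which(cond)
  arrayInd(w, dims)
}

#' Sample a volume at world points by trilinear interpolation
#'
#' @param volume A `ct_volume`.
#' @param world n x 3 world points (mm).
#' @param background Fill value outside the field of view (default: the
#'   volume minimum, i.e. air).
#' @return Numeric vector of interpolated intensities.
#' @export
sample_volume <- function(volume, world, background = min(volume$data)) {
  vox <- world_to_voxel(volume, world)
  cpp_sample_trilinear(volume$data, dim(volume$data), vox, background)
}

#' Resample a volume under a rigid transform onto a target geometry
#'
#' The output grid is `target`'s geometry; output voxel `i` takes the value of
#' `volume` at `inverse(transform)` applied to `target`'s world position of
#' `i`. In other words the content of `volume` is moved by `transform` and
#' sampled on `target`. Intensities use trilinear interpolation; label masks
#' use nearest-neighbour so labels never blend. Out-of-field voxels are filled
#' with `background` (default: the input volume's minimum, i.e. air).
#'
#' @param volume A `ct_volume` or `label_mask`.
#' @param transform A [rigid_transform()] (identity by default).
#' @param target A `ct_volume`/`label_mask` supplying the output geometry
#'   (default: `volume` itself).
#' @param background Fill value for out-of-field voxels.
#' @return An object of the same class as `volume` on `target`'s geometry.
#' @export
resample <- function(volume, transform = rigid_transform(), target = volume,
                     background = NULL) {
  is_mask <- inherits(volume, "label_mask")
  src <- if (is_mask) volume$labels else volume$data
  if (is.null(background)) background <- if (is_mask) 0 else min(src)
  # output voxel -> world -> inverse transform -> input voxel
  Tinv <- invert_transform(transform)
  Tm <- rbind(cbind(Tinv$rotation, Tinv$translation), c(0, 0, 0, 1))
  A <- solve(volume$affine) %*% Tm %*% target$affine
  dim_in <- dim(src)
  dim_out <- if (is_mask(target)) dim(target$labels) else dim(target$data)
  out <- cpp_resample_affine(src, dim_in, dim_out, A[1:3, , drop = FALSE],
                             background, is_mask)
  if (is_mask) {
    label_mask(array(as.integer(round(out)), dim_out), target$affine,
               volume$level_ids[volume$level_ids %in% out])
  } else {
    ct_volume(out, target$affine)
  }
}

is_mask <- function(x) inherits(x, "label_mask")

#' Centroid of a labelled region
#'
#' Intensity-unweighted mean of the world coordinates of all voxels carrying
#' `label`.
#'
#' @param mask A `label_mask`.
#' @param label Integer label value or level name.
#' @return World point (length-3 numeric, mm).
#' @export
mask_centroid <- function(mask, label) {
  lab <- resolve_label(mask, label)
  idx <- which_indices(mask$labels == lab, dim(mask$labels))
  if (nrow(idx) == 0) stop("label ", label, " absent from mask")
  colMeans(array_index_to_world(mask, idx))
}

resolve_label <- function(mask, label) {
  if (is.character(label)) {
    if (!label %in% names(mask$level_ids))
      stop("level '", label, "' not present in mask")
    return(unname(mask$level_ids[label]))
  }
  as.integer(label)
}

#' Gaussian smoothing of a CT volume
#'
#' Separable Gaussian blur with `sigma_mm` standard deviation in millimetres
#' (converted per-axis to voxels), truncated at 3 sigma.
#'
#' @param volume A `ct_volume`.
#' @param sigma_mm Scalar smoothing SD in mm (0 returns the input).
#' @return A smoothed `ct_volume`.
#' @export
smooth_volume <- function(volume, sigma_mm) {
  if (sigma_mm <= 0) return(volume)
  out <- cpp_gauss_blur3d(volume$data, dim(volume$data),
                          sigma_mm / volume$spacing)
  ct_volume(out, volume$affine)
}

#' Read and write volumes as NIfTI-1
#'
#' The NIfTI sform/qform affine is honoured as the voxel-to-world map; no
#' assumption is made about axis order.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_ct_volume()` returns a `ct_volume`; `read_label_mask()` a
#'   `label_mask`.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unname(structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                          class = NULL))
  aff <- matrix(as.numeric(aff[1:3, 1:4]), 3, 4)
  ct_volume(array(as.numeric(img), dim(img)[1:3]), rbind(aff, c(0, 0, 0, 1)))
}

#' @param level_ids Optional named label map for the mask (see [label_mask()]).
#' @rdname read_ct_volume
#' @export
read_label_mask <- function(path, level_ids = NULL) {
  v <- read_ct_volume(path)
  label_mask(array(as.integer(round(v$data)), dim(v$data)), v$affine, level_ids)
}

#' @param volume A `ct_volume` or `label_mask` to write.
#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(volume, path) {
  src <- if (is_mask(volume)) volume$labels else volume$data
  img <- RNifti::asNifti(src)
  RNifti::pixdim(img) <- volume$spacing
  aff <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}
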