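#' Specification of a digital instrumented-spine CT phantom
#'
#' The phantom emulates the acquisition this pipeline is designed for:
#' helical-CT-like anisotropic voxels (default 0.5 x 0.5 mm in-plane, 0.625 mm
#' slice spacing), five intensity plateaus (air, soft tissue, trabecular bone,
#' cortical bone, metal), 4.5 mm diameter screws of known length with a short
#' wider tulip head, optional 1 mm high-intensity spherical beads, per-level
#' rigid inter-scan motion, Gaussian partial-volume blur and additive Gaussian
#' noise.
#'
#' Each level is a simplified vertebra: an elliptic-cylinder body with flat
#' endplates (known inferior endplate normal), two pedicle tubes flanking a
#' canal, and a posterior lamina slab; a cortical shell lines every bone
#' surface. Bilateral screw trajectories run through the pedicle centres with
#' a medial convergence angle, entering at the posterior lamina surface.
#'
#' @param n_levels Number of vertebral levels.
#' @param spacing Voxel spacing, mm (x, y, z).
#' @param margin Air/soft-tissue padding around the anatomy, mm per axis;
#'   sized so default inter-scan motions stay in the field.
#' @param level_pitch Superior-inferior distance between level centres, mm.
#' @param level_names Level names (default consecutive from `start_level`).
#' @param start_level First level name, e.g. "T7".
#' @param intensities Named plateau intensities (HU-like): air, soft_tissue,
#'   trabecular, cortical, metal; must be strictly increasing in that order.
#' @param body_halfwidth,body_halfdepth,body_height Vertebral body elliptic
#'   cylinder semi-axes (ML, AP) and SI height, mm.
#' @param cortical_thickness Cortical shell thickness, mm.
#' @param pedicle_radius,pedicle_offset Pedicle tube radius and ML offset of
#'   each pedicle axis from the midline, mm.
#' @param canal_depth AP extent of the canal (= pedicle tube length), mm.
#' @param pedicle_overlap Anterior extension of the pedicle tube into the
#'   body, mm, so the pedicle-body junction is solid bone.
#' @param lamina_thickness,lamina_halfwidth,lamina_halfheight Posterior
#'   element slab dimensions, mm.
#' @param screw_radius,screw_length Screw shaft radius and length, mm
#'   (default 4.5 mm diameter).
#' @param screw_medial_angle_deg Medial convergence of the planned
#'   trajectories, degrees.
#' @param tulip_radius,tulip_length Poly-axial head capsule dimensions, mm.
#' @param n_beads Beads per level (0 or 4).
#' @param bead_diameter Bead diameter, mm.
#' @param texture_sd SD of the trabecular texture field, HU. Trabecular
#'   bone is spatially heterogeneous; a smooth seeded random field (sum of
#'   random 3-D cosines, ~2-6 mm wavelengths) rides on the trabecular
#'   plateau and moves rigidly with its vertebra, giving intensity-based
#'   registration the internal structure real bone provides. Set 0 for an
#'   idealized flat-plateau phantom.
#' @param blur_sigma Isotropic Gaussian blur SD, mm (partial-volume model).
#' @param noise_sd Additive Gaussian noise SD, HU.
#' @param seed Integer seed controlling all phantom randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_levels = 1,
                         spacing = c(0.5, 0.5, 0.625),
                         margin = c(15, 15, 14),
                         level_pitch = 34,
                         level_names = NULL,
                         start_level = "T7",
                         intensities = c(air = -1000, soft_tissue = 40,
                                         trabecular = 300, cortical = 1200,
                                         metal = 3000),
                         body_halfwidth = 16, body_halfdepth = 11,
                         body_height = 24,
                         cortical_thickness = 1.5,
                         pedicle_radius = 4.5, pedicle_offset = 9,
                         canal_depth = 12, pedicle_overlap = 7,
                         lamina_thickness = 8, lamina_halfwidth = 14,
                         lamina_halfheight = 9,
                         screw_radius = 2.25, screw_length = 40,
                         screw_medial_angle_deg = 10,
                         tulip_radius = 3.5, tulip_length = 6,
                         n_beads = 4, bead_diameter = 1,
                         texture_sd = 40,
                         blur_sigma = 0.3, noise_sd = 20,
                         seed = 1L) {
  ints <- intensities
  if (!all(diff(ints[c("air", "soft_tissue", "trabecular", "cortical",
                       "metal")]) > 0))
    stop("intensity plateaus must increase: air < soft tissue < trabecular < cortical < metal")
  geom <- c(body_halfwidth, body_halfdepth, body_height, cortical_thickness,
            pedicle_radius, pedicle_offset, canal_depth, lamina_thickness,
            lamina_halfwidth, lamina_halfheight, screw_radius, screw_length,
            tulip_radius, tulip_length, bead_diameter, level_pitch)
  if (any(geom <= 0)) stop("all geometric parameters must be positive")
  if (screw_radius >= pedicle_radius)
    stop("screw radius must be smaller than the pedicle radius")
  if (is.null(level_names)) level_names <- spine_level_names(n_levels, start_level)
  stopifnot(length(level_names) == n_levels)
  structure(list(
    n_levels = n_levels, spacing = spacing, margin = margin,
    level_pitch = level_pitch, level_names = level_names,
    intensities = ints,
    body_halfwidth = body_halfwidth, body_halfdepth = body_halfdepth,
    body_height = body_height, cortical_thickness = cortical_thickness,
    pedicle_radius = pedicle_radius, pedicle_offset = pedicle_offset,
    canal_depth = canal_depth, pedicle_overlap = pedicle_overlap,
    lamina_thickness = lamina_thickness,
    lamina_halfwidth = lamina_halfwidth, lamina_halfheight = lamina_halfheight,
    screw_radius = screw_radius, screw_length = screw_length,
    screw_medial_angle_deg = screw_medial_angle_deg,
    tulip_radius = tulip_radius, tulip_length = tulip_length,
    n_beads = n_beads, bead_diameter = bead_diameter,
    texture_sd = texture_sd,
    blur_sigma = blur_sigma, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Consecutive vertebral level names
#' @param n Number of levels.
#' @param start First level, between "T2" and "L4".
#' @return Character vector of level names (T2..T12 then L1..L4, wrapping is
#'   an error).
#' @export
spine_level_names <- function(n, start = "T7") {
  all <- c(paste0("T", 2:12), paste0("L", 1:4))
  i <- match(start, all)
  if (is.na(i)) stop("unknown level ", start)
  if (i + n - 1 > length(all)) stop("level range runs past L4")
  all[i:(i + n - 1)]
}

# ---- analytic scene geometry -------------------------------------------
# Local level coordinates: origin at the canal centre, +x right (ML),
# +y anterior (AP), +z superior (SI). The body sits anterior (+y), the
# lamina posterior (-y), pedicles flank the canal at x = +/- pedicle_offset.

level_center <- function(spec, l) {
  z0 <- -(spec$n_levels - 1) * spec$level_pitch / 2
  c(0, 0, z0 + (l - 1) * spec$level_pitch)
}

body_center_y <- function(spec) spec$canal_depth / 2 + spec$body_halfdepth

# signed distance (approximate outside, exact enough for rasterization)
# to the union bone solid, local coordinates (n x 3 matrix)
bone_sdf_local <- function(p, spec) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  a <- spec$body_halfwidth; b <- spec$body_halfdepth
  yb <- body_center_y(spec)
  de <- (sqrt((x / a)^2 + ((y - yb) / b)^2) - 1) * b
  dzb <- abs(z) - spec$body_height / 2
  d_body <- pmax(de, dzb)
  hp <- spec$canal_depth / 2
  # the tube overlaps into the body (anterior) and lamina (posterior) so
  # both junctions are solid bone with no knife-edge seam
  ov <- spec$pedicle_overlap
  d_ped <- pmax(sqrt((abs(x) - spec$pedicle_offset)^2 + z^2) -
                  spec$pedicle_radius,
                abs(y - (ov - 1) / 2) - (hp + (ov + 1) / 2))
  yl <- -(hp + spec$lamina_thickness / 2)
  d_lam <- pmax(pmax(abs(x) - spec$lamina_halfwidth,
                     abs(y - yl) - spec$lamina_thickness / 2),
                abs(z) - spec$lamina_halfheight)
  pmin(d_body, d_ped, d_lam)
}

# default bilateral screw plan for one level, local coordinates;
# returns list(tip, tail) of the shaft in local mm
plan_local <- function(spec, side) {
  s <- if (side == "R") 1 else -1
  ang <- spec$screw_medial_angle_deg * pi / 180
  dirn <- c(-s * sin(ang), cos(ang), 0)
  entry_y <- -(spec$canal_depth / 2 + spec$lamina_thickness)
  ped <- c(s * spec$pedicle_offset, 0, 0)
  t_back <- (entry_y - ped[2]) / dirn[2]
  tail <- ped + t_back * dirn
  tip <- tail + spec$screw_length * dirn
  list(tip = tip, tail = tail)
}

bead_offsets_local <- function(spec) {
  yb <- body_center_y(spec)
  rbind(c(-10, yb - 4, -6),
        c(10, yb - 4, 6),
        c(-6, yb + 4, 7),
        c(6, yb + 4, -7))
}

phantom_grid <- function(spec) {
  xr <- spec$body_halfwidth + spec$margin[1]
  y_lo <- -(spec$canal_depth / 2 + spec$lamina_thickness +
              spec$tulip_length + 2) - spec$margin[2]
  y_hi <- body_center_y(spec) + spec$body_halfdepth + spec$margin[2]
  zc <- vapply(seq_len(spec$n_levels), function(l) level_center(spec, l)[3], 0)
  z_lo <- min(zc) - spec$body_height / 2 - spec$margin[3]
  z_hi <- max(zc) + spec$body_height / 2 + spec$margin[3]
  sp <- spec$spacing
  nx <- ceiling(2 * xr / sp[1]); ny <- ceiling((y_hi - y_lo) / sp[2])
  nz <- ceiling((z_hi - z_lo) / sp[3])
  affine <- rbind(cbind(diag(sp), c(-xr, y_lo, z_lo)), c(0, 0, 0, 1))
  xs <- -xr + sp[1] * (0:(nx - 1))
  ys <- y_lo + sp[2] * (0:(ny - 1))
  zs <- z_lo + sp[3] * (0:(nz - 1))
  list(dim = c(nx, ny, nz), affine = affine, xs = xs, ys = ys, zs = zs)
}

grid_world <- function(g) {
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  cbind(rep(g$xs, times = ny * nz),
        rep(rep(g$ys, each = nx), times = nz),
        rep(g$zs, each = nx * ny))
}

# smooth procedural texture: a fixed sum of random 3-D cosines, entirely
# determined by the spec seed so the preop and postop rasterizations carry
# the identical field in each vertebra's local frame
texture_field <- function(p, spec) {
  if (spec$texture_sd <= 0) return(rep(0, nrow(p)))
  has_rng <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_rng) {
    rng <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", rng, envir = globalenv()))
  }
  set.seed(spec$seed + 7L)
  K <- 40
  lambda <- runif(K, 2, 6)
  dirs <- matrix(rnorm(3 * K), K, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  freq <- 2 * pi * dirs / lambda
  phase <- runif(K, 0, 2 * pi)
  acc <- numeric(nrow(p))
  for (k in seq_len(K))
    acc <- acc + cos(p %*% freq[k, ] + phase[k])
  as.numeric(acc) * spec$texture_sd * sqrt(2 / K)
}

dist_to_segment <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  rel <- sweep(p, 2, a)
  t <- pmin(pmax((rel %*% ab) / L2, 0), 1)
  dx <- rel - t %*% t(ab)
  sqrt(rowSums(dx^2))
}

# z-slab subset of linear indices whose local z is within +/- halfz of zc
slab_subset <- function(g, zc, halfz) {
  ks <- which(g$zs >= zc - halfz & g$zs <= zc + halfz)
  if (length(ks) == 0) return(integer(0))
  nxy <- g$dim[1] * g$dim[2]
  as.vector(outer(seq_len(nxy), (ks - 1) * nxy, "+"))
}

# ---- generation ---------------------------------------------------------

#' Generate the preoperative phantom scan
#'
#' Rasterizes the analytic scene on the voxel grid (hard nearest-material
#' assignment so a noise-free, blur-free phantom has exactly the five
#' declared intensity plateaus; beads alone use partial-volume occupancy
#' because they are of voxel scale), applies Gaussian blur and seeded noise,
#' and returns the volume, the per-vertebra label mask, the default bilateral
#' screw plans and the partial ground truth (bead positions, endplate planes,
#' screw frames).
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (`ct_volume`), `mask` (`label_mask`), `plans`
#'   (tibble: level, side, tip/tail coordinates, radius_mm, length_mm) and
#'   `truth` (partial ground truth).
#' @export
generate_preop <- function(spec) {
  g <- phantom_grid(spec)
  W <- grid_world(g)
  ints <- spec$intensities
  val <- rep(ints[["air"]], nrow(W))
  lab <- integer(nrow(W))
  # soft-tissue torso: elliptic cylinder nearly filling the field
  ta <- max(abs(g$xs)) - 2; tb <- (max(g$ys) - min(g$ys)) / 2 - 2
  tyc <- (max(g$ys) + min(g$ys)) / 2
  inside_torso <- (W[, 1] / ta)^2 + ((W[, 2] - tyc) / tb)^2 <= 1
  val[inside_torso] <- ints[["soft_tissue"]]
  halfz <- max(spec$body_height / 2, spec$lamina_halfheight) + 2
  for (l in seq_len(spec$n_levels)) {
    cl <- level_center(spec, l)
    sub <- slab_subset(g, cl[3], halfz)
    p <- sweep(W[sub, , drop = FALSE], 2, cl)
    d <- bone_sdf_local(p, spec)
    bone <- d < 0
    cort <- bone & d > -spec$cortical_thickness
    val[sub[bone]] <- ints[["trabecular"]] +
      texture_field(p[bone, , drop = FALSE], spec)
    val[sub[cort]] <- ints[["cortical"]]
    lab[sub[bone]] <- l
  }
  beads <- bead_positions(spec)
  if (nrow(beads) > 0) val <- paint_beads(val, W, g, beads, spec)
  val <- finish_volume(val, g, spec, spec$seed)
  mask <- label_mask(array(lab, g$dim), g$affine,
                     stats::setNames(seq_len(spec$n_levels), spec$level_names))
  plans <- default_plans(spec)
  truth <- list(
    plans = plans,
    beads_pre = beads,
    endplates = level_endplates(spec),
    frames = plan_frames(spec, plans)
  )
  list(volume = ct_volume(array(val, g$dim), g$affine), mask = mask,
       plans = plans, truth = truth)
}

bead_positions <- function(spec) {
  if (spec$n_beads == 0) return(matrix(0, 0, 3))
  off <- bead_offsets_local(spec)[seq_len(min(spec$n_beads, 4)), , drop = FALSE]
  do.call(rbind, lapply(seq_len(spec$n_levels), function(l) {
    sweep(off, 2, level_center(spec, l), "+")
  }))
}

bead_levels <- function(spec) {
  rep(spec$level_names, each = min(spec$n_beads, 4))[
    seq_len(nrow(bead_positions(spec)))]
}

paint_beads <- function(val, W, g, beads, spec) {
  r <- spec$bead_diameter / 2
  edge <- max(spec$spacing)
  for (i in seq_len(nrow(beads))) {
    b <- beads[i, ]
    sub <- which(abs(W[, 1] - b[1]) <= r + edge &
                   abs(W[, 2] - b[2]) <= r + edge &
                   abs(W[, 3] - b[3]) <= r + edge)
    if (length(sub) == 0) next
    d <- sqrt(rowSums(sweep(W[sub, , drop = FALSE], 2, b)^2))
    occ <- pmin(pmax(0.5 + (r - d) / edge, 0), 1)
    val[sub] <- val[sub] + occ * (spec$intensities[["metal"]] - val[sub])
  }
  val
}

finish_volume <- function(val, g, spec, seed) {
  arr <- array(val, g$dim)
  if (spec$blur_sigma > 0)
    arr <- cpp_gauss_blur3d(arr, g$dim, spec$blur_sigma / spec$spacing)
  if (spec$noise_sd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), g$dim)
  }
  arr
}

default_plans <- function(spec) {
  rows <- list()
  for (l in seq_len(spec$n_levels)) {
    cl <- level_center(spec, l)
    for (side in c("L", "R")) {
      pl <- plan_local(spec, side)
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = spec$level_names[l], side = side,
        tip_x = pl$tip[1] + cl[1], tip_y = pl$tip[2] + cl[2],
        tip_z = pl$tip[3] + cl[3],
        tail_x = pl$tail[1] + cl[1], tail_y = pl$tail[2] + cl[2],
        tail_z = pl$tail[3] + cl[3],
        radius_mm = spec$screw_radius, length_mm = spec$screw_length)
    }
  }
  dplyr::bind_rows(rows)
}

level_endplates <- function(spec) {
  lapply(stats::setNames(seq_len(spec$n_levels), spec$level_names), function(l) {
    cl <- level_center(spec, l)
    structure(list(point = cl + c(0, body_center_y(spec),
                                  -spec$body_height / 2),
                   normal = c(0, 0, 1)),
              class = "endplate_plane")
  })
}

plan_frames <- function(spec, plans) {
  eps <- level_endplates(spec)
  lapply(seq_len(nrow(plans)), function(i) {
    build_screw_frame(plans[i, ], eps[[plans$level[i]]])
  })
}

#' Generate the postoperative phantom scan with ground truth
#'
#' Applies per-screw deviations to the planned trajectories (offsets given in
#' each screw's ML/AP/SI frame), moves every vertebra (with its screws and
#' beads) by its level's rigid inter-scan motion, rasterizes screws as
#' metal capsules (shaft of plan radius capped by a hemispheric tip, plus a
#' wider short tulip-head capsule posterior of the tail), then applies blur
#' and seeded noise.
#'
#' @param preop Output of [generate_preop()].
#' @param spec The same [phantom_spec()].
#' @param screw_deviations Tibble/data.frame with one row per plan row:
#'   columns `tip_ML`, `tip_AP`, `tip_SI`, `tail_ML`, `tail_AP`, `tail_SI`
#'   (mm, screw-frame offsets). Zeros by default.
#' @param motions List of [rigid_transform()] per level (preop world to
#'   postop world); identity by default.
#' @return List with `volume` (postop `ct_volume`) and `truth` (completed
#'   ground truth: per-level motions, per-screw planned/true geometry and
#'   frame-resolved deviations, bead positions pre/post).
#' @export
generate_postop <- function(preop, spec, screw_deviations = NULL,
                            motions = NULL) {
  plans <- preop$plans
  n <- nrow(plans)
  if (is.null(screw_deviations))
    screw_deviations <- tibble::tibble(tip_ML = rep(0, n), tip_AP = 0,
                                       tip_SI = 0, tail_ML = 0, tail_AP = 0,
                                       tail_SI = 0)
  if (is.null(motions))
    motions <- replicate(spec$n_levels, rigid_transform(), simplify = FALSE)
  stopifnot(nrow(screw_deviations) == n, length(motions) == spec$n_levels)
  names(motions) <- spec$level_names
  g <- phantom_grid(spec)
  W <- grid_world(g)
  ints <- spec$intensities
  val <- rep(ints[["air"]], nrow(W))
  ta <- max(abs(g$xs)) - 2; tb <- (max(g$ys) - min(g$ys)) / 2 - 2
  tyc <- (max(g$ys) + min(g$ys)) / 2
  val[(W[, 1] / ta)^2 + ((W[, 2] - tyc) / tb)^2 <= 1] <- ints[["soft_tissue"]]
  # moved vertebrae
  halfz0 <- max(spec$body_height / 2, spec$lamina_halfheight) + 2
  for (l in seq_len(spec$n_levels)) {
    cl <- level_center(spec, l)
    M <- motions[[l]]
    reach <- halfz0 + rotation_angle_deg(M$rotation) * pi / 180 *
      max(spec$body_halfwidth, body_center_y(spec) + spec$body_halfdepth) +
      abs(M$translation[3])
    check_in_field(apply_transform(M, level_bbox_corners(spec, cl)), g,
                   spec$level_names[l])
    sub <- slab_subset(g, cl[3], reach)
    p <- apply_transform(invert_transform(M), W[sub, , drop = FALSE])
    p <- sweep(p, 2, cl)
    d <- bone_sdf_local(p, spec)
    bone <- d < 0
    if (any(bone)) {
      cort <- bone & d > -spec$cortical_thickness
      val[sub[bone]] <- ints[["trabecular"]] +
        texture_field(p[bone, , drop = FALSE], spec)
      val[sub[cort]] <- ints[["cortical"]]
    }
  }
  # screws: deviation applied to plan, then level motion
  frames <- preop$truth$frames
  screws <- lapply(seq_len(n), function(i) {
    fr <- frames[[i]]
    dev <- screw_deviations[i, ]
    B <- cbind(fr$e_ML, fr$e_AP, fr$e_SI)
    tip_pre <- plan_point(plans[i, ], "tip") +
      as.numeric(B %*% c(dev$tip_ML, dev$tip_AP, dev$tip_SI))
    tail_pre <- plan_point(plans[i, ], "tail") +
      as.numeric(B %*% c(dev$tail_ML, dev$tail_AP, dev$tail_SI))
    M <- motions[[plans$level[i]]]
    list(tip_pre = tip_pre, tail_pre = tail_pre,
         tip_post = apply_transform(M, tip_pre),
         tail_post = apply_transform(M, tail_pre))
  })
  for (s in screws) {
    axis <- (s$tip_post - s$tail_post) /
      sqrt(sum((s$tip_post - s$tail_post)^2))
    # the capsule's hemispheric cap forms the rounded screw tip, so the
    # segment stops one radius short of the tip landmark: the metal apex
    # coincides exactly with the true tip
    val <- paint_capsule(val, W, g, s$tail_post,
                         s$tip_post - spec$screw_radius * axis,
                         spec$screw_radius, ints[["metal"]])
    val <- paint_capsule(val, W, g, s$tail_post - spec$tulip_length * axis,
                         s$tail_post, spec$tulip_radius, ints[["metal"]])
  }
  beads_pre <- preop$truth$beads_pre
  beads_post <- beads_pre
  if (nrow(beads_pre) > 0) {
    lv <- bead_levels(spec)
    for (i in seq_len(nrow(beads_pre)))
      beads_post[i, ] <- apply_transform(motions[[lv[i]]], beads_pre[i, ])
    val <- paint_beads(val, W, g, beads_post, spec)
  }
  val <- finish_volume(val, g, spec, spec$seed + 1L)
  truth <- build_ground_truth(preop, spec, screw_deviations, motions, screws,
                              beads_post)
  list(volume = ct_volume(array(val, g$dim), g$affine), truth = truth)
}

level_bbox_corners <- function(spec, cl) {
  xr <- max(spec$body_halfwidth, spec$lamina_halfwidth)
  ylo <- -(spec$canal_depth / 2 + spec$lamina_thickness)
  yhi <- body_center_y(spec) + spec$body_halfdepth
  zr <- max(spec$body_height / 2, spec$lamina_halfheight)
  corners <- as.matrix(expand.grid(c(-xr, xr), c(ylo, yhi), c(-zr, zr)))
  sweep(corners, 2, cl, "+")
}

check_in_field <- function(pts, g, level) {
  lim <- rbind(range(g$xs), range(g$ys), range(g$zs))
  for (a in 1:3)
    if (min(pts[, a]) < lim[a, 1] + 1e-9 || max(pts[, a]) > lim[a, 2] - 1e-9)
      stop("motion moved level ", level, " out of the field of view")
  invisible(TRUE)
}

paint_capsule <- function(val, W, g, a, b, radius, value) {
  lo <- pmin(a, b) - radius - 1
  hi <- pmax(a, b) + radius + 1
  sub <- which(W[, 1] >= lo[1] & W[, 1] <= hi[1] &
                 W[, 2] >= lo[2] & W[, 2] <= hi[2] &
                 W[, 3] >= lo[3] & W[, 3] <= hi[3])
  if (length(sub) == 0) return(val)
  d <- dist_to_segment(W[sub, , drop = FALSE], a, b)
  val[sub[d <= radius]] <- value
  val
}

build_ground_truth <- function(preop, spec, screw_deviations, motions, screws,
                               beads_post) {
  plans <- preop$plans
  frames <- preop$truth$frames
  rows <- lapply(seq_len(nrow(plans)), function(i) {
    s <- screws[[i]]
    fr <- frames[[i]]
    ax_plan <- fr$e_AP
    ax_true <- (s$tip_pre - s$tail_pre) / sqrt(sum((s$tip_pre - s$tail_pre)^2))
    tibble::tibble(
      level = plans$level[i], side = plans$side[i],
      tip_pre_x = s$tip_pre[1], tip_pre_y = s$tip_pre[2], tip_pre_z = s$tip_pre[3],
      tail_pre_x = s$tail_pre[1], tail_pre_y = s$tail_pre[2], tail_pre_z = s$tail_pre[3],
      tip_post_x = s$tip_post[1], tip_post_y = s$tip_post[2], tip_post_z = s$tip_post[3],
      tail_post_x = s$tail_post[1], tail_post_y = s$tail_post[2], tail_post_z = s$tail_post[3],
      angle_true_deg = angular_deviation(ax_plan, ax_true)
    )
  })
  list(motions = motions,
       plans = plans,
       screws = dplyr::bind_cols(dplyr::bind_rows(rows), screw_deviations),
       beads_pre = preop$truth$beads_pre,
       beads_post = beads_post,
       bead_levels = bead_levels(spec),
       endplates = preop$truth$endplates,
       frames = frames)
}

#' Simulate a full pre/post phantom case with known ground truth
#'
#' Draws per-level inter-scan motions (rotation angle uniform on
#' `[0, motion_deg]` about a random axis through the level centre,
#' translation magnitude uniform on `[0, motion_mm]` in a random direction)
#' and per-screw placement deviations (a small rigid perturbation of the
#' plan: a translation up to `dev_mm` plus a rotation up to `dev_deg` about
#' the tail, so true shaft length equals plan length), then generates both
#' scans. Everything is deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param motion_deg,motion_mm Maximum per-level inter-scan motion.
#' @param dev_mm,dev_deg Maximum planted screw deviation.
#' @return List: `preop` (volume), `mask`, `plans`, `postop` (volume),
#'   `truth` (complete ground truth), `spec`.
#' @export
simulate_case <- function(spec, motion_deg = 10, motion_mm = 10,
                          dev_mm = 1.5, dev_deg = 2) {
  pre <- generate_preop(spec)
  set.seed(spec$seed + 2L)
  motions <- lapply(seq_len(spec$n_levels), function(l) {
    random_rigid_transform(runif(1, 0, motion_deg), runif(1, 0, motion_mm),
                           center = level_center(spec, l))
  })
  plans <- pre$plans
  frames <- pre$truth$frames
  devs <- lapply(seq_len(nrow(plans)), function(i) {
    tip <- plan_point(plans[i, ], "tip")
    tail <- plan_point(plans[i, ], "tail")
    dirn <- rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    delta <- dirn * runif(1, 0, dev_mm)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, dev_deg))
    tail_new <- tail + delta
    tip_new <- tail_new + as.numeric(R %*% (tip - tail))
    fr <- frames[[i]]
    B <- cbind(fr$e_ML, fr$e_AP, fr$e_SI)
    tibble::tibble(
      tip_ML = sum((tip_new - tip) * fr$e_ML),
      tip_AP = sum((tip_new - tip) * fr$e_AP),
      tip_SI = sum((tip_new - tip) * fr$e_SI),
      tail_ML = sum((tail_new - tail) * fr$e_ML),
      tail_AP = sum((tail_new - tail) * fr$e_AP),
      tail_SI = sum((tail_new - tail) * fr$e_SI))
  })
  post <- generate_postop(pre, spec, dplyr::bind_rows(devs), motions)
  list(preop = pre$volume, mask = pre$mask, plans = plans,
       postop = post$volume, truth = post$truth, spec = spec)
}

#' Write a phantom case to disk (NIfTI volumes, plan CSV, truth JSON)
#'
#' @param case Output of [simulate_case()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ct_volume(case$preop, file.path(dir, "preop.nii.gz"))
  write_ct_volume(case$postop, file.path(dir, "postop.nii.gz"))
  write_ct_volume(case$mask, file.path(dir, "mask.nii.gz"))
  readr::write_csv(case$plans, file.path(dir, "plans.csv"))
  truth <- case$truth
  jsonlite::write_json(list(
    motions = lapply(truth$motions, function(m)
      list(rotation = m$rotation, translation = m$translation)),
    screws = truth$screws,
    beads_pre = truth$beads_pre,
    beads_post = truth$beads_post,
    bead_levels = truth$bead_levels,
    level_ids = as.list(case$mask$level_ids)
  ), file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a screw plan table
#'
#' Plans may be CSV or JSON with columns `level`, `side` (L/R), `tip_x`,
#' `tip_y`, `tip_z`, `tail_x`, `tail_y`, `tail_z`, `radius_mm`, `length_mm`
#' (all coordinates world mm, preoperative space).
#'
#' @param path CSV or JSON file.
#' @return Tibble of plans.
#' @export
read_screw_plans <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
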