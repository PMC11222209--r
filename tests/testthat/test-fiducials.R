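bead_volume <- function(center, background = 300, metal = 3000,
                        spacing = c(0.5, 0.5, 0.625), dims = c(24, 24, 20),
                        blur = 0.3) {
  aff <- rbind(cbind(diag(spacing), -spacing * dims / 2), c(0, 0, 0, 1))
  v <- ct_volume(array(background, dims), aff)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  w <- voxel_to_world(v, idx - 1)
  d <- sqrt(rowSums(sweep(w, 2, center)^2))
  occ <- pmin(pmax(0.5 + (0.5 - d) / max(spacing), 0), 1)
  data <- v$data
  data[idx] <- data[idx] + occ * (metal - data[idx])
  out <- ct_volume(data, aff)
  smooth_volume(out, blur)
}

test_that("a synthetic 1 mm bead is found within 0.2 mm", {
  set.seed(40)
  for (i in 1:5) {
    center <- runif(3, -1, 1)
    v <- bead_volume(center)
    found <- detect_beads(v, bead_detection_threshold(300, 3000), 1)
    expect_equal(nrow(found), 1L)
    expect_lt(sqrt(sum((found[1, ] - center)^2)), 0.2)
  }
})

test_that("empty volumes yield no beads", {
  v <- ct_volume(array(40, c(10, 10, 10)), diag(4))
  expect_equal(nrow(detect_beads(v, 1000, 1)), 0L)
})

test_that("beads near screw components are excluded", {
  det <- coarse_detected()
  case <- det$case
  spec <- case$spec
  comps <- detect_metal_components(case$postop, det$threshold,
                                   0.5 * pi * spec$screw_radius^2 *
                                     spec$screw_length)
  bt <- bead_detection_threshold(spec$intensities[["trabecular"]],
                                 spec$intensities[["metal"]])
  with_excl <- detect_beads(case$postop, bt, spec$bead_diameter,
                            exclusion = comps, exclusion_margin_mm = 2)
  if (nrow(with_excl) > 0) {
    for (i in seq_len(nrow(with_excl))) {
      clearance <- min(vapply(comps, function(cmp)
        min(sqrt(rowSums(sweep(cmp$world, 2, with_excl[i, ])^2))), 0))
      expect_gte(clearance, 2)
    }
  }
  # with a huge margin every candidate disappears
  none <- detect_beads(case$postop, bt, spec$bead_diameter,
                       exclusion = comps, exclusion_margin_mm = 1e6)
  expect_equal(nrow(none), 0L)
})

test_that("fiducial error is zero for exactly transformed beads", {
  set.seed(41)
  pre <- matrix(rnorm(12, sd = 10), 4, 3)
  T1 <- random_rigid_transform(8, 5)
  post <- apply_transform(T1, pre)
  fs <- fiducial_set(pre, post, coarse_transform = T1)
  fre <- fiducial_registration_error(fs, T1)
  expect_equal(fre$mae_mm, 0, tolerance = 1e-12)
  expect_equal(fre$n_usable, 4L)

  # one bead offset by 0.3 mm contributes exactly that error
  post2 <- post
  post2[2, ] <- post2[2, ] + c(0.3, 0, 0)
  fre2 <- fiducial_registration_error(fiducial_set(pre, post2, T1), T1)
  expect_equal(fre2$per_bead$error_mm[2], 0.3, tolerance = 1e-12)
  expect_equal(fre2$mae_mm, 0.3 / 4, tolerance = 1e-12)
})

test_that("fiducial error matches a hand computation and ignores order", {
  set.seed(42)
  pre <- matrix(rnorm(15, sd = 8), 5, 3)
  truth <- random_rigid_transform(6, 6)
  post <- apply_transform(truth, pre) + matrix(rnorm(15, sd = 0.1), 5, 3)
  est <- compose_transform(rigid_transform(translation = c(0.05, 0, 0)),
                           truth)
  fs <- fiducial_set(pre, post, coarse_transform = truth, max_pair_mm = 2)
  fre <- fiducial_registration_error(fs, est)
  manual <- mean(sqrt(rowSums((apply_transform(est, pre) - post)^2)))
  expect_equal(fre$mae_mm, manual, tolerance = 1e-9)

  perm <- sample(5)
  fs2 <- fiducial_set(pre[perm, ], post, coarse_transform = truth,
                      max_pair_mm = 2)
  fre2 <- fiducial_registration_error(fs2, est)
  expect_equal(fre2$mae_mm, fre$mae_mm, tolerance = 1e-9)

  empty <- fiducial_set(matrix(0, 0, 3), matrix(0, 0, 3))
  expect_error(fiducial_registration_error(empty, est), "no usable")
})

test_that("with the true motion, fiducial error reduces to detection error", {
  det <- coarse_detected()
  case <- det$case
  spec <- case$spec
  bt <- bead_detection_threshold(spec$intensities[["trabecular"]],
                                 spec$intensities[["metal"]])
  comps <- detect_metal_components(case$postop, det$threshold,
                                   0.5 * pi * spec$screw_radius^2 *
                                     spec$screw_length)
  prom <- 0.25 * (spec$intensities[["metal"]] - spec$intensities[["trabecular"]])
  pre_b <- detect_beads(case$preop, bt, spec$bead_diameter,
                        min_prominence = prom)
  post_b <- detect_beads(case$postop, bt, spec$bead_diameter,
                         exclusion = comps, min_prominence = prom)
  truthM <- case$truth$motions[[1]]
  fs <- fiducial_set(pre_b, post_b, coarse_transform = truthM,
                     max_pair_mm = 2)
  expect_gte(sum(fs$usable), 3)
  fre <- fiducial_registration_error(fs, truthM)
  expect_lt(fre$mae_mm, 0.3)
})
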