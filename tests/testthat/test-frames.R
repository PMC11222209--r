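test_that("screw frames follow the declared axis conventions", {
  plan <- make_plan(tip = c(-5, 26, 0), tail = c(-5, -14, 0), side = "L")
  endp <- structure(list(point = c(0, 17, -12), normal = c(0, 0, 1)),
                    class = "endplate_plane")
  fr <- build_screw_frame(plan, endp)
  expect_equal(fr$e_AP, c(0, 1, 0))
  expect_equal(fr$e_SI, c(0, 0, 1))
  expect_equal(fr$e_ML, c(1, 0, 0))   # medial is +x for a left-sided screw

  # Gram-Schmidt removes the AP component of the endplate normal
  endp2 <- structure(list(point = c(0, 0, 0),
                          normal = c(0, sqrt(0.5), sqrt(0.5))),
                     class = "endplate_plane")
  fr2 <- build_screw_frame(plan, endp2)
  expect_equal(fr2$e_SI, c(0, 0, 1), tolerance = 1e-12)

  plan_r <- make_plan(tip = c(5, 26, 0), tail = c(5, -14, 0), side = "R")
  fr_r <- build_screw_frame(plan_r, endp)
  expect_equal(fr_r$e_ML, c(-1, 0, 0))  # medial is -x on the right
})

test_that("frames are orthonormal and consistently handed for random plans", {
  set.seed(30)
  for (i in 1:100) {
    tail <- rnorm(3) * 10
    axis <- random_unit()
    plan <- make_plan(tail + 40 * axis, tail,
                      side = sample(c("L", "R"), 1))
    normal <- random_unit()
    if (abs(sum(normal * axis)) > cos(10 * pi / 180)) next
    fr <- build_screw_frame(plan, structure(list(point = c(0, 0, 0),
                                                 normal = normal),
                                            class = "endplate_plane"))
    B <- cbind(fr$e_ML, fr$e_AP, fr$e_SI)
    expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
    expect_equal(abs(det(B)), 1, tolerance = 1e-9)
    # e_ML x e_AP is +/- e_SI: the triad is consistently handed
    expect_lt(min(max(abs(screwpose:::cross3(fr$e_ML, fr$e_AP) - fr$e_SI)),
                  max(abs(screwpose:::cross3(fr$e_ML, fr$e_AP) + fr$e_SI))),
              1e-9)
  }
})

test_that("a near-parallel endplate normal is rejected", {
  plan <- make_plan(c(0, 40, 0), c(0, 0, 0), side = "L")
  endp <- structure(list(point = c(0, 0, 0),
                         normal = c(0, cos(2 * pi / 180), sin(2 * pi / 180))),
                    class = "endplate_plane")
  expect_error(build_screw_frame(plan, endp), "degenerate frame")
})

test_that("endplate fitting recovers the constructed inferior plane", {
  pre <- clean_preop()
  endp <- fit_endplate_plane(pre$mask, "T7")
  true_ep <- pre$truth$endplates[["T7"]]
  expect_lt(angular_deviation(endp$normal, true_ep$normal), 1)
  # plane height at the constructed face within half a voxel
  expect_lt(abs(sum(endp$normal * (endp$point - true_ep$point))),
            0.5 * max(pre$mask$spacing) + 1e-9)
})

test_that("endplate fitting tracks a tilted vertebra", {
  pre <- clean_preop()
  tilt <- transform_about_point(c(0, 1, 0), 10,
                                center = mask_centroid(pre$mask, "T7"))
  tilted <- resample(pre$mask, tilt)
  endp <- fit_endplate_plane(tilted, "T7")
  expected <- as.numeric(tilt$rotation %*% c(0, 0, 1))
  expect_lt(angular_deviation(endp$normal, expected), 1.5)
})

test_that("an implausible mask yields an insufficient-surface error", {
  labs <- array(0L, c(30, 6, 6))
  labs[3:28, 3, 3] <- 1L   # thin rod, no endplate
  rod <- label_mask(labs, diag(c(0.8, 0.8, 0.8, 1)))
  expect_error(fit_endplate_plane(rod, 1), "insufficient endplate surface")
})

mid_pedicle_spec <- function() {
  memo_fixture("midped_pre", function() {
    generate_preop(phantom_spec(spacing = c(0.4, 0.4, 0.4),
                                margin = c(4, 4, 4), noise_sd = 0,
                                blur_sigma = 0, n_beads = 0, seed = 3))
  })
}

test_that("mid-pedicle locus matches construction for a parallel trajectory", {
  pre <- mid_pedicle_spec()
  s <- phantom_spec()
  # trajectory parallel to the pedicle tube, 1 mm from the medial wall:
  # medial wall plane at x = pedicle_offset - pedicle_radius = 4.5
  plan <- make_plan(tip = c(5.5, 8, 0), tail = c(5.5, -13, 0), side = "R")
  locus <- locate_mid_pedicle(plan, pre$mask, level = "T7")
  expect_equal(locus$wall_distance, 1.0, tolerance = 0.2)
  # constant distance along the tube: the tie-break returns the first
  # (smallest-arc) of the minimizing samples
  expect_lt(locus$arc_param, 9)
})

test_that("a breaching trajectory reports a negative wall distance", {
  pre <- mid_pedicle_spec()
  # tilted path whose deepest point pierces 0.5 mm past the medial wall
  # (tip placed just before the pedicle's anterior end, 0.5 mm canal-side
  # of the wall plane at x = 4.5)
  plan <- make_plan(tip = c(4.0, 5, 0), tail = c(8.0, -13, 0), side = "R")
  locus <- locate_mid_pedicle(plan, pre$mask, level = "T7")
  expect_lt(locus$wall_distance, 0)
  expect_equal(locus$wall_distance, -0.5, tolerance = 0.25)
})

test_that("the locus agrees with brute-force search over wall points", {
  pre <- mid_pedicle_spec()
  plan <- make_plan(tip = c(4.8, 8, 1), tail = c(7.5, -13, -1), side = "R")
  locus <- locate_mid_pedicle(plan, pre$mask, level = "T7")
  # independent brute force: plain loops over samples and wall points
  wall <- screwpose:::medial_wall_points(pre$mask, 1L, "R")
  tail <- c(7.5, -13, -1); tip <- c(4.8, 8, 1)
  len <- sqrt(sum((tip - tail)^2)); axis <- (tip - tail) / len
  rel <- sweep(wall, 2, tail); t_ax <- rel %*% axis
  perp2 <- rowSums((rel - t_ax %*% t(axis))^2)
  wall <- wall[sqrt(perp2) <= 8 & t_ax >= 0 & t_ax <= len, , drop = FALSE]
  best <- c(Inf, NA)
  for (t in seq(0, len, by = 0.1)) {
    p <- tail + t * axis
    dmin <- Inf
    for (k in seq_len(nrow(wall))) {
      d <- sqrt(sum((p - wall[k, ])^2))
      if (d < dmin) dmin <- d
    }
    inside <- screwpose:::sample_label_nn(pre$mask, matrix(p, 1)) == 1L
    sgn <- if (inside) dmin else -dmin
    if (sgn < best[1]) best <- c(sgn, t)
  }
  expect_equal(locus$wall_distance, best[1], tolerance = 1e-9)
  expect_lt(abs(locus$arc_param - best[2]), 0.1 + 1e-9)
})

test_that("a trajectory far from the pedicle errors", {
  pre <- mid_pedicle_spec()
  plan <- make_plan(tip = c(30, 8, 0), tail = c(30, -13, 0), side = "R")
  expect_error(locate_mid_pedicle(plan, pre$mask, level = "T7"))
})
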