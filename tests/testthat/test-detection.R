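test_that("component extraction handles empty and multi-screw volumes", {
  air <- ct_volume(array(-1000, c(10, 10, 10)), diag(4))
  expect_length(detect_metal_components(air, 2000), 0L)

  det <- coarse_detected()
  spec <- det$case$spec
  min_vol <- 0.5 * pi * spec$screw_radius^2 * spec$screw_length
  comps <- detect_metal_components(det$case$postop, det$threshold, min_vol)
  expect_length(comps, 2L)
  # beads are far below the half-shaft volume cutoff
  small <- detect_metal_components(det$case$postop, det$threshold, 0)
  expect_gte(length(small), 2L)
  expect_true(all(vapply(comps, function(cmp) cmp$size_mm3, 0) >= min_vol))
})

test_that("principal-axis initialization orients ideal capsules", {
  tip <- c(20, 24, 0); tail <- c(-20, 24, 0)   # along +x, tip at larger x
  vol <- capsule_volume(tip, tail)
  comps <- detect_metal_components(vol, 2100, 10)
  expect_length(comps, 1L)
  init <- init_screw_from_component(comps[[1]], 2.25, 40)
  # orientation rule anchors the tip away from the posterior (-y) face;
  # here the axis is x-aligned so compare axis direction only
  expect_lt(angular_deviation(init$axis, c(1, 0, 0)) %% 180, 1)

  rot <- rotation_about_axis(c(0, 0, 1), 30)
  vol2 <- capsule_volume(as.numeric(rot %*% tip), as.numeric(rot %*% tail))
  comps2 <- detect_metal_components(vol2, 2100, 10)
  init2 <- init_screw_from_component(comps2[[1]], 2.25, 40)
  target <- as.numeric(rot %*% c(1, 0, 0))
  expect_lt(min(angular_deviation(init2$axis, target),
                angular_deviation(-init2$axis, target)), 1)
})

test_that("isotropic blobs are rejected as degenerate", {
  a <- array(40, c(20, 20, 20))
  aff <- diag(c(0.5, 0.5, 0.5, 1))
  v <- ct_volume(a, aff)
  idx <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  w <- voxel_to_world(v, idx - 1)
  d <- sqrt(rowSums(sweep(w, 2, c(5, 5, 5))^2))
  a[idx[d <= 3, ]] <- 3000
  v <- ct_volume(a, aff)
  comps <- detect_metal_components(v, 2000, 1)
  expect_error(init_screw_from_component(comps[[1]], 2.25, 40),
               "degenerate")
})

test_that("the shaft fit recovers the true pose and improves its objective", {
  det <- coarse_detected()
  case <- det$case
  tr <- case$truth$screws
  for (j in seq_len(nrow(det$matches$pairs))) {
    i <- det$matches$pairs$plan[j]
    s <- det$screws[[det$matches$pairs$detection[j]]]
    tip_true <- c(tr$tip_post_x[i], tr$tip_post_y[i], tr$tip_post_z[i])
    tail_true <- c(tr$tail_post_x[i], tr$tail_post_y[i], tr$tail_post_z[i])
    expect_lt(sqrt(sum((s$tip - tip_true)^2)), 0.5)
    expect_lt(sqrt(sum((s$tail - tail_true)^2)), 0.5)
    expect_gte(s$fit_score, s$init_score)
  }
})

test_that("restarting the fit at a displaced pose returns to the optimum", {
  det <- coarse_detected()
  case <- det$case
  spec <- case$spec
  tr <- case$truth$screws
  i <- 1
  tip_true <- c(tr$tip_post_x[i], tr$tip_post_y[i], tr$tip_post_z[i])
  tail_true <- c(tr$tail_post_x[i], tr$tail_post_y[i], tr$tail_post_z[i])
  axis_true <- (tip_true - tail_true) / spec$screw_length
  off_axis <- rotation_about_axis(c(0, 0, 1), 4) %*% axis_true
  init <- screwpose:::new_detected_screw(
    tip_true + c(1.5, -1, 0.5),
    tip_true + c(1.5, -1, 0.5) - spec$screw_length * as.numeric(off_axis),
    NA_real_, "T7", tr$side[i])
  fit <- fit_screw_model(case$postop, init, spec$screw_radius,
                         spec$screw_length, det$threshold)
  expect_lt(sqrt(sum((fit$tip - tip_true)^2)), 0.5)
  expect_lt(sqrt(sum((fit$tail - tail_true)^2)), 0.5)
})

test_that("detection is equivariant under rigid motion of the volume", {
  det <- coarse_detected()
  case <- det$case
  spec <- case$spec
  M <- transform_about_point(c(0, 1, 1), 4,
                             center = c(0, 0, 0), translation = c(1.5, 1, -1))
  moved <- resample(case$postop, M)
  screws2 <- detect_screws(moved, case$plans, det$threshold)
  expect_length(screws2, length(det$screws))
  tips1 <- t(vapply(det$screws, function(s) s$tip, numeric(3)))
  tips2 <- t(vapply(screws2, function(s) s$tip, numeric(3)))
  mapped <- apply_transform(M, tips1)
  for (i in seq_len(nrow(tips1))) {
    d <- sqrt(rowSums(sweep(tips2, 2, mapped[i, ])^2))
    expect_lt(min(d), 0.5)
  }
})

test_that("plan matching is geometric, order-invariant, and reports leftovers", {
  det <- coarse_detected()
  case <- det$case
  # identity-position detections pair trivially
  plans <- case$plans
  perfect <- lapply(seq_len(nrow(plans)), function(i) {
    screwpose:::new_detected_screw(
      screwpose:::plan_point(plans[i, ], "tip"),
      screwpose:::plan_point(plans[i, ], "tail"), 0,
      plans$level[i], plans$side[i])
  })
  m1 <- match_screws_to_plans(perfect, plans)
  expect_equal(m1$pairs$plan, m1$pairs$detection)
  expect_equal(m1$pairs$distance_mm, rep(0, nrow(plans)))

  m2 <- match_screws_to_plans(rev(perfect), plans)
  expect_equal(m2$pairs$detection, rev(seq_len(nrow(plans))))
  expect_equal(m2$pairs$distance_mm, rep(0, nrow(plans)))

  # more plans than detections: the missing plan is reported, not dropped
  extra_plan <- plans[1, ]
  extra_plan$tip_x <- extra_plan$tip_x + 60
  extra_plan$tail_x <- extra_plan$tail_x + 60
  plans3 <- dplyr::bind_rows(plans, extra_plan)
  m3 <- match_screws_to_plans(perfect, plans3)
  expect_equal(nrow(m3$pairs), 2L)
  expect_equal(m3$unmatched_plans, 3L)
})
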