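simple_frame <- function(side = "L") {
  structure(list(origin = c(0, 0, 0), e_ML = c(1, 0, 0), e_AP = c(0, 1, 0),
                 e_SI = c(0, 0, 1), side = side), class = "screw_frame")
}

simple_locus <- function(arc = 15) {
  structure(list(point = c(0, arc, 0), arc_param = arc, wall_distance = 2,
                 side = "L", level = "T7"), class = "mid_pedicle_locus")
}

detected_at <- function(tip, tail) {
  screwpose:::new_detected_screw(tip, tail, 0, "T7", "L")
}

test_that("angular deviation follows the clamped arccosine", {
  expect_equal(angular_deviation(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_deviation(c(1, 0, 0), c(0, 1, 0)), 90)
  th <- 1.58 * pi / 180
  expect_equal(angular_deviation(c(0, 0, 1), c(0, sin(th), cos(th))), 1.58,
               tolerance = 1e-9)
  expect_equal(angular_deviation(c(2, 0, 0), c(1, 0, 0)), 0)  # length-free
  expect_error(angular_deviation(c(0, 0, 0), c(1, 0, 0)), "zero-length")
})

test_that("a perfectly placed screw has zero error everywhere", {
  plan <- make_plan(c(0, 40, 0), c(0, 0, 0))
  rec <- screw_errors(plan, detected_at(c(0, 40, 0), c(0, 0, 0)),
                      rigid_transform(), simple_frame(), simple_locus())
  for (col in screwpose:::metric_columns())
    expect_equal(rec[[col]], 0, tolerance = 1e-9)
  expect_equal(rec$region, "lower thoracic")
})

test_that("a pure medial offset appears in every ML component", {
  plan <- make_plan(c(0, 40, 0), c(0, 0, 0))
  rec <- screw_errors(plan, detected_at(c(1, 40, 0), c(1, 0, 0)),
                      rigid_transform(), simple_frame(), simple_locus())
  expect_equal(rec$tail_ML, 1, tolerance = 1e-9)
  expect_equal(rec$tip_ML, 1, tolerance = 1e-9)
  expect_equal(rec$mid_ML, 1, tolerance = 1e-9)
  expect_equal(rec$tail_AP + rec$tail_SI + rec$tip_AP + rec$tip_SI +
                 rec$mid_SI, 0, tolerance = 1e-9)
  expect_equal(rec$angle_deg, 0, tolerance = 1e-6)
  expect_equal(rec$tail_3D, 1, tolerance = 1e-9)
  expect_equal(rec$mid_2D, 1, tolerance = 1e-9)
})

test_that("a small axis rotation produces the closed-form errors", {
  L <- 40; arc <- 15
  plan <- make_plan(c(0, L, 0), c(0, 0, 0))
  th <- 2 * pi / 180
  # rotate the shaft 2 degrees about e_SI through the tail:
  # the axis tilts from +y toward -x (right-handed rotation about +z)
  tip_rot <- c(-L * sin(th), L * cos(th), 0)
  rec <- screw_errors(plan, detected_at(tip_rot, c(0, 0, 0)),
                      rigid_transform(), simple_frame(), simple_locus(arc))
  expect_equal(rec$angle_deg, 2, tolerance = 1e-9)
  expect_equal(abs(rec$tip_ML), L * sin(th), tolerance = 1e-9)
  # the detected axis pierces the mid-pedicle plane tan(th)*arc off-centre
  expect_equal(abs(rec$mid_ML), arc * tan(th), tolerance = 1e-9)
  expect_equal(rec$tail_3D, 0, tolerance = 1e-9)
})

test_that("errors are mirror-equivariant across the sagittal plane", {
  set.seed(31)
  mirror <- diag(c(-1, 1, 1))
  for (i in 1:20) {
    tail <- c(runif(1, 2, 10), rnorm(2) * 5)
    axis <- random_unit() * sign(runif(1)) ; axis[2] <- abs(axis[2]) + 1
    axis <- axis / sqrt(sum(axis^2))
    plan <- make_plan(tail + 40 * axis, tail, side = "R")
    normal <- c(rnorm(1, 0, 0.1), rnorm(1, 0, 0.1), 1)
    endp <- structure(list(point = c(0, 0, 0), normal = normal / sqrt(sum(normal^2))),
                      class = "endplate_plane")
    fr <- build_screw_frame(plan, endp)
    dtip <- tail + 40 * axis + rnorm(3); dtail <- tail + rnorm(3)
    det <- detected_at(dtip, dtail)
    locus <- structure(list(point = tail + 12 * axis, arc_param = 12,
                            wall_distance = 1, side = "R", level = "T7"),
                       class = "mid_pedicle_locus")
    rec <- screw_errors(plan, det, rigid_transform(), fr, locus)

    # mirrored scene: x -> -x, side R -> L
    mplan <- make_plan(as.numeric(mirror %*% (tail + 40 * axis)),
                       as.numeric(mirror %*% tail), side = "L")
    mendp <- structure(list(point = c(0, 0, 0),
                            normal = as.numeric(mirror %*% endp$normal)),
                       class = "endplate_plane")
    mfr <- build_screw_frame(mplan, mendp)
    mdet <- detected_at(as.numeric(mirror %*% dtip),
                        as.numeric(mirror %*% dtail))
    mlocus <- structure(list(point = as.numeric(mirror %*% locus$point),
                             arc_param = 12, wall_distance = 1, side = "L",
                             level = "T7"), class = "mid_pedicle_locus")
    mrec <- screw_errors(mplan, mdet, rigid_transform(), mfr, mlocus)
    for (col in screwpose:::metric_columns())
      expect_equal(mrec[[col]], rec[[col]], tolerance = 1e-9)
  }
})

test_that("summaries compute SME, MAE and 2 SD as defined", {
  recs <- dplyr::bind_rows(
    screw_errors(make_plan(c(0, 40, 0), c(0, 0, 0)),
                 detected_at(c(1, 40, 0), c(1, 0, 0)),
                 rigid_transform(), simple_frame(), simple_locus()),
    screw_errors(make_plan(c(0, 40, 0), c(0, 0, 0)),
                 detected_at(c(-1, 40, 0), c(-1, 0, 0)),
                 rigid_transform(), simple_frame(), simple_locus()))
  s <- summarize_accuracy(recs)
  ml <- s[s$metric == "tail_ML", ]
  expect_equal(ml$sme, 0)
  expect_equal(ml$mae, 1)
  expect_equal(ml$precision_2sd, 2 * sqrt(2))
  # Euclidean columns carry MAE only
  e3 <- s[s$metric == "tail_3D", ]
  expect_true(is.na(e3$sme) && is.na(e3$precision_2sd))
  expect_equal(e3$mae, 1)

  zero <- dplyr::mutate(recs, dplyr::across(dplyr::all_of(
    screwpose:::metric_columns()), ~0))
  s0 <- summarize_accuracy(zero)
  expect_true(all(s0$mae == 0))

  # permutation invariance and the MAE >= |SME| inequality
  set.seed(32)
  big <- recs[sample(rep(1:2, 10)), ]
  for (col in screwpose:::metric_columns())
    big[[col]] <- rnorm(nrow(big))
  s1 <- summarize_accuracy(big)
  s2 <- summarize_accuracy(big[sample(nrow(big)), ])
  expect_equal(s1, s2)
  signed <- !s1$metric %in% screwpose:::euclidean_columns()
  expect_true(all(s1$mae[signed] >= abs(s1$sme[signed]) - 1e-12))
})

test_that("ground-truth deviations pass through a perfect pipeline", {
  set.seed(33)
  recs <- list(); planted <- list()
  for (i in 1:20) {
    tail <- c(5, 0, 0); tip <- c(5, 40, 0)
    plan <- make_plan(tip, tail, side = "L")
    dev_tail <- rnorm(3, sd = 0.8); dev_tip <- rnorm(3, sd = 0.8)
    det <- detected_at(tip + dev_tip, tail + dev_tail)
    recs[[i]] <- screw_errors(plan, det, rigid_transform(), simple_frame(),
                              simple_locus())
    planted[[i]] <- tibble::tibble(tip_ML = dev_tip[1], tip_AP = dev_tip[2],
                                   tip_SI = dev_tip[3])
  }
  recs <- dplyr::bind_rows(recs); planted <- dplyr::bind_rows(planted)
  expect_equal(recs$tip_ML, planted$tip_ML, tolerance = 1e-9)
  s <- summarize_accuracy(recs)
  expect_equal(s$sme[s$metric == "tip_ML"], mean(planted$tip_ML),
               tolerance = 1e-9)
  expect_equal(s$precision_2sd[s$metric == "tip_AP"], 2 * sd(planted$tip_AP),
               tolerance = 1e-9)
})

test_that("regional ANOVA flags planted group differences", {
  set.seed(34)
  recs <- tibble::tibble(
    level = rep(c("T3", "T9", "L2"), each = 12),
    region = screwpose::level_region(rep(c("T3", "T9", "L2"), each = 12)),
    mid_ML = c(rnorm(12, 0, 0.02), rnorm(12, 1, 0.02), rnorm(12, 0, 0.02)))
  cmp <- regional_comparison(recs, "mid_ML")
  expect_lt(cmp$anova$p.value[1], 0.01)
  worst <- cmp$pairwise[cmp$pairwise$group1 == "lower thoracic" |
                          cmp$pairwise$group2 == "lower thoracic", ]
  expect_true(all(worst$p.value < 0.01))
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1.0))
})

test_that("levels map to their spinal regions", {
  expect_equal(level_region(c("T2", "T6", "T7", "T12", "L1", "L4")),
               c("upper thoracic", "upper thoracic", "lower thoracic",
                 "lower thoracic", "lumbar", "lumbar"))
})
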