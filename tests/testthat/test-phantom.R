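test_that("phantom generation is bit-identical for identical spec and seed", {
  s <- coarse_spec(seed = 99)
  a <- generate_preop(s)
  b <- generate_preop(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$plans, b$plans)
})

test_that("a one-level phantom has one label and posterior-entry plans", {
  pre <- clean_preop()
  labs <- unique(as.integer(pre$mask$labels))
  expect_setequal(labs, c(0L, 1L))
  # tails posterior (smaller y) of tips, shaft length as specified
  expect_true(all(pre$plans$tail_y < pre$plans$tip_y))
  len <- sqrt((pre$plans$tip_x - pre$plans$tail_x)^2 +
                (pre$plans$tip_y - pre$plans$tail_y)^2 +
                (pre$plans$tip_z - pre$plans$tail_z)^2)
  expect_equal(len, pre$plans$length_mm, tolerance = 1e-9)
})

test_that("a noise-free, blur-free, bead-free scene has exactly the five plateaus", {
  s <- coarse_spec(seed = 5, noise_sd = 0, blur_sigma = 0, n_beads = 0,
                   texture_sd = 0)
  pre <- generate_preop(s)
  post <- generate_postop(pre, s)
  for (vol in list(pre$volume, post$volume)) {
    vals <- sort(unique(as.numeric(vol$data)))
    expect_true(all(vals %in% unname(s$intensities)))
  }
  expect_setequal(sort(unique(as.numeric(post$volume$data))),
                  unname(sort(s$intensities)))
})

test_that("metal voxels form one pre-blur component per screw", {
  s <- coarse_spec(seed = 5, noise_sd = 0, blur_sigma = 0, n_beads = 0,
                   texture_sd = 0)
  pre <- generate_preop(s)
  post <- generate_postop(pre, s)
  thr <- (s$intensities[["cortical"]] + s$intensities[["metal"]]) / 2
  comps <- detect_metal_components(post$volume, thr)
  expect_length(comps, 2L)
})

test_that("zero deviations and identity motions reproduce the plan exactly", {
  s <- coarse_spec(seed = 6, n_beads = 4)
  pre <- generate_preop(s)
  post <- generate_postop(pre, s)
  tr <- post$truth$screws
  expect_equal(tr$tip_post_x, pre$plans$tip_x, tolerance = 1e-9)
  expect_equal(tr$tail_post_z, pre$plans$tail_z, tolerance = 1e-9)
  expect_equal(tr$angle_true_deg, rep(0, nrow(tr)), tolerance = 1e-9)
})

test_that("pure translation motion translates the beads", {
  s <- coarse_spec(seed = 6, n_beads = 4)
  pre <- generate_preop(s)
  shift <- rigid_transform(translation = c(2, -1, 1.5))
  post <- generate_postop(pre, s, motions = list(shift))
  expect_equal(post$truth$beads_post,
               sweep(post$truth$beads_pre, 2, c(2, -1, 1.5), "+"),
               tolerance = 1e-12)
})

test_that("frame-resolved deviations invert back from ground-truth world points", {
  s <- coarse_spec(seed = 8)
  pre <- generate_preop(s)
  n <- nrow(pre$plans)
  devs <- tibble::tibble(tip_ML = rep(1, n), tip_AP = 0, tip_SI = 0,
                         tail_ML = 0, tail_AP = 0, tail_SI = 0)
  motions <- list(random_rigid_transform(5, 4))
  post <- generate_postop(pre, s, screw_deviations = devs, motions = motions)
  tr <- post$truth$screws
  for (i in seq_len(n)) {
    fr <- pre$truth$frames[[i]]
    # map true postop tip back to preop space, then resolve against plan
    tip_post <- c(tr$tip_post_x[i], tr$tip_post_y[i], tr$tip_post_z[i])
    tip_pre <- apply_transform(invert_transform(motions[[1]]), tip_post)
    offset <- tip_pre - screwpose:::plan_point(pre$plans[i, ], "tip")
    expect_equal(sum(offset * fr$e_ML), 1, tolerance = 1e-9)
    expect_equal(sum(offset * fr$e_AP), 0, tolerance = 1e-9)
    expect_equal(sum(offset * fr$e_SI), 0, tolerance = 1e-9)
  }
})

test_that("ground truth stays self-consistent under the declared motions", {
  case <- coarse_case()
  tr <- case$truth$screws
  for (i in seq_len(nrow(tr))) {
    M <- case$truth$motions[[tr$level[i]]]
    mapped <- apply_transform(M, c(tr$tip_pre_x[i], tr$tip_pre_y[i],
                                   tr$tip_pre_z[i]))
    expect_equal(mapped, c(tr$tip_post_x[i], tr$tip_post_y[i],
                           tr$tip_post_z[i]), tolerance = 1e-9)
  }
  lv <- case$truth$bead_levels
  for (b in seq_len(nrow(case$truth$beads_pre))) {
    mapped <- apply_transform(case$truth$motions[[lv[b]]],
                              case$truth$beads_pre[b, ])
    expect_equal(mapped, unname(case$truth$beads_post[b, ]),
                 tolerance = 1e-9)
  }
})

test_that("a motion pushing the vertebra out of field is rejected", {
  s <- coarse_spec(seed = 6, n_beads = 0)
  pre <- generate_preop(s)
  far <- rigid_transform(translation = c(60, 0, 0))
  expect_error(generate_postop(pre, s, motions = list(far)),
               "out of the field")
})

test_that("a phantom case round-trips through disk", {
  case <- coarse_case()
  dir <- tempfile("case")
  write_phantom_case(case, dir)
  plans <- read_screw_plans(file.path(dir, "plans.csv"))
  expect_equal(as.data.frame(plans), as.data.frame(case$plans),
               tolerance = 1e-9)
  mask <- read_label_mask(file.path(dir, "mask.nii.gz"),
                          case$mask$level_ids)
  expect_identical(mask$labels, case$mask$labels)
  pre <- read_ct_volume(file.path(dir, "preop.nii.gz"))
  expect_lt(max(abs(pre$data - case$preop$data)), 1e-4)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(nrow(truth$screws), nrow(case$plans))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(screw_radius = 5, pedicle_radius = 4.5),
               "smaller than the pedicle")
  expect_error(phantom_spec(intensities = c(air = 0, soft_tissue = -10,
                                            trabecular = 300,
                                            cortical = 1200, metal = 3000)),
               "plateaus")
  expect_error(phantom_spec(body_height = -1), "positive")
})
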