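test_that("SVD landmark alignment recovers exact rigid transforms", {
  set.seed(20)
  base <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 0), c(10, 5, 18))
  for (i in 1:50) {
    T1 <- random_rigid_transform(runif(1, 0, 170), runif(1, 0, 40))
    est <- svd_point_align(base, apply_transform(T1, base))
    expect_lt(max(abs(est$rotation - T1$rotation)), 1e-9)
    expect_lt(max(abs(est$translation - T1$translation)), 1e-9)
  }
  # identity case
  est0 <- svd_point_align(base, base)
  expect_lt(max(abs(est0$rotation - diag(3))), 1e-9)
})

test_that("reflections are corrected to proper rotations", {
  set.seed(21)
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  reflected <- base %*% diag(c(-1, 1, 1))
  est <- svd_point_align(base, reflected)
  expect_gt(det(est$rotation), 0.999)
})

test_that("degenerate inputs are flagged or rejected", {
  expect_error(svd_point_align(matrix(0, 1, 3), matrix(0, 1, 3)),
               "at least 2")
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(5, 0, 0))
  est <- svd_point_align(line, line)
  expect_true(attr(est, "degenerate"))
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_false(attr(svd_point_align(tetra, tetra), "degenerate"))
})

test_that("MI of a volume with itself equals its masked histogram entropy", {
  set.seed(22)
  a <- array(rnorm(12^3, 500, 200), c(12, 12, 12))
  v <- ct_volume(a, diag(c(0.5, 0.5, 0.625, 1)))
  m <- label_mask(array(1L, dim(a)), v$affine)
  n_bins <- 32
  mi <- mutual_information(v, v, rigid_transform(), m, 1, Inf, n_bins)
  # independent entropy oracle on the same binning rule
  lo <- min(a); hi <- max(a)
  bins <- pmin(floor((a - lo) / ((hi - lo) / n_bins)), n_bins - 1)
  p <- tabulate(bins + 1, n_bins)
  p <- p[p > 0] / sum(p)
  expect_equal(as.numeric(mi), -sum(p * log(p)), tolerance = 1e-9)
})

test_that("MI vanishes for a constant moving volume and ignores voxel order", {
  set.seed(23)
  a <- array(rnorm(10^3, 500, 100), c(10, 10, 10))
  v <- ct_volume(a, diag(4))
  m <- label_mask(array(1L, dim(a)), diag(4))
  flat <- ct_volume(array(7, dim(a)), diag(4))
  expect_equal(as.numeric(mutual_information(v, flat, rigid_transform(),
                                             m, 1)), 0, tolerance = 1e-12)

  perm <- sample(length(a))
  ap <- array(a[perm], dim(a))
  bp <- array((a * 2 + 10)[perm], dim(a))
  mi1 <- mutual_information(v, ct_volume(a * 2 + 10, diag(4)),
                            rigid_transform(), m, 1)
  mi2 <- mutual_information(ct_volume(ap, diag(4)), ct_volume(bp, diag(4)),
                            rigid_transform(), m, 1)
  expect_equal(as.numeric(mi1), as.numeric(mi2), tolerance = 1e-9)
})

test_that("self-registration stays at the identity", {
  pre <- clean_preop()
  plans <- pre$plans
  res <- register_level(pre$volume, pre$mask, "T7", pre$volume, plans,
                        list(), metal_threshold = 1e9,
                        init = rigid_transform())
  d <- transform_discrepancy(res$transform, rigid_transform(), res$centroid)
  expect_lt(d[["translation_mm"]], 0.05)
  expect_lt(d[["rotation_deg"]], 0.05)
  expect_gte(res$mi_final, res$mi_init)
})

test_that("registration recovers known phantom motion to sub-voxel beads", {
  det <- coarse_detected()
  case <- det$case
  res <- register_level(case$preop, case$mask, "T7", case$postop,
                        case$plans, det$screws, det$threshold)
  expect_gte(res$mi_final, res$mi_init)
  fs <- fiducial_set(case$truth$beads_pre, case$truth$beads_post)
  fre <- fiducial_registration_error(fs, res$transform)
  expect_lt(fre$mae_mm, max(case$preop$spacing))  # sub-voxel
  fixture_env$coarse_reg <- res
})

test_that("registration is deterministic", {
  det <- coarse_detected()
  case <- det$case
  r1 <- register_level(case$preop, case$mask, "T7", case$postop,
                       case$plans, det$screws, det$threshold)
  r2 <- register_level(case$preop, case$mask, "T7", case$postop,
                       case$plans, det$screws, det$threshold)
  expect_identical(r1$transform$rotation, r2$transform$rotation)
  expect_identical(r1$transform$translation, r2$transform$translation)
  expect_identical(r1$mi_final, r2$mi_final)
})

test_that("an empty perturbation run yields an empty report", {
  det <- coarse_detected()
  case <- det$case
  base <- fixture_env$coarse_reg
  if (is.null(base))
    base <- register_level(case$preop, case$mask, "T7", case$postop,
                           case$plans, det$screws, det$threshold)
  rep0 <- perturbation_analysis(case$preop, case$mask, case$postop,
                                case$plans, det$screws, det$threshold,
                                base, n = 0)
  expect_equal(rep0$n_perturbations, 0)
  expect_equal(nrow(rep0$replicates), 0)
})

test_that("perturbed restarts reconverge near the baseline", {
  det <- coarse_detected()
  case <- det$case
  base <- fixture_env$coarse_reg
  if (is.null(base))
    base <- register_level(case$preop, case$mask, "T7", case$postop,
                           case$plans, det$screws, det$threshold)
  rep2 <- perturbation_analysis(case$preop, case$mask, case$postop,
                                case$plans, det$screws, det$threshold,
                                base, n = 3, seed = 77)
  expect_equal(nrow(rep2$replicates), 3)
  expect_true(all(rep2$replicates$translation_mm >= 0))
  expect_lt(rep2$mean_translation_mm, 0.3)
  expect_lt(rep2$mean_rotation_deg, 0.3)
  # glance/tidy interfaces
  expect_equal(nrow(tidy(rep2)), 3)
  expect_equal(glance(rep2)$n_perturbations, 3)
})
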