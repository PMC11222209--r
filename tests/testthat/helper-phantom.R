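# Shared fixtures, built once per test run. Unit tests use a coarsened
# phantom (0.8 mm isotropic voxels, tighter margins, lighter noise) so each
# file stays fast; acceptance checks use the study-scale phantom.

fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, fn) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- fn()
  fixture_env[[key]]
}

coarse_spec <- function(seed = 42, ...) {
  args <- list(spacing = c(0.8, 0.8, 0.8), margin = c(10, 10, 9),
               noise_sd = 10, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# a complete simulated coarse case with moderate motion and deviations
coarse_case <- function() {
  memo_fixture("coarse_case", function() {
    simulate_case(coarse_spec(), motion_deg = 6, motion_mm = 6,
                  dev_mm = 1, dev_deg = 1.5)
  })
}

coarse_threshold <- function(spec = coarse_spec()) {
  ints <- spec$intensities
  (ints[["cortical"]] + ints[["metal"]]) / 2
}

# coarse case plus detections with level/side assigned
coarse_detected <- function() {
  memo_fixture("coarse_detected", function() {
    case <- coarse_case()
    thr <- coarse_threshold(case$spec)
    screws <- detect_screws(case$postop, case$plans, thr)
    m <- match_screws_to_plans(screws, case$plans)
    for (r in seq_len(nrow(m$pairs))) {
      j <- m$pairs$detection[r]
      screws[[j]]$level <- m$pairs$level[r]
      screws[[j]]$side <- m$pairs$side[r]
    }
    list(case = case, screws = screws, matches = m, threshold = thr)
  })
}

# noise-free, blur-free preop at coarse resolution (mask-only tests)
clean_preop <- function() {
  memo_fixture("clean_preop", function() {
    generate_preop(coarse_spec(seed = 7, noise_sd = 0, blur_sigma = 0,
                               n_beads = 0))
  })
}

# a small synthetic volume holding one metal capsule, for detector tests
capsule_volume <- function(tip, tail, radius = 2.25, spacing = 0.5,
                           metal = 3000, background = 40, blur = 0.3,
                           pad = 8) {
  lo <- pmin(tip, tail) - pad
  hi <- pmax(tip, tail) + pad
  dims <- ceiling((hi - lo) / spacing)
  aff <- rbind(cbind(diag(rep(spacing, 3)), lo), c(0, 0, 0, 1))
  vol <- ct_volume(array(background, dims), aff)
  idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                               seq_len(dims[3])))
  w <- voxel_to_world(vol, idx - 1)
  ab <- tip - tail
  t <- pmin(pmax(sweep(w, 2, tail) %*% ab / sum(ab^2), 0), 1)
  d <- sqrt(rowSums((sweep(w, 2, tail) - t %*% t(ab))^2))
  data <- vol$data
  data[idx[d <= radius, , drop = FALSE]] <- metal
  out <- ct_volume(data, aff)
  if (blur > 0) out <- smooth_volume(out, blur)
  out
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# a synthetic screw plan row (tibble) from raw geometry
make_plan <- function(tip, tail, side = "L", level = "T7", radius = 2.25) {
  tibble::tibble(level = level, side = side,
                 tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
                 tail_x = tail[1], tail_y = tail[2], tail_z = tail[3],
                 radius_mm = radius,
                 length_mm = sqrt(sum((tip - tail)^2)))
}
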