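#' Phantom validation study: registration accuracy, perturbation
#' consistency and end-to-end parameter recovery
#'
#' Runs the fully automated pipeline on a cohort of seeded single-level
#' phantom cases (inter-scan motions up to 10 degrees / 10 mm, planted screw
#' deviations on the Table-1 scale, four embedded 1 mm beads, noise
#' sigma 20 HU by default) and measures, with no ground-truth input to any
#' pipeline stage:
#' \itemize{
#'   \item bead alignment error of the final registration against the
#'     phantom's true bead positions (pure registration error), and against
#'     automatically detected beads (the full fiducial-validation protocol,
#'     beads masked out during registration);
#'   \item perturbation consistency: registrations restarted from `n_perturb`
#'     random rigid perturbations of the initialization (2 degrees / 2 mm by
#'     default) compared to the unperturbed baseline;
#'   \item end-to-end recovery of the planted per-screw frame-resolved
#'     deviations (detection + registration + frames + error measurement vs
#'     the generator's ground truth).
#' }
#'
#' @param seed Master integer seed; case `i` uses `seed * 1000 + i`.
#' @param n_cases Number of phantom cases (one vertebral level each).
#' @param n_perturb_levels Number of cases also subjected to the
#'   perturbation protocol.
#' @param n_perturb Perturbation replicates per level.
#' @param rot_deg,trans_mm Perturbation magnitudes.
#' @param noise_sd Phantom noise SD (HU).
#' @param motion_deg,motion_mm Maximum inter-scan motion per level.
#' @param dev_mm,dev_deg Maximum planted screw deviation (translation of the
#'   shaft and rotation about its tail).
#' @param spec_fun Optional function(seed) returning a [phantom_spec()],
#'   for customized cohorts.
#' @param verbose Print per-case progress.
#' @return List of tibbles: `bead_truth` (per-bead registration error vs
#'   true bead positions), `bead_detected` (per-bead fiducial errors from
#'   automated bead detection), `perturbation` (per-replicate discrepancies),
#'   `recovery` (per-screw planted vs recovered deviations), and
#'   `registrations` (per-case summaries).
#' @export
run_validation_study <- function(seed = 1, n_cases = 10,
                                 n_perturb_levels = 5, n_perturb = 10,
                                 rot_deg = 2, trans_mm = 2,
                                 noise_sd = 20, motion_deg = 10,
                                 motion_mm = 10, dev_mm = 1.5, dev_deg = 2,
                                 spec_fun = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  bead_truth <- list(); bead_det <- list(); pert <- list()
  recovery <- list(); regs <- list()
  for (ci in seq_len(n_cases)) {
    case_seed <- seed * 1000 + ci
    spec <- if (is.null(spec_fun)) {
      phantom_spec(noise_sd = noise_sd, seed = case_seed)
    } else spec_fun(case_seed)
    say("case ", ci, " (seed ", case_seed, ")")
    case <- simulate_case(spec, motion_deg = motion_deg,
                          motion_mm = motion_mm, dev_mm = dev_mm,
                          dev_deg = dev_deg)
    ints <- spec$intensities
    thr <- (ints[["cortical"]] + ints[["metal"]]) / 2
    bead_thr <- bead_detection_threshold(ints[["trabecular"]],
                                         ints[["metal"]])
    screws <- detect_screws(case$postop, case$plans, thr)
    matches <- match_screws_to_plans(screws, case$plans)
    for (r in seq_len(nrow(matches$pairs))) {
      j <- matches$pairs$detection[r]
      screws[[j]]$level <- matches$pairs$level[r]
      screws[[j]]$side <- matches$pairs$side[r]
    }
    # automated bead identification in both scans
    screw_comps <- detect_metal_components(case$postop, thr,
                                           0.5 * pi * spec$screw_radius^2 *
                                             spec$screw_length)
    prom <- 0.25 * (ints[["metal"]] - ints[["trabecular"]])
    beads_pre_det <- detect_beads(case$preop, bead_thr, spec$bead_diameter,
                                  min_prominence = prom)
    beads_post_det <- detect_beads(case$postop, bead_thr,
                                   spec$bead_diameter,
                                   exclusion = screw_comps,
                                   min_prominence = prom)
    # beads are masked out of the registration metric on both sides
    excl_mov <- bead_exclusion_mask(case$postop, beads_post_det,
                                    spec$bead_diameter)
    excl_fix <- bead_exclusion_logical(case$preop, beads_pre_det,
                                       spec$bead_diameter)
    lv <- case$plans$level[1]
    reg <- register_level(case$preop, case$mask, lv, case$postop,
                          case$plans, screws, thr, exclusion = excl_mov,
                          fixed_exclude = excl_fix)
    regs[[ci]] <- dplyr::mutate(glance(reg), case = ci, .before = 1)
    # bead error vs ground-truth bead positions (registration error alone);
    # truth beads are row-matched by construction, so no pairing search
    fs_truth <- structure(list(pre = case$truth$beads_pre,
                               post = case$truth$beads_post,
                               usable = rep(TRUE, nrow(case$truth$beads_pre))),
                          class = "fiducial_set")
    fre_truth <- fiducial_registration_error(fs_truth, reg$transform)
    bead_truth[[ci]] <- dplyr::mutate(fre_truth$per_bead, case = ci,
                                      .before = 1)
    # bead error with automated identification (full fiducial protocol)
    fs_det <- fiducial_set(beads_pre_det, beads_post_det,
                           coarse_transform = reg$transform,
                           max_pair_mm = 3)
    if (sum(fs_det$usable) > 0) {
      fre_det <- fiducial_registration_error(fs_det, reg$transform)
      bead_det[[ci]] <- dplyr::mutate(fre_det$per_bead, case = ci,
                                      .before = 1)
    }
    if (ci <= n_perturb_levels && n_perturb > 0) {
      say("  perturbation x", n_perturb)
      pr <- perturbation_analysis(case$preop, case$mask, case$postop,
                                  case$plans, screws, thr, reg,
                                  n = n_perturb, rot_deg = rot_deg,
                                  trans_mm = trans_mm,
                                  seed = case_seed + 500,
                                  exclusion = excl_mov,
                                  fixed_exclude = excl_fix)
      pert[[ci]] <- dplyr::mutate(pr$replicates, case = ci, level = lv,
                                  .before = 1)
    }
    recovery[[ci]] <- recovery_records(case, screws, matches, reg, ci)
  }
  list(bead_truth = dplyr::bind_rows(bead_truth),
       bead_detected = dplyr::bind_rows(bead_det),
       perturbation = dplyr::bind_rows(pert),
       recovery = dplyr::bind_rows(recovery),
       registrations = dplyr::bind_rows(regs))
}

# per-screw planted vs recovered frame-resolved deviations for one case
recovery_records <- function(case, screws, matches, reg, ci) {
  rows <- list()
  truth <- case$truth$screws
  for (r in seq_len(nrow(matches$pairs))) {
    i <- matches$pairs$plan[r]; j <- matches$pairs$detection[r]
    plan <- case$plans[i, ]
    endp <- fit_endplate_plane(case$mask, plan$level)
    frame <- build_screw_frame(plan, endp)
    locus <- locate_mid_pedicle(plan, case$mask)
    rec <- screw_errors(plan, screws[[j]], reg$transform, frame, locus)
    tr <- truth[truth$level == plan$level & truth$side == plan$side, ]
    rows[[r]] <- dplyr::mutate(
      rec, case = ci,
      true_tip_ML = tr$tip_ML, true_tip_AP = tr$tip_AP,
      true_tip_SI = tr$tip_SI,
      true_tail_ML = tr$tail_ML, true_tail_AP = tr$tail_AP,
      true_tail_SI = tr$tail_SI,
      true_angle_deg = tr$angle_true_deg)
  }
  dplyr::bind_rows(rows)
}
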