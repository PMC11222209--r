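#' Angular deviation between two direction vectors
#'
#' Composite angular error: arccosine of the clamped dot product, in
#' degrees, symmetric in its arguments.
#'
#' @param a,b Unit (or at least nonzero) 3-vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angular_deviation <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("invalid zero-length direction vector")
  acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Per-screw placement error in the screw-aligned frame
#'
#' Maps the planned tip, tail and mid-pedicle locus through the level's
#' registration transform into postoperative space, carries the screw frame
#' axes through the transform's rotation (so errors stay expressed in the
#' anatomically anchored planned frame regardless of inter-scan motion), and
#' resolves the detected-vs-planned deviations:
#' tip and tail errors are the ML/AP/SI components of the detected minus
#' mapped-planned landmark; the mid-pedicle error is the in-plane (ML, SI)
#' offset of the point where the detected axis pierces the plane through the
#' mapped locus normal to the mapped AP axis; the angle is the angle between
#' mapped planned axis and detected axis.
#'
#' @param plan One plan row.
#' @param detected The matched `detected_screw` (postoperative space).
#' @param transform The level's [rigid_transform()] (preop to postop world).
#' @param frame The plan's `screw_frame` ([build_screw_frame()]).
#' @param locus The plan's `mid_pedicle_locus` ([locate_mid_pedicle()]).
#' @return One-row tibble (an accuracy record): level, side, region,
#'   tail_ML/AP/SI, tip_ML/AP/SI, mid_ML/SI, tail_3D, tip_3D, mid_2D (mm)
#'   and angle_deg.
#' @export
screw_errors <- function(plan, detected, transform, frame, locus) {
  R <- transform$rotation
  tip_p <- apply_transform(transform, plan_point(plan, "tip"))
  tail_p <- apply_transform(transform, plan_point(plan, "tail"))
  locus_p <- apply_transform(transform, locus$point)
  e_ML <- as.numeric(R %*% frame$e_ML)
  e_AP <- as.numeric(R %*% frame$e_AP)
  e_SI <- as.numeric(R %*% frame$e_SI)
  tip_err <- detected$tip - tip_p
  tail_err <- detected$tail - tail_p
  # detected axis pierces the plane through locus_p with normal e_AP
  denom <- sum(detected$axis * e_AP)
  if (abs(denom) < 1e-9)
    stop("detected axis parallel to the mid-pedicle plane")
  t_hit <- sum((locus_p - detected$tail) * e_AP) / denom
  hit <- detected$tail + t_hit * detected$axis
  mid_err <- hit - locus_p
  rec <- tibble::tibble(
    level = plan$level, side = plan$side, region = level_region(plan$level),
    tail_ML = sum(tail_err * e_ML), tail_AP = sum(tail_err * e_AP),
    tail_SI = sum(tail_err * e_SI),
    mid_ML = sum(mid_err * e_ML), mid_SI = sum(mid_err * e_SI),
    tip_ML = sum(tip_err * e_ML), tip_AP = sum(tip_err * e_AP),
    tip_SI = sum(tip_err * e_SI),
    angle_deg = angular_deviation(as.numeric(R %*% frame$e_AP),
                                  detected$axis))
  dplyr::mutate(rec,
                tail_3D = sqrt(.data$tail_ML^2 + .data$tail_AP^2 + .data$tail_SI^2),
                mid_2D = sqrt(.data$mid_ML^2 + .data$mid_SI^2),
                tip_3D = sqrt(.data$tip_ML^2 + .data$tip_AP^2 + .data$tip_SI^2))
}

#' Spinal region of a vertebral level
#'
#' Upper thoracic (T2-T6), lower thoracic (T7-T12), lumbar (L1-L4).
#' @param level Character vector of level names.
#' @return Character vector of regions.
#' @export
level_region <- function(level) {
  num <- suppressWarnings(as.integer(sub("^[TL]", "", level)))
  out <- rep(NA_character_, length(level))
  thoracic <- grepl("^T", level)
  out[thoracic & num <= 6] <- "upper thoracic"
  out[thoracic & num >= 7] <- "lower thoracic"
  out[grepl("^L", level)] <- "lumbar"
  out
}

metric_columns <- function() {
  c("tail_ML", "tail_AP", "tail_SI", "tail_3D", "mid_ML", "mid_SI", "mid_2D",
    "tip_ML", "tip_AP", "tip_SI", "tip_3D", "angle_deg")
}

euclidean_columns <- function() c("tail_3D", "mid_2D", "tip_3D")

#' Accuracy and precision summary (SME / MAE / 2 SD)
#'
#' Rolls per-screw accuracy records up into, per metric column: the signed
#' mean error (SME, systematic bias), the mean absolute error (MAE,
#' accuracy) and the precision expressed as 2 sample standard deviations
#' (n - 1 denominator) of the signed errors. Euclidean composite columns
#' (tail_3D, mid_2D, tip_3D) report MAE only -- a signed mean is undefined
#' for them, so SME and precision are `NA`. Groups with fewer than two
#' records report `NA` precision.
#'
#' @param records Tibble of accuracy records ([screw_errors()] rows).
#' @param group `"all"` for a single summary or `"region"` for per-region
#'   summaries.
#' @return Tibble with columns group, metric, n, sme, mae, precision_2sd.
#' @export
summarize_accuracy <- function(records, group = c("all", "region")) {
  group <- match.arg(group)
  grouped <- if (group == "region") {
    dplyr::group_by(records, group = .data$region)
  } else {
    dplyr::group_by(dplyr::mutate(records, group = "all"), .data$group)
  }
  long <- tidyr::pivot_longer(grouped, dplyr::all_of(metric_columns()),
                              names_to = "metric", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$metric),
    n = dplyr::n(),
    sme = mean(.data$value),
    mae = mean(abs(.data$value)),
    precision_2sd = if (dplyr::n() >= 2) 2 * sd(.data$value) else NA_real_,
    .groups = "drop")
  out <- dplyr::mutate(out,
    sme = ifelse(.data$metric %in% euclidean_columns(), NA_real_, .data$sme),
    precision_2sd = ifelse(.data$metric %in% euclidean_columns(), NA_real_,
                           .data$precision_2sd))
  dplyr::arrange(out, .data$group,
                 match(.data$metric, metric_columns()))
}

#' Regional accuracy comparison (one-way ANOVA + Bonferroni)
#'
#' One-way ANOVA of absolute errors across spinal regions for a chosen
#' metric, with all-pairs post hoc t-tests and Bonferroni-multiplied
#' p-values (capped at 1).
#'
#' @param records Accuracy record tibble with a `region` column.
#' @param metric Metric column name (e.g. `"mid_ML"`).
#' @return List with `anova` (tibble: term, df, sumsq, meansq, statistic,
#'   p.value), `pairwise` (tibble: group1, group2, p.value adjusted), and
#'   `metric`.
#' @export
regional_comparison <- function(records, metric = "mid_ML") {
  stopifnot(metric %in% names(records))
  dat <- data.frame(value = abs(records[[metric]]),
                    region = factor(records$region))
  present <- table(dat$region)
  if (length(present) < 3)
    warning("only ", length(present), " regions present; comparing those")
  if (sum(present >= 2) < 2) stop("need at least two regions with n >= 2")
  fit <- aov(value ~ region, data = dat)
  s <- summary(fit)[[1]]
  an <- tibble::tibble(term = trimws(rownames(s)), df = s$Df,
                       sumsq = s[["Sum Sq"]], meansq = s[["Mean Sq"]],
                       statistic = s[["F value"]], p.value = s[["Pr(>F)"]])
  pw <- pairwise.t.test(dat$value, dat$region, p.adjust.method = "bonferroni",
                        pool.sd = FALSE)
  pm <- pw$p.value
  pairs <- list()
  for (i in seq_len(nrow(pm)))
    for (j in seq_len(ncol(pm)))
      if (!is.na(pm[i, j]))
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          group1 = colnames(pm)[j], group2 = rownames(pm)[i],
          p.value = pm[i, j])
  list(anova = an, pairwise = dplyr::bind_rows(pairs), metric = metric)
}

#' Bonferroni adjustment
#'
#' Multiplies raw p-values by the number of comparisons, capping at 1.
#' @param p Numeric vector of raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) pmin(p * m, 1)
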