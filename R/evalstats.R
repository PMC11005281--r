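# Agreement and detection-accuracy statistics: mean radial error, mean
# absolute difference with angle-deviation rates, Bland-Altman limits of
# agreement, and Pearson chi-square subgroup tests.

#' Mean radial error
#'
#' Arithmetic mean of the Euclidean distances between predicted and
#' reference landmark positions, `MRE = (1/n) * sum(R_i)`; the unit (pixels
#' or millimetres) is whatever the radial errors carry.
#'
#' @param radial_errors Nonnegative numeric vector of per-landmark radial
#'   errors.
#' @return The mean radial error.
#' @examples
#' mre(c(1.2, 0.8, 2.0))
#' @export
mre <- function(radial_errors) {
  radial_errors <- as.numeric(radial_errors)
  if (length(radial_errors) == 0)
    abort("MRE is undefined for zero detected landmarks.",
          class = "limbalign_stat_error")
  if (any(!is.finite(radial_errors)) || any(radial_errors < 0))
    abort("Radial errors must be finite and nonnegative.",
          class = "limbalign_stat_error")
  mean(radial_errors)
}

#' Radial errors between two landmark sets
#'
#' @param reference,prediction n x 2 coordinate matrices (or
#'   [limb_landmarks]).
#' @param spacing_mm Optional mm/pixel factor; when given, errors are
#'   returned in millimetres.
#' @return Numeric vector of Euclidean distances.
#' @export
radial_errors <- function(reference, prediction, spacing_mm = NULL) {
  gx <- if (inherits(reference, "limb_landmarks")) reference$xy else
    as.matrix(reference)
  px <- if (inherits(prediction, "limb_landmarks")) prediction$xy else
    as.matrix(prediction)
  stopifnot(nrow(gx) == nrow(px))
  r <- sqrt(rowSums((gx - px)^2))
  if (!is.null(spacing_mm)) r <- r * spacing_mm
  unname(r)
}

#' Analytic mean radial error of a uniform-random predictor
#'
#' Closed-form expected Euclidean distance between two independent uniform
#' points in a `width` x `height` rectangle — the reference level any
#' learned landmark detector must beat. For a unit square this is
#' 0.52140543.
#'
#' @param width,height Frame size in pixels.
#' @return Expected distance in pixels.
#' @examples
#' uniform_mre_baseline(64, 128)
#' @export
uniform_mre_baseline <- function(width, height) {
  a <- width; b <- height
  d <- sqrt(a^2 + b^2)
  (1 / 15) * (a^3 / b^2 + b^3 / a^2 + d * (3 - a^2 / b^2 - b^2 / a^2)) +
    (1 / 6) * (b^2 / a * acosh(d / b) + a^2 / b * acosh(d / a))
}

#' Agreement between reference and predicted angles
#'
#' Differences are `prediction - reference`. Reports the mean absolute
#' difference (MAD) with the sample standard deviation of the absolute
#' differences, the fraction of limbs with absolute deviation strictly
#' below each threshold (AD < 1 degree and AD < 2 degrees by default), and
#' the Bland-Altman bias with 95% limits of agreement
#' `bias +/- 1.96 * sd(differences)` (sample standard deviation, n - 1
#' denominator).
#'
#' @param reference,prediction Equal-length numeric vectors of angles
#'   (degrees). Limits of agreement need at least two pairs.
#' @param thresholds Angle-deviation thresholds in degrees.
#' @return A list of class `agreement_report`: `n`, `mad`, `mad_sd`,
#'   `ad` (named fractions), `bias`, `loa_low`, `loa_high`, plus the raw
#'   `differences` and pair `means` for plotting.
#' @examples
#' agreement(c(0, 1, 2), c(0.2, 0.9, 2.4))
#' @export
agreement <- function(reference, prediction, thresholds = c(1, 2)) {
  if (length(reference) != length(prediction))
    abort("`reference` and `prediction` must have equal length.",
          class = "limbalign_stat_error")
  if (length(reference) < 1)
    abort("At least one pair is required.", class = "limbalign_stat_error")
  d <- prediction - reference
  if (any(!is.finite(d)))
    abort("Angles must be finite.", class = "limbalign_stat_error")
  ad <- vapply(thresholds, function(th) mean(abs(d) < th), 1)
  names(ad) <- paste0("ad_lt_", thresholds)
  sdd <- if (length(d) >= 2) stats::sd(d) else NA_real_
  structure(list(
    n = length(d),
    mad = mean(abs(d)),
    mad_sd = if (length(d) >= 2) stats::sd(abs(d)) else NA_real_,
    ad = ad, thresholds = thresholds,
    bias = mean(d),
    loa_low = if (is.na(sdd)) NA_real_ else mean(d) - 1.96 * sdd,
    loa_high = if (is.na(sdd)) NA_real_ else mean(d) + 1.96 * sdd,
    differences = d, means = (prediction + reference) / 2),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n  MAD %.3f +/- %.3f deg\n", x$n,
              x$mad, x$mad_sd))
  for (i in seq_along(x$ad))
    cat(sprintf("  AD < %g deg: %.2f%%\n", x$thresholds[i], 100 * x$ad[i]))
  cat(sprintf("  Bland-Altman bias %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, `df = (r - 1)(c - 1)`, p-value from the upper chi-square
#' tail. No multiplicity adjustment is applied.
#'
#' @param counts r x c matrix of nonnegative counts with at least two rows
#'   and columns and no zero marginal.
#' @return Tibble with `statistic`, `df`, `p_value`, `n`.
#' @examples
#' pearson_chi_square(matrix(c(50, 187, 8, 12), 2, 2))
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    abort("Counts must be finite and nonnegative.",
          class = "limbalign_stat_error")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    abort("Need at least a 2 x 2 table.", class = "limbalign_stat_error")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort("Degenerate table: zero row or column marginal.",
          class = "limbalign_stat_error")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value), n = sum(counts))
}

#' Per-angle agreement report for joined angle tables
#'
#' Joins a reference and a prediction angle table on `image_id` + `side`
#' and computes an [agreement] report per angle column.
#'
#' @param reference,prediction Data frames with columns `image_id`, `side`
#'   and the five angle columns (`hka`, `jcla`, `ama`, `mldfa`, `mmpta`, or
#'   any subset).
#' @param angles Angle columns to evaluate (defaults to those present in
#'   both tables).
#' @param thresholds Passed to [agreement].
#' @return Tibble with one row per angle: `angle`, `n`, `mad`, `mad_sd`,
#'   the AD fractions, `bias`, `loa_low`, `loa_high`; the per-angle
#'   reports in attribute `"reports"`.
#' @export
evaluate_angles <- function(reference, prediction, angles = NULL,
                            thresholds = c(1, 2)) {
  all_angles <- c("hka", "jcla", "ama", "mldfa", "mmpta")
  angles <- angles %||%
    intersect(all_angles, intersect(names(reference), names(prediction)))
  if (length(angles) == 0) abort("No shared angle columns to evaluate.")
  j <- dplyr::inner_join(reference, prediction, by = c("image_id", "side"),
                         suffix = c("_ref", "_pred"))
  if (nrow(j) == 0)
    abort("No image_id/side keys in common between the two tables.",
          class = "limbalign_stat_error")
  reports <- purrr::map(angles, function(a) {
    agreement(j[[paste0(a, "_ref")]], j[[paste0(a, "_pred")]], thresholds)
  })
  names(reports) <- angles
  out <- purrr::map2_dfr(angles, reports, function(a, r) {
    dplyr::bind_cols(tibble(angle = a), tidy_agreement_row(r))
  })
  attr(out, "reports") <- reports
  out
}

tidy_agreement_row <- function(r) {
  ad <- as.list(r$ad)
  dplyr::bind_cols(tibble(n = r$n, mad = r$mad, mad_sd = r$mad_sd),
                   as_tibble(ad),
                   tibble(bias = r$bias, loa_low = r$loa_low,
                          loa_high = r$loa_high))
}

#' Chi-square subgroup comparison of detection accuracy
#'
#' Cross-tabulates accurate (absolute HKA deviation strictly below
#' `accuracy_threshold`) versus inaccurate limbs across the levels of a
#' grouping variable and applies [pearson_chi_square] per grouping
#' variable.
#'
#' @param data Data frame with a reference column, a prediction column and
#'   one or more grouping columns.
#' @param reference,prediction Column names of the two angle measurements.
#' @param groups Character vector of grouping column names.
#' @param accuracy_threshold Degrees (default 1).
#' @return Tibble with one row per grouping variable: `group`, `statistic`,
#'   `df`, `p_value`; the underlying tables in attribute `"tables"`.
#' @export
subgroup_chi_square <- function(data, reference = "hka_ref",
                                prediction = "hka_pred", groups,
                                accuracy_threshold = 1) {
  acc <- abs(data[[prediction]] - data[[reference]]) < accuracy_threshold
  tables <- purrr::map(groups, function(g) {
    table(factor(data[[g]]), factor(acc, levels = c(TRUE, FALSE),
                                    labels = c("accurate", "inaccurate")))
  })
  names(tables) <- groups
  out <- purrr::map2_dfr(groups, tables, function(g, tb) {
    dplyr::bind_cols(tibble(group = g),
                     pearson_chi_square(unclass(tb))[, c("statistic", "df",
                                                         "p_value")])
  })
  attr(out, "tables") <- tables
  out
}
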