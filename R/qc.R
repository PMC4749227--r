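#' Flag a milk batch by measured-versus-predicted osmolality
#'
#' A batch is flagged when the absolute measured-minus-predicted difference
#' exceeds the model's QC threshold (suspected preparation error) or the
#' measured osmolality strictly exceeds the safety limit. Both comparisons
#' are strict, so values at the threshold pass.
#'
#' @param measured Measured osmolality, mOsm/kg (> 0). Vectorized.
#' @param predicted Predicted osmolality, mOsm/kg (> 0). Vectorized.
#' @param model An [osmolality_model()].
#' @param sample_id Optional identifier(s).
#' @return A tibble (one row per batch) with columns `sample_id`, `measured`,
#'   `predicted`, `difference` (measured - predicted), `flagged` and `reason`
#'   (one of `"none"`, `"deviation"`, `"safety_limit"`, `"both"`).
#' @export
#' @examples
#' flag_batch(470, 438, default_model()) # deviation 32 and over the limit
flag_batch <- function(measured, predicted, model, sample_id = NULL) {
  if (!is.numeric(measured) || !is.numeric(predicted))
    stop("`measured` and `predicted` must be numeric", call. = FALSE)
  if (length(predicted) != length(measured))
    stop("`measured` and `predicted` lengths differ", call. = FALSE)
  if (anyNA(measured) || anyNA(predicted) ||
      any(measured <= 0) || any(predicted <= 0))
    stop("osmolalities must be positive and non-missing", call. = FALSE)
  if (is.null(sample_id)) sample_id <- as.character(seq_along(measured))
  difference <- measured - predicted
  dev <- abs(difference) > model$qc_threshold
  lim <- measured > model$safety_limit
  reason <- rep("none", length(measured))
  reason[dev & !lim] <- "deviation"
  reason[!dev & lim] <- "safety_limit"
  reason[dev & lim] <- "both"
  tibble::tibble(sample_id = as.character(sample_id),
                 measured = measured, predicted = predicted,
                 difference = difference, flagged = dev | lim,
                 reason = reason)
}

#' Cohort agreement between measured and predicted osmolality
#'
#' Summarises measured-minus-predicted differences across a cohort: mean,
#' sample SD, Bland-Altman limits of agreement (mean +/- 1.96 SD), the
#' fraction of flagged batches, and a one-sample t statistic for mean
#' difference different from zero (reported, not thresholded).
#'
#' @param records A tibble from [flag_batch()], or any data frame with
#'   columns `difference` and `flagged` (or `measured` and `predicted`, from
#'   which differences and flags are computed with `model`).
#' @param model An [osmolality_model()]; only needed when flags must be
#'   computed from raw measured/predicted columns.
#' @return A list of class `agreement_stats`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `flag_rate`, `t_stat`, `p_value`.
#' @export
#' @examples
#' rec <- flag_batch(c(291, 303, 314), c(299, 300, 300), default_model())
#' agreement_stats(rec)
agreement_stats <- function(records, model = NULL) {
  d <- as.data.frame(records)
  if (!"difference" %in% names(d)) {
    if (!all(c("measured", "predicted") %in% names(d)))
      stop("`records` needs `difference` or `measured`+`predicted` columns",
           call. = FALSE)
    if (is.null(model))
      stop("supply `model` to compute flags from measured/predicted",
           call. = FALSE)
    d <- flag_batch(d$measured, d$predicted, model,
                    sample_id = d$sample_id %||% NULL)
  }
  n <- nrow(d)
  if (n < 2L)
    stop("insufficient data: agreement statistics need n >= 2", call. = FALSE)
  m <- mean(d$difference)
  s <- stats::sd(d$difference)
  t_stat <- if (s > 0) m / (s / sqrt(n)) else if (m == 0) 0 else Inf
  p_value <- if (is.finite(t_stat)) {
    2 * stats::pt(-abs(t_stat), df = n - 1)
  } else 0
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         flag_rate = if ("flagged" %in% names(d)) mean(d$flagged) else NA_real_,
         t_stat = t_stat, p_value = p_value),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n = %d: difference %.1f +/- %.1f mOsm/kg, LoA [%.1f, %.1f], %.1f%% flagged\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, 100 * x$flag_rate))
  invisible(x)
}

#' Seeded preparation-error detection experiment
#'
#' Simulates a clinical cohort with a known fraction of mis-prepared batches
#' (a fixed osmolality shift injected on top of measurement noise), runs the
#' deviation-based QC flag on every batch, and reports how many injected
#' errors were caught (sensitivity) and how many clean batches were flagged
#' (false-flag rate). Only deviation flags count here: safety-limit flags
#' respond to the feed's absolute osmolality, not to preparation errors, and
#' would contaminate both rates in a cohort that sits near the limit.
#'
#' @param n Cohort size (ignored when `cohort` is supplied).
#' @param error_rate Fraction of batches with an injected error, in \[0, 1\].
#' @param error_magnitude Injected shift in mOsm/kg.
#' @param noise_sd Measurement noise SD in mOsm/kg.
#' @param model An [osmolality_model()].
#' @param seed Integer seed; the experiment is deterministic given it.
#' @param cohort Optional pre-generated cohort from [simulate_cohort()]
#'   (must carry `measured_osm`, `predicted_osm`, `is_error`).
#' @return A list: `sensitivity`, `false_flag_rate`, `n_errors`, `n_clean`,
#'   `threshold`.
#' @export
#' @examples
#' error_detection_experiment(n = 200, seed = 42)
error_detection_experiment <- function(n = 1000, error_rate = 0.05,
                                       error_magnitude = 60, noise_sd = 11,
                                       model = default_model(), seed = 1,
                                       cohort = NULL) {
  if (is.null(cohort)) {
    cfg <- cohort_config(n = n, measurement_noise_sd = noise_sd,
                         error_rate = error_rate,
                         error_magnitude = error_magnitude, seed = seed)
    cohort <- simulate_cohort(cfg, model)
  }
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0L)
    stop("insufficient data: empty cohort", call. = FALSE)
  need <- c("measured_osm", "predicted_osm", "is_error")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns ", paste(need, collapse = ", "), call. = FALSE)
  dev_flag <- abs(cohort$measured_osm - cohort$predicted_osm) >
    model$qc_threshold
  err <- as.logical(cohort$is_error)
  list(
    sensitivity = if (any(err)) mean(dev_flag[err]) else NA_real_,
    false_flag_rate = if (any(!err)) mean(dev_flag[!err]) else NA_real_,
    n_errors = sum(err), n_clean = sum(!err),
    threshold = model$qc_threshold
  )
}
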