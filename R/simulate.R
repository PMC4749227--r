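# Hierarchical seeding: one user-facing integer seed, split into a fixed
# substream per generated column. Adding a new column (new key) never
# perturbs draws of existing columns.
stream_seed <- function(seed, key) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 1103 + key * 7919 + 12345) %% 2147483647)
}

.ladders <- list(
  carbohydrate = c(0.5, 1.0, 1.5, 2.0),   # g/100 mL
  protein      = c(0.2, 0.5, 1.0, 2.0),   # g/100 mL
  fat          = c(0.5, 1.0, 2.0, 4.0)    # mL/100 mL
)

#' Default titration concentration ladder for a macronutrient
#'
#' Bench ladders per 100 mL of milk (prepared as 25 mL aliquots and scaled
#' by 4): carbohydrate 0.5-2.0 g, protein 0.2-2.0 g, fat 0.5-4.0 mL.
#'
#' @param kind `"carbohydrate"`, `"protein"` or `"fat"`.
#' @return Numeric vector of amounts per 100 mL.
#' @export
default_ladder <- function(kind = c("carbohydrate", "protein", "fat")) {
  .ladders[[match.arg(kind)]]
}

#' Simulate a titration calibration series
#'
#' Generates osmolality increases on a concentration ladder under a known
#' true slope with Gaussian measurement noise:
#' `increase_i = true_slope * amount_i + N(0, noise_sd^2)`.
#' Deterministic given the seed.
#'
#' @param product Product name for the series.
#' @param true_slope True coefficient, mOsm/kg per unit per 100 mL.
#' @param levels Amounts per 100 mL; default is the ladder for `kind`.
#' @param noise_sd Measurement noise SD, mOsm/kg (>= 0).
#' @param seed Integer seed.
#' @param native_osm Native osmolality recorded with the series.
#' @param kind Macronutrient kind selecting the default ladder.
#' @return A [titration_series()].
#' @export
#' @examples
#' simulate_titration("Polycose", 20, noise_sd = 2, seed = 1)
simulate_titration <- function(product, true_slope, levels = NULL,
                               noise_sd = 0, seed = 1, native_osm = 299,
                               kind = "carbohydrate") {
  if (is.null(levels)) levels <- default_ladder(kind)
  if (length(levels) == 0L) stop("`levels` must be nonempty", call. = FALSE)
  check_number(noise_sd, "noise_sd", min = 0)
  set.seed(stream_seed(seed, 101))
  eps <- if (noise_sd > 0) stats::rnorm(length(levels), 0, noise_sd) else 0
  titration_series(product, amount = levels,
                   increase = true_slope * levels + eps,
                   native_osm = native_osm)
}

#' Simulate a paired fortifier offset experiment
#'
#' Native milk batches measured before and immediately after one full HMF
#' dose per 100 mL; the per-batch offsets scatter around the true offset.
#'
#' @param n Number of batches.
#' @param true_offset True per-dose offset, mOsm/kg.
#' @param offset_sd Between-batch SD of the offset, mOsm/kg.
#' @param native_mean,native_sd Native osmolality distribution, mOsm/kg.
#' @param seed Integer seed.
#' @return A tibble with columns `native` and `fortified`.
#' @export
simulate_hmf_pairs <- function(n = 10, true_offset = 106, offset_sd = 4,
                               native_mean = 299, native_sd = 6, seed = 1) {
  stopifnot(n >= 1)
  set.seed(stream_seed(seed, 201))
  native <- stats::rnorm(n, native_mean, native_sd)
  set.seed(stream_seed(seed, 202))
  fortified <- native + stats::rnorm(n, true_offset, offset_sd)
  tibble::tibble(native = native, fortified = fortified)
}

#' Configure a synthetic clinical cohort
#'
#' Study conditions for [simulate_cohort()]: native osmolality N(299, 6^2)
#' mOsm/kg, literature-typical native macronutrient composition, supplement
#' additions drawn within the clinical target-fortification ranges
#' (fat 0.0-3.2 mL, protein 0.6-1.5 g, carbohydrate 1.1-2.7 g per 100 mL),
#' a full HMF dose per batch, 11 mOsm/kg measurement noise and a 5%
#' preparation-error rate.
#'
#' @param n Cohort size (>= 1).
#' @param native_osm_mean,native_osm_sd Native osmolality distribution.
#' @param comp_mean,comp_sd Named (`fat`, `protein`, `carbohydrate`) means
#'   and SDs of the native composition, g/100 mL.
#' @param add_ranges Named list of `c(min, max)` addition ranges per 100 mL.
#' @param addition_dist `"uniform"` over each range (default) or
#'   `"triangular"` centred on `add_modes`.
#' @param add_modes Named modes for the triangular option (defaults: the
#'   clinical mean additions 1.3 mL fat, 1.2 g protein, 1.8 g carbohydrate).
#' @param hmf HMF product name added to every batch (`NULL` for none).
#' @param hmf_sachets Sachets per 100 mL (default 4 = one full dose).
#' @param measurement_noise_sd Osmometer noise SD, mOsm/kg.
#' @param error_rate Fraction of batches mis-prepared, in \[0, 1\].
#' @param error_magnitude Osmolality shift of a mis-prepared batch, mOsm/kg.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n,
                          native_osm_mean = 299, native_osm_sd = 6,
                          comp_mean = c(fat = 3.5, protein = 1.2,
                                        carbohydrate = 6.6),
                          comp_sd = c(fat = 0.6, protein = 0.25,
                                      carbohydrate = 0.4),
                          add_ranges = list(fat = c(0.0, 3.2),
                                            protein = c(0.6, 1.5),
                                            carbohydrate = c(1.1, 2.7)),
                          addition_dist = c("uniform", "triangular"),
                          add_modes = c(fat = 1.3, protein = 1.2,
                                        carbohydrate = 1.8),
                          hmf = "HMF1", hmf_sachets = 4,
                          measurement_noise_sd = 11,
                          error_rate = 0.05, error_magnitude = 60,
                          seed = 1) {
  addition_dist <- match.arg(addition_dist)
  stopifnot(n >= 1, native_osm_sd >= 0, all(comp_sd >= 0),
            measurement_noise_sd >= 0,
            error_rate >= 0, error_rate <= 1)
  for (k in names(add_ranges)) {
    r <- add_ranges[[k]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0)
      stop("addition range for '", k, "' must be c(lower, upper) with ",
           "0 <= lower <= upper", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), native_osm_mean = native_osm_mean,
         native_osm_sd = native_osm_sd, comp_mean = comp_mean,
         comp_sd = comp_sd, add_ranges = add_ranges,
         addition_dist = addition_dist, add_modes = add_modes,
         hmf = hmf, hmf_sachets = hmf_sachets,
         measurement_noise_sd = measurement_noise_sd,
         error_rate = error_rate, error_magnitude = error_magnitude,
         seed = seed),
    class = "cohort_config"
  )
}

rtri <- function(n, lo, hi, mode) {
  # inverse-CDF triangular draw
  u <- stats::runif(n)
  f <- (mode - lo) / (hi - lo)
  ifelse(u < f,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

#' Simulate a target-fortification clinical cohort
#'
#' Draws native milk samples, per-batch supplement additions within the
#' clinical ranges and a full HMF dose, computes each batch's true final
#' osmolality with the supplied model (linear mode), and overlays
#' measurement noise plus injected preparation errors on the measured value.
#' The output carries every column needed to run prediction, QC and dosing
#' end-to-end, and is a pure function of (config, model).
#'
#' @param config A [cohort_config()].
#' @param model An [osmolality_model()].
#' @return A tibble with columns `sample_id`, `native_osm`, `fat`, `protein`,
#'   `cho`, `volume_ml`, one `add_<product>` column per addition,
#'   `true_osm` (model prediction on the true recipe), `predicted_osm`
#'   (identical by construction: the recipe is recorded faithfully),
#'   `measured_osm` and `is_error`.
#' @export
#' @examples
#' simulate_cohort(cohort_config(n = 5, seed = 7), default_model())
simulate_cohort <- function(config, model) {
  if (!inherits(config, "cohort_config"))
    stop("`config` must be a cohort_config", call. = FALSE)
  if (!inherits(model, "osmolality_model"))
    stop("`model` must be an osmolality_model", call. = FALSE)
  n <- config$n
  seed <- config$seed

  set.seed(stream_seed(seed, 1))
  native_osm <- stats::rnorm(n, config$native_osm_mean, config$native_osm_sd)
  comp <- list()
  comp_keys <- c(fat = 2, protein = 3, carbohydrate = 4)
  for (k in names(comp_keys)) {
    set.seed(stream_seed(seed, comp_keys[[k]]))
    comp[[k]] <- pmax(0, stats::rnorm(n, config$comp_mean[[k]],
                                      config$comp_sd[[k]]))
  }

  chosen <- select_supplements(model)
  add_keys <- c(fat = 5, protein = 6, carbohydrate = 7)
  adds <- list()
  for (k in names(config$add_ranges)) {
    r <- config$add_ranges[[k]]
    set.seed(stream_seed(seed, add_keys[[k]]))
    adds[[k]] <- if (config$addition_dist == "uniform") {
      stats::runif(n, r[1], r[2])
    } else {
      rtri(n, r[1], r[2], config$add_modes[[k]])
    }
    if (is.na(chosen[[k]]))
      stop("model has no supplement of kind '", k, "'", call. = FALSE)
  }

  # true final osmolality: linear model prediction on the true recipe
  true_osm <- native_osm
  for (k in names(adds)) {
    p <- model$products[[chosen[[k]]]]
    true_osm <- true_osm + p$linear_coeff * adds[[k]]
  }
  if (!is.null(config$hmf)) {
    p <- resolve_product(model, config$hmf)
    true_osm <- true_osm + p$dose_offset * config$hmf_sachets /
      p$sachets_per_dose
  }

  set.seed(stream_seed(seed, 8))
  noise <- if (config$measurement_noise_sd > 0) {
    stats::rnorm(n, 0, config$measurement_noise_sd)
  } else 0
  set.seed(stream_seed(seed, 9))
  is_error <- stats::runif(n) < config$error_rate
  measured <- true_osm + noise + config$error_magnitude * is_error

  out <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    native_osm = native_osm,
    fat = comp$fat, protein = comp$protein, cho = comp$carbohydrate,
    volume_ml = 100
  )
  if (!is.null(config$hmf))
    out[[paste0("add_", config$hmf)]] <- config$hmf_sachets
  for (k in names(adds)) out[[paste0("add_", chosen[[k]])]] <- adds[[k]]
  out$true_osm <- true_osm
  out$predicted_osm <- true_osm
  out$measured_osm <- measured
  out$is_error <- is_error
  out
}

#' Simulate a 24 h cold-storage experiment
#'
#' Applies the model's storage adjustment to each point of a carbohydrate
#' titration (baseline absolute osmolality = native + increase) and overlays
#' optional measurement noise, preserving the paired structure.
#'
#' @param series A carbohydrate [titration_series()] with a finite
#'   `native_osm`.
#' @param model An [osmolality_model()].
#' @param noise_sd Measurement noise SD on the stored value, mOsm/kg.
#' @param seed Integer seed.
#' @return A tibble with columns `amount`, `baseline_osm`, `stored_osm`.
#' @export
simulate_storage_series <- function(series, model, noise_sd = 0, seed = 1) {
  if (!inherits(series, "titration_series"))
    stop("`series` must be a titration_series", call. = FALSE)
  if (!is.finite(series$native_osm))
    stop("series must carry `native_osm` to form absolute osmolalities",
         call. = FALSE)
  check_number(noise_sd, "noise_sd", min = 0)
  baseline <- series$native_osm + series$points$increase
  stored <- vapply(seq_along(baseline), function(i) {
    storage_adjust(baseline[i], carb_added = series$points$amount[i],
                   model = model)
  }, numeric(1))
  set.seed(stream_seed(seed, 301))
  if (noise_sd > 0) stored <- stored + stats::rnorm(length(stored), 0, noise_sd)
  tibble::tibble(amount = series$points$amount, baseline_osm = baseline,
                 stored_osm = stored)
}
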