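#' Construct a titration series
#'
#' One product's calibration experiment: amounts added per 100 mL of a pooled
#' native milk and the resulting osmolality increase over native at each
#' step. Absolute measured osmolalities can be supplied instead via
#' `measured`, in which case `native_osm` is subtracted.
#'
#' @param product Product name the series calibrates.
#' @param amount Amounts added per 100 mL (g or mL), >= 0. An explicit (0, 0)
#'   anchor point is permitted.
#' @param increase Osmolality increase over native at each amount, mOsm/kg.
#' @param measured Alternative to `increase`: absolute measured osmolalities.
#' @param native_osm Native osmolality of the pooled milk, mOsm/kg. Required
#'   with `measured`.
#' @param unit Unit of `amount` (`"g"` or `"mL"`), informational.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(product, amount, increase = NULL,
                             measured = NULL, native_osm = NA_real_,
                             unit = "g") {
  stopifnot(is.character(product), length(product) == 1L)
  if (!is.numeric(amount) || length(amount) < 1L || anyNA(amount))
    stop("`amount` must be numeric and non-missing", call. = FALSE)
  if (any(amount < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (is.null(increase)) {
    if (is.null(measured))
      stop("supply either `increase` or `measured`", call. = FALSE)
    if (!is.finite(native_osm))
      stop("`native_osm` is required to convert absolute osmolalities ",
           "to increases", call. = FALSE)
    increase <- measured - native_osm
  }
  if (length(increase) != length(amount))
    stop("`amount` and `increase` lengths differ", call. = FALSE)
  if (length(unique(amount)) < 2L)
    stop("a titration series needs at least 2 distinct amounts", call. = FALSE)
  structure(
    list(product = product,
         points = tibble::tibble(amount = amount, increase = increase),
         native_osm = native_osm, unit = unit),
    class = "titration_series"
  )
}

#' Fit a linear osmolality coefficient from a titration series
#'
#' Ordinary least squares of osmolality increase on amount added. The slope
#' is the product's `linear_coeff`: mOsm/kg per unit of product per 100 mL.
#' A free intercept reproduces spreadsheet-style regression; through-origin
#' enforces the physical constraint that zero addition yields zero increase.
#'
#' @param series A [titration_series()], or a data frame with columns
#'   `amount` and `increase`.
#' @param intercept_mode `"free"` (default) or `"through_origin"`.
#' @return An object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared` (computed against the mean for a free intercept, against
#'   zero for through-origin), `slope_se`, `n_points`, `residuals`.
#' @export
#' @examples
#' s <- titration_series("Polycose", c(0.5, 1, 1.5, 2), c(10, 20, 30, 40))
#' fit_titration(s)$slope # 20
fit_titration <- function(series, intercept_mode = c("free", "through_origin")) {
  intercept_mode <- match.arg(intercept_mode)
  if (inherits(series, "titration_series")) {
    d <- series$points
  } else {
    d <- tibble::as_tibble(series)
    if (!all(c("amount", "increase") %in% names(d)))
      stop("need columns `amount` and `increase`", call. = FALSE)
  }
  n <- nrow(d)
  n_par <- if (intercept_mode == "free") 2L else 1L
  if (n < n_par)
    stop("insufficient data: ", n, " point(s) for ", n_par, " parameter(s)",
         call. = FALSE)
  if (intercept_mode == "free" && length(unique(d$amount)) < 2L)
    stop("degenerate design: all amounts identical", call. = FALSE)
  if (intercept_mode == "through_origin" && all(d$amount == 0))
    stop("degenerate design: all amounts zero", call. = FALSE)
  fit <- if (intercept_mode == "free") {
    stats::lm(increase ~ amount, data = d)
  } else {
    stats::lm(increase ~ 0 + amount, data = d)
  }
  # summary.lm warns on exact fits; noiseless calibrations are legitimate here
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(co["amount", "Estimate"])
  slope_se <- unname(co["amount", "Std. Error"])
  intercept <- if (intercept_mode == "free") unname(stats::coef(fit)[1]) else 0
  res <- unname(stats::residuals(fit))
  ss_res <- sum(res^2)
  ss_tot <- if (intercept_mode == "free") {
    sum((d$increase - mean(d$increase))^2)
  } else {
    sum(d$increase^2)
  }
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = max(0, min(1, r2)), slope_se = slope_se,
         n_points = n, residuals = res, intercept_mode = intercept_mode),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> slope %.3f +/- %.3f mOsm/kg per unit, intercept %.3f, R2 %.3f (n = %d)\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Estimate a per-dose fortifier offset from paired measurements
#'
#' Mean and sample SD of the fortified-minus-native osmolality differences
#' from batches measured before and immediately after standard fortification
#' at one full dose per 100 mL.
#'
#' @param native Native osmolalities, mOsm/kg (or a 2-column data frame with
#'   columns `native` and `fortified`).
#' @param fortified Fortified osmolalities, same length.
#' @return An object of class `offset_estimate`: `mean_offset`, `sd`
#'   (sample, n - 1 denominator; `NA` when n = 1), `n`.
#' @export
#' @examples
#' fit_offset(c(299, 301, 298), c(404, 407, 405))
fit_offset <- function(native, fortified = NULL) {
  if (is.data.frame(native)) {
    fortified <- native$fortified
    native <- native$native
  }
  if (is.null(native) || length(native) == 0L)
    stop("insufficient data: no pairs supplied", call. = FALSE)
  if (length(fortified) != length(native))
    stop("`native` and `fortified` lengths differ", call. = FALSE)
  if (any(fortified < 0)) stop("fortified osmolality must be >= 0", call. = FALSE)
  d <- fortified - native
  structure(
    list(mean_offset = mean(d),
         sd = if (length(d) > 1L) stats::sd(d) else NA_real_,
         n = length(d)),
    class = "offset_estimate"
  )
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate> %.1f +/- %.1f mOsm/kg per dose (n = %d)\n",
              x$mean_offset, x$sd, x$n))
  invisible(x)
}

#' Assemble a model from calibration fits plus packaged defaults
#'
#' Replaces the coefficients of a base model with freshly fitted values:
#' a [fit_titration()] slope overwrites a product's `linear_coeff`, a
#' [fit_offset()] mean overwrites an HMF's `dose_offset`. Products without a
#' fit keep their packaged coefficient. Mechanistic-mode `osmoles_per_gram`
#' is re-derived from the new slope for powders. Per-product provenance
#' (`"fitted"` or `"packaged"`) is recorded in the `"provenance"` attribute.
#'
#' @param fits Named list mapping product name to a `calibration_fit` or
#'   `offset_estimate`. May be empty.
#' @param base_config An [osmolality_model()] supplying defaults
#'   (default: [default_model()]).
#' @return An [osmolality_model()].
#' @export
coefficients_to_model <- function(fits = list(), base_config = default_model()) {
  if (!inherits(base_config, "osmolality_model"))
    stop("`base_config` must be an osmolality_model", call. = FALSE)
  if (length(fits) > 0 && (is.null(names(fits)) || any(!nzchar(names(fits)))))
    stop("`fits` must be a named list keyed by product name", call. = FALSE)
  if (anyDuplicated(names(fits)))
    stop("duplicate product name(s) in `fits`: ",
         paste(unique(names(fits)[duplicated(names(fits))]), collapse = ", "),
         call. = FALSE)
  model <- base_config
  provenance <- stats::setNames(rep("packaged", length(model$products)),
                                names(model$products))
  for (nm in names(fits)) {
    p <- model$products[[nm]]
    if (is.null(p))
      stop("fit supplied for product '", nm,
           "' which the base config does not define", call. = FALSE)
    f <- fits[[nm]]
    if (inherits(f, "calibration_fit")) {
      if (p$kind == "hmf")
        stop("product '", nm, "' is an HMF: supply an offset_estimate",
             call. = FALSE)
      p$linear_coeff <- f$slope
    } else if (inherits(f, "offset_estimate")) {
      if (p$kind != "hmf")
        stop("product '", nm, "' is not an HMF: supply a calibration_fit",
             call. = FALSE)
      p$dose_offset <- f$mean_offset
    } else {
      stop("fit for '", nm,
           "' must be a calibration_fit or offset_estimate", call. = FALSE)
    }
    if (p$form == "powder" && p$kind != "hmf") {
      p$osmoles_per_gram <- p$linear_coeff * model$water_mass / 100
    }
    model$products[[nm]] <- p
    provenance[nm] <- "fitted"
  }
  attr(model, "provenance") <- provenance
  model
}
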