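# atomic CSV/JSON writers: write to a sibling temp file, then rename, so a
# failure never leaves a partial output behind
write_atomic_csv <- function(x, path) {
  tmp <- tempfile(pattern = ".milkosm-", tmpdir = dirname(path),
                  fileext = ".csv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  readr::write_csv(x, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_atomic_json <- function(x, path) {
  tmp <- tempfile(pattern = ".milkosm-", tmpdir = dirname(path),
                  fileext = ".json")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a batch prediction CSV
#'
#' Expects a header with `sample_id`, `native_osm`, `fat`, `protein`, `cho`
#' and `volume_ml` (order- and case-insensitive) plus zero or more
#' `add_<product>` columns giving amounts of each additive. Amounts weighed
#' per 25 mL bench aliquot are converted to the per-100 mL basis
#' (multiplied by 4) when `basis = "per_25ml"`.
#'
#' @param path CSV path.
#' @param basis `"per_100ml"` (default) or `"per_25ml"` for the `add_*`
#'   amount columns.
#' @param required Columns that must be present; defaults to the batch
#'   schema above.
#' @return A tibble with canonical lower-case column names; row order
#'   preserved for error reporting.
#' @export
read_batch <- function(path, basis = c("per_100ml", "per_25ml"),
                       required = c("sample_id", "native_osm", "fat",
                                    "protein", "cho", "volume_ml")) {
  basis <- match.arg(basis)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0L) stop("empty input: ", path, call. = FALSE)
  # canonicalise schema columns case-insensitively; product (add_*) columns
  # keep their case, which must match the model's product names
  lower <- tolower(names(d))
  for (req in tolower(required)) {
    hit <- which(lower == req)
    if (length(hit) > 0) names(d)[hit[1]] <- req
  }
  missing <- setdiff(tolower(required), names(d))
  if (length(missing) > 0)
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(names(d), c("sample_id", "unit", "reason"))
  for (nm in intersect(numeric_cols,
                       c("native_osm", "measured_osm", "predicted_osm",
                         grep("^add_", names(d), value = TRUE),
                         "fat", "protein", "cho", "volume_ml"))) {
    v <- d[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0)
        stop("non-numeric value in column '", nm, "' at data row ", bad[1],
             ": '", v[bad[1]], "'", call. = FALSE)
      d[[nm]] <- num
    }
  }
  if (basis == "per_25ml") {
    for (nm in grep("^add_", names(d), value = TRUE)) d[[nm]] <- d[[nm]] * 4
  }
  d
}

row_recipe <- function(row, model) {
  base <- milk_sample(
    id = as.character(row$sample_id),
    osmolality = row$native_osm,
    fat = row$fat %||% 0, protein = row$protein %||% 0,
    carbohydrate = row$cho %||% 0,
    volume = row$volume_ml %||% 100,
    water_mass = model$water_mass
  )
  add_cols <- grep("^add_", names(row), value = TRUE)
  adds <- NULL
  if (length(add_cols) > 0) {
    prods <- sub("^add_", "", add_cols)
    amts <- as.numeric(row[add_cols])
    keep <- !is.na(amts) & amts > 0
    if (any(keep)) {
      units <- vapply(prods[keep], function(nm) {
        p <- resolve_product(model, nm)
        switch(p$kind, hmf = "sachet", fat = "mL", "g")
      }, character(1))
      adds <- tibble::tibble(product = prods[keep], amount = amts[keep],
                             unit = units)
    }
  }
  fortification_recipe(base, adds)
}

#' Predict osmolality for every row of a batch table
#'
#' Runs [predict_recipe()] per row and appends `pred_osm`,
#' `pred_osm_stored`, `exceeds_limit` and one `contrib_<product>` column per
#' additive present in the batch.
#'
#' @param data A batch tibble as returned by [read_batch()] (or
#'   [simulate_cohort()]).
#' @param model An [osmolality_model()].
#' @param mode Prediction mode, `"linear"` or `"mechanistic"`.
#' @return The input tibble with prediction columns appended.
#' @export
predict_batch <- function(data, model, mode = "linear") {
  data <- tibble::as_tibble(data)
  add_cols <- grep("^add_", names(data), value = TRUE)
  n <- nrow(data)
  pred <- numeric(n); stored <- numeric(n); exceeds <- logical(n)
  contribs <- matrix(0, nrow = n, ncol = length(add_cols),
                     dimnames = list(NULL, sub("^add_", "contrib_", add_cols)))
  for (i in seq_len(n)) {
    r <- row_recipe(data[i, ], model)
    p <- predict_recipe(r, model, mode = mode)
    pred[i] <- p$total; stored[i] <- p$storage_adjusted
    exceeds[i] <- p$exceeds_limit
    for (nm in names(p$contributions))
      contribs[i, paste0("contrib_", nm)] <- p$contributions[[nm]]
  }
  out <- data
  out$pred_osm <- pred
  out$pred_osm_stored <- stored
  out$exceeds_limit <- exceeds
  cbind(out, tibble::as_tibble(contribs))
}

#' QC-evaluate a batch of measured vs predicted osmolalities
#'
#' When `predicted_osm` is absent it is computed from the recipe columns via
#' [predict_batch()]. Appends `difference`, `flagged` and `reason` per row.
#'
#' @param data Tibble with `measured_osm` and either `predicted_osm` or full
#'   recipe columns.
#' @param model An [osmolality_model()].
#' @param mode Prediction mode when predictions must be computed.
#' @return The input tibble with QC columns appended.
#' @export
qc_batch <- function(data, model, mode = "linear") {
  data <- tibble::as_tibble(data)
  if (!"measured_osm" %in% names(data))
    stop("missing required column(s): measured_osm", call. = FALSE)
  if (!"predicted_osm" %in% names(data)) {
    data <- predict_batch(data, model, mode = mode)
    data$predicted_osm <- data$pred_osm
  }
  rec <- flag_batch(data$measured_osm, data$predicted_osm, model,
                    sample_id = data$sample_id %||% NULL)
  data$difference <- rec$difference
  data$flagged <- rec$flagged
  data$reason <- rec$reason
  data
}

#' Dose every row of a batch table to a target profile
#'
#' Computes per-sample deficits after the HMF dose, converts them to
#' supplement amounts and appends the predicted osmolality with safety
#' flags.
#'
#' @param data Batch tibble with `sample_id`, `native_osm`, `fat`,
#'   `protein`, `cho` columns.
#' @param model An [osmolality_model()].
#' @param target A [target_profile()]; default from the model config's
#'   `target_profile` attribute.
#' @param hmf_product HMF name (default `"HMF1"`); `NULL` for none.
#' @param hmf_comp An [hmf_composition()]; default from the model config.
#' @return The input tibble with `dose_<product>` columns, `pred_osm`,
#'   `pred_osm_stored`, `exceeds_limit` and `volume_flag` appended.
#' @export
dose_batch <- function(data, model, target = NULL, hmf_product = "HMF1",
                       hmf_comp = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(target)) {
    tp <- attr(model, "target_profile")
    if (is.null(tp))
      stop("no `target` supplied and the model config has no target_profile",
           call. = FALSE)
    target <- target_profile(tp$fat, tp$protein, tp$carbohydrate)
  }
  if (is.null(hmf_comp) && !is.null(hmf_product)) {
    hc <- attr(model, "hmf_composition")[[hmf_product]]
    if (is.null(hc))
      stop("no `hmf_comp` supplied and the model config has no ",
           "hmf_composition for ", hmf_product, call. = FALSE)
    hmf_comp <- hmf_composition(hc$fat, hc$protein, hc$carbohydrate)
  }
  n <- nrow(data)
  dose_cols <- list()
  pred <- numeric(n); stored <- numeric(n)
  exceeds <- logical(n); vol_flag <- logical(n)
  for (i in seq_len(n)) {
    row <- data[i, ]
    base <- milk_sample(as.character(row$sample_id), row$native_osm,
                        fat = row$fat, protein = row$protein,
                        carbohydrate = row$cho,
                        volume = row$volume_ml %||% 100,
                        water_mass = model$water_mass)
    def <- compute_deficit(base, hmf_comp, target)
    dr <- compute_dose(def, model, base, hmf_product = hmf_product)
    for (nm in names(dr$amounts)) {
      col <- paste0("dose_", nm)
      if (is.null(dose_cols[[col]])) dose_cols[[col]] <- numeric(n)
      dose_cols[[col]][i] <- dr$amounts[[nm]]
    }
    pred[i] <- dr$prediction$total
    stored[i] <- dr$prediction$storage_adjusted
    exceeds[i] <- dr$safety$flagged
    vol_flag[i] <- dr$volume_flag
  }
  out <- data
  for (col in names(dose_cols)) out[[col]] <- dose_cols[[col]]
  out$pred_osm <- pred
  out$pred_osm_stored <- stored
  out$exceeds_limit <- exceeds
  out$volume_flag <- vol_flag
  out
}

#' Read a titration calibration CSV
#'
#' Schema: `product,amount_per_100ml,unit,osm_native,osm_measured`, one row
#' per enrichment step; rows are grouped by product into one
#' [titration_series()] each, converting absolute measured osmolalities to
#' increases over native.
#'
#' @param path CSV path.
#' @return Named list of [titration_series()] objects.
#' @export
read_titration_csv <- function(path) {
  d <- read_batch(path, required = c("product", "amount_per_100ml",
                                     "osm_native", "osm_measured"))
  if (!is.numeric(d$amount_per_100ml) || !is.numeric(d$osm_measured) ||
      !is.numeric(d$osm_native)) {
    suppressWarnings({
      d$amount_per_100ml <- as.numeric(d$amount_per_100ml)
      d$osm_native <- as.numeric(d$osm_native)
      d$osm_measured <- as.numeric(d$osm_measured)
    })
    bad <- which(is.na(d$amount_per_100ml) | is.na(d$osm_native) |
                   is.na(d$osm_measured))
    if (length(bad) > 0)
      stop("non-numeric titration value at data row ", bad[1], call. = FALSE)
  }
  lapply(split(d, d$product), function(g) {
    titration_series(g$product[1], amount = g$amount_per_100ml,
                     measured = g$osm_measured, native_osm = g$osm_native[1],
                     unit = if ("unit" %in% names(g)) as.character(g$unit[1]) else "g")
  })
}

#' Tabulate calibration fits for reporting
#'
#' @param fits Named list of `calibration_fit` / `offset_estimate` objects.
#' @return A tibble with one row per product: slope (or mean offset),
#'   intercept, `r_squared`, `slope_se`, `n`.
#' @export
fit_report <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (inherits(f, "calibration_fit")) {
      tibble::tibble(product = nm, type = "titration", slope = f$slope,
                     intercept = f$intercept, r_squared = f$r_squared,
                     slope_se = f$slope_se, n = f$n_points)
    } else {
      tibble::tibble(product = nm, type = "offset", slope = f$mean_offset,
                     intercept = NA_real_, r_squared = NA_real_,
                     slope_se = if (is.na(f$sd)) NA_real_ else f$sd / sqrt(f$n),
                     n = f$n)
    }
  })
  do.call(rbind, rows)
}
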