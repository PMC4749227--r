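#' Read an osmolality model from a JSON or YAML config file
#'
#' The config schema mirrors the packaged default
#' (`system.file("extdata", "default_model.json", package = "milkosm")`):
#' a `products` array with the [supplement_product()] fields, model-level
#' `storage_factor`/`storage_mode`/`storage_slope`, `safety_limit`,
#' `qc_threshold` and `water_mass`, plus optional `hmf_composition` (grams of
#' each macronutrient per full HMF dose per 100 mL) and `target_profile`
#' blocks used by the dosing functions. The latter two are attached to the
#' returned model as attributes of the same names.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [osmolality_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  }
  model_from_config(cfg)
}

model_from_config <- function(cfg) {
  if (is.null(cfg$products))
    stop("model config must define a `products` array", call. = FALSE)
  products <- lapply(cfg$products, function(p) {
    supplement_product(
      name = p$name, kind = p$kind, form = p$form,
      potency = p$potency %||% 0,
      water_per_unit = p$water_per_unit %||% 0,
      linear_coeff = p$linear_coeff,
      osmoles_per_gram = p$osmoles_per_gram,
      dose_offset = p$dose_offset,
      sachets_per_dose = p$sachets_per_dose %||% 4
    )
  })
  model <- osmolality_model(
    products,
    storage_factor = cfg$storage_factor %||% 1.04,
    storage_mode = cfg$storage_mode %||% "flat",
    storage_slope = cfg$storage_slope %||% 9,
    safety_limit = cfg$safety_limit %||% 450,
    qc_threshold = cfg$qc_threshold %||% 22,
    water_mass = cfg$water_mass %||% 87.5
  )
  attr(model, "hmf_composition") <- cfg$hmf_composition
  attr(model, "target_profile") <- cfg$target_profile
  model
}

#' Write an osmolality model to a JSON config file
#'
#' @param model An [osmolality_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    products = lapply(unname(model$products), function(p) {
      p <- unclass(p)
      p[!vapply(p, is.null, logical(1))]
    }),
    storage_factor = model$storage_factor,
    storage_mode = model$storage_mode,
    storage_slope = model$storage_slope,
    safety_limit = model$safety_limit,
    qc_threshold = model$qc_threshold,
    water_mass = model$water_mass
  )
  if (!is.null(attr(model, "hmf_composition")))
    cfg$hmf_composition <- attr(model, "hmf_composition")
  if (!is.null(attr(model, "target_profile")))
    cfg$target_profile <- attr(model, "target_profile")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' The packaged default osmolality model
#'
#' Loads the coefficient set shipped with the package: glucose polymer
#' +20 mOsm/kg per g, whey protein (Protein1) +4, hydrolyzed protein
#' (Protein2) +38, fat emulsion -1.7 per mL (dilution), HMF offsets +106
#' (HMF1) and +56 (HMF2) per full dose, flat 4% storage factor, 450 mOsm/kg
#' safety limit and 22 mOsm/kg QC threshold.
#'
#' @return An [osmolality_model()].
#' @export
#' @examples
#' default_model()
default_model <- function() {
  read_model_config(system.file("extdata", "default_model.json",
                                package = "milkosm", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
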