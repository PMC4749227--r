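#' Create a milk sample
#'
#' A single breast-milk aliquot: its native osmolality and macronutrient
#' composition per 100 mL, as reported by a milk analyzer, plus the solvent
#' water mass used by the mechanistic (osmole-bookkeeping) prediction mode.
#'
#' @param id Sample identifier.
#' @param osmolality Native osmolality in mOsm/kg water (freezing-point
#'   depression scale). Must lie in (0, 2000).
#' @param fat,protein,carbohydrate Macronutrient content in g per 100 mL
#'   (all non-negative; their sum must stay below 100).
#' @param volume Aliquot volume in mL (> 0). Bookkeeping only; all
#'   concentrations are already per 100 mL.
#' @param water_mass Solvent water mass in g per 100 mL of milk.
#'   Default 87.5 g, a literature-typical value for mature human milk;
#'   must lie in (50, 100).
#'
#' @return An object of class `milk_sample`.
#' @export
#' @examples
#' milk_sample("BM-01", osmolality = 299, fat = 3.5, protein = 1.2,
#'             carbohydrate = 6.6)
milk_sample <- function(id = "sample", osmolality, fat = 0, protein = 0,
                        carbohydrate = 0, volume = 100, water_mass = 87.5) {
  stopifnot(is.character(id), length(id) == 1L)
  check_number(osmolality, "osmolality")
  check_number(fat, "fat", min = 0)
  check_number(protein, "protein", min = 0)
  check_number(carbohydrate, "carbohydrate", min = 0)
  check_number(volume, "volume")
  check_number(water_mass, "water_mass")
  if (osmolality <= 0 || osmolality >= 2000)
    stop("`osmolality` must lie in (0, 2000) mOsm/kg, got ", osmolality,
         call. = FALSE)
  if (fat + protein + carbohydrate >= 100)
    stop("fat + protein + carbohydrate must be < 100 g/100 mL", call. = FALSE)
  if (volume <= 0) stop("`volume` must be > 0 mL", call. = FALSE)
  if (water_mass <= 50 || water_mass >= 100)
    stop("`water_mass` must lie in (50, 100) g/100 mL", call. = FALSE)
  structure(
    list(id = id, osmolality = osmolality, fat = fat, protein = protein,
         carbohydrate = carbohydrate, volume = volume, water_mass = water_mass),
    class = "milk_sample"
  )
}

#' Define a fortification supplement product
#'
#' Describes how one additive behaves osmotically: its macronutrient kind and
#' potency, how much water it carries per unit added (emulsions), and either a
#' linear osmolality coefficient (macronutrient supplements) or a per-dose
#' offset (human milk fortifiers, HMF).
#'
#' @param name Unique product name.
#' @param kind One of `"carbohydrate"`, `"protein"`, `"fat"`, `"hmf"`.
#' @param form One of `"powder"`, `"emulsion"`, `"sachet"`.
#' @param potency Grams of macronutrient delivered per g of powder (must lie
#'   in \[0, 1\]) or per mL of emulsion.
#' @param water_per_unit Grams of water contributed per g (powder) or per mL
#'   (emulsion) added. Must be 0 for powders and > 0 for emulsions; a 50% fat
#'   in water emulsion has `water_per_unit = 0.5`.
#' @param linear_coeff Osmolality increase in mOsm/kg per unit of product
#'   added per 100 mL of milk. Required for every kind except `"hmf"`.
#' @param osmoles_per_gram Effective osmotic load per unit of product, in the
#'   mechanistic mode's water units (see [predict_recipe()]). If `NULL`, it is
#'   derived for powders as `linear_coeff * water_mass / 100`; emulsions whose
#'   effect is pure dilution default to 0.
#' @param dose_offset Osmolality increase in mOsm/kg per full standard HMF
#'   dose per 100 mL. Required (and only allowed) when `kind = "hmf"`.
#' @param sachets_per_dose Sachets making up one full dose per 100 mL
#'   (default 4, i.e. one sachet per 25 mL).
#'
#' @return An object of class `supplement_product`.
#' @export
#' @examples
#' supplement_product("Polycose", kind = "carbohydrate", form = "powder",
#'                    potency = 0.94, linear_coeff = 20)
supplement_product <- function(name, kind, form, potency,
                               water_per_unit = 0,
                               linear_coeff = NULL,
                               osmoles_per_gram = NULL,
                               dose_offset = NULL,
                               sachets_per_dose = 4) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("carbohydrate", "protein", "fat", "hmf"))
  form <- match.arg(form, c("powder", "emulsion", "sachet"))
  check_number(potency, "potency", min = 0)
  check_number(water_per_unit, "water_per_unit", min = 0)
  if (form == "powder") {
    if (potency > 1)
      stop("powder `potency` must lie in [0, 1] g macronutrient per g",
           call. = FALSE)
    if (water_per_unit != 0)
      stop("powders are assumed anhydrous: `water_per_unit` must be 0",
           call. = FALSE)
  }
  if (form == "emulsion" && water_per_unit <= 0)
    stop("emulsions must declare `water_per_unit` > 0 g water per mL",
         call. = FALSE)
  if (kind == "hmf") {
    if (is.null(dose_offset) || !is.null(linear_coeff))
      stop("HMF products take `dose_offset`, not `linear_coeff`",
           call. = FALSE)
    check_number(dose_offset, "dose_offset")
    check_number(sachets_per_dose, "sachets_per_dose", min = 1)
  } else {
    if (is.null(linear_coeff) || !is.null(dose_offset))
      stop("non-HMF products take `linear_coeff`, not `dose_offset`",
           call. = FALSE)
    check_number(linear_coeff, "linear_coeff")
  }
  if (!is.null(osmoles_per_gram)) check_number(osmoles_per_gram, "osmoles_per_gram")
  structure(
    list(name = name, kind = kind, form = form, potency = potency,
         water_per_unit = water_per_unit,
         linear_coeff = linear_coeff,
         osmoles_per_gram = osmoles_per_gram,
         dose_offset = dose_offset,
         sachets_per_dose = sachets_per_dose),
    class = "supplement_product"
  )
}

#' Assemble an osmolality prediction model
#'
#' Bundles a set of supplement products with model-level settings: the
#' cold-storage adjustment, the enteral safety limit, and the QC deviation
#' threshold.
#'
#' @param products List of [supplement_product()] objects with unique names.
#' @param storage_factor Multiplier applied after 24 h storage at 4 degrees C
#'   when added carbohydrate is present (default 1.04, a 4% rise driven by
#'   amylase breakdown of glucose polymer). Must be >= 1.
#' @param storage_mode `"flat"` (multiply the total by `storage_factor`) or
#'   `"proportional_to_carb"` (add `storage_slope` mOsm/kg per gram of added
#'   carbohydrate, reflecting the observed amount dependence).
#' @param storage_slope mOsm/kg per g of added carbohydrate, used only in
#'   proportional mode (default 9).
#' @param safety_limit Upper enteral feeding limit in mOsm/kg (default 450).
#' @param qc_threshold Absolute measured-minus-predicted difference in
#'   mOsm/kg beyond which a batch is flagged as a suspected preparation error
#'   (default 22, i.e. roughly mean + 2 SD of clinical agreement).
#' @param water_mass Default solvent water mass in g/100 mL used when a
#'   sample does not carry its own (default 87.5).
#'
#' @return An object of class `osmolality_model`.
#' @seealso [default_model()] for the packaged coefficient set.
#' @export
osmolality_model <- function(products,
                             storage_factor = 1.04,
                             storage_mode = c("flat", "proportional_to_carb"),
                             storage_slope = 9,
                             safety_limit = 450,
                             qc_threshold = 22,
                             water_mass = 87.5) {
  storage_mode <- match.arg(storage_mode)
  if (inherits(products, "supplement_product")) products <- list(products)
  stopifnot(is.list(products), length(products) >= 1L)
  ok <- vapply(products, inherits, logical(1), "supplement_product")
  if (!all(ok)) stop("`products` must be supplement_product objects", call. = FALSE)
  nms <- vapply(products, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate product name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(products) <- nms
  check_number(storage_factor, "storage_factor", min = 1)
  check_number(storage_slope, "storage_slope", min = 0)
  check_number(safety_limit, "safety_limit")
  check_number(qc_threshold, "qc_threshold", min = 0)
  check_number(water_mass, "water_mass")
  if (safety_limit <= 0) stop("`safety_limit` must be > 0", call. = FALSE)
  structure(
    list(products = products, storage_factor = storage_factor,
         storage_mode = storage_mode, storage_slope = storage_slope,
         safety_limit = safety_limit, qc_threshold = qc_threshold,
         water_mass = water_mass),
    class = "osmolality_model"
  )
}

#' Build a fortification recipe
#'
#' Pairs a base milk sample with a list of additions, each an amount of a
#' named product per 100 mL of base milk. Amounts measured per 25 mL aliquot
#' (the usual bench volume) must be multiplied by 4 before entry;
#' [read_batch()] does this when the unit flag says so.
#'
#' @param base A [milk_sample()].
#' @param additions A data frame with columns `product` (name), `amount`
#'   (per 100 mL, >= 0) and optionally `unit` (`"g"`, `"mL"` or `"sachet"`).
#'   An empty data frame (or `NULL`) is a valid, unfortified recipe.
#'
#' @return An object of class `fortification_recipe`.
#' @export
#' @examples
#' base <- milk_sample("BM-01", osmolality = 299)
#' fortification_recipe(base, data.frame(product = c("HMF1", "Polycose"),
#'                                       amount = c(4, 1.8),
#'                                       unit = c("sachet", "g")))
fortification_recipe <- function(base, additions = NULL) {
  if (!inherits(base, "milk_sample"))
    stop("`base` must be a milk_sample", call. = FALSE)
  if (is.null(additions) || nrow(as.data.frame(additions)) == 0L) {
    additions <- tibble::tibble(product = character(), amount = numeric(),
                                unit = character())
  } else {
    additions <- tibble::as_tibble(additions)
    if (!all(c("product", "amount") %in% names(additions)))
      stop("`additions` needs columns `product` and `amount`", call. = FALSE)
    if (!"unit" %in% names(additions)) additions$unit <- NA_character_
    additions <- additions[, c("product", "amount", "unit")]
    if (!is.numeric(additions$amount) || anyNA(additions$amount))
      stop("addition amounts must be numeric and non-missing", call. = FALSE)
    if (any(additions$amount < 0))
      stop("addition amounts must be >= 0", call. = FALSE)
  }
  structure(list(base = base, additions = additions),
            class = "fortification_recipe")
}

# shared scalar validator
check_number <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", what, "` must be a single finite number", call. = FALSE)
  if (x < min) stop("`", what, "` must be >= ", min, call. = FALSE)
  invisible(x)
}

resolve_product <- function(model, name) {
  p <- model$products[[name]]
  if (is.null(p))
    stop("unknown product '", name, "'; model defines: ",
         paste(names(model$products), collapse = ", "), call. = FALSE)
  p
}

#' @export
print.osmolality_model <- function(x, ...) {
  cat("<osmolality_model>\n")
  for (p in x$products) {
    coeff <- if (p$kind == "hmf") {
      sprintf("%+g mOsm/kg per full dose (%g sachets)", p$dose_offset,
              p$sachets_per_dose)
    } else {
      sprintf("%+g mOsm/kg per unit/100 mL", p$linear_coeff)
    }
    cat(sprintf("  %-12s %-12s %s\n", p$name, paste0("(", p$kind, ")"), coeff))
  }
  cat(sprintf("  storage: %s x%g (slope %g), safety limit %g mOsm/kg, QC threshold %g mOsm/kg\n",
              x$storage_mode, x$storage_factor, x$storage_slope,
              x$safety_limit, x$qc_threshold))
  invisible(x)
}

#' @export
print.milk_sample <- function(x, ...) {
  cat(sprintf("<milk_sample> %s: %g mOsm/kg; F/P/C %g/%g/%g g/100 mL; %g mL\n",
              x$id, x$osmolality, x$fat, x$protein, x$carbohydrate, x$volume))
  invisible(x)
}
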