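#' Predicted osmolality increment for a single addition
#'
#' Computes the signed osmolality change caused by adding `amount` of one
#' product per 100 mL of base milk.
#'
#' In **linear** mode the increment is `linear_coeff * amount` for
#' macronutrient supplements and `dose_offset * amount / sachets_per_dose`
#' for human milk fortifiers (HMF amounts are denominated in sachets).
#'
#' In **mechanistic** mode the product contributes `osmoles_per_gram * amount`
#' effective osmoles and `water_per_unit * amount` grams of water, and the
#' increment follows from osmole conservation: solute-free emulsions (fat)
#' dilute, powders raise osmolality exactly linearly.
#'
#' @param product A [supplement_product()] or a product name resolvable in
#'   `model`.
#' @param amount Amount added per 100 mL of base milk: g (powders),
#'   mL (emulsions) or sachets (HMF). Must be >= 0.
#' @param base A [milk_sample()]; its osmolality and water mass anchor the
#'   mechanistic computation (linear increments do not depend on it).
#' @param mode `"linear"` (default) or `"mechanistic"`.
#' @param unit Optional unit string for the amount. HMF amounts given in
#'   `"g"` are rejected: sachet mass is not modelled.
#' @param model Optional [osmolality_model()], needed only when `product` is
#'   given by name.
#'
#' @return The predicted increment in mOsm/kg (signed; negative only for
#'   water-contributing, solute-poor products such as fat emulsion).
#' @export
#' @examples
#' m <- default_model()
#' base <- milk_sample("BM", osmolality = 299)
#' predict_increase("Polycose", 1.0, base, model = m)   # +20 mOsm/kg
#' predict_increase("Microlipid", 1.0, base, model = m) # slightly negative
predict_increase <- function(product, amount, base,
                             mode = c("linear", "mechanistic"),
                             unit = NULL, model = NULL) {
  mode <- match.arg(mode)
  if (is.character(product)) {
    if (is.null(model))
      stop("supply `model` to resolve product '", product, "' by name",
           call. = FALSE)
    product <- resolve_product(model, product)
  }
  if (!inherits(product, "supplement_product"))
    stop("`product` must be a supplement_product or a name", call. = FALSE)
  check_number(amount, "amount", min = 0)
  if (!inherits(base, "milk_sample"))
    stop("`base` must be a milk_sample", call. = FALSE)
  if (product$kind == "hmf" && !is.null(unit) && !is.na(unit) &&
      tolower(unit) %in% c("g", "gram", "grams"))
    stop("HMF amount given in grams but sachet mass is not modelled; ",
         "express HMF amounts in sachets per 100 mL", call. = FALSE)
  if (mode == "linear") {
    return(linear_increment(product, amount))
  }
  w0 <- base$water_mass / 100
  osm <- osmoles_added(product, amount, base$water_mass)
  wadd <- product$water_per_unit * amount / 100
  (base$osmolality * w0 + osm) / (w0 + wadd) - base$osmolality
}

linear_increment <- function(product, amount) {
  if (product$kind == "hmf") {
    product$dose_offset * amount / product$sachets_per_dose
  } else {
    product$linear_coeff * amount
  }
}

# Effective osmoles contributed by `amount` of product, in the bookkeeping
# convention where water is counted as water_mass/100 (so that
# osmoles_per_gram = linear_coeff * water_mass/100 reproduces the linear
# increment exactly for anhydrous powders).
osmoles_added <- function(product, amount, water_mass) {
  opg <- product$osmoles_per_gram
  if (is.null(opg)) {
    opg <- if (product$kind == "hmf") {
      product$dose_offset / product$sachets_per_dose * water_mass / 100
    } else if (product$form == "powder") {
      product$linear_coeff * water_mass / 100
    } else {
      0 # solute-free emulsion: pure dilution
    }
  }
  opg * amount
}

#' Predict the final osmolality of a fortification recipe
#'
#' Applies every addition in the recipe to the base milk and returns the
#' predicted total osmolality, per-product contributions, the cold-storage
#' adjusted value, and whether the feed exceeds the safety limit.
#'
#' Linear mode is exactly additive and order-independent:
#' `total = base osmolality + sum(contributions)`. Mechanistic mode conserves
#' osmoles: all additions pool their effective osmoles and water, and the
#' reported per-product contributions decompose the total exactly
#' (`contribution_i = (osmoles_i - base_osm * water_i) / total_water`).
#'
#' @param recipe A [fortification_recipe()].
#' @param model An [osmolality_model()] resolving every product named in the
#'   recipe.
#' @param mode `"linear"` (default) or `"mechanistic"`.
#'
#' @return An object of class `osmolality_prediction` with fields `total`,
#'   `contributions` (named, signed, mOsm/kg), `mode`, `storage_adjusted`,
#'   `carb_added` (g/100 mL of carbohydrate-kind supplement) and
#'   `exceeds_limit`.
#' @export
#' @examples
#' m <- default_model()
#' r <- fortification_recipe(
#'   milk_sample("BM", osmolality = 299),
#'   data.frame(product = c("HMF1", "Polycose", "Protein1"),
#'              amount = c(4, 1.8, 1.2))
#' )
#' predict_recipe(r, m)
predict_recipe <- function(recipe, model, mode = c("linear", "mechanistic")) {
  mode <- match.arg(mode)
  if (!inherits(recipe, "fortification_recipe"))
    stop("`recipe` must be a fortification_recipe", call. = FALSE)
  if (!inherits(model, "osmolality_model"))
    stop("`model` must be an osmolality_model", call. = FALSE)
  base <- recipe$base
  add <- recipe$additions
  products <- lapply(add$product, resolve_product, model = model)
  carb_added <- 0
  if (nrow(add) > 0) {
    kinds <- vapply(products, `[[`, character(1), "kind")
    carb_added <- sum(add$amount[kinds == "carbohydrate"])
  }
  contributions <- stats::setNames(numeric(nrow(add)), add$product)
  if (mode == "linear") {
    for (i in seq_along(products)) {
      if (products[[i]]$kind == "hmf" && !is.null(add$unit) &&
          !is.na(add$unit[i]) && tolower(add$unit[i]) %in% c("g", "gram", "grams"))
        stop("HMF amount given in grams but sachet mass is not modelled",
             call. = FALSE)
      contributions[i] <- linear_increment(products[[i]], add$amount[i])
    }
    total <- base$osmolality + sum(contributions)
  } else {
    w0 <- base$water_mass / 100
    osm <- numeric(nrow(add))
    wadd <- numeric(nrow(add))
    for (i in seq_along(products)) {
      osm[i] <- osmoles_added(products[[i]], add$amount[i], base$water_mass)
      wadd[i] <- products[[i]]$water_per_unit * add$amount[i] / 100
    }
    wf <- w0 + sum(wadd)
    total <- (base$osmolality * w0 + sum(osm)) / wf
    # exact decomposition: solute gain minus the share of base dilution
    contributions[] <- (osm - base$osmolality * wadd) / wf
  }
  # duplicate products: collapse contributions by name
  if (anyDuplicated(names(contributions))) {
    contributions <- tapply(contributions, names(contributions), sum)
    contributions <- contributions[unique(add$product)]
  }
  stored <- storage_adjust(total, carb_added, model)
  structure(
    list(total = total, contributions = as.list(contributions), mode = mode,
         storage_adjusted = stored, carb_added = carb_added,
         exceeds_limit = total > model$safety_limit,
         base_osmolality = base$osmolality),
    class = "osmolality_prediction"
  )
}

#' @export
print.osmolality_prediction <- function(x, ...) {
  cat(sprintf("<osmolality_prediction> %s mode\n", x$mode))
  cat(sprintf("  base      %8.0f mOsm/kg\n", x$base_osmolality))
  for (nm in names(x$contributions))
    cat(sprintf("  %-9s %+8.1f mOsm/kg\n", nm, x$contributions[[nm]]))
  cat(sprintf("  total     %8.0f mOsm/kg (after 24 h at 4 C: %.0f)\n",
              x$total, x$storage_adjusted))
  cat(sprintf("  exceeds safety limit: %s\n",
              if (x$exceeds_limit) "YES" else "no"))
  invisible(x)
}

#' Dilute an osmolality by added water
#'
#' Pure dilution with conservation of total milliosmoles: adding solute-free
#' water `w` to a solution of osmolality `x` over water mass `w0` yields
#' `x * w0 / (w0 + w)`. This is the entire osmotic effect of a 50% fat in
#' water emulsion.
#'
#' @param osmolality Starting osmolality, mOsm/kg.
#' @param water_added Grams of water added (>= 0).
#' @param water_base Grams of solvent water before the addition (> 0).
#' @return The diluted osmolality in mOsm/kg.
#' @export
#' @examples
#' apply_dilution(300, 12.5, 87.5) # 262.5
apply_dilution <- function(osmolality, water_added, water_base) {
  check_number(osmolality, "osmolality")
  check_number(water_added, "water_added", min = 0)
  check_number(water_base, "water_base")
  if (water_base <= 0) stop("`water_base` must be > 0 g", call. = FALSE)
  osmolality * water_base / (water_base + water_added)
}

#' Adjust a prediction for 24 h cold storage
#'
#' Milk amylase breaks glucose polymer down into smaller saccharides during
#' storage, raising osmolality; feeds with no added carbohydrate are
#' unaffected. Flat mode multiplies the total by the model's
#' `storage_factor` whenever added carbohydrate is present; proportional
#' mode adds `storage_slope` mOsm/kg per gram of added carbohydrate, so the
#' adjustment is non-decreasing in the amount added.
#'
#' @param prediction An `osmolality_prediction` or a numeric total, mOsm/kg.
#' @param carb_added Grams of carbohydrate supplement added per 100 mL
#'   (taken from the prediction when one is supplied).
#' @param model An [osmolality_model()].
#' @return The storage-adjusted osmolality in mOsm/kg.
#' @export
#' @examples
#' m <- default_model()
#' storage_adjust(400, carb_added = 1.5, model = m) # 416
#' storage_adjust(400, carb_added = 0,   model = m) # 400
storage_adjust <- function(prediction, carb_added = NULL, model) {
  if (inherits(prediction, "osmolality_prediction")) {
    if (is.null(carb_added)) carb_added <- prediction$carb_added
    total <- prediction$total
  } else {
    total <- prediction
    check_number(total, "prediction")
    if (is.null(carb_added))
      stop("`carb_added` is required with a numeric total", call. = FALSE)
  }
  check_number(carb_added, "carb_added", min = 0)
  if (carb_added == 0) return(total)
  switch(model$storage_mode,
         flat = total * model$storage_factor,
         proportional_to_carb = total + model$storage_slope * carb_added)
}
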