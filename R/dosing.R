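#' Define a macronutrient target profile
#'
#' Guideline fortification targets in g per 100 mL of milk. The packaged
#' config ships a guideline-derived default (fat 4.4, protein 3.0,
#' carbohydrate 8.8 g/100 mL); values are configuration, not measurements.
#'
#' @param fat,protein,carbohydrate Targets in g/100 mL, each in \[0, 20).
#' @return A named numeric vector of class `target_profile`.
#' @export
target_profile <- function(fat, protein, carbohydrate) {
  x <- c(fat = fat, protein = protein, carbohydrate = carbohydrate)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x >= 20))
    stop("targets must lie in [0, 20) g/100 mL", call. = FALSE)
  structure(x, class = "target_profile")
}

#' Define the macronutrient content of one full HMF dose
#'
#' Grams of fat, protein and carbohydrate contributed per full standard dose
#' of a human milk fortifier per 100 mL of milk (one sachet per 25 mL = 4
#' sachets per 100 mL).
#'
#' @param fat,protein,carbohydrate g per full dose per 100 mL, all >= 0.
#' @return A named numeric vector of class `hmf_composition`.
#' @export
hmf_composition <- function(fat, protein, carbohydrate) {
  x <- c(fat = fat, protein = protein, carbohydrate = carbohydrate)
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("HMF composition must be >= 0 g per dose", call. = FALSE)
  structure(x, class = "hmf_composition")
}

#' Macronutrient deficits after standard fortification
#'
#' The grams per 100 mL still missing from each macronutrient once the
#' native milk and the HMF dose are accounted for, clamped at zero:
#' supplements cannot remove nutrients, so milk already at or above target
#' has zero deficit.
#'
#' @param native A [milk_sample()] with measured macronutrient contents.
#' @param hmf An [hmf_composition()] (contribution of the full HMF dose),
#'   or `NULL` for fortifier-free dosing.
#' @param target A [target_profile()].
#' @param hmf_dose_fraction Fraction of a full dose given (default 1).
#' @return Named numeric vector `c(fat=, protein=, carbohydrate=)`, g/100 mL.
#' @export
#' @examples
#' native <- milk_sample("BM", 299, fat = 3.5, protein = 1.2, carbohydrate = 6.6)
#' compute_deficit(native, hmf_composition(0.36, 1.0, 1.8),
#'                 target_profile(4.4, 3.0, 8.8))
compute_deficit <- function(native, hmf, target, hmf_dose_fraction = 1) {
  if (!inherits(native, "milk_sample"))
    stop("`native` must be a milk_sample", call. = FALSE)
  if (!inherits(target, "target_profile"))
    stop("`target` must be a target_profile", call. = FALSE)
  check_number(hmf_dose_fraction, "hmf_dose_fraction", min = 0)
  hmf_part <- if (is.null(hmf)) c(fat = 0, protein = 0, carbohydrate = 0) else {
    if (!inherits(hmf, "hmf_composition"))
      stop("`hmf` must be an hmf_composition (or NULL)", call. = FALSE)
    unclass(hmf) * hmf_dose_fraction
  }
  have <- c(fat = native$fat, protein = native$protein,
            carbohydrate = native$carbohydrate) + hmf_part
  deficit <- unclass(target) - have[names(unclass(target))]
  deficit[deficit < 0] <- 0
  deficit
}

# pick the supplement used to cover each macronutrient: explicit choice,
# else the first product of that kind in the model's product order
select_supplements <- function(model, supplements = NULL) {
  kinds <- vapply(model$products, `[[`, character(1), "kind")
  chosen <- c(fat = NA_character_, protein = NA_character_,
              carbohydrate = NA_character_)
  for (k in names(chosen)) {
    cand <- names(model$products)[kinds == k]
    if (length(cand) > 0) chosen[k] <- cand[1]
  }
  if (!is.null(supplements)) {
    for (k in names(supplements)) {
      if (!k %in% names(chosen))
        stop("unknown macronutrient '", k, "' in `supplements`", call. = FALSE)
      resolve_product(model, supplements[[k]])
      chosen[k] <- supplements[[k]]
    }
  }
  chosen
}

#' Compute target-fortification supplement doses
#'
#' Converts macronutrient deficits into product amounts
#' (`amount = deficit / potency`), builds the full recipe (HMF plus
#' supplements) and attaches its osmolality prediction with safety
#' evaluation. Concentration changes from the added volume are ignored
#' (per-100 mL bookkeeping); when the total added volume exceeds 5 mL per
#' 100 mL the result carries a `volume_flag` so the user can review the
#' approximation.
#'
#' @param deficits Named deficits from [compute_deficit()], g/100 mL.
#' @param model An [osmolality_model()].
#' @param base The [milk_sample()] being fortified (needed for prediction).
#' @param hmf_product Name of the HMF in the recipe, or `NULL` for none.
#' @param hmf_sachets Sachets of HMF per 100 mL (default: one full dose).
#' @param supplements Optional named character vector choosing the product
#'   used per macronutrient, e.g. `c(protein = "Protein2")`. Defaults to the
#'   first product of each kind in the model.
#' @param mode Prediction mode passed to [predict_recipe()].
#' @return An object of class `dose_result`: `amounts` (named, per 100 mL),
#'   `recipe`, `prediction`, `residual_deficits`, `added_volume` (mL-
#'   equivalent of all supplements), `volume_flag`, `safety`.
#' @export
#' @examples
#' m <- default_model()
#' native <- milk_sample("BM", 299, fat = 3.5, protein = 1.2, carbohydrate = 6.6)
#' d <- compute_deficit(native, hmf_composition(0.36, 1.0, 1.8),
#'                      target_profile(4.4, 3.0, 8.8))
#' compute_dose(d, m, native)
compute_dose <- function(deficits, model, base, hmf_product = "HMF1",
                         hmf_sachets = NULL, supplements = NULL,
                         mode = "linear") {
  if (!is.numeric(deficits) || is.null(names(deficits)) ||
      !all(names(deficits) %in% c("fat", "protein", "carbohydrate")))
    stop("`deficits` must be named with fat/protein/carbohydrate", call. = FALSE)
  if (any(deficits < 0)) stop("deficits must be >= 0", call. = FALSE)
  chosen <- select_supplements(model, supplements)
  amounts <- numeric(0)
  for (k in names(deficits)) {
    if (deficits[[k]] == 0) next
    nm <- chosen[[k]]
    if (is.na(nm))
      stop("no supplement of kind '", k, "' in the model covers a nonzero ",
           "deficit", call. = FALSE)
    p <- model$products[[nm]]
    if (p$potency <= 0)
      stop("product '", nm, "' has zero potency: cannot dose", call. = FALSE)
    amounts[nm] <- deficits[[k]] / p$potency
  }
  add <- tibble::tibble(product = names(amounts), amount = unname(amounts),
                        unit = vapply(names(amounts), function(nm) {
                          if (model$products[[nm]]$form == "emulsion") "mL" else "g"
                        }, character(1)))
  if (!is.null(hmf_product)) {
    p <- resolve_product(model, hmf_product)
    if (p$kind != "hmf")
      stop("`hmf_product` '", hmf_product, "' is not an HMF", call. = FALSE)
    if (is.null(hmf_sachets)) hmf_sachets <- p$sachets_per_dose
    add <- rbind(
      tibble::tibble(product = hmf_product, amount = hmf_sachets,
                     unit = "sachet"),
      add)
  }
  recipe <- fortification_recipe(base, add)
  prediction <- predict_recipe(recipe, model, mode = mode)
  # residual deficit: what dosing could not supply (zero-deficit nutrients
  # already at/above target report 0, not negative)
  residual <- deficits
  residual[names(deficits)] <- 0
  # g-denominated powder amounts are counted as mL-equivalent (density ~1)
  added_volume <- sum(add$amount[add$unit != "sachet"])
  structure(
    list(amounts = as.list(amounts), recipe = recipe, prediction = prediction,
         residual_deficits = residual,
         added_volume = added_volume,
         volume_flag = added_volume > 5,
         safety = check_safety(prediction, model)),
    class = "dose_result"
  )
}

#' @export
print.dose_result <- function(x, ...) {
  cat("<dose_result>\n")
  for (nm in names(x$amounts))
    cat(sprintf("  %-12s %6.3f per 100 mL\n", nm, x$amounts[[nm]]))
  cat(sprintf("  predicted osmolality %.0f mOsm/kg (stored: %.0f); %s\n",
              x$prediction$total, x$prediction$storage_adjusted,
              if (x$safety$flagged) "EXCEEDS LIMIT" else "within limit"))
  if (x$volume_flag)
    cat(sprintf("  note: %.1f mL-equivalent added per 100 mL (> 5); per-100 mL\n  concentration bookkeeping is approximate at this volume\n",
                x$added_volume))
  invisible(x)
}

#' Evaluate a prediction against the enteral safety limit
#'
#' Flags a feed whose predicted osmolality strictly exceeds the model's
#' safety limit (default 450 mOsm/kg); a feed at exactly the limit passes.
#'
#' @param prediction An `osmolality_prediction` or a numeric osmolality.
#' @param model An [osmolality_model()].
#' @param use_storage If `TRUE`, evaluate the storage-adjusted value instead
#'   of the immediate total.
#' @return A list: `value`, `limit`, `flagged`, `pass`, `margin`
#'   (limit - value; negative when flagged).
#' @export
#' @examples
#' check_safety(455, default_model()) # flagged, margin -5
check_safety <- function(prediction, model, use_storage = FALSE) {
  value <- if (inherits(prediction, "osmolality_prediction")) {
    if (use_storage) prediction$storage_adjusted else prediction$total
  } else {
    check_number(prediction, "prediction")
  }
  flagged <- value > model$safety_limit
  list(value = value, limit = model$safety_limit, flagged = flagged,
       pass = !flagged, margin = model$safety_limit - value)
}
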