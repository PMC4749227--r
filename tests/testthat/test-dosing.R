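hmf1_comp <- hmf_composition(fat = 0.36, protein = 1.0, carbohydrate = 1.8)
target_std <- target_profile(fat = 4.4, protein = 3.0, carbohydrate = 8.8)

test_that("deficits are target minus supply, clamped at zero", {
  native <- milk_sample("n", 299, fat = 3.5, protein = 1.2, carbohydrate = 6.6)
  d <- compute_deficit(native, hmf1_comp, target_std)
  expect_equal(d[["carbohydrate"]], 8.8 - 6.6 - 1.8)
  expect_equal(d[["protein"]], 3.0 - 1.2 - 1.0)
  expect_equal(d[["fat"]], 4.4 - 3.5 - 0.36)

  # rich milk at or above target: nothing to add
  rich <- milk_sample("r", 299, fat = 6, protein = 3.5, carbohydrate = 9)
  expect_equal(unname(compute_deficit(rich, hmf1_comp, target_std)),
               c(0, 0, 0))
  # boundary: exactly at target
  exact <- milk_sample("e", 299, fat = 4.4 - 0.36, protein = 2.0,
                       carbohydrate = 7.0)
  d2 <- compute_deficit(exact, hmf1_comp, target_profile(4.4, 3.0, 8.8))
  expect_equal(d2[["fat"]], 0)
})

test_that("doses are deficit over potency, with predicted osmolality attached", {
  native <- milk_sample("n", 299, fat = 3.5, protein = 1.2, carbohydrate = 6.6)
  d <- c(fat = 0, protein = 0, carbohydrate = 0.4)
  dr <- compute_dose(d, test_model, native)
  expect_equal(dr$amounts$Polycose, 0.4 / 0.94, tolerance = 1e-12)
  # prediction includes the HMF dose
  expect_equal(dr$prediction$total,
               299 + 106 + 20 * 0.4 / 0.94, tolerance = 1e-12)

  # fat deficit through a 0.5 g/mL emulsion
  dr2 <- compute_dose(c(fat = 0.65, protein = 0, carbohydrate = 0),
                      test_model, native)
  expect_equal(dr2$amounts$Microlipid, 1.3, tolerance = 1e-12)

  # zero deficits: HMF-only recipe
  dr3 <- compute_dose(c(fat = 0, protein = 0, carbohydrate = 0),
                      test_model, native)
  expect_length(dr3$amounts, 0)
  expect_equal(dr3$prediction$total, 299 + 106)
})

test_that("dosing error paths name the problem", {
  native <- milk_sample("n", 299)
  zero_pot <- osmolality_model(list(
    supplement_product("BadCarb", "carbohydrate", "powder", potency = 0,
                       linear_coeff = 20)))
  expect_error(compute_dose(c(carbohydrate = 0.5), zero_pot, native,
                            hmf_product = NULL), "zero potency")
  no_fat <- osmolality_model(test_model$products[c("Polycose", "Protein1")])
  expect_error(compute_dose(c(fat = 0.5), no_fat, native, hmf_product = NULL),
               "no supplement of kind 'fat'")
  expect_error(compute_dose(c(carbohydrate = -0.1), test_model, native),
               ">= 0")
})

test_that("computed doses reproduce the target profile (round trip)", {
  set.seed(31)
  potency <- c(fat = 0.5, protein = 0.857, carbohydrate = 0.94)
  kind_of <- c(Microlipid = "fat", Protein1 = "protein", Polycose = "carbohydrate")
  for (rep in 1:100) {
    native <- random_sample()
    def <- compute_deficit(native, hmf1_comp, target_std)
    dr <- compute_dose(def, test_model, native)
    achieved <- c(fat = native$fat, protein = native$protein,
                  carbohydrate = native$carbohydrate) + unclass(hmf1_comp)
    for (nm in names(dr$amounts)) {
      k <- kind_of[[nm]]
      achieved[k] <- achieved[k] + dr$amounts[[nm]] * potency[[k]]
    }
    for (k in names(def)) {
      if (def[[k]] > 0) {
        expect_equal(achieved[[k]], unclass(target_std)[[k]],
                     tolerance = 1e-9)
      }
    }
    # round trip: re-predicting the stored recipe reproduces the stored
    # prediction exactly
    expect_equal(predict_recipe(dr$recipe, test_model)$total,
                 dr$prediction$total, tolerance = 1e-12)
    expect_true(all(unlist(dr$amounts) >= 0))
  }
})

test_that("raising a target never lowers its dose", {
  native <- milk_sample("n", 299, fat = 3.5, protein = 1.2, carbohydrate = 6.6)
  doses <- vapply(seq(8.5, 10.5, by = 0.5), function(tc) {
    def <- compute_deficit(native, hmf1_comp, target_profile(4.4, 3.0, tc))
    dr <- compute_dose(def, test_model, native)
    if (is.null(dr$amounts$Polycose)) 0 else dr$amounts$Polycose
  }, numeric(1))
  expect_true(all(diff(doses) >= 0))
})

test_that("safety check is strict at the 450 mOsm/kg limit", {
  s <- check_safety(455, test_model)
  expect_true(s$flagged)
  expect_equal(s$margin, -5)
  expect_false(check_safety(450, test_model)$flagged)  # boundary passes
  expect_false(check_safety(436, test_model)$flagged)  # tolerated in practice
  # storage-adjusted value can flag when the fresh one passes
  rec <- fortification_recipe(milk_sample("s", 299),
                              data.frame(product = c("HMF1", "Polycose"),
                                         amount = c(4, 2.1)))
  p <- predict_recipe(rec, test_model)
  expect_false(check_safety(p, test_model)$flagged)
  expect_true(check_safety(p, test_model, use_storage = TRUE)$flagged)
})

test_that("large added volumes raise the bookkeeping flag", {
  native <- milk_sample("thin", 299, fat = 1.0, protein = 0.5,
                        carbohydrate = 5.0)
  def <- compute_deficit(native, hmf1_comp, target_std)
  dr <- compute_dose(def, test_model, native)
  expect_gt(dr$added_volume, 5)
  expect_true(dr$volume_flag)
})
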