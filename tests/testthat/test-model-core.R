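test_that("single-addition increments match the calibrated coefficients", {
  # glucose polymer: +20 mOsm/kg per g per 100 mL
  expect_equal(predict_increase("Polycose", 1.0, base_299, model = test_model), 20)
  # zero addition contributes nothing, for every product
  for (nm in names(test_model$products)) {
    expect_equal(predict_increase(nm, 0, base_299, model = test_model), 0)
    expect_equal(predict_increase(nm, 0, base_299, mode = "mechanistic",
                                  model = test_model), 0)
  }
  # hydrolyzed protein: 0.5 g of a 38 mOsm/kg-per-g supplement
  expect_equal(predict_increase("Protein2", 0.5, base_299, model = test_model), 19)
  # HMF dosing is per sachet: a full 4-sachet dose gives the full offset
  expect_equal(predict_increase("HMF1", 4, base_299, model = test_model), 106)
  expect_equal(predict_increase("HMF1", 2, base_299, model = test_model), 53)
})

test_that("increment validation rejects bad inputs", {
  expect_error(predict_increase("NoSuchProduct", 1, base_299, model = test_model),
               "unknown product")
  expect_error(predict_increase("Polycose", -1, base_299, model = test_model),
               ">=")
  expect_error(predict_increase("HMF1", 3, base_299, unit = "g",
                                model = test_model), "sachet")
})

test_that("recipe prediction is additive over the base osmolality", {
  # identity: no additions
  empty <- fortification_recipe(milk_sample("e", 300))
  p0 <- predict_recipe(empty, test_model)
  expect_equal(p0$total, 300)
  expect_false(p0$exceeds_limit)
  expect_equal(p0$storage_adjusted, p0$total)

  # base 300 + full HMF1 dose
  r <- fortification_recipe(milk_sample("h", 300),
                            data.frame(product = "HMF1", amount = 4,
                                       unit = "sachet"))
  expect_equal(predict_recipe(r, test_model)$total, 406)

  # clinical-style combination: 299 + 106 + 1.8 g carb + 1.2 g whey
  r <- fortification_recipe(
    milk_sample("c", 299),
    data.frame(product = c("HMF1", "Polycose", "Protein1"),
               amount = c(4, 1.8, 1.2)))
  p <- predict_recipe(r, test_model)
  expect_equal(p$total, 445.8)
  expect_false(p$exceeds_limit)
})

test_that("linear totals equal base + independent increments, any order", {
  set.seed(11)
  for (rep in 1:25) {
    rec <- random_recipe()
    p <- predict_recipe(rec, test_model)
    inc <- vapply(seq_len(nrow(rec$additions)), function(i) {
      predict_increase(rec$additions$product[i], rec$additions$amount[i],
                       rec$base, model = test_model)
    }, numeric(1))
    expect_equal(p$total, rec$base$osmolality + sum(inc),
                 tolerance = 1e-12)
    expect_equal(p$total, rec$base$osmolality +
                   sum(unlist(p$contributions)), tolerance = 1e-12)
    # permuting the addition rows changes nothing
    perm <- sample(nrow(rec$additions))
    rec2 <- fortification_recipe(rec$base, rec$additions[perm, ])
    expect_equal(predict_recipe(rec2, test_model)$total, p$total,
                 tolerance = 1e-12)
  }
})

test_that("mechanistic mode agrees with linear mode for anhydrous powders", {
  set.seed(12)
  for (rep in 1:20) {
    base <- random_sample()
    amount <- runif(1, 0.1, 3)
    for (nm in c("Polycose", "Protein1", "Protein2")) {
      lin <- predict_increase(nm, amount, base, model = test_model)
      mech <- predict_increase(nm, amount, base, mode = "mechanistic",
                               model = test_model)
      # osmoles_per_gram is derived from the slope at the sample's own water
      # mass, so the two routes coincide exactly
      expect_equal(mech, lin, tolerance = 1e-12)
    }
  }
})

test_that("mechanistic mode conserves osmoles across any recipe", {
  set.seed(13)
  for (rep in 1:20) {
    rec <- random_recipe()
    p <- predict_recipe(rec, test_model, mode = "mechanistic")
    w0 <- rec$base$water_mass / 100
    wadd <- 0; osm_add <- 0
    for (i in seq_len(nrow(rec$additions))) {
      prod <- test_model$products[[rec$additions$product[i]]]
      a <- rec$additions$amount[i]
      wadd <- wadd + prod$water_per_unit * a / 100
      opg <- if (prod$kind == "hmf") {
        prod$dose_offset / prod$sachets_per_dose * rec$base$water_mass / 100
      } else if (prod$form == "powder") {
        prod$linear_coeff * rec$base$water_mass / 100
      } else 0
      osm_add <- osm_add + opg * a
    }
    lhs <- p$total * (w0 + wadd)
    rhs <- rec$base$osmolality * w0 + osm_add
    expect_equal(lhs, rhs, tolerance = 1e-12)
    # contributions still decompose the total exactly
    expect_equal(p$total,
                 rec$base$osmolality + sum(unlist(p$contributions)),
                 tolerance = 1e-9)
  }
})

test_that("dilution is exact, monotone and minimal for fat emulsion", {
  expect_equal(apply_dilution(300, 0, 87.5), 300)
  expect_equal(apply_dilution(300, 12.5, 87.5), 262.5)
  # 1 mL of a 50% fat-in-water emulsion adds 0.5 g water
  expect_equal(apply_dilution(300, 0.5, 87.5), 300 * 87.5 / 88)
  expect_error(apply_dilution(300, -1, 87.5), ">=")
  expect_error(apply_dilution(300, 1, 0), "> 0")

  # adding a solute-free emulsion strictly decreases osmolality, by less
  # than 2 mOsm/kg per mL at a 300 mOsm/kg / 87.5 g-water baseline
  base <- milk_sample("d", 300, water_mass = 87.5)
  prev <- 300
  for (ml in c(1, 2, 3, 4)) {
    inc <- predict_increase("Microlipid", ml, base, mode = "mechanistic",
                            model = test_model)
    expect_lt(inc, 0)
    expect_lt(300 + inc, prev)
    prev <- 300 + inc
  }
  per_ml <- predict_increase("Microlipid", 1, base, mode = "mechanistic",
                             model = test_model)
  expect_lt(abs(per_ml), 2)
})

test_that("storage adjustment follows the carbohydrate rule", {
  expect_equal(storage_adjust(400, carb_added = 1.5, model = test_model), 416)
  expect_equal(storage_adjust(400, carb_added = 0, model = test_model), 400)

  prop <- osmolality_model(test_model$products,
                           storage_mode = "proportional_to_carb",
                           storage_slope = 9)
  vals <- vapply(c(0.5, 1, 1.5, 2), function(c_add) {
    storage_adjust(400, carb_added = c_add, model = prop)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, 400 + 9 * c(0.5, 1, 1.5, 2))

  # a recipe with carbohydrate stores higher than fresh; without, unchanged
  rec <- fortification_recipe(base_299,
                              data.frame(product = "Polycose", amount = 1.5))
  p <- predict_recipe(rec, test_model)
  expect_gt(p$storage_adjusted, p$total)
  rec0 <- fortification_recipe(base_299,
                               data.frame(product = "Protein1", amount = 1))
  p0 <- predict_recipe(rec0, test_model)
  expect_equal(p0$storage_adjusted, p0$total)
})

test_that("predicted totals are finite and positive over random recipes", {
  set.seed(14)
  for (rep in 1:30) {
    for (mode in c("linear", "mechanistic")) {
      p <- predict_recipe(random_recipe(), test_model, mode = mode)
      expect_true(is.finite(p$total) && p$total > 0)
    }
  }
})

test_that("domain type invariants are enforced", {
  expect_error(milk_sample("x", osmolality = 0), "0, 2000")
  expect_error(milk_sample("x", 300, fat = 60, protein = 30, carbohydrate = 15),
               "< 100")
  expect_error(milk_sample("x", 300, water_mass = 45), "50, 100")
  expect_error(supplement_product("p", "carbohydrate", "powder", potency = 1.2,
                                  linear_coeff = 20), "0, 1")
  expect_error(supplement_product("p", "carbohydrate", "powder", potency = 0.9,
                                  water_per_unit = 0.1, linear_coeff = 20),
               "anhydrous")
  expect_error(supplement_product("p", "hmf", "sachet", potency = 0,
                                  linear_coeff = 5, dose_offset = 100),
               "dose_offset")
  expect_error(supplement_product("p", "protein", "powder", potency = 0.9,
                                  dose_offset = 100), "linear_coeff")
  dup <- test_model$products[[1]]
  expect_error(osmolality_model(list(dup, dup)), "duplicate")
  expect_error(osmolality_model(test_model$products, storage_factor = 0.9),
               ">= 1")
})
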