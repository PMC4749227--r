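# shared fixtures: the packaged model and a plain 299 mOsm/kg base sample
test_model <- default_model()
base_299 <- milk_sample("BM", osmolality = 299, fat = 3.5, protein = 1.2,
                        carbohydrate = 6.6)

# a random but valid milk sample, for property-style loops
random_sample <- function() {
  milk_sample("rnd",
              osmolality = runif(1, 280, 320),
              fat = runif(1, 2, 5), protein = runif(1, 0.8, 2),
              carbohydrate = runif(1, 5, 8),
              water_mass = runif(1, 85, 90))
}

# a random recipe over the packaged products (amounts in clinical ranges)
random_recipe <- function(base = random_sample()) {
  fortification_recipe(base, data.frame(
    product = c("HMF1", "Polycose", "Protein1", "Protein2", "Microlipid"),
    amount = c(sample(0:4, 1), runif(1, 0, 2.7), runif(1, 0, 1.5),
               runif(1, 0, 1.5), runif(1, 0, 3.2)),
    unit = c("sachet", "g", "g", "g", "mL")))
}
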