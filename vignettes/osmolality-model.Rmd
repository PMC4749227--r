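---
title: "Predicting the osmolality of fortified breast milk: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the osmolality of fortified breast milk: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkosm)
```

## The additive linear model

Freezing-point osmolality of a milk feed responds, over the clinically
relevant range, linearly and independently to each supplement added.
`milkosm`'s core assumption is therefore additivity: for a base milk of
osmolality $O_0$ (mOsm/kg) fortified per 100 mL with $m_C$ g of glucose
polymer, $m_P$ g of a protein supplement, $v_F$ mL of fat emulsion and $s$
sachets of a human milk fortifier,

$$O_\text{pred} = O_0 + k_C m_C + k_P m_P + k_F v_F +
  \Delta_\text{HMF}\,\frac{s}{4}.$$

The coefficients are *product properties*, not universal constants: a
hydrolyzed protein carries almost ten times the osmotic load per gram of a
whey isolate, because hydrolysis multiplies the number of dissolved
particles and the two powders differ in mineral content. The packaged
defaults are:

| product | kind | coefficient | unit |
|---|---|---|---|
| Polycose | glucose polymer | +20 | mOsm/kg per g |
| Protein1 | whey protein isolate | +4 | mOsm/kg per g |
| Protein2 | hydrolyzed whey/casein | +38 | mOsm/kg per g |
| Microlipid | 50% fat-in-water emulsion | −1.7 | mOsm/kg per mL |
| HMF1 | multi-component fortifier | +106 | mOsm/kg per full dose |
| HMF2 | multi-component fortifier | +56 | mOsm/kg per full dose |

HMF amounts are denominated in sachets (4 per 100 mL = one full dose;
fractional doses scale linearly). Gram-denominated HMF amounts are rejected
rather than guessed at, since sachet mass is not part of the model.

Any product not in this table must be calibrated before use — coefficients
do not transfer between brands. All amounts are normalised to "per 100 mL
of base milk"; bench work on 25 mL aliquots is converted on ingestion
(`read_batch(..., basis = "per_25ml")` multiplies by 4).

## Mechanistic mode and the fat coefficient

Fat emulsion has no printed calibration slope; its osmotic effect is pure
dilution by its aqueous phase. The default $k_F$ is therefore derived, not
fitted: 1 mL of a 50% emulsion adds 0.5 g of solute-free water to the
~87.5 g of solvent water in 100 mL of milk, giving

$$\Delta O = O_0\left(\frac{87.5}{87.5 + 0.5} - 1\right) \approx
  -1.70\ \text{mOsm/kg per mL at } O_0 = 300.$$

The config value (−1.7) is overridable for units that fit their own
emulsion slope.

The **mechanistic** prediction mode makes this bookkeeping explicit for all
products: each addition contributes effective osmoles
(`osmoles_per_gram × amount`) and water (`water_per_unit × amount`), and
the final osmolality is total osmoles over total water. For anhydrous
powders the derivation `osmoles_per_gram = linear_coeff × water_mass/100`
makes the two modes agree exactly, which the test suite checks to 1e-9
relative; the modes differ only where water is added. Internally water is
counted in units of `water_mass/100`; the convention cancels out of every
observable, and osmole conservation — final osmolality × final water =
initial osmoles + added osmoles — holds to machine precision by
construction. The default solvent water mass, 87.5 g/100 mL, is a
literature-typical value for mature human milk and is configurable per
sample; powders are assumed anhydrous.

## Storage adjustment

Milk amylase hydrolyses glucose polymer during refrigerated storage,
multiplying dissolved particles. Feeds with added carbohydrate stored 24 h
at 4 °C rise by about 4% in osmolality; feeds without added carbohydrate do
not. The default (`storage_mode = "flat"`) multiplies the predicted total
by `storage_factor = 1.04` whenever added carbohydrate is positive. Because
the rise in fact grows with the amount of carbohydrate added, a
`proportional_to_carb` mode is provided that adds `storage_slope` mOsm/kg
per gram of added glucose polymer. No calibrated slope is published, so the
default (9 mOsm/kg per g) was set once so that the mean adjustment over the
clinical carbohydrate range (1.1–2.7 g/100 mL) matches the flat 4% on a
typical ~400 mOsm/kg feed. Whether the 4% applies to the whole osmolality
or only its carbohydrate-attributable fraction is empirically open; the
flat whole-total reading is the default because it is what a percent-change
report most directly supports.

## Target-fortification dosing

Dosing proceeds per 100 mL: deficit = max(0, target − native − HMF
contribution) for each macronutrient, then amount = deficit / potency for
the designated supplement. Clamping at zero is a deliberate policy —
supplements cannot remove nutrients, and milk already above target is left
alone rather than diluted. The safety comparison is strict (`> 450`
flags; exactly 450 passes) and is applied to both the immediate and the
storage-adjusted prediction.

Two bookkeeping choices matter. First, added volume is ignored when
computing concentrations: doses are computed against 100 mL of *base* milk,
matching clinical per-100 mL arithmetic. A `volume_flag` is raised when
more than 5 mL-equivalent of supplements is added per 100 mL, where that
approximation starts to bite. Second, where a model carries two protein
products, the default supplement per macronutrient is the *first* of its
kind in the product list — the packaged config lists the whey isolate
first, since low-osmolality whey is what target-fortification practice
reaches for; pass `supplements = c(protein = "Protein2")` to override.
The target profile and HMF macronutrient composition ship in the config as
guideline-derived defaults and are configuration, not claims.

## Calibration

`fit_titration()` is ordinary least squares of osmolality *increase over
native* on amount added. The default estimates a free intercept —
spreadsheet regression style, and robust to a small constant measurement
offset — while `through_origin` enforces the physical constraint that zero
addition yields zero increase; for clean data the two converge, which is
tested. $R^2$ is computed against the mean (free) or against zero
(through-origin), and inputs can be given as increments or as absolute
osmolalities with a native reference, since published fit statistics do not
always say which was used. Fortifier offsets (`fit_offset()`) are the mean
and sample SD (n−1 denominator throughout the package) of paired
fortified-minus-native differences. `coefficients_to_model()` overlays any
subset of freshly fitted coefficients on the packaged defaults and records
per-product provenance.

## QC flagging

A batch is flagged when |measured − predicted| exceeds `qc_threshold`
(default 22 mOsm/kg ≈ |mean| + 2 SD of clinical measured-vs-predicted
agreement, there being no published explicit threshold), or when the
measured value exceeds the safety limit; the `reason` field distinguishes
`deviation`, `safety_limit` and `both`. Differences are measured −
predicted. Cohort agreement is summarised Bland–Altman style: mean, sample
SD, mean ± 1.96 SD limits of agreement, plus an unthresholded one-sample
t statistic.

The error-detection experiment counts **deviation flags only** when
computing sensitivity and false-flag rate. Safety flags respond to a feed's
absolute osmolality, not to whether it was mixed correctly; a
target-fortified cohort sits near the 450 limit, so including them would
inflate the false-flag rate with correctly prepared, merely concentrated
feeds. Under Gaussian noise with SD 11 and threshold 22 = 2 SD, the
expected false-flag rate is the two-sided 2-SD tail, ≈ 4.6%, and a +60
mOsm/kg error is detected with probability ≈ 0.9997 — both checked against
simulation in the acceptance tests.

## The synthetic-data generator

Every statistical claim in the test suite runs on generated data, so what
the generator does and does not emulate bounds what the tests show.
`simulate_cohort()` draws native osmolality from N(299, 6²) mOsm/kg; native
composition from independent normals (fat 3.5 ± 0.6, protein 1.2 ± 0.25,
carbohydrate 6.6 ± 0.4 g/100 mL — literature-typical values, a generator
assumption); supplement additions uniformly within the clinical ranges
(fat 0.0–3.2 mL, protein 0.6–1.5 g, carbohydrate 1.1–2.7 g per 100 mL),
with a triangular option centred on the clinical means (1.3, 1.2, 1.8) for
users who prefer mass near the centre; a full HMF1 dose per batch; then
computes the *true* final osmolality with the prediction model itself and
overlays N(0, 11²) osmometer noise plus a +60 mOsm/kg shift on a seeded 5%
of batches. Titration ladders default to the bench protocol per 100 mL:
carbohydrate {0.5, 1, 1.5, 2} g, protein {0.2, 0.5, 1, 2} g, fat
{0.5, 1, 2, 4} mL.

Because the generator's truth *is* the model's prediction, closed-loop
tests (calibration recovers generator slopes; QC sees zero mean and SD at
zero noise) demonstrate internal consistency and correct statistics — they
cannot detect real-world model misspecification, nonlinearity at extreme
doses, product lot variation, or amylase kinetics. Those require titration
and cohort CSVs from an actual laboratory, which the same entry points
accept.

Seeding is hierarchical: the single user seed is split into a fixed
substream per generated column (an affine map into [0, 2³¹) per column
key), so every generator is a pure function of (config, seed) and adding a
new column never perturbs existing ones — tested by toggling the error rate
and checking the osmolality columns bit-for-bit.

## Numerical choices and problem sizes

All computation is in double precision with no internal rounding; print
methods round osmolality to whole mOsm/kg, the field's reporting precision.
Degenerate calibration designs (all amounts identical, or fewer points than
parameters) raise errors rather than NaN slopes. Exact-fit checks use 1e-9
relative tolerance; Monte-Carlo checks use 3-standard-error bands at fixed
seeds. The routine suite runs calibration recovery at 1000 replicates per
product (noise SD 2), cohort distribution checks at n = 10⁴, error
detection at n = 1000, and dosing round-trips on 100 random samples —
sizes at which every assertion's sampling error is far below its tolerance
while the whole suite stays interactive.

## Limitations

The model is product-specific: coefficients must be refitted for other
brands. It covers macronutrient supplements and fortifiers only — no
medications, micronutrient adjuvants or >1000 mOsm/kg additive scenarios,
no osmolarity (mOsm/L) conversion without an explicit density, and no claim
about clinical outcomes of any osmolality level. The 450 mOsm/kg default
limit and the 22 mOsm/kg QC threshold are configurable policies, not
physiological facts.
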