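test_that("the batch protein/nitrogen balance matches the published one", {
  pn <- batch_protein_nitrogen(baseline_batch())
  expect_equal(pn$protein_retained, 62.1)
  expect_equal(pn$protein_fed, 258.75)          # prints as ~260
  expect_equal(pn$protein_waste, 196.65)        # prints as ~200
  expect_equal(pn$nitrogen_waste, 31.46, tolerance = 1e-3)  # ~31 kg
  # perfect conversion leaves nothing in the media
  f <- unclass(baseline_batch()); f$protein_conversion_efficiency <- 1
  pn1 <- batch_protein_nitrogen(suppressWarnings(do.call(cm_batch_spec, f)))
  expect_equal(pn1$protein_waste, 0)
  expect_equal(pn1$nitrogen_waste, 0)
  f$protein_conversion_efficiency <- 0.5
  pn2 <- batch_protein_nitrogen(suppressWarnings(do.call(cm_batch_spec, f)))
  expect_equal(pn2$protein_waste, 62.1)
  expect_equal(pn2$nitrogen_waste, 9.936)
})

test_that("the water balance leaves ~1% of input water in the meat", {
  ww <- batch_water(baseline_batch())
  expect_equal(ww, 30 - 345 * 0.83 / 1000)  # 29.71 m3
  expect_equal((30 - ww) / 30, 0.00955, tolerance = 1e-2)
  expect_equal(batch_water(baseline_batch(), include_cleaning = TRUE), ww + 45)
})

test_that("nitrogen concentration is 1.06 kg/m3 and scale-invariant", {
  pn <- batch_protein_nitrogen(baseline_batch())
  ww <- batch_water(baseline_batch())
  conc <- nitrogen_concentration(pn$nitrogen_waste, ww)
  expect_equal(conc, 1.06, tolerance = 2e-3)
  expect_equal(nitrogen_concentration(pn$nitrogen_waste * 1160,
                                      ww * 1160), conc)
  expect_equal(nitrogen_concentration(0, 5), 0)
  expect_error(nitrogen_concentration(1, 0), "> 0")
})

test_that("oxygen uptake follows the mean-cell-count procedure", {
  # arithmetic mean of 3e12 and 6e13 cells over 118 h, plus 6e13 over
  # 72 h, at 332.2 nmol O2/h per 1e6 cells, 32 g/mol
  expect_equal(oxygen_uptake(baseline_batch()), 85.44, tolerance = 1e-3)
  f <- unclass(baseline_batch()); f$maturation_duration <- 0
  expect_equal(oxygen_uptake(suppressWarnings(do.call(cm_batch_spec, f))),
               39.51, tolerance = 1e-3)  # proliferation term only
  f <- unclass(baseline_batch()); f$oxygen_uptake_rate <- 0
  expect_equal(oxygen_uptake(suppressWarnings(do.call(cm_batch_spec, f))),
               0)
  # geometric mean weighs the early low-density phase less
  expect_lt(oxygen_uptake(baseline_batch(), "geometric"),
            oxygen_uptake(baseline_batch(), "arithmetic"))
})

test_that("respiration stoichiometry gives ~80 kg glucose per batch", {
  expect_equal(glucose_respired(oxygen_uptake(baseline_batch())), 80.1,
               tolerance = 1e-3)
  expect_equal(glucose_respired(192), 180)
  expect_equal(glucose_respired(0), 0)
  expect_error(glucose_respired(-1), ">= 0")
})

test_that("glucose ledger and COD match the published shares", {
  cm <- baseline_batch()
  fed <- glucose_feed_per_kg(1400, 0.17, 4000) * 345
  resp <- glucose_respired(oxygen_uptake(cm))
  gc <- glucose_cod(cm, fed, resp)
  expect_equal(resp / fed, 0.113, tolerance = 3e-3)  # 11.3% respired
  expect_equal(gc$glucose_retained / fed, 0.17)
  expect_equal(gc$glucose_waste, 509.4, tolerance = 1e-3)
  expect_equal(gc$cod_waste, gc$glucose_waste * 0.40 * 2.66)
  z <- glucose_cod(cm, fed, fed * (1 - 0.17))
  expect_equal(z$glucose_waste, 0)
  expect_equal(z$cod_waste, 0)
  expect_error(glucose_cod(cm, fed, fed), "negative glucose waste")
})

test_that("protein and glucose ledgers close exactly on random specs", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:1000) {
    spec <- random_cm_spec()
    pn <- batch_protein_nitrogen(spec)
    expect_equal(pn$protein_fed,
                 pn$protein_retained + pn$protein_waste,
                 tolerance = 1e-14)
    fed <- glucose_feed_per_kg(spec$meat_energy_density,
                               spec$calorie_conversion_efficiency,
                               spec$glucose_energy_density) *
      spec$batch_meat_mass
    resp <- glucose_respired(oxygen_uptake(spec))
    if (fed - spec$calorie_conversion_efficiency * fed - resp >= 0) {
      gc <- glucose_cod(spec, fed, resp)
      expect_equal(gc$glucose_retained + gc$glucose_waste + resp, fed,
                   tolerance = 1e-12)
      n_checked <- n_checked + 1
    } else {
      expect_error(glucose_cod(spec, fed, resp), "negative")
    }
  }
  expect_gt(n_checked, 500)  # the ledger check must actually exercise
})

test_that("scenario scaling reproduces the published annual loads", {
  cm <- baseline_batch()
  high <- scale_scenario(cm, 25, 1e7)
  expect_equal(high$annual_mass, 400000)
  expect_equal(high$batches_per_year, 1160)
  expect_equal(high$batches_per_reactor_year, 33)
  expect_equal(high$annual_nitrogen, 36500, tolerance = 1e-3)
  expect_equal(high$annual_cod, 628000, tolerance = 3e-3)
  low <- scale_scenario(cm, 10, 1e7)
  expect_equal(low$annual_mass, 1e6)
  expect_equal(low$batches_per_year, 2899)     # prints as 2,900
  expect_equal(low$reactors, 88)
  expect_equal(low$annual_nitrogen, 91200, tolerance = 1e-3)
  expect_equal(low$annual_cod, 1570000, tolerance = 2e-3)
  zero <- scale_scenario(cm, 25, 0)
  expect_equal(zero$annual_mass, 0)
  expect_equal(zero$batches_per_year, 0)
  expect_equal(zero$annual_nitrogen, 0)
  expect_error(scale_scenario(cm, 0), "> 0")
})

test_that("annual loads equal a batch-by-batch accumulation", {
  cm <- baseline_batch()
  bb <- batch_balance(cm)
  sc <- scale_scenario(cm, 25, 1e7, bb)
  n_loop <- 0
  for (b in seq_len(sc$batches_per_year)) n_loop <- n_loop + bb$nitrogen_waste
  expect_equal(sc$annual_nitrogen, n_loop, tolerance = 1e-9)
})

test_that("annual nitrogen falls strictly as PCE rises", {
  pces <- seq(0.17, 0.33, by = 0.02)
  loads <- vapply(pces, function(p) {
    f <- unclass(baseline_batch()); f$protein_conversion_efficiency <- p
    spec <- suppressWarnings(do.call(cm_batch_spec, f))
    scale_scenario(spec, 25, 1e7, batch_balance(spec))$annual_nitrogen
  }, numeric(1))
  expect_true(all(diff(loads) < 0))
})
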