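test_that("application geometry matches the published areas and radii", {
  high <- application_area(36498.24, 168, 0.35)
  expect_equal(high$required_area, 217, tolerance = 2e-3)
  expect_equal(high$adjusted_area, 620, tolerance = 2e-3)
  expect_equal(high$service_radius_km, 1.4, tolerance = 5e-3)
  low <- application_area(91214.14, 168, 0.35)
  expect_equal(low$required_area, 543, tolerance = 1e-3)
  expect_equal(low$adjusted_area, 1550, tolerance = 1e-3)
  expect_equal(low$service_radius_km, 2.2, tolerance = 1.1e-2)
  same <- application_area(1000, 168, 1)
  expect_equal(same$adjusted_area, same$required_area)
  expect_error(application_area(1, 0), "> 0")
})

test_that("the beyond-threshold fraction matches the area ratio", {
  low <- application_area(91214.14, 168, 0.35)
  frac <- fraction_beyond_threshold(low$adjusted_area, 1)
  expect_equal(frac, 0.476, tolerance = 2e-3)  # prints as 48%
  high <- application_area(36498.24, 168, 0.35)
  expect_equal(fraction_beyond_threshold(high$adjusted_area, 1), 0)
})

test_that("closed-form beyond-threshold fraction agrees with quadrature", {
  # midpoint quadrature of the indicator 1(r > 1 mile) against the
  # uniform measure 2*pi*r dr over the service disc, 1e4 radial cells
  for (area_ha in c(1551.26, 2500, 900)) {
    radius_m <- sqrt(area_ha * 1e4 / pi)
    n <- 1e4
    h <- radius_m / n
    r_mid <- (seq_len(n) - 0.5) * h
    w <- 2 * pi * r_mid * h
    frac_num <- sum(w[r_mid > 1609.34]) / sum(w)
    expect_equal(fraction_beyond_threshold(area_ha, 1), frac_num,
                 tolerance = 1e-3)
  }
})

test_that("application cost reproduces the published scenario costs", {
  econ <- preset_econ_costs()
  high_geom <- application_area(36498.24, 168, 0.35)
  high <- application_cost(34467.87, high_geom$adjusted_area, econ)
  expect_equal(high$fraction_beyond, 0)
  expect_equal(high$total_cost, 114000, tolerance = 2e-3)
  low_geom <- application_area(91214.14, 168, 0.35)
  low <- application_cost(86139.9, low_geom$adjusted_area, econ)
  expect_equal(low$total_cost, 322300, tolerance = 1e-3)  # prints 332,000
  # specific costs per kg meat reproduce at printed precision
  expect_equal(high$total_cost / 4e5, 0.28, tolerance = 2e-2)
  expect_equal(low$total_cost / 1e6, 0.32, tolerance = 1e-2)
  expect_gt(low$total_cost / 1e6, high$total_cost / 4e5)
})

test_that("application cost is monotone in volume, surcharge, fraction", {
  econ <- preset_econ_costs()
  a <- application_cost(1000, 1551, econ)
  b <- application_cost(2000, 1551, econ)
  expect_gt(b$total_cost, a$total_cost)
  econ2 <- econ_costs(application_distance_surcharge = 0.01)
  expect_gt(application_cost(1000, 1551, econ2)$total_cost, a$total_cost)
  expect_gt(a$total_cost, application_cost(1000, 600, econ)$total_cost)
  # with no surcharge the cost is linear in volume
  econ0 <- econ_costs(application_distance_surcharge = 0)
  expect_equal(application_cost(2000, 1551, econ0)$total_cost,
               2 * application_cost(1000, 1551, econ0)$total_cost)
})

test_that("wastewater treatment cost reproduces the published breakdown", {
  econ <- preset_econ_costs()
  low <- wwt_cost(91214.14, 1571409, econ, 1e6)
  expect_equal(low$specific_total, 0.85, tolerance = 5e-3)
  expect_equal(low$specific_cod, 0.62, tolerance = 2e-2)
  expect_equal(low$specific_n, 0.22, tolerance = 2e-2)
  high <- wwt_cost(36498.24, 628780.3, econ, 4e5)
  expect_equal(high$total_cost, 340900, tolerance = 1e-3) # prints 339,000
  expect_equal(signif(high$total_cost, 2), 340000)
  expect_equal(signif(low$total_cost, 2), 850000)
  z <- wwt_cost(0, 0, econ, 1)
  expect_equal(z$total_cost, 0)
  expect_error(wwt_cost(1, 1, econ, 0), "> 0")
})

test_that("manure application costs follow lifetime volumes", {
  econ <- preset_econ_costs()
  beef <- manure_application_cost(preset_animal("beef"), econ)
  expect_equal(beef, 0.135, tolerance = 2e-3)
  broiler <- manure_application_cost(preset_animal("broiler"), econ)
  expect_equal(broiler, 0.0128, tolerance = 2e-2)
  f <- unclass(preset_animal("swine")); f$lifetime_manure_volume <- 0
  expect_equal(manure_application_cost(do.call(animal_spec, f), econ), 0)
})

test_that("the cost comparison table covers every system and strategy", {
  ct <- cost_table()
  expect_equal(nrow(ct), 7)  # 3 manure + 2 prices x 2 strategies
  expect_true(all(ct$specific_cost > 0))
  cm_rows <- grepl("cultured", ct$system)
  # spent-media handling costs more per kg than any manure system
  expect_gt(min(ct$specific_cost[cm_rows]),
            max(ct$specific_cost[!cm_rows]))
})
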