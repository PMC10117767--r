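test_that("feed requirements per kg meat match the published figures", {
  expect_equal(protein_feed_per_kg(0.18, 0.24), 0.75)
  expect_equal(protein_feed_per_kg(0.2, 1), 0.2)
  expect_equal(protein_feed_per_kg(0.22, 0.05), 4.4)  # beef-equivalent
  expect_error(protein_feed_per_kg(0.18, 0), "\\(0, 1\\]")
  expect_equal(glucose_feed_per_kg(1400, 0.17, 4000), 2.0588,
               tolerance = 1e-4)
  expect_equal(glucose_feed_per_kg(4000, 1, 4000), 1)
  expect_equal(glucose_feed_per_kg(1400, 0.17, 4000) * 345, 710.3,
               tolerance = 1e-3)
  expect_error(glucose_feed_per_kg(1400, 0), "\\(0, 1\\]")
})

test_that("cropland per kg crop is the reciprocal yield", {
  expect_equal(crop_land_per_kg(4.12), 2.427, tolerance = 1e-3)
  expect_equal(crop_land_per_kg(13), 0.769, tolerance = 1e-3)
  expect_equal(crop_land_per_kg(10), 1)
  expect_error(crop_land_per_kg(0), "> 0")
})

test_that("price allocation reproduces the soy oil/meal split", {
  sh <- price_allocation(c(oil = 0.20, meal = 0.80),
                         c(oil = 0.87, meal = 0.33))
  expect_equal(unname(sh["oil"]), 0.397, tolerance = 1e-3)
  expect_equal(unname(sh["meal"]), 0.603, tolerance = 1e-3)
  expect_equal(unname(price_allocation(c(a = 1), c(a = 5))), 1)
  expect_equal(unname(price_allocation(c(a = 0.5, b = 0.25),
                                       c(a = 1, b = 2))),
               c(0.5, 0.5))
  expect_error(price_allocation(c(a = 1, b = 1), c(a = 0, b = 0)),
               "value must be > 0")
})

test_that("price-allocation shares always normalise and stay in [0,1]", {
  set.seed(7)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    m <- runif(k); p <- runif(k, 0, 10)
    if (sum(m * p) == 0) p[1] <- 1
    sh <- price_allocation(setNames(m, letters[1:k]),
                           setNames(p, letters[1:k]))
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    expect_true(all(sh >= 0 & sh <= 1))
  }
})

test_that("soy land reproduces the published footprint per kg meat", {
  soy <- preset_feedstock("soy")
  expect_equal(soy_land_per_kg_cm(soy, 0.75), 2.31, tolerance = 2e-3)
  # the full narrative chain carries the meal fraction and recovery, so
  # it is strictly larger
  expect_equal(soy_land_per_kg_cm(soy, 0.75, chain_mode = "stated_chain"),
               3.615, tolerance = 1e-3)
  expect_gt(soy_land_per_kg_cm(soy, 0.75, chain_mode = "stated_chain"),
            soy_land_per_kg_cm(soy, 0.75, chain_mode = "as_printed"))
  expect_equal(soy_land_per_kg_cm(soy, 0), 0)
})

test_that("corn land follows the starch chain with price allocation", {
  corn <- preset_feedstock("corn")
  g <- glucose_feed_per_kg(1400, 0.17, 4000)
  expect_equal(corn_land_per_kg_cm(corn, g), 1.749, tolerance = 1e-3)
  f <- unclass(corn); f$allocation_share <- 1
  expect_equal(corn_land_per_kg_cm(do.call(feedstock_chain, f), g),
               2.36, tolerance = 2e-3)
  expect_equal(corn_land_per_kg_cm(corn, 0), 0)
})

test_that("land use scales linearly in need and inversely in yield", {
  soy <- preset_feedstock("soy")
  l1 <- soy_land_per_kg_cm(soy, 0.75)
  expect_equal(soy_land_per_kg_cm(soy, 1.5), 2 * l1)
  f <- unclass(soy); f$yield <- 2 * f$yield
  expect_equal(soy_land_per_kg_cm(do.call(feedstock_chain, f), 0.75),
               l1 / 2)
})

test_that("productivity conversion matches the published examples", {
  cm <- landuse_to_productivity(4.58, 0.18, 1400)
  expect_equal(cm$protein_productivity, 39.3, tolerance = 1e-3)  # ~40
  expect_equal(cm$energy_productivity, 1.28, tolerance = 1e-2)   # ~1.3
  br <- landuse_to_productivity(8.7, 0.17, 1430)
  expect_equal(br$protein_productivity, 19.5, tolerance = 1e-2)
  expect_equal(br$energy_productivity, 0.69, tolerance = 1e-2)
  expect_equal(landuse_to_productivity(1, 1, 1000)$protein_productivity,
               1000)
  expect_error(landuse_to_productivity(0, 0.2, 1400), "> 0")
})

test_that("productivity times land use recovers the nutrient content", {
  set.seed(3)
  for (i in 1:50) {
    lu <- runif(1, 0.1, 500); pf <- runif(1); en <- runif(1, 500, 4000)
    r <- landuse_to_productivity(lu, pf, en)
    expect_equal(r$protein_productivity * lu, 1000 * pf,
                 tolerance = 1e-12)
    expect_equal(r$energy_productivity * lu, en * 4.184 / 1000,
                 tolerance = 1e-12)
  }
})

test_that("the modelled cultured-meat land ledger is reproducible", {
  lu <- cm_land_use()
  expect_equal(lu$protein_land, 2.31, tolerance = 2e-3)
  expect_equal(lu$total_land, lu$protein_land + lu$energy_land)
  expect_equal(lu$ledger$protein_need, 0.75)
  expect_equal(lu$ledger$glucose_need, 2.059, tolerance = 1e-3)
  expect_equal(lu$ledger$soy_allocation, 0.61)
  expect_equal(lu$ledger$corn_allocation, 0.74)
  at <- areal_table()
  expect_equal(nrow(at), 4)
  expect_true(all(at$protein_productivity > 0))
  # the modelled system out-produces the livestock midpoints per m2
  cm_row <- at[at$source == "cultured meat", ]
  expect_true(all(cm_row$protein_productivity >
                    at$protein_productivity[at$source != "cultured meat"]))
})
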