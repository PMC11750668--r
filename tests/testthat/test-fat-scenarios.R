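test_that("carbohydrate sparing follows the energy-density ratio", {
  expect_equal(cho_sparing_rate(0.63), 0.63 * 38.0 / 17.3)  # ~1.384 g/min
  expect_equal(cho_sparing_rate(0), 0)
  expect_equal(cho_sparing_rate(1, energy_constants(19, 38)), 2)
  expect_error(cho_sparing_rate(-0.1), "non-negative")
})

test_that("raised fat oxidation reduces the exogenous requirement as derived", {
  expect_equal(required_exogenous_under_fat(90, 0.07, 0.07), 90)
  # 90 - 60 * (0.43 * 38/17.3) = 33.33 g/hr
  expect_equal(required_exogenous_under_fat(90, 0.07, 0.5),
               90 - 60 * 0.43 * 38 / 17.3)
  expect_equal(required_exogenous_under_fat(90, 0.07, 2), 0)  # clamped
  expect_error(required_exogenous_under_fat(90, 0.07, 0.05), "baseline")
})

test_that("closed-form zero crossing agrees with the forward model", {
  # 0.07 + 1.5 * 17.3/38 = 0.753; 0.06 + (106/60) * 17.3/38 = 0.864
  expect_equal(zero_exogenous_fat_rate(90, 0.07), 0.07 + 1.5 * 17.3 / 38)
  expect_equal(zero_exogenous_fat_rate(106, 0.06), 0.8643, tolerance = 1e-4)
  expect_equal(zero_exogenous_fat_rate(0, 0.4), 0.4)
  cases <- withr::with_seed(42, data.frame(
    base = stats::runif(200, 0, 150),
    baseline = stats::runif(200, 0, 1),
    e_cho = stats::runif(200, 15, 19)))
  for (i in seq_len(nrow(cases))) {
    k <- energy_constants(cases$e_cho[i], 38)
    zc <- zero_exogenous_fat_rate(cases$base[i], cases$baseline[i], k)
    expect_equal(required_exogenous_under_fat(cases$base[i],
                                              cases$baseline[i], zc, k), 0)
  }
})

test_that("before clamping the requirement is affine in fat rate with slope -60*e_fat/e_cho", {
  k <- energy_constants()
  grid <- seq(0.07, 0.60, by = 0.01)  # below the 90 g/hr zero crossing
  req <- required_exogenous_under_fat(90, 0.07, grid, k)
  slopes <- diff(req) / diff(grid)
  expect_equal(slopes, rep(-60 * k$e_fat / k$e_cho, length(slopes)),
               tolerance = 1e-9)
  full <- seq(0.07, 2, by = 0.01)
  expect_true(all(diff(required_exogenous_under_fat(90, 0.07, full, k)) <= 0))
})

test_that("fat energy share reproduces the high-fat-oxidation bracket", {
  expect_equal(fat_energy_share(1.5, 76), 0.75)       # 57 of 76 kJ/min
  expect_equal(fat_energy_share(1.5, 89), 57 / 89)    # ~0.64
  expect_equal(fat_energy_share(0, 80), 0)
  expect_gt(fat_energy_share(3, 80), 1)               # not clamped
  expect_error(fat_energy_share(1, 0), "positive")
})

test_that("scenario sweep records the grid and the zero crossing", {
  sw <- fat_scenario_sweep(90, 0.07, seq(0.07, 1, by = 0.01))
  expect_s3_class(sw, "fat_scenario_sweep")
  expect_named(sw, c("scenario_fat_rate", "spared_cho_rate",
                     "required_exogenous_rate"))
  zc <- attr(sw, "zero_crossing_fat_rate")
  # grid scan locates the crossing to within one grid step
  first_zero <- min(sw$scenario_fat_rate[sw$required_exogenous_rate == 0])
  expect_lte(first_zero - zc, 0.01 + 1e-12)
  expect_gte(first_zero, zc - 1e-12)
  expect_error(fat_scenario_sweep(90, 0.07, numeric(0)), "non-empty")
})
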