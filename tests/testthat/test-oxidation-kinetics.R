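test_that("drink arithmetic: concentration times fluid rate gives g/hr", {
  expect_equal(ingestion_rate(22.5, 400), 90)
  expect_equal(ingestion_rate(15, 800), 120)
  expect_equal(ingestion_rate(0, 1000), 0)
  expect_equal(ingestion_rate(11, 1000), 110)
  expect_error(ingestion_rate(120, 400), "w/v")
  expect_error(ingestion_rate(10, -1), "non-negative")
})

test_that("oxidation curve validation rejects malformed input", {
  expect_error(oxidation_curve(c(5, 10), c(1, 1)), "time 0")
  expect_error(oxidation_curve(c(0, 10, 10), c(1, 1, 1)), "increasing")
  expect_error(oxidation_curve(c(0, 10), c(1, -1)), "non-negative")
  expect_error(oxidation_curve(0, 1), "2 points")
})

test_that("bin averaging integrates a constant curve exactly", {
  flat <- oxidation_curve(c(0, 120), c(1, 1))
  co <- cumulative_oxidation(flat, 120, 30)
  expect_equal(attr(co, "total_oxidized"), 120)
  expect_equal(co$oxidized_per_bin, rep(30, 4))
  expect_equal(co$cumulative_oxidized, c(30, 60, 90, 120))
})

test_that("the synthetic bin-average fixture reproduces the 137 g / 48% summary", {
  co <- cumulative_oxidation(jentjens_curve(), 120, 30,
                             ingestion_rate_g_hr = 144)
  expect_equal(co$oxidized_per_bin / 30, c(0.30, 0.95, 1.30, 2.02))
  expect_equal(attr(co, "total_oxidized"), 137.1)
  expect_equal(attr(co, "total_ingested"), 288)
  eff <- oxidation_efficiency(attr(co, "total_oxidized"), 288)
  expect_equal(round(100 * eff), 48)
  expect_true(all(diff(co$cumulative_oxidized) >= 0))
  expect_true(all(co$unoxidized >= 0))
})

test_that("bin averaging matches the analytic ramp integral within 1%", {
  for (tau in c(15, 30, 45)) {
    rc <- make_ramp_curve(r_max = 1.5, tau = tau, duration = 120, step = 5)
    truth <- ramp_integral(1.5, tau, 120)
    for (bw in c(5, 10)) {
      got <- attr(cumulative_oxidation(rc, 120, bw), "total_oxidized")
      expect_lt(abs(got - truth) / truth, 0.01)
    }
  }
})

test_that("refining the bin width converges on the trapezoid integral of the curve", {
  rc <- make_ramp_curve(r_max = 1.8, tau = 25, duration = 120, step = 5)
  trap <- sum(diff(rc$time) * (head(rc$rate, -1) + tail(rc$rate, -1)) / 2)
  errs <- vapply(c(60, 30, 15, 5), function(bw)
    abs(attr(cumulative_oxidation(rc, 120, bw), "total_oxidized") - trap),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-9))  # non-increasing error
  expect_lt(errs[length(errs)], 1e-9)   # exact at the curve's own resolution
})

test_that("oxidized never exceeds ingested when rates stay below the ingestion rate", {
  ing <- 90  # g/hr -> 1.5 g/min
  rc <- make_ramp_curve(r_max = 1.5, tau = 20, duration = 120, step = 5)
  co <- cumulative_oxidation(rc, 120, 30, ingestion_rate_g_hr = ing)
  expect_true(all(co$cumulative_oxidized <= co$cumulative_ingested + 1e-9))
})

test_that("coverage and divisibility are enforced", {
  short <- oxidation_curve(c(0, 90), c(0.5, 0.5))
  expect_error(cumulative_oxidation(short, 120, 30), "ends at 90")
  flat <- oxidation_curve(c(0, 120), c(1, 1))
  expect_error(cumulative_oxidation(flat, 120, 45), "evenly")
})

test_that("residual, efficiency and average rate agree with the published bouts", {
  expect_equal(unoxidized_residual(288, 137), 151)
  expect_equal(unoxidized_residual(240, 90), 150)
  expect_equal(unoxidized_residual(50, 50), 0)
  expect_error(unoxidized_residual(100, 137), "exceeds")

  expect_equal(oxidation_efficiency(137, 288), 137 / 288)  # 48%
  expect_equal(round(100 * oxidation_efficiency(132, 180)), 73)
  expect_equal(oxidation_efficiency(0, 100), 0)
  expect_error(oxidation_efficiency(10, 0), "positive")

  expect_equal(average_rate(137, 120), 68.5)
  expect_equal(average_rate(132, 120), 66)
  expect_equal(average_rate(0, 120), 0)
})

test_that("residual and efficiency are complementary for random totals", {
  cases <- withr::with_seed(7, {
    ing <- stats::runif(300, 1, 400)
    data.frame(ing = ing, ox = ing * stats::runif(300))
  })
  resid <- unoxidized_residual(cases$ing, cases$ox)
  eff <- oxidation_efficiency(cases$ox, cases$ing)
  expect_equal(resid / cases$ing, 1 - eff, tolerance = 1e-12)
})

test_that("curve CSV round-trips through the two-column dialect", {
  rc <- make_ramp_curve(r_max = 1.2, tau = 18, duration = 120, step = 10)
  path <- tempfile(fileext = ".csv")
  write_oxidation_curve(rc, path)
  back <- read_oxidation_curve(path, label = attr(rc, "label"))
  expect_equal(back$time, rc$time)
  expect_equal(back$rate, rc$rate, tolerance = 1e-12)
  writeLines("a,b\n1,2", path)
  expect_error(read_oxidation_curve(path), "time_min")
})
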