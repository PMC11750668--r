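test_that("the budget object recomputes every cell from the profile", {
  for (sex in c("male", "female")) {
    fb <- fuel_budget(sex)
    want <- expected_budget_cells[[sex]]
    expect_identical(fb$total_cho_required, want$demand)
    for (tn in c("32", "20")) {
      expect_identical(fb$glycogen[[tn]]$remnant, want$remnant[[tn]])
      expect_identical(fb$glycogen[[tn]]$usable, want$usable[[tn]])
      expect_identical(fb$requirement[[tn]]$deficit, want$deficit[[tn]])
      expect_identical(fb$requirement[[tn]]$exogenous_total,
                       want$exogenous[[tn]])
      expect_equal(fb$requirement[[tn]]$exogenous_rate,
                   want$exogenous[[tn]] / 2)
    }
    expect_identical(fb$windfall, want$windfall)
  }
})

test_that("a total-depletion threshold exposes the whole store plus liver", {
  fb <- fuel_budget("male", thresholds = 1.0)
  expect_identical(fb$glycogen[["100"]]$usable, 0)
  expect_identical(fb$requirement[["100"]]$deficit, 612)
  expect_identical(fb$requirement[["100"]]$exogenous_total, 680)  # 612 + 68
  expect_true(is.na(fb$windfall))
})

test_that("strict liver mode drops the liver term from the headline", {
  fb <- fuel_budget("male", liver_mode = "strict")
  expect_identical(fb$requirement[["32"]]$exogenous_total, 143)
  expect_identical(fb$requirement[["20"]]$exogenous_total, 60)
})

test_that("print and summary render the budget rows", {
  fb <- fuel_budget("male")
  out <- paste(capture.output(print(fb)), collapse = "\n")
  for (cell in c("612", "221", "138", "469", "552", "143", "211", "128",
                 "105.5", "83")) {
    expect_match(out, cell, fixed = TRUE)
  }
  out2 <- paste(capture.output(summary(fb)), collapse = "\n")
  expect_match(out2, "closure")
  expect_match(out2, "17.3", fixed = TRUE)
})

test_that("coef exposes the flat numeric record", {
  cf <- coef(fuel_budget("female"))
  expect_identical(unname(cf["exogenous_total_32"]), 238)
  expect_identical(unname(cf["windfall"]), 60)
})

test_that("predict reproduces the scenario engine and plot returns the sweep", {
  fb <- fuel_budget("male")
  sw <- predict(fb, fat_rate = c(0.07, 0.5), base_rate = 90)
  expect_equal(sw$required_exogenous_rate[1], 90)
  expect_equal(sw$required_exogenous_rate[2], 90 - 60 * 0.43 * 38 / 17.3)
  # default basis is the stricter threshold's computed requirement
  sw2 <- predict(fb, fat_rate = 0.07)
  expect_equal(sw2$required_exogenous_rate[1], 105.5)
  expect_error(predict(fb, threshold = "55"), "not in this budget")
  pdf(NULL)
  on.exit(dev.off())
  got <- plot(fb, base_rate = 90)
  expect_s3_class(got, "fat_scenario_sweep")
})

test_that("reports round-trip through CSV and JSON field for field", {
  fb <- fuel_budget("female", liver_mode = "printed")
  rec <- as.data.frame(fb)
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_report(fb, path)
    back <- read_report(path)
    expect_identical(names(back), names(rec))
    num <- vapply(rec, is.numeric, logical(1))
    expect_equal(as.numeric(back[1, num]), as.numeric(rec[1, num]),
                 tolerance = 1e-12)
    expect_identical(back$label, rec$label)
    expect_identical(back$liver_mode, rec$liver_mode)
  }
})

test_that("the command-line tool reproduces the in-package budget", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "fuelbudget.R", package = "fuelbudget")
  out <- tempfile(fileext = ".csv")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "table1", "--profile", "male",
                   "--threshold", "32,20", "--quiet", "--out", out),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(out))
  rep <- read_report(out)
  expect_equal(rep$exogenous_total_32, 211)
  expect_equal(rep$exogenous_total_20, 128)
  expect_equal(rep$windfall, 83)
})
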