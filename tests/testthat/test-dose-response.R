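test_that("exactly linear mortality data recover the line and LC50", {
  # y% = 10 * log10(dose) + 30 at doses 10^0..10^4
  doses <- 10^(0:4)
  tab <- make_table(doses, (10 * (0:4) + 30) / 100)
  fit <- fit_linear_logdose(tab)
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  expect_equal(fit$intercept, 30, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$chi_squared_gof, 1e-9)
  # solve 50 = 10 x + 30 -> x = 2 -> LC50 = 100
  lc <- estimate_lc(fit, 0.5)
  expect_equal(lc$value, 100, tolerance = 1e-10)
  expect_equal(lc$unit, "mg/L")
})

test_that("linear fit equals the independent least-squares oracle", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(3:7, 1)
    doses <- sort(random_positive(k))
    corrected <- runif(k)
    tab <- make_table(doses, corrected)
    fit <- fit_linear_logdose(tab)
    oracle <- stats::lm(I(100 * corrected) ~ log10(doses))
    expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
    expect_equal(fit$r_squared, summary(oracle)$r.squared, tolerance = 1e-10)
  }
})

test_that("degenerate linear inputs are handled", {
  expect_error(fit_linear_logdose(make_table(5, 0.4)), "2 distinct")
  expect_warning(fit <- fit_linear_logdose(make_table(c(1, 10, 100), rep(0.4, 3))),
                 "zero-slope")
  expect_equal(fit$slope, 0)
  expect_error(estimate_lc(fit), "slope is zero")
})

test_that("probit fit recovers generating parameters at large n", {
  slope <- 1.5
  lc50 <- 5.76
  series <- serial_dilution(100 * lc50, 10, 5)
  rec <- make_expected_records(lc50, slope, series, n = 100000)
  fit <- fit_probit(rec)
  # truth on the probit scale: qnorm(p) = -slope*log10(lc50) + slope*x
  expect_equal(fit$slope, slope, tolerance = 0.01)
  expect_equal(fit$intercept, -slope * log10(lc50), tolerance = 0.01)
  expect_equal(estimate_lc(fit, 0.5)$value, lc50, tolerance = 0.01)
})

test_that("probit inverse prediction follows the normal quantile", {
  fit <- structure(
    list(model_kind = "probit", slope = 1, intercept = 0, r_squared = 1,
         chi_squared_gof = 0, dose_unit = "mg/L", n_doses = 5, log_base = 10,
         convention = "log10_concentration", treatment_id = "t", table = NULL),
    class = "dose_response_fit"
  )
  expect_equal(estimate_lc(fit, 0.5)$value, 1)
  expect_equal(estimate_lc(fit, 0.9)$value, 10^qnorm(0.9))
})

test_that("a saturated two-dose probit fit has zero lack of fit", {
  rec <- make_records(c(1, 10), matrix(c(30, 60), nrow = 2), n = 90)
  fit <- fit_probit(rec)
  expect_lt(fit$chi_squared_gof, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
})

test_that("complete separation aborts the probit fit with guidance", {
  rec <- make_records(c(1, 10, 100), matrix(c(0, 0, 30), ncol = 1))
  expect_error(fit_probit(rec), "separation")
})

test_that("LC50 rescales exactly with the dose unit", {
  set.seed(5)
  dead <- matrix(rbinom(15, 30, rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 3)),
                 nrow = 5, byrow = TRUE)
  rec <- make_records(10^(0:4), dead)
  lc1 <- estimate_lc(fit_linear_logdose(aggregate_mortality(rec)))
  for (c_scale in c(0.01, 3, 1000)) {
    rec2 <- rec
    rec2$dose <- rec2$dose * c_scale
    lc2 <- estimate_lc(fit_linear_logdose(aggregate_mortality(rec2)))
    expect_equal(lc2$value, lc1$value * c_scale, tolerance = 1e-9)
  }
})

test_that("probit and linear LC50s agree on a symmetric mid-range curve", {
  # mortality spans ~0.1..0.9 over the 5-dose series
  slope <- 0.64
  lc50 <- 10
  series <- serial_dilution(100 * lc50, 10, 5)
  rec <- make_expected_records(lc50, slope, series, n = 10000)
  tab <- aggregate_mortality(rec)
  lc_lin <- estimate_lc(fit_linear_logdose(tab))$value
  lc_pro <- estimate_lc(fit_probit(tab))$value
  expect_lt(abs(lc_lin - lc_pro) / lc_pro, 0.05)
})

test_that("bootstrap LC50 interval is deterministic and ordered", {
  rec <- simulate_bioassay(5, 1.5, serial_dilution(500, 10, 5), seed = 3)
  ci1 <- bootstrap_lc_ci(rec, n_boot = 300, seed = 11)
  ci2 <- bootstrap_lc_ci(rec, n_boot = 300, seed = 11)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$value)
  expect_gte(ci1$ci_high, ci1$value)
  ci3 <- bootstrap_lc_ci(rec, n_boot = 300, seed = 12)
  expect_false(identical(ci1$ci_low, ci3$ci_low))
  # probit path honors the same determinism contract
  cip1 <- bootstrap_lc_ci(rec, n_boot = 50, seed = 4, model = "probit")
  cip2 <- bootstrap_lc_ci(rec, n_boot = 50, seed = 4, model = "probit")
  expect_identical(cip1, cip2)
})

test_that("replicate-unit bootstrap on identical replicates collapses to the estimate", {
  dead <- matrix(rep(c(3, 9, 15, 21, 27), each = 3), nrow = 5, byrow = TRUE)
  rec <- make_records(10^(0:4), dead)
  ci <- bootstrap_lc_ci(rec, n_boot = 100, seed = 1, boot_unit = "replicate")
  expect_equal(ci$ci_low, ci$value, tolerance = 1e-9)
  expect_equal(ci$ci_high, ci$value, tolerance = 1e-9)
})
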