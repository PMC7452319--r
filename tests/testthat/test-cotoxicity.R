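test_that("the toxicity-index chain reproduces direct arithmetic", {
  res <- compute_ctc(10, 5, 4, mixture_ratio(1, 1))
  expect_equal(res$ti_a, 100)
  expect_equal(res$ti_b, 200)
  expect_equal(res$actual_ti, 250)
  expect_equal(res$theoretical_ti, 150)
  expect_equal(res$ctc, 250 / 150 * 100)
  expect_equal(res$label, "synergism")

  sym <- compute_ctc(2, 2, 2, mixture_ratio(1, 1))
  expect_equal(sym$ctc, 100)
  expect_equal(sym$label, "cumulative")
})

test_that("additive reference LC50 is the ratio-weighted harmonic mean", {
  expect_equal(additive_lc50(10, 5, mixture_ratio(1, 1)), 20 / 3)
  for (r in list(mixture_ratio(9, 1), mixture_ratio(1, 4)))
    expect_equal(additive_lc50(3.7, 3.7, r), 3.7)
  expect_equal(additive_lc50(10, 5, mixture_ratio(1, 0)), 10)
  expect_equal(additive_lc50(10, 5, mixture_ratio(0, 1)), 5)
})

test_that("a mixture at the additive LC50 scores CTC = 100 for any inputs", {
  set.seed(1)
  for (i in 1:200) {
    a <- random_positive(1)
    b <- random_positive(1)
    r <- mixture_ratio(runif(1), runif(1))
    res <- compute_ctc(a, b, additive_lc50(a, b, r), r)
    expect_equal(res$ctc, 100, tolerance = 1e-9)
  }
})

test_that("the TI chain equals the harmonic-mean closed form and its invariances", {
  set.seed(2)
  for (i in 1:200) {
    a <- random_positive(1); b <- random_positive(1); m <- random_positive(1)
    w <- runif(1)
    r <- mixture_ratio(w, 1 - w)
    res <- compute_ctc(a, b, m, r)
    # closed form
    expect_equal(res$ctc, 100 * additive_lc50(a, b, r) / m, tolerance = 1e-9)
    # reference swap: B as the index-100 agent, weights exchanged
    swapped <- compute_ctc(b, a, m, mixture_ratio(1 - w, w))
    expect_equal(swapped$ctc, res$ctc, tolerance = 1e-9)
    # scale invariance
    s <- random_positive(1)
    scaled <- compute_ctc(a * s, b * s, m * s, r)
    expect_equal(scaled$ctc, res$ctc, tolerance = 1e-9)
    # halving the mixture LC50 doubles the CTC
    halved <- compute_ctc(a, b, m / 2, r)
    expect_equal(halved$ctc, 2 * res$ctc, tolerance = 1e-9)
  }
})

test_that("interaction classification follows the 120/80 thresholds", {
  expect_equal(classify_interaction(294.23), "synergism")
  expect_equal(classify_interaction(104.18), "cumulative")
  expect_equal(classify_interaction(86.60), "cumulative")
  expect_equal(classify_interaction(54.41), "antagonism")
  expect_equal(classify_interaction(41.03), "antagonism")
  # boundaries are inclusive for the cumulative class
  expect_equal(classify_interaction(120), "cumulative")
  expect_equal(classify_interaction(80), "cumulative")
  expect_equal(classify_interaction(120.0001), "synergism")
  expect_equal(classify_interaction(79.9999), "antagonism")
  expect_error(classify_interaction(0), "positive")
  expect_error(classify_interaction(-5), "positive")
})

test_that("LC50 unit bookkeeping is enforced across the chain", {
  lc <- function(v, u) structure(
    list(p = 0.5, value = v, unit = u, ci_low = NA_real_, ci_high = NA_real_,
         ci_level = NA_real_, method = "linear_logdose"),
    class = "lc_estimate"
  )
  r <- mixture_ratio(1, 1)
  expect_error(compute_ctc(lc(10, "mg/L"), lc(5, "conidia/mL"), lc(4, "mg/L"), r),
               "unit mismatch")
  expect_error(additive_lc50(lc(10, "mg/L"), lc(5, "conidia/mL"), r),
               "unit mismatch")
  ok <- compute_ctc(lc(10, "mg/L"), lc(5, "mg/L"), lc(4, "mg/L"), r)
  expect_equal(ok$unit, "mg/L")
  expect_error(compute_ctc(-1, 5, 4, r), "positive")
})

test_that("mixture ratios normalize and reject degenerate parts", {
  r <- mixture_ratio(9, 1)
  expect_equal(r$w_a, 0.9)
  expect_equal(r$w_b, 0.1)
  expect_equal(r$label, "9:1")
  expect_equal(mixture_ratio(3, 1)$w_a, 0.75)
  expect_error(mixture_ratio(0, 0), "positive sum")
  expect_error(mixture_ratio(-1, 2), "non-negative")
})

test_that("joint CTC bootstrap is deterministic and brackets the point estimate", {
  cfg <- sim_config(true_ctc = 150, seed = 21)
  e <- simulate_mixture_experiment(cfg)
  b1 <- ctc_bootstrap(e$records_a, e$records_b, e$records_m, cfg$ratio,
                      n_boot = 300, seed = 9)
  b2 <- ctc_bootstrap(e$records_a, e$records_b, e$records_m, cfg$ratio,
                      n_boot = 300, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_equal(b1$ci_level, 0.95)
})

test_that("zero-variance assays give a degenerate point interval (replicate unit)", {
  mk <- function(id) make_records(10^(0:4),
                                  matrix(rep(c(3, 9, 15, 21, 27), each = 3),
                                         nrow = 5, byrow = TRUE), id = id)
  b <- ctc_bootstrap(mk("A"), mk("B"), mk("M"), mixture_ratio(1, 1),
                     n_boot = 100, seed = 1, boot_unit = "replicate")
  expect_equal(b$ci_low, b$ctc, tolerance = 1e-9)
  expect_equal(b$ci_high, b$ctc, tolerance = 1e-9)
})
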