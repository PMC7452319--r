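# Deterministic seed derivation: affine counter scheme keeping every
# derived seed a valid 32-bit integer. Distinct (master, k) pairs map to
# distinct streams for all practical counter ranges.
.derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1009 + as.numeric(k) * 104729) %% 2147483629)
}

#' Configuration for a simulated binary-mixture experiment
#'
#' Bundles the ground truth and design constants for
#' [simulate_mixture_experiment()]. The defaults mirror the standard
#' whitefly immersion-bioassay design: 5 dose levels spaced 10-fold,
#' 3 replicates of 30 insects, mortality scored at a fixed endpoint.
#' Dose gradients default to a stock of 100 x the true LC50 so that the
#' LC50 sits at the middle dilution level, as a pilot-informed design
#' would arrange.
#'
#' @param true_lc50_a,true_lc50_b True LC50s of agents A and B (same
#'   unit).
#' @param slope_a,slope_b,slope_m True probit slopes (per log10 dose).
#' @param true_ctc True co-toxicity coefficient; the implied mixture LC50
#'   is `additive_lc50(a, b, ratio) * 100 / true_ctc`.
#' @param ratio A [mixture_ratio()] (default 1:1).
#' @param series_a,series_b,series_m Optional [serial_dilution()] gradients
#'   per treatment; defaults are built from the true LC50s.
#' @param n_exposed Insects per replicate (default 30).
#' @param n_replicates Replicates per dose (default 3).
#' @param control_mortality Background mortality fraction (default 0).
#' @param unit Dose unit label (default `"mg/L"`).
#' @param seed Master RNG seed.
#' @return A `sim_config` list, including the implied `true_lc50_m`.
#' @export
sim_config <- function(true_lc50_a = 5.76, true_lc50_b = 20,
                       slope_a = 1.5, slope_b = 1.5, slope_m = 1.5,
                       true_ctc = 100, ratio = mixture_ratio(1, 1),
                       series_a = NULL, series_b = NULL, series_m = NULL,
                       n_exposed = 30, n_replicates = 3,
                       control_mortality = 0, unit = "mg/L", seed = 1) {
  stopifnot(true_lc50_a > 0, true_lc50_b > 0, true_ctc > 0,
            slope_a > 0, slope_b > 0, slope_m > 0,
            n_exposed >= 1, n_replicates >= 1,
            control_mortality >= 0, control_mortality < 1,
            inherits(ratio, "mixture_ratio"))
  true_lc50_m <- additive_lc50(true_lc50_a, true_lc50_b, ratio) * 100 / true_ctc
  default_series <- function(lc50) serial_dilution(100 * lc50, 10, 5, unit)
  cfg <- list(
    true_lc50_a = true_lc50_a, true_lc50_b = true_lc50_b,
    true_lc50_m = true_lc50_m,
    slope_a = slope_a, slope_b = slope_b, slope_m = slope_m,
    true_ctc = true_ctc, ratio = ratio,
    series_a = if (is.null(series_a)) default_series(true_lc50_a) else series_a,
    series_b = if (is.null(series_b)) default_series(true_lc50_b) else series_b,
    series_m = if (is.null(series_m)) default_series(true_lc50_m) else series_m,
    n_exposed = as.integer(n_exposed),
    n_replicates = as.integer(n_replicates),
    control_mortality = control_mortality, unit = unit,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate one dose-mortality bioassay
#'
#' Draws dead counts per dose and replicate from a binomial model with a
#' probit dose-response truth:
#' `p = c + (1 - c) * pnorm(slope * (log10(dose) - log10(lc50)))`, where
#' `c` is the background (control) mortality. Control replicates at dose 0
#' are drawn at mortality `c`. The probit generative model produces the
#' gently sigmoid mortality curves real assays show, so downstream linear
#' fits are exercised on realistically curved data.
#'
#' @param lc50 True LC50 (> 0, in the series' unit).
#' @param slope True probit slope per log10 dose (> 0).
#' @param series A [serial_dilution()] gradient.
#' @param n_exposed Insects per replicate (default 30).
#' @param n_replicates Replicates per dose (default 3).
#' @param control_mortality Background mortality fraction (default 0).
#' @param seed Integer RNG seed; the output is reproducible per seed.
#' @param treatment_id Label for the simulated treatment.
#' @return A bioassay record data.frame (one row per dose x replicate,
#'   plus control replicates), ready for [aggregate_mortality()].
#' @export
simulate_bioassay <- function(lc50, slope, series, n_exposed = 30,
                              n_replicates = 3, control_mortality = 0,
                              seed = 1, treatment_id = "sim") {
  stopifnot(inherits(series, "dilution_series"), lc50 > 0, slope > 0,
            n_exposed >= 1, n_replicates >= 1,
            control_mortality >= 0, control_mortality < 1)
  set.seed(seed)
  doses <- series$concentrations
  p <- control_mortality +
    (1 - control_mortality) * stats::pnorm(slope * (log10(doses) - log10(lc50)))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose_idx = seq_along(doses))
  dead <- stats::rbinom(nrow(grid), n_exposed, p[grid$dose_idx])
  out <- data.frame(
    treatment_id = treatment_id,
    dose = doses[grid$dose_idx],
    unit = series$unit,
    n_exposed = as.integer(n_exposed),
    n_dead = as.integer(dead),
    replicate = as.integer(grid$replicate),
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  ctl_dead <- stats::rbinom(n_replicates, n_exposed, control_mortality)
  ctl <- data.frame(
    treatment_id = treatment_id, dose = 0, unit = series$unit,
    n_exposed = as.integer(n_exposed), n_dead = as.integer(ctl_dead),
    replicate = seq_len(n_replicates), is_control = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(out, ctl)
}

#' Simulate a full binary-mixture experiment with known truth
#'
#' Simulates three bioassays — agent A, agent B, and their mixture M —
#' where the mixture's true LC50 is set so that the experiment has a known
#' true co-toxicity coefficient:
#' `lc50_m = additive_lc50(a, b, ratio) * 100 / true_ctc`. Per-assay seeds
#' derive from the master seed by a fixed counter scheme, so the whole
#' experiment is a pure function of the seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return A list with `records_a`, `records_b`, `records_m` and `truth`
#'   (all latent values: LC50s, slopes, ratio, true CTC).
#' @export
simulate_mixture_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  span_m <- range(config$series_m$concentrations)
  if (config$true_lc50_m < span_m[1] || config$true_lc50_m > span_m[2])
    warning("implied mixture LC50 lies outside the mixture dose series; ",
            "estimation will extrapolate")
  records_a <- simulate_bioassay(
    config$true_lc50_a, config$slope_a, config$series_a,
    config$n_exposed, config$n_replicates, config$control_mortality,
    seed = .derive_seed(seed, 1), treatment_id = "A"
  )
  records_b <- simulate_bioassay(
    config$true_lc50_b, config$slope_b, config$series_b,
    config$n_exposed, config$n_replicates, config$control_mortality,
    seed = .derive_seed(seed, 2), treatment_id = "B"
  )
  records_m <- simulate_bioassay(
    config$true_lc50_m, config$slope_m, config$series_m,
    config$n_exposed, config$n_replicates, config$control_mortality,
    seed = .derive_seed(seed, 3), treatment_id = "M"
  )
  list(
    records_a = records_a, records_b = records_b, records_m = records_m,
    truth = list(
      lc50_a = config$true_lc50_a, lc50_b = config$true_lc50_b,
      lc50_m = config$true_lc50_m, ctc = config$true_ctc,
      ratio = config$ratio, unit = config$unit,
      slopes = c(a = config$slope_a, b = config$slope_b, m = config$slope_m)
    )
  )
}

#' Parameter-recovery study over repeated simulated experiments
#'
#' Runs `n_experiments` independent simulate-fit-CTC cycles under one
#' configuration, estimating the three LC50s and the CTC in each, and
#' summarizes bias and RMSE against the known truth. Optionally computes a
#' bootstrap CI on the CTC per experiment and reports empirical coverage
#' of the true value. Per-experiment seeds derive from the master seed, so
#' the whole study is reproducible.
#'
#' @param n_experiments Number of simulated experiments (>= 2).
#' @param config A [sim_config()].
#' @param model Dose-response model used for estimation: `"linear"`
#'   (default, the virulence-equation fit) or `"probit"`.
#' @param n_boot Bootstrap resamples per experiment for the CTC CI; 0
#'   (default) skips CIs and coverage.
#' @param level CI level when `n_boot > 0`.
#' @return A `recovery_summary` list: `summary` (data.frame of truth,
#'   mean/median estimate, bias, RMSE per parameter), `estimates`
#'   (per-experiment values), `n_failed`, and `ci_coverage` (fraction of
#'   CIs covering the true CTC, or `NA`).
#' @export
recovery_summary <- function(n_experiments, config, model = c("linear", "probit"),
                             n_boot = 0, level = 0.95) {
  stopifnot(n_experiments >= 2, inherits(config, "sim_config"))
  model <- match.arg(model)
  fit_fun <- if (model == "linear") fit_linear_logdose else fit_probit

  est <- data.frame(
    experiment = seq_len(n_experiments),
    lc50_a = NA_real_, lc50_b = NA_real_, lc50_m = NA_real_, ctc = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, covered = NA
  )
  n_failed <- 0L
  for (i in seq_len(n_experiments)) {
    base_seed <- .derive_seed(config$seed, i)
    exp_i <- simulate_mixture_experiment(config, seed = base_seed)
    # warnings (mortality clamping, zero-slope) are benign here; only a
    # failed fit excludes the experiment
    res <- tryCatch(suppressWarnings({
      lcs <- lapply(exp_i[c("records_a", "records_b", "records_m")],
                    function(r) estimate_lc(fit_fun(aggregate_mortality(r))))
      ct <- compute_ctc(lcs[[1]], lcs[[2]], lcs[[3]], config$ratio)
      if (n_boot > 0) {
        ct <- ctc_bootstrap(exp_i$records_a, exp_i$records_b, exp_i$records_m,
                            config$ratio, level = level, n_boot = n_boot,
                            seed = .derive_seed(base_seed, 4), model = model)
      }
      ct
    }), error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    est$lc50_a[i] <- res$lc50_a
    est$lc50_b[i] <- res$lc50_b
    est$lc50_m[i] <- res$lc50_m
    est$ctc[i] <- res$ctc
    if (n_boot > 0) {
      est$ci_low[i] <- res$ci_low
      est$ci_high[i] <- res$ci_high
      est$covered[i] <- res$ci_low <= config$true_ctc &&
        config$true_ctc <= res$ci_high
    }
  }

  truth <- c(lc50_a = config$true_lc50_a, lc50_b = config$true_lc50_b,
             lc50_m = config$true_lc50_m, ctc = config$true_ctc)
  summary_df <- do.call(rbind, lapply(names(truth), function(par) {
    v <- est[[par]]
    v <- v[is.finite(v)]
    data.frame(
      parameter = par, truth = truth[[par]],
      mean_estimate = mean(v), median_estimate = stats::median(v),
      bias = mean(v) - truth[[par]],
      rmse = sqrt(mean((v - truth[[par]])^2)),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      summary = summary_df, estimates = est, n_failed = n_failed,
      ci_coverage = if (n_boot > 0) mean(est$covered, na.rm = TRUE) else NA_real_,
      model = model, config = config
    ),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery study: %d experiments (%s model), %d failed\n",
              nrow(x$estimates), x$model, x$n_failed))
  print(x$summary, row.names = FALSE)
  if (!is.na(x$ci_coverage))
    cat(sprintf("CTC CI coverage: %.3f\n", x$ci_coverage))
  invisible(x)
}
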