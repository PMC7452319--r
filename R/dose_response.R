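# Closed-form simple OLS of y on x; returns slope, intercept, r_squared.
# Kept as plain arithmetic so the vectorized bootstrap can reuse it cheaply.
.ols <- function(x, y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("all x values identical: cannot fit a line", call. = FALSE)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum((y - (intercept + slope * x))^2) / ss_tot
  list(slope = slope, intercept = intercept, r_squared = min(max(r2, 0), 1))
}

# Pearson chi-square of observed vs expected dead counts under fitted
# per-dose mortality p. Doses whose expected dead (or expected alive)
# count is < 1 are merged with their right neighbour (the final cell
# merges leftwards) before the statistic is computed, so sparse tail
# doses do not inflate it. If a merged cell is still degenerate (fitted p
# pinned at 0 or 1), p is bounded away from the boundary by half a count
# when computing the variance.
.chisq_gof <- function(n, observed_dead, p) {
  p <- pmin(pmax(p, 0), 1)
  exp_dead <- n * p
  exp_alive <- n * (1 - p)
  groups <- integer(length(n))
  g <- 1L
  acc_d <- 0
  acc_a <- 0
  for (i in seq_along(n)) {
    groups[i] <- g
    acc_d <- acc_d + exp_dead[i]
    acc_a <- acc_a + exp_alive[i]
    if (acc_d >= 1 && acc_a >= 1 && i < length(n)) {
      g <- g + 1L
      acc_d <- 0
      acc_a <- 0
    }
  }
  # if the last group is still sparse, fold it into the previous one
  last <- groups == max(groups)
  if ((sum(exp_dead[last]) < 1 || sum(exp_alive[last]) < 1) && max(groups) > 1)
    groups[last] <- max(groups) - 1L
  n_g <- as.numeric(tapply(n, groups, sum))
  obs_g <- as.numeric(tapply(observed_dead, groups, sum))
  exp_g <- as.numeric(tapply(exp_dead, groups, sum))
  p_eff <- pmin(pmax(exp_g / n_g, 0.5 / n_g), 1 - 0.5 / n_g)
  contrib <- ifelse(abs(obs_g - exp_g) < 1e-9, 0,
                    (obs_g - n_g * p_eff)^2 / (n_g * p_eff * (1 - p_eff)))
  sum(contrib)
}

.new_fit <- function(model_kind, slope, intercept, r_squared, chi_squared_gof,
                     dose_unit, n_doses, treatment_id, table) {
  structure(
    list(
      model_kind = model_kind, slope = slope, intercept = intercept,
      r_squared = r_squared, chi_squared_gof = chi_squared_gof,
      dose_unit = dose_unit, n_doses = n_doses, log_base = 10,
      convention = "log10_concentration",
      treatment_id = treatment_id, table = table
    ),
    class = "dose_response_fit"
  )
}

#' Fit a linear mortality-vs-log-dose regression
#'
#' Ordinary least squares of Abbott-corrected mortality, expressed as a
#' percentage, on log10(dose). This is the simple virulence-equation model
#' routinely used in mixture bioassays: `mortality% = intercept + slope *
#' log10(dose)`. Predictions are clamped to `[0, 100]` only when the fitted
#' curve is evaluated (e.g. for the goodness-of-fit statistic), never
#' during fitting.
#'
#' @param table A `mortality_table` from [aggregate_mortality()], or a raw
#'   record data.frame (pooled automatically).
#' @return A `dose_response_fit` with `model_kind = "linear_logdose"`,
#'   `slope` and `intercept` on the percentage scale, `r_squared`, and a
#'   Pearson `chi_squared_gof` of observed vs expected dead counts.
#' @examples
#' rec <- simulate_bioassay(lc50 = 5, slope = 2,
#'                          series = serial_dilution(500, 10, 5), seed = 1)
#' fit <- fit_linear_logdose(aggregate_mortality(rec))
#' estimate_lc(fit, 0.5)
#' @export
fit_linear_logdose <- function(table) {
  if (is.data.frame(table)) table <- aggregate_mortality(table)
  stopifnot(inherits(table, "mortality_table"))
  d <- table$doses
  if (length(unique(d$dose)) < 2)
    stop("need at least 2 distinct positive doses to fit", call. = FALSE)
  x <- log10(d$dose)
  y <- 100 * d$corrected_mortality
  if (length(unique(y)) == 1) {
    warning("all corrected mortalities identical; zero-slope fit")
    fit <- list(slope = 0, intercept = y[1], r_squared = 1)
  } else {
    fit <- .ols(x, y)
  }
  p_hat <- pmin(pmax((fit$intercept + fit$slope * x) / 100, 0), 1)
  chisq <- .chisq_gof(d$n_exposed, d$n_dead,
                      table$control_mortality +
                        (1 - table$control_mortality) * p_hat)
  .new_fit("linear_logdose", fit$slope, fit$intercept, fit$r_squared, chisq,
           table$unit, nrow(d), table$treatment_id, table)
}

#' Fit a probit dose-response model
#'
#' Maximum-likelihood binomial regression of dead counts on log10(dose)
#' with a probit link, the field-standard model for quantal mortality
#' data. Control mortality is handled by Abbott pre-correction of the
#' pooled observed proportions before the likelihood fit.
#'
#' @param records A data.frame of bioassay records (see
#'   [aggregate_mortality()]) or a `mortality_table`.
#' @return A `dose_response_fit` with `model_kind = "probit"`; `slope` and
#'   `intercept` parameterize the probit line
#'   `qnorm(p) = intercept + slope * log10(dose)`. `r_squared` is the
#'   squared correlation between observed and fitted mortality.
#' @export
fit_probit <- function(records) {
  table <- if (inherits(records, "mortality_table")) records
           else aggregate_mortality(records)
  d <- table$doses
  if (length(unique(d$dose)) < 2)
    stop("need at least 2 distinct positive doses to fit", call. = FALSE)
  y <- d$corrected_mortality
  if (all(y %in% c(0, 1)))
    stop("complete separation: every corrected mortality is 0 or 1; ",
         "add intermediate doses or use fit_linear_logdose()", call. = FALSE)
  x <- log10(d$dose)
  g <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(link = "probit"),
               weights = d$n_exposed)
  )
  if (!g$converged)
    stop("probit fit did not converge; the dose range may not bracket the ",
         "LC50 or the responses may be separated", call. = FALSE)
  co <- stats::coef(g)
  p_hat <- stats::pnorm(co[1] + co[2] * x)
  r2 <- if (stats::sd(y) == 0) 1 else min(max(stats::cor(y, p_hat)^2, 0), 1)
  chisq <- .chisq_gof(d$n_exposed, d$n_dead,
                      table$control_mortality +
                        (1 - table$control_mortality) * p_hat)
  .new_fit("probit", unname(co[2]), unname(co[1]), r2, chisq,
           table$unit, nrow(d), table$treatment_id, table)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$model_kind, x$treatment_id))
  if (x$model_kind == "linear_logdose") {
    cat(sprintf("  mortality%% = %.4g + %.4g * log10(dose [%s])\n",
                x$intercept, x$slope, x$dose_unit))
  } else {
    cat(sprintf("  qnorm(p) = %.4g + %.4g * log10(dose [%s])\n",
                x$intercept, x$slope, x$dose_unit))
  }
  cat(sprintf("  r^2 = %.4f, chi^2 GOF = %.4g, %d doses\n",
              x$r_squared, x$chi_squared_gof, x$n_doses))
  invisible(x)
}

#' Inverse-predict a lethal concentration from a fitted model
#'
#' Solves the fitted dose-response line for the dose giving target
#' mortality `p`: `10^((100*p - intercept)/slope)` for the linear model,
#' `10^((qnorm(p) - intercept)/slope)` for the probit model.
#'
#' @param fit A `dose_response_fit`.
#' @param p Target mortality fraction (default 0.5, i.e. the LC50).
#' @return An `lc_estimate`: list with `p`, `value`, `unit`, `method`, and
#'   `ci_low`/`ci_high`/`ci_level` (`NA` unless bootstrapped).
#' @seealso [bootstrap_lc_ci()]
#' @export
estimate_lc <- function(fit, p = 0.5) {
  stopifnot(inherits(fit, "dose_response_fit"), p > 0, p < 1)
  if (fit$slope == 0)
    stop("slope is zero: lethal concentration undefined", call. = FALSE)
  target <- if (fit$model_kind == "linear_logdose") 100 * p else stats::qnorm(p)
  log_dose <- (target - fit$intercept) / fit$slope
  value <- 10^log_dose
  if (!is.finite(value) || value <= 0)
    stop("lethal concentration estimate is not finite", call. = FALSE)
  structure(
    list(p = p, value = value, unit = fit$dose_unit,
         ci_low = NA_real_, ci_high = NA_real_, ci_level = NA_real_,
         method = fit$model_kind),
    class = "lc_estimate"
  )
}

#' @export
print.lc_estimate <- function(x, ...) {
  cat(sprintf("LC%g = %.4g %s (%s)\n", 100 * x$p, x$value, x$unit, x$method))
  if (!is.na(x$ci_low))
    cat(sprintf("  %g%% CI: [%.4g, %.4g]\n",
                100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

# Decompose validated records into per-dose replicate strata for the
# stratified bootstrap: dead/exposed count vectors per dose plus controls.
.records_strata <- function(records) {
  records <- validate_bioassay_records(records)
  trt <- records[!records$is_control, , drop = FALSE]
  ctl <- records[records$is_control, , drop = FALSE]
  doses <- sort(unique(trt$dose))
  list(
    dose = doses,
    dead = lapply(doses, function(d) trt$n_dead[trt$dose == d]),
    n = lapply(doses, function(d) trt$n_exposed[trt$dose == d]),
    ctl_dead = ctl$n_dead,
    ctl_n = ctl$n_exposed,
    unit = unique(trt$unit)[1],
    treatment_id = unique(trt$treatment_id)[1]
  )
}

# Vectorized stratified bootstrap of the linear log-dose LC_p. With
# unit = "insect" the pooled insects of each dose stratum (and of the
# control group) are resampled, i.e. dead counts are redrawn binomially
# at the pooled per-dose mortality; with unit = "replicate" whole
# replicates are resampled with replacement within each dose. Each
# resample is re-pooled, Abbott-corrected, and the OLS line solved, all
# as matrix arithmetic over the n_boot replicates. Returns a vector of
# LC_p values (NaN/Inf mark failed replicates). Draws from the current
# RNG stream: seed handling belongs to the caller.
.boot_lc_linear <- function(strata, n_boot, p = 0.5, unit = "insect") {
  k_d <- length(strata$dose)
  dead <- matrix(0, n_boot, k_d)
  n_exp <- matrix(0, n_boot, k_d)
  for (i in seq_len(k_d)) {
    if (unit == "insect") {
      n_i <- sum(strata$n[[i]])
      dead[, i] <- stats::rbinom(n_boot, n_i, sum(strata$dead[[i]]) / n_i)
      n_exp[, i] <- n_i
    } else {
      k <- length(strata$dead[[i]])
      idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), n_boot, k)
      dead[, i] <- rowSums(matrix(strata$dead[[i]][idx], n_boot, k))
      n_exp[, i] <- rowSums(matrix(strata$n[[i]][idx], n_boot, k))
    }
  }
  kc <- length(strata$ctl_dead)
  if (kc > 0) {
    if (unit == "insect") {
      c_n <- rep(sum(strata$ctl_n), n_boot)
      c_dead <- stats::rbinom(n_boot, c_n[1], sum(strata$ctl_dead) / c_n[1])
    } else {
      idx <- matrix(sample.int(kc, kc * n_boot, replace = TRUE), n_boot, kc)
      c_dead <- rowSums(matrix(strata$ctl_dead[idx], n_boot, kc))
      c_n <- rowSums(matrix(strata$ctl_n[idx], n_boot, kc))
    }
    cm <- c_dead / c_n
  } else {
    cm <- rep(0, n_boot)
  }
  raw <- dead / n_exp
  corrected <- pmin(pmax((raw - cm) / (1 - cm), 0), 1)
  y <- 100 * corrected
  x <- log10(strata$dose)
  xc <- x - mean(x)
  slope <- as.vector(y %*% xc) / sum(xc^2)
  intercept <- rowMeans(y) - slope * mean(x)
  10^((100 * p - intercept) / slope)
}

#' Bootstrap confidence interval for a lethal concentration
#'
#' Nonparametric bootstrap stratified by dose, with a percentile
#' interval; deterministic for a fixed seed. Two resampling units are
#' offered. The default, `"insect"`, resamples the pooled insects within
#' each dose stratum (equivalently, redraws each pooled dead count
#' binomially at its observed mortality), which tracks the binomial
#' sampling variability of the assay. `"replicate"` resamples whole
#' replicates with replacement within each dose, additionally capturing
#' between-replicate overdispersion, but with very few replicates per
#' dose (e.g. the standard 3) it understates variance and its intervals
#' undercover markedly.
#'
#' @param records Bioassay record data.frame for one treatment.
#' @param p Target mortality fraction (default 0.5).
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @param model `"linear"` (default) or `"probit"`.
#' @param boot_unit Resampling unit, `"insect"` (default) or
#'   `"replicate"`.
#' @return An `lc_estimate` whose `ci_low`/`ci_high`/`ci_level` are filled
#'   in; the point estimate is the fit on the full data.
#' @export
bootstrap_lc_ci <- function(records, p = 0.5, level = 0.95, n_boot = 1000,
                            seed = 1, model = c("linear", "probit"),
                            boot_unit = c("insect", "replicate")) {
  model <- match.arg(model)
  boot_unit <- match.arg(boot_unit)
  fit_fun <- if (model == "linear") fit_linear_logdose else fit_probit
  est <- estimate_lc(fit_fun(aggregate_mortality(records)), p)
  strata <- .records_strata(records)
  set.seed(seed)
  if (model == "linear") {
    lcs <- .boot_lc_linear(strata, n_boot, p, unit = boot_unit)
  } else {
    lcs <- vapply(seq_len(n_boot), function(b) {
      res <- .resample_records(strata, unit = boot_unit)
      tryCatch(estimate_lc(fit_probit(res), p)$value,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  ok <- is.finite(lcs) & lcs > 0
  if (mean(ok) < 0.5)
    stop(sprintf("bootstrap failed: %d of %d resamples produced no valid fit",
                 sum(!ok), n_boot), call. = FALSE)
  qs <- stats::quantile(lcs[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  est$ci_low <- qs[1]
  est$ci_high <- qs[2]
  est$ci_level <- level
  est
}

# One stratified resample as a record data.frame (probit bootstrap path).
.resample_records <- function(strata, unit = "insect") {
  rows <- list()
  for (i in seq_along(strata$dose)) {
    if (unit == "insect") {
      n_i <- sum(strata$n[[i]])
      rows[[length(rows) + 1]] <- data.frame(
        treatment_id = strata$treatment_id, dose = strata$dose[i],
        unit = strata$unit, n_exposed = n_i,
        n_dead = stats::rbinom(1, n_i, sum(strata$dead[[i]]) / n_i),
        replicate = 1L, is_control = FALSE
      )
    } else {
      k <- length(strata$dead[[i]])
      pick <- sample.int(k, k, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        treatment_id = strata$treatment_id, dose = strata$dose[i],
        unit = strata$unit, n_exposed = strata$n[[i]][pick],
        n_dead = strata$dead[[i]][pick], replicate = seq_len(k),
        is_control = FALSE
      )
    }
  }
  kc <- length(strata$ctl_dead)
  if (kc > 0) {
    if (unit == "insect") {
      n_c <- sum(strata$ctl_n)
      rows[[length(rows) + 1]] <- data.frame(
        treatment_id = strata$treatment_id, dose = 0,
        unit = strata$unit, n_exposed = n_c,
        n_dead = stats::rbinom(1, n_c, sum(strata$ctl_dead) / n_c),
        replicate = 1L, is_control = TRUE
      )
    } else {
      pick <- sample.int(kc, kc, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        treatment_id = strata$treatment_id, dose = 0,
        unit = strata$unit, n_exposed = strata$ctl_n[pick],
        n_dead = strata$ctl_dead[pick], replicate = seq_len(kc),
        is_control = TRUE
      )
    }
  }
  do.call(rbind, rows)
}
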