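#' Construct a binary mixture ratio
#'
#' Normalizes integer (or real) parts of agents A and B, e.g. 9:1, into
#' weight fractions summing to 1.
#'
#' @param parts_a,parts_b Non-negative parts of agents A and B; their sum
#'   must be positive.
#' @return A `mixture_ratio`: list with `w_a`, `w_b` and a `label` such as
#'   `"9:1"`.
#' @examples
#' mixture_ratio(1, 4) # w_a = 0.2, w_b = 0.8
#' @export
mixture_ratio <- function(parts_a, parts_b) {
  if (!is.finite(parts_a) || !is.finite(parts_b) || parts_a < 0 || parts_b < 0)
    stop("ratio parts must be finite and non-negative", call. = FALSE)
  total <- parts_a + parts_b
  if (total <= 0) stop("ratio parts must have positive sum", call. = FALSE)
  structure(
    list(w_a = parts_a / total, w_b = parts_b / total,
         label = paste0(format(parts_a), ":", format(parts_b))),
    class = "mixture_ratio"
  )
}

#' @export
print.mixture_ratio <- function(x, ...) {
  cat(sprintf("mixture ratio %s (w_a = %.4g, w_b = %.4g)\n",
              x$label, x$w_a, x$w_b))
  invisible(x)
}

.lc50_value <- function(x, role) {
  if (inherits(x, "lc_estimate")) return(list(value = x$value, unit = x$unit))
  if (is.numeric(x) && length(x) == 1) return(list(value = x, unit = NA_character_))
  stop("lc50_", role, " must be a single number or an lc_estimate", call. = FALSE)
}

.check_units <- function(units) {
  units <- units[!is.na(units)]
  if (length(unique(units)) > 1)
    stop("LC50 unit mismatch: ", paste(unique(units), collapse = " vs "),
         "; convert to a common potency unit first", call. = FALSE)
  if (length(units) > 0) units[1] else NA_character_
}

#' Classify a mixture interaction from its co-toxicity coefficient
#'
#' CTC above 120 indicates marked synergism, values in the closed interval
#' \[80, 120\] a cumulative (additive) effect, and values below 80
#' antagonism.
#'
#' @param ctc Positive co-toxicity coefficient(s). Vectorized.
#' @return Character vector with values `"synergism"`, `"cumulative"` or
#'   `"antagonism"`.
#' @export
classify_interaction <- function(ctc) {
  if (any(!is.finite(ctc)) || any(ctc <= 0))
    stop("ctc must be positive and finite", call. = FALSE)
  ifelse(ctc > 120, "synergism", ifelse(ctc < 80, "antagonism", "cumulative"))
}

#' Additive-reference LC50 of a binary mixture
#'
#' The LC50 a mixture would need for exact dose additivity (CTC = 100):
#' the ratio-weighted harmonic mean
#' \deqn{LC50_{add} = 1 / (w_A/LC50_A + w_B/LC50_B).}
#'
#' @param lc50_a,lc50_b Standalone LC50s of agents A and B (numbers or
#'   `lc_estimate`s in the same unit).
#' @param ratio A [mixture_ratio()].
#' @return The additive mixture LC50 (positive scalar).
#' @export
additive_lc50 <- function(lc50_a, lc50_b, ratio) {
  stopifnot(inherits(ratio, "mixture_ratio"))
  a <- .lc50_value(lc50_a, "a")
  b <- .lc50_value(lc50_b, "b")
  .check_units(c(a$unit, b$unit))
  if (a$value <= 0 || b$value <= 0)
    stop("LC50 values must be positive", call. = FALSE)
  1 / (ratio$w_a / a$value + ratio$w_b / b$value)
}

#' Co-toxicity coefficient of a binary mixture
#'
#' Computes the toxicity-index chain with agent A as the reference
#' (TI of A = 100):
#' \itemize{
#'   \item TI of B = LC50_A / LC50_B x 100
#'   \item actual TI of M = LC50_A / LC50_M x 100
#'   \item theoretical TI of M = TI_A * w_A + TI_B * w_B
#'   \item CTC = actual TI / theoretical TI x 100
#' }
#' CTC = 100 indicates dose additivity; the interaction label follows
#' [classify_interaction()].
#'
#' @param lc50_a,lc50_b,lc50_m Standalone LC50s of agents A and B and of
#'   the mixture M, as numbers or `lc_estimate`s carrying the same unit.
#' @param ratio A [mixture_ratio()] giving the weight fractions of A and B
#'   in M.
#' @return A `cotoxicity_result`: list with `ti_a` (100), `ti_b`,
#'   `actual_ti`, `theoretical_ti`, `ctc`, `label`, the three LC50s,
#'   `ratio`, `unit` and `ci_low`/`ci_high`/`ci_level` (`NA` unless
#'   bootstrapped).
#' @examples
#' compute_ctc(10, 5, 4, mixture_ratio(1, 1)) # ctc ~ 166.7, synergism
#' @export
compute_ctc <- function(lc50_a, lc50_b, lc50_m, ratio) {
  stopifnot(inherits(ratio, "mixture_ratio"))
  a <- .lc50_value(lc50_a, "a")
  b <- .lc50_value(lc50_b, "b")
  m <- .lc50_value(lc50_m, "m")
  unit <- .check_units(c(a$unit, b$unit, m$unit))
  if (a$value <= 0 || b$value <= 0 || m$value <= 0)
    stop("all LC50 values must be positive", call. = FALSE)
  ti_b <- a$value / b$value * 100
  actual_ti <- a$value / m$value * 100
  theoretical_ti <- 100 * ratio$w_a + ti_b * ratio$w_b
  ctc <- actual_ti / theoretical_ti * 100
  structure(
    list(
      ti_a = 100, ti_b = ti_b, actual_ti = actual_ti,
      theoretical_ti = theoretical_ti, ctc = ctc,
      label = classify_interaction(ctc),
      lc50_a = a$value, lc50_b = b$value, lc50_m = m$value,
      ratio = ratio, unit = unit,
      ci_low = NA_real_, ci_high = NA_real_, ci_level = NA_real_
    ),
    class = "cotoxicity_result"
  )
}

#' @export
print.cotoxicity_result <- function(x, ...) {
  cat(sprintf("Co-toxicity, mixture %s", x$ratio$label))
  if (!is.na(x$unit)) cat(sprintf(" (LC50s in %s)", x$unit))
  cat("\n")
  cat(sprintf("  LC50: A = %.4g, B = %.4g, M = %.4g\n",
              x$lc50_a, x$lc50_b, x$lc50_m))
  cat(sprintf("  TI(B) = %.2f, actual TI = %.2f, theoretical TI = %.2f\n",
              x$ti_b, x$actual_ti, x$theoretical_ti))
  cat(sprintf("  CTC = %.2f -> %s\n", x$ctc, x$label))
  if (!is.na(x$ci_low))
    cat(sprintf("  %g%% CI: [%.2f, %.2f]\n",
                100 * x$ci_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Joint bootstrap confidence interval for the co-toxicity coefficient
#'
#' Resamples each of the three assays (agent A, agent B, mixture M)
#' independently with the dose-stratified scheme of [bootstrap_lc_ci()],
#' recomputes the three LC50s and the CTC per resample, and reports the
#' percentile interval. Deterministic for a fixed seed.
#'
#' @param records_a,records_b,records_m Bioassay record data.frames for
#'   agent A, agent B and the mixture.
#' @param ratio A [mixture_ratio()].
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @param model `"linear"` (default) or `"probit"` dose-response model.
#' @param boot_unit Resampling unit, `"insect"` (default) or
#'   `"replicate"`; see [bootstrap_lc_ci()] for the trade-off.
#' @return A `cotoxicity_result` with `ci_low`/`ci_high`/`ci_level` set;
#'   point values come from fits on the full data.
#' @export
ctc_bootstrap <- function(records_a, records_b, records_m, ratio,
                          level = 0.95, n_boot = 1000, seed = 1,
                          model = c("linear", "probit"),
                          boot_unit = c("insect", "replicate")) {
  model <- match.arg(model)
  boot_unit <- match.arg(boot_unit)
  fit_fun <- if (model == "linear") fit_linear_logdose else fit_probit
  lc <- lapply(list(records_a, records_b, records_m),
               function(r) estimate_lc(fit_fun(aggregate_mortality(r))))
  point <- compute_ctc(lc[[1]], lc[[2]], lc[[3]], ratio)

  set.seed(seed)
  strata <- lapply(list(records_a, records_b, records_m), .records_strata)
  if (model == "linear") {
    draws <- lapply(strata, .boot_lc_linear, n_boot = n_boot, unit = boot_unit)
  } else {
    draws <- lapply(strata, function(s) {
      vapply(seq_len(n_boot), function(b) {
        tryCatch(
          estimate_lc(fit_probit(.resample_records(s, unit = boot_unit)))$value,
          error = function(e) NA_real_)
      }, numeric(1))
    })
  }
  a <- draws[[1]]; b <- draws[[2]]; m <- draws[[3]]
  ti_b <- a / b * 100
  ctcs <- (a / m * 100) / (100 * ratio$w_a + ti_b * ratio$w_b) * 100
  ok <- is.finite(ctcs) & ctcs > 0
  if (mean(ok) < 0.5)
    stop(sprintf("bootstrap failed: %d of %d resamples invalid",
                 sum(!ok), n_boot), call. = FALSE)
  qs <- stats::quantile(ctcs[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  point$ci_low <- qs[1]
  point$ci_high <- qs[2]
  point$ci_level <- level
  point
}
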