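#' Abbott's correction for control mortality
#'
#' Adjusts an observed treatment mortality for background mortality seen in
#' untreated controls, using the standard form
#' \deqn{p_{corr} = (p_t - p_c) / (1 - p_c)}
#' where \eqn{p_t} is the treatment mortality and \eqn{p_c} the control
#' mortality, both as fractions. When the treatment mortality falls below
#' the control mortality the corrected value is clamped to 0 with a
#' warning; values are likewise clamped at 1.
#'
#' @param treatment_mortality Observed treatment mortality fraction in
#'   `[0, 1]`. Vectorized.
#' @param control_mortality Control mortality fraction in `[0, 1)`.
#' @return Corrected mortality fraction(s) in `[0, 1]`.
#' @examples
#' abbott_correct(0.55, 0.10) # 0.5
#' abbott_correct(0.40, 0)    # identity when controls are clean
#' @export
abbott_correct <- function(treatment_mortality, control_mortality) {
  if (any(!is.finite(treatment_mortality)) || any(!is.finite(control_mortality)))
    stop("mortality fractions must be finite numbers", call. = FALSE)
  if (any(treatment_mortality < 0 | treatment_mortality > 1))
    stop("treatment_mortality must lie in [0, 1]", call. = FALSE)
  if (any(control_mortality < 0 | control_mortality > 1))
    stop("control_mortality must lie in [0, 1]", call. = FALSE)
  if (any(control_mortality >= 1))
    stop("control_mortality >= 1: correction undefined (all controls dead)",
         call. = FALSE)
  corrected <- (treatment_mortality - control_mortality) / (1 - control_mortality)
  if (any(corrected < -1e-12))
    warning("treatment mortality below control mortality; corrected value clamped to 0")
  pmin(pmax(corrected, 0), 1)
}

# Checks the bioassay record data.frame contract shared by every consumer.
# Returns the records with columns coerced to their canonical types.
validate_bioassay_records <- function(records) {
  required <- c("treatment_id", "dose", "unit", "n_exposed", "n_dead",
                "replicate", "is_control")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0)
    stop("bioassay records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  records$treatment_id <- as.character(records$treatment_id)
  records$unit <- as.character(records$unit)
  records$dose <- as.numeric(records$dose)
  records$n_exposed <- as.integer(records$n_exposed)
  records$n_dead <- as.integer(records$n_dead)
  records$replicate <- as.integer(records$replicate)
  records$is_control <- as.logical(records$is_control)
  if (any(!is.finite(records$dose)) || any(records$dose < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  if (any(records$n_exposed <= 0))
    stop("n_exposed must be a positive count", call. = FALSE)
  if (any(records$n_dead < 0))
    stop("n_dead must be non-negative", call. = FALSE)
  bad <- which(records$n_dead > records$n_exposed)
  if (length(bad) > 0)
    stop("n_dead > n_exposed in record(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  mismatch <- which(records$is_control != (records$dose == 0))
  if (length(mismatch) > 0)
    stop("is_control flag must agree with dose == 0 (record(s) ",
         paste(mismatch, collapse = ", "), ")", call. = FALSE)
  records
}

#' Pool bioassay replicates into a per-dose mortality table
#'
#' Pools dead/exposed counts over replicates at each dose of a single
#' treatment, computes raw mortality fractions, pools control records
#' (dose 0) into a control mortality estimate, and applies Abbott's
#' correction. This is the canonical preprocessing step before any
#' dose-response fit.
#'
#' @param records A data.frame of bioassay records with columns
#'   `treatment_id`, `dose`, `unit`, `n_exposed`, `n_dead`, `replicate`,
#'   `is_control`. All records must belong to one treatment and share one
#'   dose unit.
#' @return A `mortality_table` object: a list with elements
#'   `treatment_id`, `unit`, `doses` (data.frame of `dose`, `n_exposed`,
#'   `n_dead`, `raw_mortality`, `corrected_mortality`, sorted by
#'   increasing dose), `control_mortality` and `control_n`.
#' @seealso [abbott_correct()], [fit_linear_logdose()]
#' @export
aggregate_mortality <- function(records) {
  records <- validate_bioassay_records(records)
  ids <- unique(records$treatment_id)
  if (length(ids) != 1)
    stop("records mix treatment_ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  units <- unique(records$unit)
  if (length(units) != 1)
    stop("records mix dose units within treatment '", ids, "': ",
         paste(units, collapse = ", "), call. = FALSE)
  dup <- duplicated(records[, c("dose", "replicate")])
  if (any(dup))
    stop("duplicate (dose, replicate) combinations in records", call. = FALSE)

  ctl <- records[records$is_control, , drop = FALSE]
  trt <- records[!records$is_control, , drop = FALSE]
  if (nrow(trt) == 0)
    stop("no non-control dose records for treatment '", ids, "'", call. = FALSE)

  control_n <- sum(ctl$n_exposed)
  control_mortality <- if (control_n > 0) sum(ctl$n_dead) / control_n else 0

  pooled_exposed <- tapply(trt$n_exposed, trt$dose, sum)
  pooled_dead <- tapply(trt$n_dead, trt$dose, sum)
  dose <- as.numeric(names(pooled_exposed))
  ord <- order(dose)
  dose <- dose[ord]
  n_exposed <- as.integer(pooled_exposed[ord])
  n_dead <- as.integer(pooled_dead[ord])
  raw <- n_dead / n_exposed
  corrected <- abbott_correct(raw, control_mortality)

  structure(
    list(
      treatment_id = ids,
      unit = units,
      doses = data.frame(
        dose = dose, n_exposed = n_exposed, n_dead = n_dead,
        raw_mortality = raw, corrected_mortality = corrected,
        row.names = NULL
      ),
      control_mortality = control_mortality,
      control_n = control_n
    ),
    class = "mortality_table"
  )
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("Mortality table:", x$treatment_id, "(", x$unit, ")\n")
  cat(sprintf("Control mortality: %.3f (n = %d)\n",
              x$control_mortality, x$control_n))
  print(x$doses, row.names = FALSE)
  invisible(x)
}

#' Validate a pooled bioassay against quality criteria
#'
#' Screens a mortality table for the usual reasons a bioassay is rejected
#' or viewed with suspicion: excessive control mortality, too few dose
#' levels to fit a curve, and corrected mortality that decreases with
#' dose. Findings are reported; nothing is mutated.
#'
#' @param table A `mortality_table` from [aggregate_mortality()].
#' @param max_control_mortality Highest acceptable control mortality
#'   fraction (default 0.20).
#' @return A data.frame with columns `check`, `status`
#'   (`"pass"`/`"fail"`/`"warning"`) and `message`.
#' @export
validate_assay <- function(table, max_control_mortality = 0.20) {
  stopifnot(inherits(table, "mortality_table"))
  findings <- list()
  add <- function(check, status, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      check = check, status = status, message = message,
      stringsAsFactors = FALSE
    )
  }

  if (table$control_mortality > max_control_mortality) {
    add("control_mortality", "fail",
        sprintf("control mortality %.3f exceeds threshold %.3f",
                table$control_mortality, max_control_mortality))
  } else {
    add("control_mortality", "pass",
        sprintf("control mortality %.3f within threshold %.3f",
                table$control_mortality, max_control_mortality))
  }

  n_doses <- nrow(table$doses)
  if (n_doses < 3) {
    add("n_doses", "fail",
        sprintf("only %d dose level(s); at least 3 recommended", n_doses))
  } else {
    add("n_doses", "pass", sprintf("%d dose levels", n_doses))
  }

  cm <- table$doses$corrected_mortality
  if (any(diff(cm) < 0)) {
    add("monotonicity", "warning",
        "corrected mortality decreases over increasing doses")
  } else {
    add("monotonicity", "pass",
        "corrected mortality non-decreasing in dose")
  }

  do.call(rbind, findings)
}
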