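# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Hand-build a mortality_table with given corrected mortalities (fractions)
# at given doses, bypassing aggregation. Useful for exact-arithmetic fits.
make_table <- function(doses, corrected, n = 90, control_mortality = 0,
                       unit = "mg/L", id = "fix") {
  raw <- control_mortality + (1 - control_mortality) * corrected
  structure(
    list(
      treatment_id = id, unit = unit,
      doses = data.frame(
        dose = doses, n_exposed = rep(n, length(doses)),
        n_dead = raw * n, raw_mortality = raw,
        corrected_mortality = corrected, row.names = NULL
      ),
      control_mortality = control_mortality,
      control_n = if (control_mortality > 0) n else 0L
    ),
    class = "mortality_table"
  )
}

# Raw record data.frame from per-replicate dead counts. `dead` is a
# matrix: rows = doses, cols = replicates.
make_records <- function(doses, dead, n = 30, unit = "mg/L", id = "fix",
                         ctl_dead = NULL) {
  rows <- expand.grid(replicate = seq_len(ncol(dead)),
                      dose_idx = seq_along(doses))
  out <- data.frame(
    treatment_id = id, dose = doses[rows$dose_idx], unit = unit,
    n_exposed = n, n_dead = as.vector(t(dead)),
    replicate = rows$replicate, is_control = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(ctl_dead)) {
    out <- rbind(out, data.frame(
      treatment_id = id, dose = 0, unit = unit, n_exposed = n,
      n_dead = ctl_dead, replicate = seq_along(ctl_dead),
      is_control = TRUE, stringsAsFactors = FALSE
    ))
  }
  out
}

# Noise-free records: dead counts are the expected counts (rounded) under
# the probit truth, at large n so rounding error is negligible.
make_expected_records <- function(lc50, slope, series, n = 100000, id = "exp") {
  p <- stats::pnorm(slope * (log10(series$concentrations) - log10(lc50)))
  make_records(series$concentrations,
               matrix(round(n * p), ncol = 1), n = n,
               unit = series$unit, id = id)
}

random_positive <- function(n, min_log = -2, max_log = 3) {
  10^stats::runif(n, min_log, max_log)
}
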