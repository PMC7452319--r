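#' Mycelial growth inhibition rate
#'
#' Percentage reduction of fungal colony diameter on amended medium
#' relative to the unamended control:
#' `(control - test) / control * 100`. A negative value (growth
#' stimulation) is returned as-is with a warning.
#'
#' @param control_diameter Mean colony diameter on control plates (> 0).
#' @param test_diameter Mean colony diameter on treated plates (>= 0).
#'   Vectorized.
#' @return Inhibition rate(s) in percent (<= 100).
#' @examples
#' inhibition_rate(5, 4) # 20
#' @export
inhibition_rate <- function(control_diameter, test_diameter) {
  if (any(!is.finite(control_diameter)) || any(control_diameter <= 0))
    stop("control_diameter must be positive", call. = FALSE)
  if (any(!is.finite(test_diameter)) || any(test_diameter < 0))
    stop("test_diameter must be non-negative", call. = FALSE)
  rate <- (control_diameter - test_diameter) / control_diameter * 100
  if (any(rate < 0))
    warning("negative inhibition rate: treated colonies grew larger than controls")
  rate
}

#' Spore germination rate
#'
#' Percentage of observed spores that germinated:
#' `germinated / observed * 100`.
#'
#' @param germinated Count of germinated spores, `0 <= germinated <=
#'   observed`. Vectorized.
#' @param observed Count of spores scored, > 0.
#' @return Germination rate(s) in `[0, 100]`.
#' @examples
#' germination_rate(73, 200) # 36.5
#' @export
germination_rate <- function(germinated, observed) {
  if (any(observed <= 0))
    stop("observed spore count must be positive", call. = FALSE)
  if (any(germinated < 0))
    stop("germinated count must be non-negative", call. = FALSE)
  if (any(germinated > observed))
    stop("germinated count exceeds observed count", call. = FALSE)
  germinated / observed * 100
}

#' Summarize a chemical-fungus compatibility assay
#'
#' Takes replicate-level plate measurements (colony diameters and spore
#' germination counts per chemical concentration, with concentration 0 as
#' the control), averages diameters per concentration, and computes the
#' growth inhibition rate against the control mean plus pooled spore
#' germination rates.
#'
#' @param data A data.frame with columns `concentration`, `unit`,
#'   `replicate`, `colony_diameter_cm`, and optionally `germinated`,
#'   `observed`. Rows with `concentration == 0` are the controls.
#' @param subtract_plug If `TRUE`, subtract the inoculation-plug diameter
#'   from every measured colony diameter before the inhibition formula.
#' @param plug_diameter_cm Plug diameter in cm (default 0.5).
#' @return A `compatibility_result` data.frame with one row per non-zero
#'   concentration: `concentration`, `unit`, `mean_control_diameter`,
#'   `mean_test_diameter`, `sd_test_diameter`, `inhibition_pct`, and (when
#'   spore counts are present) `germinated`, `observed`,
#'   `germination_pct`.
#' @export
summarize_compatibility <- function(data, subtract_plug = FALSE,
                                    plug_diameter_cm = 0.5) {
  required <- c("concentration", "unit", "replicate", "colony_diameter_cm")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0)
    stop("compatibility data missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!any(data$concentration == 0))
    stop("no control rows (concentration == 0) present", call. = FALSE)
  diam <- data$colony_diameter_cm
  if (subtract_plug) diam <- pmax(diam - plug_diameter_cm, 0)

  ctl <- data$concentration == 0
  control_mean <- mean(diam[ctl])
  conc <- sort(unique(data$concentration[!ctl]))
  has_spores <- all(c("germinated", "observed") %in% names(data))

  rows <- lapply(conc, function(cc) {
    sel <- data$concentration == cc
    row <- data.frame(
      concentration = cc,
      unit = unique(data$unit[sel])[1],
      mean_control_diameter = control_mean,
      mean_test_diameter = mean(diam[sel]),
      sd_test_diameter = stats::sd(diam[sel]),
      stringsAsFactors = FALSE
    )
    row$inhibition_pct <- inhibition_rate(control_mean, row$mean_test_diameter)
    if (has_spores) {
      row$germinated <- sum(data$germinated[sel])
      row$observed <- sum(data$observed[sel])
      row$germination_pct <- germination_rate(row$germinated, row$observed)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("compatibility_result", "data.frame")
  out
}
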