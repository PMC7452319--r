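#' Build a series of mixture ratios from parts
#'
#' Converts integer part pairs such as 9:1 into normalized
#' [mixture_ratio()] objects. The default series is the five-ratio design
#' commonly used to scan for an optimal binary blend.
#'
#' @param parts A list of length-2 numeric vectors `(parts_a, parts_b)`.
#' @return A list of `mixture_ratio` objects, named by their labels.
#' @examples
#' build_ratio_series() # 9:1, 4:1, 1:1, 1:4, 1:9
#' @export
build_ratio_series <- function(parts = list(c(9, 1), c(4, 1), c(1, 1),
                                            c(1, 4), c(1, 9))) {
  ratios <- lapply(parts, function(p) {
    if (length(p) != 2)
      stop("each element of parts must be a length-2 vector", call. = FALSE)
    mixture_ratio(p[1], p[2])
  })
  names(ratios) <- vapply(ratios, `[[`, character(1), "label")
  ratios
}

#' Serial-dilution dose gradient
#'
#' Concentrations obtained by repeatedly diluting a stock by a constant
#' fold factor: `stock / fold^(0:(levels-1))`, the 5-level 10-fold gradient
#' being the standard dose-mortality design.
#'
#' @param stock Stock (highest) concentration, > 0.
#' @param fold Dilution factor between consecutive levels, > 1 (default 10).
#' @param levels Number of concentration levels, >= 1 (default 5).
#' @param unit Concentration unit label (default `"mg/L"`).
#' @return A `dilution_series`: list with `stock`, `fold`, `levels`,
#'   `unit` and the decreasing `concentrations` vector.
#' @examples
#' serial_dilution(500, 10, 5)$concentrations # 500 50 5 0.5 0.05
#' @export
serial_dilution <- function(stock, fold = 10, levels = 5, unit = "mg/L") {
  if (!is.finite(stock) || stock <= 0)
    stop("stock concentration must be positive", call. = FALSE)
  if (!is.finite(fold) || fold <= 1)
    stop("fold must be > 1", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  structure(
    list(stock = stock, fold = fold, levels = levels, unit = unit,
         concentrations = stock / fold^(seq_len(levels) - 1)),
    class = "dilution_series"
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("%d-level %g-fold dilution series (%s): %s\n",
              x$levels, x$fold, x$unit,
              paste(signif(x$concentrations, 4), collapse = ", ")))
  invisible(x)
}

#' Tabulate a mixture experimental design
#'
#' Crosses a ratio series with a dilution gradient into the long-format
#' design table used for plate layout and CSV export.
#'
#' @param ratios A list of `mixture_ratio` objects
#'   (see [build_ratio_series()]).
#' @param series A `dilution_series`, or a list of one series per ratio
#'   (to allow ratio-specific stock concentrations).
#' @return A data.frame with columns `ratio_label`, `level_index`,
#'   `concentration`, `unit`.
#' @export
mixture_design_table <- function(ratios, series) {
  if (inherits(series, "dilution_series"))
    series <- rep(list(series), length(ratios))
  stopifnot(length(series) == length(ratios))
  rows <- Map(function(r, s) {
    data.frame(
      ratio_label = r$label,
      level_index = seq_len(s$levels),
      concentration = s$concentrations,
      unit = s$unit,
      stringsAsFactors = FALSE
    )
  }, ratios, series)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
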