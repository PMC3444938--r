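#' Cell-count increase factor over the labeling window
#'
#' The pulse experiment is run under slow, approximately exponential growth;
#' the increase in cell number over the labeling window sets the growth
#' dilution every protein experiences.  With exactly two time points the
#' factor is the plain count ratio between the window end and start.  With
#' more points an exponential (log-linear least-squares) fit is used and the
#' factor is the fitted fold change across the window.
#'
#' @param counts Data frame with columns `time_h` and `cell_count`.
#' @return The fold increase in cell count over the observed window
#'   (dimensionless, > 0).
#' @export
growth_factor_from_counts <- function(counts) {
  if (!all(c("time_h", "cell_count") %in% names(counts))) {
    abort("`counts` needs columns `time_h` and `cell_count`.")
  }
  counts <- dplyr::arrange(tibble::as_tibble(counts), .data$time_h)
  if (nrow(counts) < 2) abort("Need at least two cell-count time points.")
  if (any(counts$cell_count <= 0)) abort("Cell counts must be positive.")
  window <- max(counts$time_h) - min(counts$time_h)
  if (window <= 0) abort("Cell counts must span a positive time window.")
  if (nrow(counts) == 2) {
    return(counts$cell_count[2] / counts$cell_count[1])
  }
  fit <- lm(log(cell_count) ~ time_h, data = counts)
  exp(unname(coef(fit)["time_h"]) * window)
}

#' Doubling time from a growth factor
#'
#' Under exponential growth `P(t) = P0 * 2^(t / t_double)`, a fold increase
#' `g` over a window `w` gives `t_double = w / log2(g)`.  A factor of 1.3
#' over 24 h gives 63.41 h (displayed as 63 h).  A factor at or below 1
#' means no net growth; the doubling time is reported as `Inf` rather than
#' raising an error, so downstream dilution correction degrades to zero.
#'
#' @param growth_factor Fold increase over the window (> 0).
#' @param window_h Window length in hours (> 0).
#' @return Doubling time in hours (`Inf` if `growth_factor <= 1`).
#' @export
doubling_time <- function(growth_factor, window_h) {
  if (growth_factor <= 0) abort("`growth_factor` must be positive.")
  if (window_h <= 0) abort("`window_h` must be positive.")
  if (growth_factor <= 1) return(Inf)
  window_h / log2(growth_factor)
}

#' Expected H/L ratio of a protein with zero degradation
#'
#' If a protein is only synthesized to keep pace with biomass increase
#' (no proteolytic turnover), the heavy (new) over light (pre-existing)
#' ratio after a pulse of length `t` is `2^(t / t_double) - 1`.  For the
#' 63.41 h doubling time this is 0.300 at 24 h: proteins whose observed
#' ratio exceeds it are turned over, ratios below it indicate synthesis
#' slower than biomass increase.
#'
#' @param t_h Pulse time in hours (>= 0); vectorized.
#' @param t_double Doubling time in hours (> 0, may be `Inf`).
#' @return Expected H/L ratio (0 at `t_h = 0`).
#' @export
expected_ratio <- function(t_h, t_double) {
  if (any(t_h < 0)) abort("`t_h` must be non-negative.")
  if (any(t_double <= 0)) abort("`t_double` must be positive.")
  2^(t_h / t_double) - 1
}

#' Build the exponential growth model used for dilution correction
#'
#' Either supply a `counts` data frame (factor and window are derived from
#' it) or the `growth_factor` / `window_h` pair directly.  The model fixes
#' the dilution rate `k_dil = ln(2) / t_double`, the apparent loss rate of
#' pre-existing (light) protein caused purely by growth.
#'
#' @param growth_factor Fold increase over the window; ignored if `counts`
#'   is given.
#' @param window_h Window length in hours (default 24, the pulse length).
#' @param counts Optional data frame of `time_h` / `cell_count`.
#' @return An object of class `growth_model`: a list with
#'   `growth_factor`, `window_h`, `t_double` (h) and `k_dil` (1/h).
#' @examples
#' m <- growth_model(1.3, 24)
#' m$t_double  # 63.41 h
#' @export
growth_model <- function(growth_factor = NULL, window_h = 24, counts = NULL) {
  if (!is.null(counts)) {
    growth_factor <- growth_factor_from_counts(counts)
    window_h <- max(counts$time_h) - min(counts$time_h)
  }
  if (is.null(growth_factor)) {
    abort("Supply either `growth_factor` or `counts`.")
  }
  t_double <- doubling_time(growth_factor, window_h)
  structure(
    list(
      growth_factor = growth_factor,
      window_h = window_h,
      t_double = t_double,
      k_dil = if (is.finite(t_double)) log(2) / t_double else 0
    ),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Exponential growth model\n")
  cat(sprintf("  growth factor : %.4g over %.4g h\n", x$growth_factor, x$window_h))
  cat(sprintf("  doubling time : %s h\n",
              if (is.finite(x$t_double)) sprintf("%.0f (%.2f)", round(x$t_double), x$t_double) else "Inf"))
  cat(sprintf("  dilution rate : %.4g /h\n", x$k_dil))
  invisible(x)
}

#' @rdname growth_model
#' @param x A `growth_model`.
#' @param ... Unused.
#' @method tidy growth_model
#' @export
tidy.growth_model <- function(x, ...) {
  tibble::tibble(
    growth_factor = x$growth_factor,
    window_h = x$window_h,
    t_double_h = x$t_double,
    k_dil = x$k_dil,
    expected_ratio_24h = expected_ratio(24, x$t_double)
  )
}
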