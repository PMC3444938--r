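#' Filter proteins quantified with sufficient confidence in one sample
#'
#' Applies the standard quantification-confidence filters: an H/L ratio must
#' be present, supported by at least `min_ratio_count` independent peptide
#' ratio measurements, and the protein identified with at least
#' `min_unique_peptides` unique peptides.
#'
#' @param proteins Long protein tibble ([read_protein_groups()]).
#' @param sample A `sample_id` present in `proteins`.
#' @param min_ratio_count Minimum ratio count (default 3).
#' @param min_unique_peptides Minimum unique peptides (default 2).
#' @return The filtered subset for that sample, input order preserved.
#' @export
filter_quantified <- function(proteins, sample, min_ratio_count = 3,
                              min_unique_peptides = 2) {
  if (!sample %in% proteins$sample_id) {
    abort(paste0("Unknown sample '", sample, "'."))
  }
  dplyr::filter(
    proteins,
    .data$sample_id == sample,
    !is.na(.data$ratio_hl) | min_ratio_count == 0,
    .data$ratio_count >= min_ratio_count,
    .data$unique_peptides >= min_unique_peptides
  )
}

#' Fit a protein loss rate by regression through the origin
#'
#' Under exponential growth, exponential decay of pre-existing (light)
#' protein and full incorporation of the heavy label into new protein, the
#' H/L ratio follows `R(t) = exp(k_loss * t) - 1`, so `ln(1 + R)` is linear
#' in time through the origin.  The fit is the through-origin least-squares
#' slope `k_loss = sum(t * y) / sum(t^2)` with `y = ln(1 + R)`; the pulse
#' start `(0, 0)` is an implicit anchor (it contributes nothing to either
#' sum).  `use_linear_ratio = TRUE` instead regresses the raw ratio on time,
#' the small-ratio linearization.
#'
#' @param times_h Time points in hours (>= 0); replicate measurements at
#'   the same time are pooled into one regression.
#' @param ratios Observed H/L ratios (>= 0), same length.
#' @param use_linear_ratio Regress raw `R` instead of `ln(1 + R)`.
#' @return A list with `k_loss` (1/h), `fit_residual` (minimized sum of
#'   squares) and `n_points` (measurements used, excluding the anchor).
#' @export
fit_loss_rate <- function(times_h, ratios, use_linear_ratio = FALSE) {
  if (length(times_h) != length(ratios)) {
    abort("`times_h` and `ratios` must have the same length.")
  }
  keep <- !is.na(times_h) & !is.na(ratios)
  times_h <- times_h[keep]
  ratios <- ratios[keep]
  if (any(times_h < 0)) abort("Time points must be non-negative.")
  if (any(ratios < 0)) abort("H/L ratios must be non-negative.")
  pos <- times_h > 0
  if (!any(pos)) abort("All time points are zero; no information on the loss rate.")
  if (length(unique(times_h[pos])) < 2) {
    abort("Need ratios at two or more distinct positive time points.")
  }
  t <- times_h[pos]
  y <- if (use_linear_ratio) ratios[pos] else log1p(ratios[pos])
  k <- sum(t * y) / sum(t^2)
  list(
    k_loss = k,
    fit_residual = sum((y - k * t)^2),
    n_points = length(t)
  )
}

#' Degradation rate from loss rate and growth dilution
#'
#' The observed loss of light protein mixes true proteolysis with dilution
#' by growth; subtracting the dilution rate isolates degradation:
#' `k_deg = k_loss - k_dil`.  The result may be zero or negative for
#' proteins synthesized more slowly than biomass increases; it is recorded
#' as-is and only censored when half-lives are derived.
#'
#' @param k_loss Loss rate in 1/h (vectorized).
#' @param model A [growth_model()] or a numeric dilution rate `k_dil`.
#' @return Degradation rate(s) in 1/h.
#' @export
degradation_rate <- function(k_loss, model) {
  k_dil <- if (inherits(model, "growth_model")) model$k_dil else as.numeric(model)
  if (is.na(k_dil) || k_dil < 0) abort("Dilution rate must be a non-negative number.")
  k_loss - k_dil
}

#' Protein half-life with censoring of non-positive degradation rates
#'
#' `T1/2 = ln(2) / k_deg` when `k_deg` exceeds `epsilon`; otherwise the
#' half-life is censored (`NA`) rather than reported as a huge or negative
#' number, since measurement noise around zero degradation would otherwise
#' produce arbitrarily long lifetimes.
#'
#' @param k_deg Degradation rate(s) in 1/h.
#' @param epsilon Censoring threshold in 1/h (default 1e-6, i.e. half-lives
#'   are capped near 7e5 h).
#' @return Half-life in hours, `NA` where censored.
#' @export
protein_half_life <- function(k_deg, epsilon = 1e-6) {
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  ifelse(k_deg > epsilon, log(2) / k_deg, NA_real_)
}

#' Fit growth-corrected turnover for every protein in a pulse time course
#'
#' The main turnover pipeline: joins sample metadata onto the long protein
#' table, keeps the configured fit time points, applies the
#' quantification-confidence filters, pools replicate cultures into one
#' through-origin regression of `ln(1 + R)` on time per protein, subtracts
#' growth dilution and converts to half-lives.
#'
#' @param proteins Long protein tibble ([read_protein_groups()] or
#'   [gen_turnover_dataset()]).
#' @param metadata Sample metadata tibble.
#' @param model A [growth_model()].
#' @param times_h Pulse time points used in the regression (default
#'   `c(3, 8, 24)`; the 1 h point is excluded by default because arginine
#'   uptake has not yet equilibrated, include it by adding it here).  The
#'   `(0, 0)` anchor is always implicit.
#' @param min_ratio_count,min_unique_peptides Confidence filters, see
#'   [filter_quantified()].
#' @param use_linear_ratio Passed to [fit_loss_rate()].
#' @param epsilon Censoring threshold, see [protein_half_life()].
#' @return A `turnover_fit` tibble with one row per protein:
#'   `protein_id`, `n_points`, `k_loss`, `k_deg`, `half_life_h`,
#'   `fit_residual`, `status` (one of `ok`, `censored_nonpositive_kdeg`,
#'   `insufficient_data`).
#' @export
fit_turnover <- function(proteins, metadata, model, times_h = c(3, 8, 24),
                         min_ratio_count = 3, min_unique_peptides = 2,
                         use_linear_ratio = FALSE, epsilon = 1e-6) {
  if (!inherits(model, "growth_model")) abort("`model` must be a growth_model.")
  data <- proteins |>
    dplyr::inner_join(metadata[, c("sample_id", "time_h")], by = "sample_id") |>
    dplyr::filter(
      .data$time_h %in% times_h,
      !is.na(.data$ratio_hl),
      .data$ratio_count >= min_ratio_count,
      .data$unique_peptides >= min_unique_peptides
    )
  ids <- unique(proteins$protein_id)
  fits <- data |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      fit = list(if (dplyr::n_distinct(.data$time_h) >= 2)
        fit_loss_rate(.data$time_h, .data$ratio_hl,
                      use_linear_ratio = use_linear_ratio) else NULL),
      .groups = "drop"
    )
  fitted <- fits |>
    dplyr::mutate(
      k_loss = purrr::map_dbl(.data$fit, ~ if (is.null(.x)) NA_real_ else .x$k_loss),
      fit_residual = purrr::map_dbl(.data$fit, ~ if (is.null(.x)) NA_real_ else .x$fit_residual)
    ) |>
    dplyr::select(-"fit")
  out <- tibble::tibble(protein_id = ids) |>
    dplyr::left_join(fitted, by = "protein_id") |>
    dplyr::mutate(
      n_points = dplyr::coalesce(.data$n_points, 0L),
      k_deg = degradation_rate(.data$k_loss, model),
      half_life_h = protein_half_life(.data$k_deg, epsilon = epsilon),
      status = dplyr::case_when(
        is.na(.data$k_loss) ~ "insufficient_data",
        is.na(.data$half_life_h) ~ "censored_nonpositive_kdeg",
        TRUE ~ "ok"
      )
    )
  structure(out,
            class = c("turnover_fit", class(tibble::tibble()))) |>
    set_turnover_attrs(model, times_h, min_ratio_count, min_unique_peptides,
                       use_linear_ratio, epsilon)
}

set_turnover_attrs <- function(x, model, times_h, min_ratio_count,
                               min_unique_peptides, use_linear_ratio, epsilon) {
  attr(x, "growth_model") <- model
  attr(x, "params") <- list(times_h = times_h, min_ratio_count = min_ratio_count,
                            min_unique_peptides = min_unique_peptides,
                            use_linear_ratio = use_linear_ratio, epsilon = epsilon)
  x
}

#' Summarize a set of turnover fits
#'
#' Median and quartiles are computed over status-`ok` fits only; censored
#' proteins (non-positive degradation rate) are counted separately and
#' never imputed into the median.
#'
#' @param fits A `turnover_fit` tibble ([fit_turnover()]).
#' @return One-row tibble: `n_proteins`, `n_ok`, `n_censored`,
#'   `n_insufficient`, `median_h`, `q25_h`, `q75_h`.  With zero `ok` fits
#'   the medians are `NA` and a warning is raised.
#' @export
summarize_half_lives <- function(fits) {
  if (nrow(fits) == 0) abort("No fits to summarize.")
  ok <- fits$half_life_h[fits$status == "ok"]
  if (length(ok) == 0) {
    warn("No uncensored fits; median half-life is undefined.")
  }
  tibble::tibble(
    n_proteins = nrow(fits),
    n_ok = length(ok),
    n_censored = sum(fits$status == "censored_nonpositive_kdeg"),
    n_insufficient = sum(fits$status == "insufficient_data"),
    median_h = if (length(ok)) median(ok) else NA_real_,
    q25_h = if (length(ok)) unname(quantile(ok, 0.25)) else NA_real_,
    q75_h = if (length(ok)) unname(quantile(ok, 0.75)) else NA_real_
  )
}

#' Single-time-point half-life estimate
#'
#' A per-time-point companion to the regression estimate: from one ratio
#' `R` at time `t`, `k_loss = ln(1 + R) / t`, then dilution-corrected as
#' usual.  Noisier than the pooled regression; emitted for comparison
#' across time points.
#'
#' @param ratio H/L ratio(s) (> 0).
#' @param t_h Time point in hours (> 0).
#' @param model [growth_model()].
#' @param epsilon Censoring threshold (see [protein_half_life()]).
#' @return Half-life in hours (`NA` where censored).
#' @export
single_point_half_life <- function(ratio, t_h, model, epsilon = 1e-6) {
  if (any(t_h <= 0)) abort("`t_h` must be positive.")
  if (any(ratio < 0, na.rm = TRUE)) abort("`ratio` must be non-negative.")
  k_loss <- log1p(ratio) / t_h
  protein_half_life(degradation_rate(k_loss, model), epsilon = epsilon)
}

#' @rdname fit_turnover
#' @param x A `turnover_fit`.
#' @param ... Unused.
#' @method tidy turnover_fit
#' @export
tidy.turnover_fit <- function(x, ...) {
  out <- x
  attr(out, "growth_model") <- NULL
  attr(out, "params") <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname fit_turnover
#' @method glance turnover_fit
#' @export
glance.turnover_fit <- function(x, ...) {
  model <- attr(x, "growth_model")
  dplyr::bind_cols(
    summarize_half_lives(x),
    tibble::tibble(t_double_h = model$t_double, k_dil = model$k_dil)
  )
}
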