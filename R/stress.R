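#' Z-normalize H/L ratios within one condition
#'
#' Standardizes the log2 ratios of one condition to mean 0 and sample
#' standard deviation 1.  Working on the log scale keeps the strongly
#' right-skewed ratio distribution symmetric, and the location/scale
#' normalization absorbs condition-wide multiplicative bias (such as the
#' ratio underestimation caused by metabolic labeling of proline and
#' glutamate), making conditions comparable.  `log_scale = FALSE` gives the
#' raw-scale variant for comparison.
#'
#' @param ratios Positive H/L ratios (length >= 3).
#' @param log_scale Standardize `log2(ratio)` (default) or the raw ratio.
#' @return Z-scores, same length and order as `ratios`.
#' @export
z_normalize <- function(ratios, log_scale = TRUE) {
  if (length(ratios) < 3) abort("Need at least 3 ratios to Z-normalize.")
  if (any(is.na(ratios))) abort("Ratios must not be missing.")
  if (log_scale && any(ratios <= 0)) abort("Ratios must be positive on the log scale.")
  x <- if (log_scale) log2(ratios) else ratios
  s <- sd(x)
  if (s == 0) abort("Zero variance: ratios are all equal, Z-scores undefined.")
  (x - mean(x)) / s
}

#' Z-normalize late-pulse ratios per condition
#'
#' Convenience wrapper building the cross-condition comparison table:
#' mean H/L ratio per protein and condition at the chosen time point,
#' then [z_normalize()] within each condition.
#'
#' @param proteins Long protein tibble.
#' @param metadata Sample metadata tibble.
#' @param time_h Time point to compare at (default 24).
#' @param min_ratio_count,min_unique_peptides Confidence filters.
#' @param log_scale Passed to [z_normalize()].
#' @return Tibble: `protein_id`, `condition` (NaCl mM), `source_ratio`, `z`.
#' @export
normalized_ratios <- function(proteins, metadata, time_h = 24,
                              min_ratio_count = 3, min_unique_peptides = 2,
                              log_scale = TRUE) {
  tab <- proteins |>
    dplyr::inner_join(metadata[, c("sample_id", "time_h", "nacl_mM")],
                      by = "sample_id") |>
    dplyr::filter(.data$time_h == !!time_h,
                  !is.na(.data$ratio_hl),
                  .data$ratio_count >= min_ratio_count,
                  .data$unique_peptides >= min_unique_peptides) |>
    dplyr::group_by(protein_id = .data$protein_id, condition = .data$nacl_mM) |>
    dplyr::summarise(source_ratio = mean(.data$ratio_hl), .groups = "drop")
  tab |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(z = z_normalize(.data$source_ratio, log_scale = log_scale)) |>
    dplyr::ungroup()
}

#' Select extreme stress responders shared by all stress conditions
#'
#' For each stress condition the shift relative to the control,
#' `delta = z_condition - z_control`, is computed over the proteins shared
#' by all conditions.  The `up` set is the intersection of the top
#' `floor(fraction * n)` proteins by `delta` in every stress condition;
#' `down` analogously for the lower tail.  Ties are broken
#' lexicographically by `protein_id` so the selection is deterministic.
#'
#' @param ztab Tibble with `protein_id`, `condition`, `z`
#'   ([normalized_ratios()]).
#' @param fraction Tail fraction in (0, 0.5) (default 0.05, the upper and
#'   lower 5 percent).
#' @param control Condition value identifying the control (default the
#'   smallest, typically 0 mM NaCl).
#' @return A `responder_set`: list with character vectors `up` and `down`,
#'   plus `fraction`, `n_shared`, `k_per_condition`.
#' @export
select_responders <- function(ztab, fraction = 0.05, control = NULL) {
  if (fraction <= 0 || fraction >= 0.5) {
    abort("`fraction` must lie strictly between 0 and 0.5.")
  }
  conds <- sort(unique(ztab$condition))
  if (length(conds) < 2) abort("Need a control plus at least one stress condition.")
  if (is.null(control)) control <- conds[1]
  if (!control %in% conds) abort("`control` is not one of the conditions.")
  stress <- setdiff(conds, control)
  wide <- ztab |>
    dplyr::select("protein_id", "condition", "z") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "z") |>
    tidyr::drop_na()
  n <- nrow(wide)
  if (n < 20) abort("Conditions share fewer than 20 proteins.")
  k <- floor(fraction * n)
  if (k == 0) {
    warn("`fraction` too small for the number of shared proteins; empty responder sets.")
    return(structure(list(up = character(), down = character(),
                          fraction = fraction, n_shared = n,
                          k_per_condition = 0L),
                     class = "responder_set"))
  }
  top_set <- function(delta, decreasing) {
    ord <- order(if (decreasing) -delta else delta, wide$protein_id)
    wide$protein_id[ord[seq_len(k)]]
  }
  deltas <- lapply(stress, function(cc) wide[[as.character(cc)]] -
                     wide[[as.character(control)]])
  up <- sort(Reduce(intersect, lapply(deltas, top_set, decreasing = TRUE)))
  down <- sort(Reduce(intersect, lapply(deltas, top_set, decreasing = FALSE)))
  structure(list(up = up, down = down, fraction = fraction,
                 n_shared = n, k_per_condition = k),
            class = "responder_set")
}

#' @export
print.responder_set <- function(x, ...) {
  cat(sprintf("Responder set (tail fraction %.3g, %d shared proteins, %d per tail per condition)\n",
              x$fraction, x$n_shared, x$k_per_condition))
  cat(sprintf("  up   (%d): %s\n", length(x$up),
              paste(head(x$up, 8), collapse = ", ")))
  cat(sprintf("  down (%d): %s\n", length(x$down),
              paste(head(x$down, 8), collapse = ", ")))
  invisible(x)
}

#' @rdname select_responders
#' @param x A `responder_set`.
#' @param ... Unused.
#' @method tidy responder_set
#' @export
tidy.responder_set <- function(x, ...) {
  tibble::tibble(
    protein_id = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' Rank concordance between two conditions
#'
#' Spearman rank correlation (ties mid-ranked) between paired per-protein
#' scores of two conditions; 1 means the regulation ranking is identical.
#'
#' @param z_a,z_b Paired numeric vectors (same proteins, same order,
#'   length >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
rank_concordance <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) abort("Inputs must have the same length.")
  if (length(z_a) < 3) abort("Need at least 3 paired values.")
  cor(z_a, z_b, method = "spearman")
}

#' Correlation between growth and mean labeling ratio
#'
#' Pearson correlation of per-sample mean H/L ratio against cell count; a
#' high value is the experiment-level check that label incorporation
#' tracks biomass increase across conditions and time points.
#'
#' @param mean_ratios Per-sample mean H/L ratios (length >= 3).
#' @param cell_counts Matched per-sample cell counts.
#' @return Pearson correlation.
#' @export
growth_ratio_correlation <- function(mean_ratios, cell_counts) {
  if (length(mean_ratios) != length(cell_counts)) {
    abort("Inputs must have the same length.")
  }
  if (length(mean_ratios) < 3) abort("Need at least 3 paired samples.")
  if (sd(mean_ratios) == 0 || sd(cell_counts) == 0) {
    abort("Zero variance in one of the inputs.")
  }
  cor(mean_ratios, cell_counts)
}

#' Per-sample mean H/L ratio
#'
#' @param proteins Long protein tibble.
#' @param min_ratio_count Confidence filter (default 1).
#' @return Tibble: `sample_id`, `mean_ratio`, `n_proteins`.
#' @export
mean_ratio_by_sample <- function(proteins, min_ratio_count = 1) {
  proteins |>
    dplyr::filter(!is.na(.data$ratio_hl),
                  .data$ratio_count >= min_ratio_count) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio_hl),
                     n_proteins = dplyr::n(), .groups = "drop")
}
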