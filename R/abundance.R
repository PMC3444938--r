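#' Abundance index: summed intensity per dalton
#'
#' A simple intra-sample relative abundance measure: the summed protein
#' intensity divided by the molecular mass, so that large proteins do not
#' look abundant merely because they yield more peptides and signal.  Units
#' are arbitrary (instrument-dependent); only within-sample comparisons
#' and ranks are meaningful.
#'
#' @param intensity Summed protein intensity (>= 0, vectorized).
#' @param molecular_mass Molecular mass in Da (> 0).
#' @return Abundance index values (intensity per Da).
#' @export
abundance_index <- function(intensity, molecular_mass) {
  if (any(molecular_mass <= 0, na.rm = TRUE)) {
    abort("`molecular_mass` must be positive.")
  }
  if (any(intensity < 0, na.rm = TRUE)) abort("`intensity` must be non-negative.")
  intensity / molecular_mass
}

#' Exponentially modified protein abundance index (emPAI)
#'
#' The reference index the abundance index is benchmarked against:
#' `10^(PAI) - 1` where PAI is the ratio of observed to observable
#' peptides for a protein.
#'
#' @param observed_peptides Number of peptides observed (>= 0, vectorized).
#' @param observable_peptides Number of theoretically observable peptides
#'   (> 0).
#' @return emPAI values (0 when nothing was observed).
#' @export
empai <- function(observed_peptides, observable_peptides) {
  if (any(observable_peptides <= 0)) abort("`observable_peptides` must be positive.")
  if (any(observed_peptides < 0)) abort("`observed_peptides` must be non-negative.")
  10^(observed_peptides / observable_peptides) - 1
}

#' Stoichiometry between two proteins from their abundance indices
#'
#' Because the abundance index is intensity per unit mass, the ratio of two
#' indices within one sample estimates the molar stoichiometry of the two
#' proteins (e.g. the near 1:1 ratio of the two RuBisCO subunits).
#'
#' @param ai_a,ai_b Abundance indices (> 0).
#' @return `ai_a / ai_b`.
#' @export
stoichiometry_ratio <- function(ai_a, ai_b) {
  if (any(ai_a <= 0) || any(ai_b <= 0)) {
    abort("Abundance indices must be positive.")
  }
  ai_a / ai_b
}

#' Per-sample abundance records with ranks
#'
#' Computes the abundance index for every protein x sample and ranks
#' proteins within each sample (1 = most abundant).  Ties are broken by
#' `protein_id` so ranks are a deterministic permutation of `1..n`.
#'
#' @param proteins Long protein tibble with `protein_id`, `sample_id`,
#'   `intensity`, `molecular_mass`, `unique_peptides`.
#' @param min_unique_peptides Identification filter (default 0: keep all).
#' @return Tibble: `protein_id`, `sample_id`, `abundance_index`, `rank`.
#' @export
abundance_records <- function(proteins, min_unique_peptides = 0) {
  proteins |>
    dplyr::filter(!is.na(.data$intensity),
                  .data$unique_peptides >= min_unique_peptides) |>
    dplyr::mutate(abundance_index = abundance_index(.data$intensity,
                                                    .data$molecular_mass)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$abundance_index), .data$protein_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "sample_id", "abundance_index", "rank")
}

#' Average abundance of each protein across time points
#'
#' Arithmetic mean and standard deviation of the abundance index across all
#' samples a protein was quantified in (the time-course average reported
#' alongside selected proteins).
#'
#' @param proteins Long protein tibble.
#' @return Tibble: `protein_id`, `mean_ai`, `sd_ai`, `n_samples`.
#' @export
average_abundance <- function(proteins) {
  proteins |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::mutate(ai = abundance_index(.data$intensity, .data$molecular_mass)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(mean_ai = mean(.data$ai),
                     sd_ai = sd(.data$ai),
                     n_samples = dplyr::n(),
                     .groups = "drop")
}

#' Reproducibility of the abundance index on a known dilution series
#'
#' Given abundance records for a defined protein mixture spanning known
#' concentration levels, summarizes how tightly the log10 abundance index
#' clusters within each level and whether level means are ordered with the
#' true concentrations.  This is the calibration check for treating the
#' abundance index as a relative concentration scale.
#'
#' @param records Tibble with `protein_id` and `abundance_index` (e.g. from
#'   [abundance_records()] for one sample).
#' @param truth Tibble with `protein_id` and integer `level` (higher level =
#'   higher true concentration).
#' @return Tibble per level: `level`, `n`, `mean_log10_ai`, `sd_log10_ai`,
#'   `cv` (raw-scale coefficient of variation).  Attributes:
#'   `monotonic` (logical, level means strictly increasing) and
#'   `spearman_level` (Spearman correlation of level vs mean log10 AI).
#'   Levels with fewer than two proteins are dropped with a warning.
#' @export
dilution_series_spread <- function(records, truth) {
  data <- dplyr::inner_join(records, truth, by = "protein_id")
  if (nrow(data) == 0) abort("No overlap between records and truth map.")
  if (any(data$abundance_index <= 0)) abort("Abundance indices must be positive.")
  counts <- dplyr::count(data, .data$level)
  thin <- counts$level[counts$n < 2]
  if (length(thin) > 0) {
    warn(paste0("Dropping level(s) with fewer than 2 proteins: ",
                paste(thin, collapse = ", ")))
    data <- dplyr::filter(data, !.data$level %in% thin)
  }
  out <- data |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_log10_ai = mean(log10(.data$abundance_index)),
      sd_log10_ai = sd(log10(.data$abundance_index)),
      cv = sd(.data$abundance_index) / mean(.data$abundance_index),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$level)
  attr(out, "monotonic") <- all(diff(out$mean_log10_ai) > 0)
  attr(out, "spearman_level") <- cor(out$level, out$mean_log10_ai,
                                     method = "spearman")
  out
}
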