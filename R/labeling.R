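#' Built-in GC-MS fragment mass-isotopomer pairs
#'
#' The declared light/heavy fragment m/z pairs used to follow 13C label
#' from arginine into downstream free metabolites: putrescine (4TMS)
#' 86/87, 100/101, 174/175; proline (2TMS) 142/146; glutamate (3TMS)
#' 84/85, 100/101, 156/157, 246/248; ornithine (3TMS) 174/175.  The mass
#' shift of each pair is the number of heavy carbons the fragment can
#' carry (at most 6, a full arginine backbone).
#'
#' @return Tibble: `metabolite`, `derivative`, `light_mz`, `heavy_mz`,
#'   `mass_shift`.
#' @export
builtin_fragments <- function() {
  out <- tibble::tribble(
    ~metabolite,  ~derivative, ~light_mz, ~heavy_mz,
    "putrescine", "4TMS",       86L,       87L,
    "putrescine", "4TMS",      100L,      101L,
    "putrescine", "4TMS",      174L,      175L,
    "proline",    "2TMS",      142L,      146L,
    "glutamate",  "3TMS",       84L,       85L,
    "glutamate",  "3TMS",      100L,      101L,
    "glutamate",  "3TMS",      156L,      157L,
    "glutamate",  "3TMS",      246L,      248L,
    "ornithine",  "3TMS",      174L,      175L
  )
  out$mass_shift <- out$heavy_mz - out$light_mz
  out
}

#' Normalize a metabolite intensity by internal standard and cell number
#'
#' Raw GC-MS intensities are made comparable across samples by dividing by
#' the recovery of the internal standard (13C sorbitol) and the number of
#' cells extracted.
#'
#' @param raw Raw intensity (>= 0, vectorized).
#' @param internal_standard Internal-standard intensity in the same sample
#'   (> 0).
#' @param cell_count Cells in the extracted aliquot (> 0).
#' @return Normalized intensity (arbitrary units per cell).
#' @export
normalize_metabolite <- function(raw, internal_standard, cell_count) {
  if (any(internal_standard <= 0)) abort("`internal_standard` must be positive.")
  if (any(cell_count <= 0)) abort("`cell_count` must be positive.")
  if (any(raw < 0)) abort("`raw` must be non-negative.")
  raw / (internal_standard * cell_count)
}

#' Log2 fold change of a normalized metabolite level versus control
#'
#' @param norm_treated,norm_control Normalized intensities (> 0,
#'   vectorized).
#' @return `log2(treated / control)`.
#' @export
fold_change_vs_control <- function(norm_treated, norm_control) {
  if (any(norm_treated <= 0) || any(norm_control <= 0)) {
    abort("Normalized intensities must be positive.")
  }
  log2(norm_treated / norm_control)
}

#' Percent 13C label from one fragment pair with control subtraction
#'
#' The label readout of a fragment is the heavy-mass over light-mass
#' intensity ratio; subtracting the same ratio measured in an unlabeled
#' control removes the natural 13C abundance contribution:
#' `100 * (H/L - H_control/L_control)`.  Note the heavy/light convention:
#' a pool whose molecules are 9.09 percent labeled has H/L = 0.1 and reads
#' as 10 percent.  Values can be slightly negative after control
#' subtraction in unlabeled samples.
#'
#' @param heavy_i,light_i Heavy- and light-mass intensities of the sample
#'   (light > 0; vectorized).
#' @param control_heavy_i,control_light_i The same intensities (or their
#'   means) in the unlabeled control.
#' @return Percent label (may be negative near zero).
#' @export
percent_label <- function(heavy_i, light_i, control_heavy_i, control_light_i) {
  if (any(light_i <= 0) || any(control_light_i <= 0)) {
    abort("Light-mass intensities must be positive.")
  }
  if (any(heavy_i < 0) || any(control_heavy_i < 0)) {
    abort("Heavy-mass intensities must be non-negative.")
  }
  100 * (heavy_i / light_i - control_heavy_i / control_light_i)
}

#' Per-fragment percent label against the mean control ratio
#'
#' For every declared fragment pair, computes the heavy/light ratio in
#' each non-control sample and subtracts that fragment's mean ratio over
#' the control samples.
#'
#' @param table Long metabolite tibble ([read_metabolite_table()] or
#'   [gen_isotopomer_dataset()]).
#' @param control_samples Character vector of unlabeled control
#'   `sample_id`s (>= 1) defining the natural-abundance baseline.
#' @param fragments Declared fragment pairs (default
#'   [builtin_fragments()]); every declared pair must be present in
#'   `table` for its metabolite.
#' @return Tibble: `metabolite`, `derivative`, `light_mz`, `heavy_mz`,
#'   `sample_id`, `percent_label`.
#' @export
fragment_label <- function(table, control_samples,
                           fragments = builtin_fragments()) {
  if (length(control_samples) < 1) abort("Need at least one control sample.")
  missing_ctrl <- setdiff(control_samples, table$sample_id)
  if (length(missing_ctrl) > 0) {
    abort(paste0("Control sample(s) not in table: ",
                 paste(missing_ctrl, collapse = ", ")))
  }
  keys <- c("metabolite", "light_mz", "heavy_mz")
  declared <- dplyr::semi_join(fragments, table, by = "metabolite")
  absent <- dplyr::anti_join(declared, dplyr::distinct(table[, keys]), by = keys)
  if (nrow(absent) > 0) {
    abort(sprintf("Missing declared fragment pair %d/%d for metabolite '%s'.",
                  absent$light_mz[1], absent$heavy_mz[1], absent$metabolite[1]))
  }
  data <- dplyr::semi_join(table, declared, by = keys)
  if (any(data$light_intensity <= 0, na.rm = TRUE)) {
    abort("Light-mass intensities must be positive.")
  }
  ctrl <- data |>
    dplyr::filter(.data$sample_id %in% control_samples) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      control_ratio = mean(.data$heavy_intensity / .data$light_intensity),
      .groups = "drop"
    )
  data |>
    dplyr::filter(!.data$sample_id %in% control_samples) |>
    dplyr::inner_join(ctrl, by = keys) |>
    dplyr::mutate(percent_label = 100 * (.data$heavy_intensity / .data$light_intensity -
                                           .data$control_ratio)) |>
    dplyr::select("metabolite", "derivative", "light_mz", "heavy_mz",
                  "sample_id", "percent_label")
}

#' Metabolite-level percent 13C label
#'
#' Aggregates [fragment_label()] to one value per metabolite and sample by
#' an unweighted mean across the metabolite's fragment pairs.  Per-fragment
#' spread is reported alongside; a large spread (default over
#' `spread_flag` percentage points) flags discordant fragments, e.g. a
#' co-eluting contamination on one mass.
#'
#' @inheritParams fragment_label
#' @param spread_flag Flag threshold on the fragment standard deviation in
#'   percentage points (default 5).
#' @return Tibble: `metabolite`, `sample_id`, `percent_label`,
#'   `n_fragments`, `fragment_spread` (`NA` for single-fragment
#'   metabolites), `flagged`.
#' @export
metabolite_label <- function(table, control_samples,
                             fragments = builtin_fragments(),
                             spread_flag = 5) {
  frag <- fragment_label(table, control_samples, fragments = fragments)
  frag |>
    dplyr::group_by(.data$metabolite, .data$sample_id) |>
    dplyr::summarise(
      n_fragments = dplyr::n(),
      fragment_spread = sd(.data$percent_label),
      percent_label = mean(.data$percent_label),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = !is.na(.data$fragment_spread) &
                    .data$fragment_spread > spread_flag) |>
    dplyr::select("metabolite", "sample_id", "percent_label", "n_fragments",
                  "fragment_spread", "flagged")
}
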