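#' Simulation configuration for the pulse-labeling generator
#'
#' Defaults mirror the study conditions: a cohort of 710 proteins with
#' log-normally distributed half-lives (median 45 h, geometric SD 1.8),
#' slow exponential growth with a 63.41 h doubling time, sampling at 0, 1,
#' 3, 8 and 24 h in duplicate cultures, and 15 percent multiplicative
#' noise on the H/L ratios.
#'
#' @param seed Integer seed; the same configuration always produces
#'   identical output.
#' @param n_proteins Number of proteins (default 710).
#' @param median_half_life_h Median true half-life in hours (default 45).
#' @param half_life_geometric_sd Geometric SD of the half-life
#'   distribution (> 1, default 1.8).
#' @param t_double_h Doubling time in hours (default 63.41).
#' @param times_h Sampling times in hours (default `c(0, 1, 3, 8, 24)`).
#' @param ratio_cv Multiplicative CV of ratio noise (default 0.15).
#' @param ratio_count_mean Mean of the shifted-Poisson ratio counts
#'   (`1 + rpois(mean - 1)`, default 5).
#' @param unique_peptides_mean Mean unique peptides (`2 + rpois(mean - 2)`,
#'   default 4).
#' @param intensity_cv Multiplicative CV of intensity noise (default 0.2).
#' @param n_replicates Independent cultures per condition (default 2).
#' @param start_cell_count Cells/mL at pulse start (default 1e6).
#' @param conditions List of conditions, each a list with `nacl_mM`,
#'   `growth_scale` (scales the dilution rate; salt slows growth) and
#'   `synthesis_scale` (global multiplier on emitted ratios, emulating the
#'   condition-wide synthesis slowdown absorbed later by Z-normalization).
#'   Default: the unstressed control only; see [salt_conditions()].
#' @param n_up,n_down Number of planted responder proteins whose ratios
#'   under stress conditions are additionally scaled by `responder_effect`
#'   (up) or its inverse (down).  Default 0.
#' @param responder_effect Multiplier for planted responders (default 4).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, n_proteins = 710, median_half_life_h = 45,
                       half_life_geometric_sd = 1.8, t_double_h = 63.41,
                       times_h = c(0, 1, 3, 8, 24), ratio_cv = 0.15,
                       ratio_count_mean = 5, unique_peptides_mean = 4,
                       intensity_cv = 0.2, n_replicates = 2,
                       start_cell_count = 1e6,
                       conditions = list(control_condition()),
                       n_up = 0, n_down = 0, responder_effect = 4) {
  cfg <- list(seed = as.integer(seed), n_proteins = n_proteins,
              median_half_life_h = median_half_life_h,
              half_life_geometric_sd = half_life_geometric_sd,
              t_double_h = t_double_h, times_h = sort(unique(times_h)),
              ratio_cv = ratio_cv, ratio_count_mean = ratio_count_mean,
              unique_peptides_mean = unique_peptides_mean,
              intensity_cv = intensity_cv, n_replicates = n_replicates,
              start_cell_count = start_cell_count, conditions = conditions,
              n_up = n_up, n_down = n_down, responder_effect = responder_effect)
  if (cfg$n_proteins < 1) abort("`n_proteins` must be positive.")
  if (cfg$median_half_life_h <= 0) abort("`median_half_life_h` must be positive.")
  if (cfg$half_life_geometric_sd <= 1) abort("`half_life_geometric_sd` must exceed 1.")
  if (cfg$t_double_h <= 0) abort("`t_double_h` must be positive.")
  if (any(cfg$times_h < 0)) abort("`times_h` must be non-negative.")
  if (cfg$ratio_cv < 0 || cfg$intensity_cv < 0) abort("CVs must be non-negative.")
  if (cfg$ratio_count_mean < 1) abort("`ratio_count_mean` must be >= 1.")
  if (cfg$n_up + cfg$n_down > cfg$n_proteins) abort("Too many planted responders.")
  for (cc in cfg$conditions) {
    if (is.null(cc$nacl_mM) || is.null(cc$growth_scale) || is.null(cc$synthesis_scale)) {
      abort("Each condition needs nacl_mM, growth_scale and synthesis_scale.")
    }
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
control_condition <- function() {
  list(nacl_mM = 0, growth_scale = 1, synthesis_scale = 1)
}

#' @rdname sim_config
#' @details `salt_conditions()` returns the three-condition salt-stress
#'   design (0, 100, 150 mM NaCl) with mildly reduced growth and a global
#'   synthesis slowdown under salt.
#' @export
salt_conditions <- function() {
  list(
    list(nacl_mM = 0, growth_scale = 1, synthesis_scale = 1),
    list(nacl_mM = 100, growth_scale = 0.85, synthesis_scale = 0.8),
    list(nacl_mM = 150, growth_scale = 0.7, synthesis_scale = 0.65)
  )
}

#' Generate a pulse-labeling protein dataset with known ground truth
#'
#' Per protein a true degradation rate is drawn so that the half-life
#' `ln(2)/k_deg` is log-normal with the configured median and geometric
#' SD.  The noise-free ratio at time `t` under a condition with dilution
#' rate `k_dil_c` is `exp((k_deg + k_dil_c) * t) - 1`; emitted ratios are
#' multiplied by the condition's synthesis scale, any planted responder
#' effect and mean-1 log-normal noise.  At `t = 0` no label is present:
#' the ratio is missing with ratio count 0 (the regression anchors at
#' `(0, 0)` regardless).  Cell counts follow
#' `count(t) = start * 2^(t * growth_scale / t_double)`.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (long tibble as from
#'   [read_protein_groups()]), `metadata` (sample metadata tibble with
#'   cell counts) and `truth` (per protein: `half_life_true_h`,
#'   `k_deg_true`, `responder` in `{"up","down","no"}`).
#' @export
gen_turnover_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  half_life <- exp(rnorm(n, log(config$median_half_life_h),
                         log(config$half_life_geometric_sd)))
  k_deg <- log(2) / half_life
  mass <- runif(n, 1e4, 2e5)
  abundance <- 10^runif(n, 4, 9)
  responder <- rep("no", n)
  if (config$n_up + config$n_down > 0) {
    picked <- sample(n, config$n_up + config$n_down)
    responder[picked[seq_len(config$n_up)]] <- "up"
    if (config$n_down > 0) responder[picked[config$n_up + seq_len(config$n_down)]] <- "down"
  }
  resp_mult <- unname(c(up = config$responder_effect, no = 1,
                        down = 1 / config$responder_effect)[responder])
  k_dil <- log(2) / config$t_double_h
  grid <- expand.grid(cond_i = seq_along(config$conditions),
                      time_h = config$times_h,
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$cond_i, grid$time_h, grid$replicate), ]
  blocks <- purrr::pmap(grid, function(cond_i, time_h, replicate) {
    cc <- config$conditions[[cond_i]]
    sid <- sprintf("c%g_t%g_r%d", cc$nacl_mM, time_h, replicate)
    meta <- tibble::tibble(
      sample_id = sid, time_h = time_h, nacl_mM = cc$nacl_mM,
      replicate = as.integer(replicate),
      cell_count = config$start_cell_count *
        2^(time_h * cc$growth_scale / config$t_double_h)
    )
    is_stress <- cc$nacl_mM > 0
    if (time_h == 0) {
      ratio <- rep(NA_real_, n)
      count <- rep(0L, n)
    } else {
      clean <- expm1((k_deg + k_dil * cc$growth_scale) * time_h)
      mult <- cc$synthesis_scale * (if (is_stress) resp_mult else 1)
      ratio <- clean * mult * rlnorm_unit(n, config$ratio_cv)
      count <- 1L + rpois(n, config$ratio_count_mean - 1)
      ratio[count == 0L] <- NA_real_
    }
    prot <- tibble::tibble(
      protein_id = ids,
      description = NA_character_, mapman_bin = NA_character_,
      molecular_mass = mass, sample_id = sid,
      ratio_hl = ratio, ratio_count = count,
      intensity = abundance * mass * rlnorm_unit(n, config$intensity_cv),
      unique_peptides = 2L + rpois(n, max(config$unique_peptides_mean - 2, 0))
    )
    list(meta = meta, prot = prot)
  })
  list(
    proteins = purrr::map_dfr(blocks, "prot"),
    metadata = purrr::map_dfr(blocks, "meta"),
    truth = tibble::tibble(protein_id = ids, half_life_true_h = half_life,
                           k_deg_true = k_deg, responder = responder)
  )
}

#' Noise-free exponential cell-count series
#'
#' @param t_double_h Doubling time in hours (> 0).
#' @param times_h Sampling times (>= 0).
#' @param start_count Count at time 0 (> 0).
#' @return Tibble: `time_h`, `cell_count = start * 2^(t / t_double)`.
#' @export
gen_cell_counts <- function(t_double_h, times_h, start_count) {
  if (t_double_h <= 0 || start_count <= 0) abort("Inputs must be positive.")
  if (any(times_h < 0)) abort("`times_h` must be non-negative.")
  tibble::tibble(time_h = times_h,
                 cell_count = start_count * 2^(times_h / t_double_h))
}

#' Generate the calibration dilution series of recombinant proteins
#'
#' Emulates a defined mixture of `n_proteins` proteins spread evenly over
#' `n_levels` concentration levels spanning `n_levels - 1` orders of
#' magnitude (default 48 proteins, 6 levels).  True intensity is
#' concentration times molecular mass, so the true abundance index equals
#' the assigned concentration exactly; observed intensities carry mean-1
#' log-normal noise.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of proteins (default 48; must be divisible by
#'   `n_levels`).
#' @param n_levels Number of concentration levels (default 6).
#' @param intensity_cv Multiplicative intensity CV (default 0.1).
#' @return List with `records` (tibble `protein_id`, `sample_id`,
#'   `molecular_mass`, `intensity`, `abundance_index`) and `truth`
#'   (tibble `protein_id`, `level`, `concentration`).
#' @export
gen_mixture_dataset <- function(seed, n_proteins = 48, n_levels = 6,
                                intensity_cv = 0.1) {
  if (n_proteins %% n_levels != 0) {
    abort("`n_proteins` must be divisible by `n_levels`.")
  }
  set.seed(seed)
  per <- n_proteins / n_levels
  level <- rep(seq_len(n_levels), each = per)
  concentration <- 10^(level - 1)
  ids <- sprintf("STD%02d", seq_len(n_proteins))
  mass <- runif(n_proteins, 1e4, 2e5)
  intensity <- concentration * mass * rlnorm_unit(n_proteins, intensity_cv)
  records <- tibble::tibble(
    protein_id = ids, sample_id = "mixture",
    molecular_mass = mass, intensity = intensity,
    abundance_index = abundance_index(intensity, mass)
  )
  list(records = records,
       truth = tibble::tibble(protein_id = ids, level = level,
                              concentration = concentration))
}

#' Generate fragment mass-isotopomer intensities with known label ratio
#'
#' For every declared fragment pair and sample, the light-mass intensity
#' is a noisy base intensity and the heavy-mass intensity is
#' `light * (natural_background + true_label_ratio) * noise`; control
#' samples are generated with a true label ratio of 0, so the control
#' heavy/light ratio estimates the natural 13C background alone.
#'
#' @param seed Integer seed.
#' @param fragments Fragment pairs to simulate (default
#'   [builtin_fragments()]).
#' @param true_label_ratio True heavy/light label ratio above background;
#'   a scalar or a named vector by metabolite (default 0.10).
#' @param nat_background_ratio Natural-abundance heavy/light ratio
#'   (default 0.05).
#' @param cv Multiplicative intensity CV (default 0.05).
#' @param n_replicates Labeled replicates and control replicates
#'   (default 6 each).
#' @param base_intensity Mean light-mass intensity (default 1e6).
#' @return List with `table` (long metabolite tibble), `labeled_samples`,
#'   `control_samples` and `truth` (tibble `metabolite`,
#'   `true_percent_label`).
#' @export
gen_isotopomer_dataset <- function(seed, fragments = builtin_fragments(),
                                   true_label_ratio = 0.10,
                                   nat_background_ratio = 0.05, cv = 0.05,
                                   n_replicates = 6, base_intensity = 1e6) {
  if (any(true_label_ratio < 0) || nat_background_ratio < 0) {
    abort("Label and background ratios must be non-negative.")
  }
  set.seed(seed)
  mets <- unique(fragments$metabolite)
  ratio_for <- function(m) {
    if (length(true_label_ratio) == 1 && is.null(names(true_label_ratio))) {
      true_label_ratio
    } else {
      if (!m %in% names(true_label_ratio)) {
        abort(paste0("No true_label_ratio given for metabolite '", m, "'."))
      }
      unname(true_label_ratio[m])
    }
  }
  labeled <- sprintf("lab_r%d", seq_len(n_replicates))
  controls <- sprintf("ctrl_r%d", seq_len(n_replicates))
  samples <- tibble::tibble(sample_id = c(labeled, controls),
                            labeled = rep(c(TRUE, FALSE), each = n_replicates))
  table <- purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    lab <- ratio_for(fr$metabolite)
    light <- base_intensity * rlnorm_unit(nrow(samples), cv)
    heavy <- light * (nat_background_ratio + ifelse(samples$labeled, lab, 0)) *
      rlnorm_unit(nrow(samples), cv)
    tibble::tibble(
      metabolite = fr$metabolite, derivative = fr$derivative,
      light_mz = fr$light_mz, heavy_mz = fr$heavy_mz,
      sample_id = samples$sample_id,
      light_intensity = light, heavy_intensity = heavy
    )
  })
  list(
    table = table,
    labeled_samples = labeled,
    control_samples = controls,
    truth = tibble::tibble(metabolite = mets,
                           true_percent_label = unname(100 * vapply(mets, ratio_for, 0)))
  )
}
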