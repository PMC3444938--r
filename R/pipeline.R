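#' Assemble a pipeline run configuration
#'
#' Collects input paths and per-stage parameters for [run_pipeline()].
#' Validation is deferred to [validate_config()] so that all problems are
#' reported together.
#'
#' @param metadata_path Sample metadata YAML (required).
#' @param protein_path Protein-group TSV (optional; protein stages are
#'   skipped without it).
#' @param metabolite_path Metabolite fragment TSV (optional; the labeling
#'   stage is skipped without it).
#' @param out_dir Output directory (created if absent).
#' @param times_h Turnover fit time points (default `c(3, 8, 24)`).
#' @param min_ratio_count,min_unique_peptides Confidence filters.
#' @param use_linear_ratio,epsilon Turnover options, see [fit_turnover()].
#' @param stress_time_h Time point for the cross-condition comparison
#'   (default 24).
#' @param fraction Responder tail fraction (default 0.05).
#' @param log_scale_z Z-normalize log2 ratios (default TRUE).
#' @param control_nacl_mM Control condition (default 0).
#' @param label_controls Control `sample_id`s for natural-abundance
#'   subtraction (required when `metabolite_path` is given).
#' @param t_double_h Optional fixed doubling time; when `NULL` (default)
#'   the growth model is fitted from the control cell counts in the
#'   metadata.
#' @return A `run_config` list.
#' @export
run_config <- function(metadata_path, protein_path = NULL,
                       metabolite_path = NULL, out_dir = "silacdyn_out",
                       times_h = c(3, 8, 24), min_ratio_count = 3,
                       min_unique_peptides = 2, use_linear_ratio = FALSE,
                       epsilon = 1e-6, stress_time_h = 24, fraction = 0.05,
                       log_scale_z = TRUE, control_nacl_mM = 0,
                       label_controls = NULL, t_double_h = NULL) {
  structure(
    list(metadata_path = metadata_path, protein_path = protein_path,
         metabolite_path = metabolite_path, out_dir = out_dir,
         times_h = times_h, min_ratio_count = min_ratio_count,
         min_unique_peptides = min_unique_peptides,
         use_linear_ratio = use_linear_ratio, epsilon = epsilon,
         stress_time_h = stress_time_h, fraction = fraction,
         log_scale_z = log_scale_z, control_nacl_mM = control_nacl_mM,
         label_controls = label_controls, t_double_h = t_double_h),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Collects every problem rather than stopping at the first one.
#'
#' @param config A [run_config()].
#' @return Character vector of error messages; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  errors <- character()
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$metadata_path) || !file.exists(config$metadata_path)) {
    add(paste0("metadata_path does not exist: ", config$metadata_path))
  }
  for (p in c("protein_path", "metabolite_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      add(paste0(p, " does not exist: ", config[[p]]))
    }
  }
  if (config$fraction <= 0 || config$fraction >= 0.5) {
    add("fraction must lie strictly between 0 and 0.5")
  }
  if (config$min_ratio_count < 0) add("min_ratio_count must be >= 0")
  if (config$min_unique_peptides < 0) add("min_unique_peptides must be >= 0")
  if (config$epsilon <= 0) add("epsilon must be positive")
  if (length(config$times_h) < 2 || any(config$times_h <= 0)) {
    add("times_h needs at least two positive time points")
  }
  if (config$stress_time_h <= 0) add("stress_time_h must be positive")
  if (!is.null(config$t_double_h) && config$t_double_h <= 0) {
    add("t_double_h must be positive when given")
  }
  if (!is.null(config$metabolite_path) && is.null(config$label_controls)) {
    add("label_controls must be given when metabolite_path is set")
  }
  errors
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full proteome-dynamics pipeline
#'
#' Executes growth -> turnover -> abundance -> stress -> labeling on the
#' configured inputs.  Stages whose inputs are absent are skipped and
#' logged; a failing stage aborts with the stage name while earlier
#' outputs remain on disk.  All outputs are deterministic functions of the
#' inputs (no timestamps inside data files).
#'
#' Outputs written to `out_dir`: `turnover_fits.tsv`,
#' `abundance_records.tsv`, `normalized_ratios.tsv`, `responders.tsv`,
#' `metabolite_label.tsv` (as applicable) and `report.yaml` with the
#' headline numbers (doubling time, expected ratio at 24 h, filter and fit
#' counts, median half-life, responder counts, per-metabolite label).
#'
#' @param config A valid [run_config()].
#' @return The report as a list, invisibly.
#' @export
run_pipeline <- function(config) {
  errors <- validate_config(config)
  if (length(errors) > 0) {
    abort(paste0("Invalid configuration:\n", paste("-", errors, collapse = "\n")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config[setdiff(names(config),
                                             c("metadata_path", "protein_path",
                                               "metabolite_path", "out_dir"))])

  metadata <- run_stage("metadata", read_sample_metadata(config$metadata_path))
  stage_log("metadata", sprintf("%d samples", nrow(metadata)))

  # growth: control-condition cell counts -> doubling time and dilution rate
  model <- run_stage("growth", {
    if (!is.null(config$t_double_h)) {
      growth_model(2^(24 / config$t_double_h), 24)
    } else {
      counts <- metadata |>
        dplyr::filter(.data$nacl_mM == config$control_nacl_mM,
                      !is.na(.data$cell_count)) |>
        dplyr::group_by(.data$time_h) |>
        dplyr::summarise(cell_count = mean(.data$cell_count), .groups = "drop")
      if (nrow(counts) < 2) {
        abort("Need control cell counts at >= 2 time points (or set t_double_h).")
      }
      growth_model(counts = counts)
    }
  })
  stage_log("growth", sprintf("t_double = %.2f h, k_dil = %.5f /h",
                              model$t_double, model$k_dil))
  report$growth <- list(
    growth_factor = model$growth_factor,
    window_h = model$window_h,
    t_double_h = model$t_double,
    t_double_display_h = round(model$t_double),
    k_dil_per_h = model$k_dil,
    expected_ratio_24h = expected_ratio(24, model$t_double)
  )

  proteins <- NULL
  if (!is.null(config$protein_path)) {
    proteins <- run_stage("read_proteins",
                          read_protein_groups(config$protein_path, metadata))
    stage_log("read_proteins", sprintf("%d proteins x %d samples",
                                       dplyr::n_distinct(proteins$protein_id),
                                       dplyr::n_distinct(proteins$sample_id)))
  } else {
    stage_log("read_proteins", "no protein table; protein stages skipped")
  }

  if (!is.null(proteins)) {
    control_samples <- metadata$sample_id[metadata$nacl_mM == config$control_nacl_mM]
    fits <- run_stage("turnover", fit_turnover(
      dplyr::filter(proteins, .data$sample_id %in% control_samples),
      metadata, model, times_h = config$times_h,
      min_ratio_count = config$min_ratio_count,
      min_unique_peptides = config$min_unique_peptides,
      use_linear_ratio = config$use_linear_ratio, epsilon = config$epsilon
    ))
    summary <- summarize_half_lives(fits)
    write_results(tidy(fits), file.path(config$out_dir, "turnover_fits.tsv"))
    stage_log("turnover", sprintf("%d fits ok, median half-life %.1f h",
                                  summary$n_ok, summary$median_h))
    report$turnover <- as.list(summary)

    records <- run_stage("abundance", abundance_records(proteins))
    write_results(records, file.path(config$out_dir, "abundance_records.tsv"))
    stage_log("abundance", sprintf("%d records", nrow(records)))
    report$abundance <- list(n_records = nrow(records))

    n_cond <- dplyr::n_distinct(metadata$nacl_mM)
    if (n_cond >= 2) {
      stress <- run_stage("stress", {
        ztab <- normalized_ratios(proteins, metadata,
                                  time_h = config$stress_time_h,
                                  min_ratio_count = config$min_ratio_count,
                                  min_unique_peptides = config$min_unique_peptides,
                                  log_scale = config$log_scale_z)
        responders <- select_responders(ztab, fraction = config$fraction,
                                        control = config$control_nacl_mM)
        list(ztab = ztab, responders = responders)
      })
      write_results(stress$ztab, file.path(config$out_dir, "normalized_ratios.tsv"))
      if (nrow(tidy(stress$responders)) > 0) {
        write_results(tidy(stress$responders),
                      file.path(config$out_dir, "responders.tsv"))
      }
      stage_log("stress", sprintf("%d up / %d down responders",
                                  length(stress$responders$up),
                                  length(stress$responders$down)))
      report$stress <- list(n_shared = stress$responders$n_shared,
                            n_up = length(stress$responders$up),
                            n_down = length(stress$responders$down),
                            up = stress$responders$up,
                            down = stress$responders$down)
    } else {
      stage_log("stress", "single condition; skipped")
    }
  }

  if (!is.null(config$metabolite_path)) {
    labels <- run_stage("labeling", {
      table <- read_metabolite_table(config$metabolite_path, metadata = NULL)
      metabolite_label(table, config$label_controls)
    })
    write_results(labels, file.path(config$out_dir, "metabolite_label.tsv"))
    stage_log("labeling", sprintf("%d metabolite x sample values", nrow(labels)))
    report$labeling <- labels |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(mean_percent_label = mean(.data$percent_label),
                       .groups = "drop") |>
      (\(d) stats::setNames(as.list(d$mean_percent_label), d$metabolite))()
  } else {
    stage_log("labeling", "no metabolite table; skipped")
  }

  yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  stage_log("report", file.path(config$out_dir, "report.yaml"))
  invisible(report)
}
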