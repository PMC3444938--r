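#' Read per-sample experiment metadata from YAML
#'
#' The metadata file is the single source of truth for the experimental
#' design: one entry per MS sample with the pulse time point, the NaCl
#' concentration of the culture, the biological replicate and (optionally)
#' the cell count at harvest.
#'
#' Expected YAML layout:
#' ```yaml
#' samples:
#'   - sample_id: c0_t24_r1
#'     time_h: 24
#'     nacl_mM: 0
#'     replicate: 1
#'     cell_count: 1.3e6
#' ```
#'
#' @param path Path to the YAML file.
#' @return A tibble with columns `sample_id`, `time_h`, `nacl_mM`,
#'   `replicate`, `cell_count` (NA when not recorded).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("Metadata file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$samples) || length(raw$samples) == 0) {
    abort("Metadata YAML must contain a non-empty `samples` list.")
  }
  meta <- purrr::map_dfr(raw$samples, function(s) {
    for (f in c("sample_id", "time_h", "nacl_mM", "replicate")) {
      if (is.null(s[[f]])) abort(paste0("Metadata sample entry missing field `", f, "`."))
    }
    tibble::tibble(
      sample_id = as.character(s$sample_id),
      time_h = as.numeric(s$time_h),
      nacl_mM = as.numeric(s$nacl_mM),
      replicate = as.integer(s$replicate),
      cell_count = if (is.null(s$cell_count)) NA_real_ else as.numeric(s$cell_count)
    )
  })
  validate_sample_metadata(meta)
}

validate_sample_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("Duplicated sample_id in metadata: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  if (any(meta$time_h < 0)) abort("time_h must be non-negative.")
  if (any(meta$nacl_mM < 0)) abort("nacl_mM must be non-negative.")
  if (any(meta$replicate < 1)) abort("replicate must be a positive integer.")
  if (any(!is.na(meta$cell_count) & meta$cell_count <= 0)) {
    abort("cell_count must be positive when present.")
  }
  meta
}

#' Write experiment metadata to YAML
#'
#' @param meta Tibble as returned by [read_sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_sample_metadata(meta)
  samples <- purrr::pmap(meta, function(sample_id, time_h, nacl_mM, replicate,
                                        cell_count, ...) {
    s <- list(sample_id = sample_id, time_h = time_h, nacl_mM = nacl_mM,
              replicate = as.integer(replicate))
    if (!is.na(cell_count)) s$cell_count <- cell_count
    s
  })
  yaml::write_yaml(list(samples = samples), path)
  invisible(path)
}

# Parse a character column to numeric; "" and "NaN" (any case) are missing.
# Anything else non-numeric is a loud parse error with row and column.
parse_numeric_column <- function(x, col) {
  x_trim <- trimws(x)
  miss <- is.na(x_trim) | x_trim == "" | toupper(x_trim) == "NAN"
  out <- suppressWarnings(as.numeric(x_trim))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Non-numeric value '%s' in column '%s' (data row %d).",
                  x[i], col, i))
  }
  out[miss] <- NA_real_
  out
}

read_strict_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path,
                  col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

#' Read a protein-group quantification table
#'
#' Reads a MaxQuant-style protein-group table restricted to the columns this
#' pipeline uses.  The file is strict TSV with one row per protein group and
#' per-sample column blocks addressed by suffix:
#' `ratio_hl.<sample_id>`, `ratio_count.<sample_id>`,
#' `intensity.<sample_id>`, `unique_peptides.<sample_id>`.
#' Fixed columns: `protein_id`, `molecular_mass` (Da) and optionally
#' `description` and `mapman_bin`.
#'
#' Missing H/L ratios may be encoded as an empty cell or as `NaN`; they are
#' preserved as `NA`, never as 0.  A ratio with `ratio_count` 0 is treated
#' as missing.
#'
#' @param path Path to the TSV file.
#' @param metadata Sample metadata tibble ([read_sample_metadata()]); its
#'   `sample_id` values must match the column suffixes in the file.
#' @return A long tibble, one row per protein x sample:
#'   `protein_id`, `description`, `mapman_bin`, `molecular_mass`,
#'   `sample_id`, `ratio_hl`, `ratio_count`, `intensity`, `unique_peptides`.
#' @export
read_protein_groups <- function(path, metadata) {
  raw <- read_strict_tsv(path)
  for (col in c("protein_id", "molecular_mass")) {
    if (!col %in% names(raw)) {
      abort(paste0("Protein table is missing required column '", col, "'."))
    }
  }
  if (anyDuplicated(raw$protein_id)) {
    abort(paste0("Duplicated protein_id: ",
                 paste(unique(raw$protein_id[duplicated(raw$protein_id)]), collapse = ", ")))
  }
  mass <- parse_numeric_column(raw$molecular_mass, "molecular_mass")
  if (any(is.na(mass) | mass <= 0)) {
    abort("molecular_mass must be present and > 0 for every protein.")
  }
  fixed <- tibble::tibble(
    protein_id = raw$protein_id,
    description = if ("description" %in% names(raw)) raw$description else NA_character_,
    mapman_bin = if ("mapman_bin" %in% names(raw)) raw$mapman_bin else NA_character_,
    molecular_mass = mass
  )
  fields <- c("ratio_hl", "ratio_count", "intensity", "unique_peptides")
  out <- purrr::map_dfr(metadata$sample_id, function(sid) {
    cols <- paste0(fields, ".", sid)
    missing_cols <- setdiff(cols, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("Protein table is missing required column '",
                   missing_cols[1], "' for sample '", sid, "'."))
    }
    block <- fixed
    block$sample_id <- sid
    block$ratio_hl <- parse_numeric_column(raw[[cols[1]]], cols[1])
    block$ratio_count <- as.integer(parse_numeric_column(raw[[cols[2]]], cols[2]))
    block$intensity <- parse_numeric_column(raw[[cols[3]]], cols[3])
    block$unique_peptides <- as.integer(parse_numeric_column(raw[[cols[4]]], cols[4]))
    block
  })
  out$ratio_count[is.na(out$ratio_count)] <- 0L
  out$unique_peptides[is.na(out$unique_peptides)] <- 0L
  # quantification with no supporting peptide ratio is not a measurement
  out$ratio_hl[out$ratio_count == 0L] <- NA_real_
  if (any(out$ratio_hl < 0, na.rm = TRUE)) abort("ratio_hl must be non-negative.")
  out
}

#' Write a long protein-group table back to the wide on-disk layout
#'
#' Inverse of [read_protein_groups()]: pivots the long protein x sample
#' tibble to the per-sample suffix columns and writes strict TSV (missing
#' ratios as empty cells).
#'
#' @param proteins Long tibble as returned by [read_protein_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(proteins, path) {
  wide <- tidyr::pivot_wider(
    proteins,
    id_cols = c("protein_id", "description", "mapman_bin", "molecular_mass"),
    names_from = "sample_id",
    values_from = c("ratio_hl", "ratio_count", "intensity", "unique_peptides"),
    names_sep = "."
  )
  write_results(wide, path)
}

#' Read a metabolite fragment-intensity table
#'
#' Reads a MetMax-style matrix of GC-MS fragment intensities.  Each row is
#' one declared mass-isotopomer fragment pair of a metabolite; per-sample
#' intensities of the light and heavy mass are in suffix columns
#' `light.<sample_id>` / `heavy.<sample_id>`.  Fixed columns: `metabolite`,
#' `derivative`, `light_mz`, `heavy_mz`.
#'
#' Validated invariants: `heavy_mz > light_mz` and a mass shift of at most
#' 6 (a fully labeled arginine backbone carries six heavy carbons).
#'
#' @param path Path to the TSV file.
#' @param metadata Optional sample metadata; when supplied the sample
#'   columns in the file must match `metadata$sample_id` exactly (unknown
#'   or missing sample columns are errors).
#' @return A long tibble: `metabolite`, `derivative`, `light_mz`,
#'   `heavy_mz`, `sample_id`, `light_intensity`, `heavy_intensity`.
#' @export
read_metabolite_table <- function(path, metadata = NULL) {
  raw <- read_strict_tsv(path)
  for (col in c("metabolite", "derivative", "light_mz", "heavy_mz")) {
    if (!col %in% names(raw)) {
      abort(paste0("Metabolite table is missing required column '", col, "'."))
    }
  }
  light_mz <- parse_numeric_column(raw$light_mz, "light_mz")
  heavy_mz <- parse_numeric_column(raw$heavy_mz, "heavy_mz")
  bad <- heavy_mz <= light_mz
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Invalid fragment pair for '%s': heavy m/z %g <= light m/z %g.",
                  raw$metabolite[i], heavy_mz[i], light_mz[i]))
  }
  shift <- heavy_mz - light_mz
  if (any(shift > 6)) {
    i <- which(shift > 6)[1]
    abort(sprintf("Mass shift %g for '%s' exceeds 6 labeled carbons.",
                  shift[i], raw$metabolite[i]))
  }
  light_cols <- grep("^light\\.", names(raw), value = TRUE)
  heavy_cols <- grep("^heavy\\.", names(raw), value = TRUE)
  sids <- sub("^light\\.", "", light_cols)
  if (!setequal(sids, sub("^heavy\\.", "", heavy_cols))) {
    abort("Every sample needs both a light.<sample_id> and a heavy.<sample_id> column.")
  }
  if (length(sids) == 0) abort("Metabolite table has no sample intensity columns.")
  if (!is.null(metadata)) {
    unknown <- setdiff(sids, metadata$sample_id)
    if (length(unknown) > 0) {
      abort(paste0("Unknown sample column(s) in metabolite table: ",
                   paste(unknown, collapse = ", ")))
    }
    absent <- setdiff(metadata$sample_id, sids)
    if (length(absent) > 0) {
      abort(paste0("Metabolite table is missing sample column(s): ",
                   paste(absent, collapse = ", ")))
    }
  }
  fixed <- tibble::tibble(
    metabolite = raw$metabolite,
    derivative = raw$derivative,
    light_mz = as.integer(light_mz),
    heavy_mz = as.integer(heavy_mz)
  )
  purrr::map_dfr(sids, function(sid) {
    block <- fixed
    block$sample_id <- sid
    block$light_intensity <- parse_numeric_column(raw[[paste0("light.", sid)]],
                                                  paste0("light.", sid))
    block$heavy_intensity <- parse_numeric_column(raw[[paste0("heavy.", sid)]],
                                                  paste0("heavy.", sid))
    block
  })
}

#' Write a long metabolite table back to the wide on-disk layout
#'
#' @param table Long tibble as returned by [read_metabolite_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(table, path) {
  wide <- tidyr::pivot_wider(
    table,
    id_cols = c("metabolite", "derivative", "light_mz", "heavy_mz"),
    names_from = "sample_id",
    values_from = c("light_intensity", "heavy_intensity"),
    names_glue = "{sub('_intensity', '', .value)}.{sample_id}"
  )
  write_results(wide, path)
}

#' Write a result table as strict TSV
#'
#' The on-disk dialect is deliberately strict: tab-separated, `.` decimal
#' separator, no quoting, header row, missing values as empty cells, rows
#' in input order.  Fields containing tabs or newlines are rejected rather
#' than quoted, so a written file always round-trips.
#'
#' @param records A non-empty data frame with atomic columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0 || ncol(records) == 0) {
    abort("`records` must be a non-empty data frame.")
  }
  for (col in names(records)) {
    x <- records[[col]]
    if (is.list(x)) abort(paste0("Column '", col, "' is not atomic."))
    if (is.character(x) && any(grepl("[\t\n\r]", x))) {
      abort(paste0("Column '", col, "' contains tab or newline characters; ",
                   "the strict TSV dialect does not quote."))
    }
  }
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a TSV written by this package.
#' @return A tibble with column types guessed from the data; empty cells
#'   become `NA`.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path, na = "", progress = FALSE, show_col_types = FALSE)
}
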