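# Small in-code fixtures shared across test files.

# Two-sample metadata for hand-written protein fixtures.
tiny_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2"),
    time_h = c(8, 24),
    nacl_mM = c(0, 0),
    replicate = c(1L, 1L),
    cell_count = c(NA_real_, NA_real_)
  )
}

# Write a 3-protein, 2-sample protein-group TSV and return its path.
# P2 has an empty ratio cell in s1; P3 uses the MaxQuant "NaN" encoding.
write_tiny_protein_tsv <- function(path = tempfile(fileext = ".tsv")) {
  header <- paste(c("protein_id", "description", "mapman_bin", "molecular_mass",
                    "ratio_hl.s1", "ratio_count.s1", "intensity.s1", "unique_peptides.s1",
                    "ratio_hl.s2", "ratio_count.s2", "intensity.s2", "unique_peptides.s2"),
                  collapse = "\t")
  rows <- c(
    paste(c("P1", "histone", "27", "21000", "0.5", "4", "1e8", "3",
            "1.2", "5", "2e8", "3"), collapse = "\t"),
    paste(c("P2", "rbcL", "1.3.1", "52000", "", "0", "3e9", "8",
            "0.7", "12", "4e9", "8"), collapse = "\t"),
    paste(c("P3", "psbA", "1.1.1.2", "38000", "NaN", "0", "5e8", "2",
            "4.3", "3", "6e8", "2"), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}

# Write a proline 142/146 fragment TSV for two samples.
write_tiny_metabolite_tsv <- function(path = tempfile(fileext = ".tsv"),
                                      heavy_mz = 146) {
  header <- paste(c("metabolite", "derivative", "light_mz", "heavy_mz",
                    "light.s1", "heavy.s1", "light.s2", "heavy.s2"),
                  collapse = "\t")
  row <- paste(c("proline", "2TMS", "142", heavy_mz,
                 "1e6", "5e4", "2e6", "3e5"), collapse = "\t")
  writeLines(c(header, row), path)
  path
}

# Noise-free ratio time course for a protein with the given degradation
# rate, under the standard 63.41 h doubling time.
clean_ratios <- function(k_deg, times_h = c(3, 8, 24), t_double = 63.41) {
  expm1((k_deg + log(2) / t_double) * times_h)
}

# Brute-force 1-D grid minimizer of the through-origin objective
# sum((y - k t)^2), evaluated on an explicit grid.  Independent oracle for
# the closed-form least-squares slope.
grid_k_loss <- function(times_h, ratios, lo = 0, hi = 1, step = 1e-6) {
  y <- log1p(ratios)
  ks <- seq(lo, hi, by = step)
  obj <- sum(y^2) - 2 * ks * sum(times_h * y) + ks^2 * sum(times_h^2)
  ks[which.min(obj)]
}
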