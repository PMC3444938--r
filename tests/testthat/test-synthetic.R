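test_that("identical configurations generate byte-identical output", {
  cfg <- sim_config(seed = 61, n_proteins = 30, conditions = salt_conditions())
  a <- gen_turnover_dataset(cfg)
  b <- gen_turnover_dataset(cfg)
  fa <- tempfile(); fb <- tempfile()
  write_protein_groups(a$proteins, fa)
  write_protein_groups(b$proteins, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
})

test_that("noise-free ratios obey the kinetic law exactly", {
  cfg <- sim_config(seed = 62, n_proteins = 20, ratio_cv = 0,
                    times_h = c(0, 3, 8, 24))
  d <- gen_turnover_dataset(cfg)
  obs <- d$proteins |>
    dplyr::inner_join(d$metadata[, c("sample_id", "time_h")], by = "sample_id") |>
    dplyr::filter(time_h > 0)
  # ln(1+R)/t is constant over time for every protein
  rates <- obs |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(spread = diff(range(log1p(ratio_hl) / time_h)))
  expect_true(all(rates$spread < 1e-12))
  # and equals k_deg + k_dil from the truth table
  joined <- obs |>
    dplyr::filter(time_h == 24) |>
    dplyr::distinct(protein_id, ratio_hl) |>
    dplyr::inner_join(d$truth, by = "protein_id")
  k_dil <- log(2) / cfg$t_double_h
  expect_equal(log1p(joined$ratio_hl) / 24, joined$k_deg_true + k_dil,
               tolerance = 1e-12)
})

test_that("the median-half-life protein hits the closed-form 24 h ratio", {
  k_dil <- log(2) / 63.41
  k_deg_median <- log(2) / 45
  expected_r24 <- expm1((k_deg_median + k_dil) * 24)
  cfg <- sim_config(seed = 63, n_proteins = 1, ratio_cv = 0,
                    half_life_geometric_sd = 1.0000001,
                    times_h = c(0, 24), n_replicates = 1)
  d <- gen_turnover_dataset(cfg)
  r24 <- d$proteins$ratio_hl[!is.na(d$proteins$ratio_hl)]
  expect_equal(r24, expected_r24, tolerance = 1e-4)
  # a protein with zero degradation would sit at the expected ratio 0.300
  expect_equal(expm1(k_dil * 24), 0.300, tolerance = 1e-3)
})

test_that("half-life draws have the configured median and geometric SD", {
  cfg <- sim_config(seed = 64, n_proteins = 5000)
  d <- gen_turnover_dataset(cfg)
  expect_equal(median(d$truth$half_life_true_h), 45, tolerance = 0.05)
  expect_equal(exp(sd(log(d$truth$half_life_true_h))), 1.8, tolerance = 0.05)
})

test_that("cell counts follow start * 2^(t/Td)", {
  counts <- gen_cell_counts(63.41, c(0, 24), 1e6)
  expect_equal(counts$cell_count[1], 1e6)
  expect_equal(counts$cell_count[2], 1.3e6, tolerance = 1e-4)
  expect_equal(gen_cell_counts(63.41, 63.41, 1e6)$cell_count, 2e6)
  expect_error(gen_cell_counts(-1, c(0, 24), 1e6), "positive")
})

test_that("the mixture spans six orders with the delta-method spread", {
  clean <- gen_mixture_dataset(seed = 65, intensity_cv = 0)
  expect_equal(clean$records$abundance_index, clean$truth$concentration)
  spread0 <- dilution_series_spread(clean$records, clean$truth)
  expect_equal(spread0$mean_log10_ai, 0:5, tolerance = 1e-12)

  # cv = 0.1 -> sd of log10 AI approx log10(e) * 0.1 = 0.0434 per level
  sds <- vapply(1:20, function(s) {
    mix <- gen_mixture_dataset(seed = 900 + s, intensity_cv = 0.1)
    mean(dilution_series_spread(mix$records, mix$truth)$sd_log10_ai)
  }, 0)
  expect_equal(mean(sds), log10(exp(1)) * 0.1, tolerance = 0.5)
  expect_error(gen_mixture_dataset(seed = 1, n_proteins = 49), "divisible")
})

test_that("isotopomer generation inverts exactly without noise", {
  iso <- gen_isotopomer_dataset(seed = 66, cv = 0,
                                true_label_ratio = 0.10,
                                nat_background_ratio = 0.05)
  met <- metabolite_label(iso$table, iso$control_samples)
  expect_equal(met$percent_label, rep(10, nrow(met)), tolerance = 1e-12)
})

test_that("per-metabolite label ratios can differ", {
  iso <- gen_isotopomer_dataset(seed = 67, cv = 0,
    true_label_ratio = c(proline = 0.10, glutamate = 0.03,
                         putrescine = 0.01, ornithine = 0.02))
  met <- metabolite_label(iso$table, iso$control_samples)
  means <- met |>
    dplyr::group_by(metabolite) |>
    dplyr::summarise(m = mean(percent_label))
  expect_equal(means$m[means$metabolite == "proline"], 10, tolerance = 1e-12)
  expect_equal(means$m[means$metabolite == "glutamate"], 3, tolerance = 1e-12)
  expect_equal(iso$truth$true_percent_label[iso$truth$metabolite == "ornithine"], 2)
})

test_that("planted responders scale salt ratios by the configured effect", {
  cfg <- sim_config(seed = 68, n_proteins = 60, ratio_cv = 0,
                    conditions = salt_conditions(), n_up = 4, n_down = 4,
                    responder_effect = 4, times_h = c(0, 24), n_replicates = 1)
  d <- gen_turnover_dataset(cfg)
  obs <- d$proteins |>
    dplyr::inner_join(d$metadata[, c("sample_id", "time_h", "nacl_mM")],
                      by = "sample_id") |>
    dplyr::filter(time_h == 24) |>
    dplyr::inner_join(d$truth, by = "protein_id")
  k_dil <- log(2) / cfg$t_double_h
  at100 <- obs[obs$nacl_mM == 100, ]
  # noise-free ratio at salt = kinetic part x synthesis scale x responder effect
  unplanted <- expm1((at100$k_deg_true + 0.85 * k_dil) * 24) * 0.8
  effect <- c(up = 4, no = 1, down = 0.25)[at100$responder]
  expect_equal(at100$ratio_hl, unplanted * unname(effect), tolerance = 1e-12)
  expect_equal(sum(d$truth$responder == "up"), 4)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(seed = 1, half_life_geometric_sd = 1), "exceed 1")
  expect_error(sim_config(seed = 1, median_half_life_h = -2), "positive")
  expect_error(sim_config(seed = 1, n_up = 500, n_down = 400), "Too many")
  expect_error(sim_config(seed = 1, conditions = list(list(nacl_mM = 0))),
               "growth_scale")
})
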