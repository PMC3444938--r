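test_that("built-in fragment pairs match the declared mass isotopomers", {
  fr <- builtin_fragments()
  pro <- fr[fr$metabolite == "proline", ]
  expect_equal(nrow(pro), 1)
  expect_equal(c(pro$light_mz, pro$heavy_mz, pro$mass_shift), c(142L, 146L, 4L))
  glu <- fr[fr$metabolite == "glutamate", ]
  expect_equal(nrow(glu), 4)
  expect_equal(glu$light_mz, c(84L, 100L, 156L, 246L))
  expect_equal(nrow(fr[fr$metabolite == "putrescine", ]), 3)
  expect_equal(nrow(fr[fr$metabolite == "ornithine", ]), 1)
  expect_true(all(fr$mass_shift >= 1 & fr$mass_shift <= 6))
})

test_that("internal-standard and cell-number normalization is a plain quotient", {
  expect_equal(normalize_metabolite(1e6, 1e5, 1e6), 1e-5)
  expect_equal(normalize_metabolite(1e6, 2e5, 1e6),
               normalize_metabolite(1e6, 1e5, 1e6) / 2)
  # equal biology, different internal-standard recovery
  raw_a <- 3e6; raw_b <- 3e6 * 1.4
  expect_equal(normalize_metabolite(raw_a, 1e5, 2e6),
               normalize_metabolite(raw_b, 1.4e5, 2e6))
  expect_error(normalize_metabolite(1e6, 0, 1e6), "positive")
})

test_that("fold changes are log2 and antisymmetric", {
  expect_equal(fold_change_vs_control(5, 5), 0)
  expect_equal(fold_change_vs_control(4, 1), 2)
  set.seed(51)
  a <- runif(20, 0.1, 10); b <- runif(20, 0.1, 10)
  expect_equal(fold_change_vs_control(a, b), -fold_change_vs_control(b, a))
  expect_error(fold_change_vs_control(0, 1), "positive")
})

test_that("percent label subtracts the control heavy/light ratio", {
  L <- 2.7e6
  expect_equal(percent_label(0.211 * L, L, 0.111 * L, L), 10.0)
  expect_equal(percent_label(0.05 * L, L, 0.05 * L, L), 0)
  # invariant to scaling both masses by the same factor (ion counts)
  expect_equal(percent_label(0.2 * L * 3, L * 3, 0.1 * L, L),
               percent_label(0.2 * L, L, 0.1 * L, L))
  expect_error(percent_label(1, 0, 1, 1), "positive")
})

test_that("single-fragment metabolites equal their fragment value", {
  iso <- gen_isotopomer_dataset(seed = 52,
    fragments = builtin_fragments()[builtin_fragments()$metabolite == "proline", ],
    true_label_ratio = 0.10, cv = 0.05)
  frag <- fragment_label(iso$table, iso$control_samples)
  met <- metabolite_label(iso$table, iso$control_samples)
  joined <- dplyr::inner_join(met, frag, by = c("metabolite", "sample_id"),
                              suffix = c("_met", "_frag"))
  expect_equal(joined$percent_label_met, joined$percent_label_frag)
  expect_true(all(met$n_fragments == 1))
  expect_true(all(is.na(met$fragment_spread)))
})

test_that("equal-truth fragments agree and discordant ones are flagged", {
  glu <- builtin_fragments()[builtin_fragments()$metabolite == "glutamate", ]
  iso <- gen_isotopomer_dataset(seed = 53, fragments = glu,
                                true_label_ratio = 0.10, cv = 0.02)
  met <- metabolite_label(iso$table, iso$control_samples)
  frag <- fragment_label(iso$table, iso$control_samples)
  per_frag <- dplyr::group_by(frag, light_mz) |>
    dplyr::summarise(m = mean(percent_label))
  expect_true(all(abs(per_frag$m - mean(met$percent_label)) < 1))
  expect_false(any(met$flagged))

  # contaminate one fragment's heavy mass in the labeled samples
  poisoned <- iso$table
  hit <- poisoned$light_mz == 84 & grepl("^lab", poisoned$sample_id)
  poisoned$heavy_intensity[hit] <- poisoned$heavy_intensity[hit] * 3
  met_bad <- metabolite_label(poisoned, iso$control_samples)
  expect_true(all(met_bad$flagged))
})

test_that("missing declared fragments and controls are loud errors", {
  iso <- gen_isotopomer_dataset(seed = 54,
    fragments = builtin_fragments()[builtin_fragments()$metabolite == "glutamate", ])
  dropped <- iso$table[iso$table$light_mz != 156, ]
  expect_error(fragment_label(dropped, iso$control_samples), "156/157.*glutamate")
  expect_error(fragment_label(iso$table, "no_such_sample"), "no_such_sample")
  expect_error(fragment_label(iso$table, character()), "control")
})

test_that("control samples against their own mean average to zero label", {
  iso <- gen_isotopomer_dataset(seed = 55,
    fragments = builtin_fragments()[builtin_fragments()$metabolite == "proline", ],
    true_label_ratio = 0.10, cv = 0.05, n_replicates = 6)
  # score the controls themselves against the control mean: exact zero mean
  frag <- fragment_label(iso$table[grepl("^ctrl", iso$table$sample_id), ],
                         control_samples = iso$control_samples[1])
  expect_equal(nrow(frag), 5)
  frag_all <- fragment_label(
    dplyr::mutate(iso$table[grepl("^ctrl", iso$table$sample_id), ],
                  sample_id = sub("ctrl", "probe", sample_id)) |>
      dplyr::bind_rows(iso$table[grepl("^ctrl", iso$table$sample_id), ]),
    control_samples = iso$control_samples)
  expect_equal(mean(frag_all$percent_label), 0, tolerance = 1e-12)
})

test_that("label recovery is unbiased across the tested range", {
  for (true_ratio in c(0.01, 0.03, 0.10, 0.30)) {
    iso <- gen_isotopomer_dataset(seed = 56,
      fragments = builtin_fragments()[builtin_fragments()$metabolite == "proline", ],
      true_label_ratio = true_ratio, nat_background_ratio = 0.05,
      cv = 0.05, n_replicates = 100)
    met <- metabolite_label(iso$table, iso$control_samples)
    expect_equal(mean(met$percent_label), 100 * true_ratio,
                 tolerance = 0.10)  # within 10% relative
  }
})
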