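model_63 <- growth_model(1.3, 24)

test_that("quantification-confidence filters keep exactly the supported proteins", {
  prot <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:10),
    description = NA_character_, mapman_bin = NA_character_,
    molecular_mass = 5e4, sample_id = "s1",
    ratio_hl = c(1.1, NA, 0.9, 1.4, NA, 0.7, 2.2, NA, NA, NA),
    ratio_count = c(3L, 0L, 4L, 5L, 2L, 7L, 2L, 0L, 0L, 0L),
    intensity = 1e8,
    unique_peptides = c(2L, 5L, 3L, 2L, 4L, 6L, 9L, 1L, 2L, 3L)
  )
  kept <- filter_quantified(prot, "s1")
  expect_equal(kept$protein_id, c("P01", "P03", "P04", "P06"))
  expect_equal(filter_quantified(prot, "s1", 0, 0), prot)
  none <- dplyr::mutate(prot, ratio_hl = NA_real_)
  expect_equal(nrow(filter_quantified(none, "s1")), 0)
  expect_error(filter_quantified(prot, "nope"), "Unknown sample")
})

test_that("loss-rate regression inverts the exponential model exactly", {
  times <- c(3, 8, 24)
  fit <- fit_loss_rate(times, expm1(0.0264 * times))
  expect_equal(fit$k_loss, 0.0264, tolerance = 1e-12)
  expect_equal(fit$fit_residual, 0, tolerance = 1e-20)

  # a zero-degradation protein recovers exactly the dilution rate
  fit0 <- fit_loss_rate(times, expected_ratio(times, model_63$t_double))
  expect_equal(fit0$k_loss, model_63$k_dil, tolerance = 1e-12)

  expect_error(fit_loss_rate(c(0, 0), c(0, 0)), "zero")
  expect_error(fit_loss_rate(times, c(1, -0.1, 2)), "non-negative")
  expect_error(fit_loss_rate(c(3, 3), c(1, 1.1)), "distinct")
})

test_that("closed-form slope equals the brute-force grid minimizer", {
  set.seed(11)
  for (i in 1:10) {
    k <- runif(1, 0.005, 0.08)
    times <- c(3, 8, 24)
    ratios <- expm1(k * times) * exp(rnorm(3, 0, 0.15))
    fit <- fit_loss_rate(times, ratios)
    expect_lt(abs(fit$k_loss - grid_k_loss(times, ratios)), 2e-6)
  }
})

test_that("raising any ratio strictly raises the fitted loss rate", {
  set.seed(12)
  times <- c(3, 8, 24)
  ratios <- expm1(0.03 * times) * exp(rnorm(3, 0, 0.1))
  k0 <- fit_loss_rate(times, ratios)$k_loss
  for (i in seq_along(ratios)) {
    up <- ratios
    up[i] <- up[i] * 1.05
    expect_gt(fit_loss_rate(times, up)$k_loss, k0)
  }
})

test_that("degradation rate and half-life follow the dilution correction", {
  # k_dil = ln(2)/Td = ln(1.3)/24 under the fitted growth factor
  expect_equal(degradation_rate(0.0264, model_63), 0.0264 - log(1.3) / 24,
               tolerance = 1e-12)
  expect_equal(degradation_rate(model_63$k_dil, model_63), 0)
  expect_equal(degradation_rate(0.005, model_63), 0.005 - model_63$k_dil)

  expect_equal(protein_half_life(log(2) / 45), 45)
  expect_true(is.na(protein_half_life(0)))
  expect_true(is.na(protein_half_life(-0.01)))
  # chained example: k_loss 0.0264 under 63.41 h doubling -> ~44.8 h
  expect_equal(protein_half_life(degradation_rate(0.0264, model_63)),
               44.8, tolerance = 1e-2)
})

test_that("noise-free time courses round-trip through the full fit", {
  for (k_deg in seq(0.001, 0.1, length.out = 21)) {
    fit <- fit_loss_rate(c(3, 8, 24), clean_ratios(k_deg))
    k_hat <- degradation_rate(fit$k_loss, growth_model(2^(24 / 63.41), 24))
    expect_equal(k_hat, k_deg, tolerance = 1e-9 * k_deg)
  }
})

test_that("proteins synthesized below the dilution rate are censored", {
  td <- model_63$t_double
  # noise-free ratios below the zero-degradation expectation at every point
  low <- 0.8 * expected_ratio(c(3, 8, 24), td)
  k_deg <- degradation_rate(fit_loss_rate(c(3, 8, 24), low)$k_loss, model_63)
  expect_lte(k_deg, 0)
  expect_true(is.na(protein_half_life(k_deg)))
})

test_that("the pipeline fit recovers every ground-truth rate without noise", {
  cfg <- sim_config(seed = 5, n_proteins = 40, ratio_cv = 0, intensity_cv = 0,
                    times_h = c(0, 3, 8, 24))
  d <- gen_turnover_dataset(cfg)
  model <- growth_model(counts = gen_cell_counts(cfg$t_double_h, c(0, 24), 1e6))
  fits <- fit_turnover(d$proteins, d$metadata, model, min_ratio_count = 0,
                       min_unique_peptides = 0)
  joined <- dplyr::inner_join(tidy(fits), d$truth, by = "protein_id")
  expect_true(all(abs(joined$k_deg - joined$k_deg_true) <=
                    1e-9 * joined$k_deg_true))
})

test_that("summaries use uncensored fits only and median matches", {
  fits <- structure(
    tibble::tibble(
      protein_id = c("a", "b", "c", "d"),
      n_points = 6L, k_loss = 0.02, fit_residual = 0,
      k_deg = c(log(2) / 30, log(2) / 45, log(2) / 60, -0.001),
      half_life_h = c(30, 45, 60, NA),
      status = c("ok", "ok", "ok", "censored_nonpositive_kdeg")
    ),
    class = c("turnover_fit", class(tibble::tibble()))
  )
  s <- summarize_half_lives(fits)
  expect_equal(s$median_h, 45)
  expect_equal(s$n_ok, 3)
  expect_equal(s$n_censored, 1)

  one <- fits[2, ]
  expect_equal(summarize_half_lives(one)$median_h, 45)

  all_cens <- fits[4, ]
  expect_warning(s2 <- summarize_half_lives(all_cens), "undefined")
  expect_true(is.na(s2$median_h))
})

test_that("single-point estimates agree with the regression on clean data", {
  k_deg <- 0.02
  r24 <- clean_ratios(k_deg, 24)
  expect_equal(single_point_half_life(r24, 24, growth_model(2^(24 / 63.41), 24)),
               log(2) / k_deg, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit table and headline summary", {
  cfg <- sim_config(seed = 6, n_proteins = 50, times_h = c(0, 3, 8, 24))
  d <- gen_turnover_dataset(cfg)
  fits <- fit_turnover(d$proteins, d$metadata, model_63)
  td <- tidy(fits)
  expect_false(inherits(td, "turnover_fit"))
  expect_named(td, c("protein_id", "n_points", "k_loss", "fit_residual",
                     "k_deg", "half_life_h", "status"))
  g <- glance(fits)
  expect_equal(g$n_proteins, 50)
  expect_equal(g$t_double_h, model_63$t_double)
})
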