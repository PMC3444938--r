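# silacdyn

Proteome dynamics from pulsed-SILAC time courses, with growth-dilution
correction, plus ¹³C label tracing into free metabolites — built for
slow-growing photosynthetic cells such as *Chlamydomonas reinhardtii*
fed ¹³C₆ arginine, and for anyone who needs protein half-lives, relative
abundance and cross-condition synthesis responses out of MaxQuant-style
protein-group tables and MetMax-style GC-MS fragment matrices.

## What it computes

After a heavy-arginine pulse at $t = 0$, a protein's heavy/light ratio
follows $R(t) = e^{(k_{deg} + k_{dil})t} - 1$ under exponential growth
($k_{dil} = \ln 2 / T_{double}$) and exponential decay of the
pre-existing light pool. The package:

* fits $k_{loss}$ per protein by least squares through the origin on
  $\ln(1 + R)$ vs $t$ (anchored at the 0 h point), subtracts growth
  dilution and reports half-lives $T_{1/2} = \ln 2 / k_{deg}$ with
  explicit censoring of non-positive degradation rates;
* derives the growth model from cell counts (a 1.3-fold increase over
  24 h ⇒ $T_{double} = 63$ h, expected zero-degradation ratio 0.30 at
  24 h);
* ranks relative abundance by the abundance index (summed intensity /
  molecular mass), with emPAI and stoichiometry helpers and a
  dilution-series reproducibility check;
* compares synthesis across salt conditions via per-condition
  Z-normalized log2 ratios, selecting the shared upper/lower 5 %
  responders and measuring rank concordance;
* quantifies percent ¹³C label in metabolites from declared GC-MS
  fragment pairs (proline 142/146, glutamate 84/85 … 246/248, …) with
  natural-abundance subtraction from unlabeled controls;
* generates seeded synthetic datasets with ground truth for every stage
  (`gen_turnover_dataset()`, `gen_mixture_dataset()`,
  `gen_isotopomer_dataset()`), so the whole pipeline is testable without
  raw MS data.

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(silacdyn)
library(dplyr)

# a study-scale synthetic cohort: 710 proteins, duplicate cultures,
# sampling at 0/3/8/24 h, 15% ratio noise, true median half-life 45 h
cfg  <- sim_config(seed = 1, n_proteins = 710, times_h = c(0, 3, 8, 24))
d    <- gen_turnover_dataset(cfg)

model <- growth_model(counts = unique(d$metadata[, c("time_h", "cell_count")]))
tidy(model)
#> # A tibble: 1 × 5
#>   growth_factor window_h t_double_h  k_dil expected_ratio_24h
#>           <dbl>    <dbl>      <dbl>  <dbl>              <dbl>
#> 1           1.3       24       63.4 0.0109              0.300

fits <- fit_turnover(d$proteins, d$metadata, model)
glance(fits)
#> # A tibble: 1 × 9
#>   n_proteins  n_ok n_censored n_insufficient median_h q25_h q75_h t_double_h  k_dil
#>        <int> <int>      <int>          <int>    <dbl> <dbl> <dbl>      <dbl>  <dbl>
#> 1        710   709          1              0     43.7  30.8  69.0       63.4 0.0109
```

The growth model recovers the 63 h doubling time and the 0.30
zero-degradation ratio from the cell counts alone; the turnover fit
returns a 43.7 h median half-life for this cohort, within sampling error
of the 45 h truth, with one protein censored because its estimated
degradation rate fell below zero. `autoplot(fits)` draws the half-life
distribution; `summarize_half_lives(fits)` gives the same summary as
`glance()` without the growth columns.

Label tracing works the same way:

```r
iso <- gen_isotopomer_dataset(seed = 1,
  fragments = builtin_fragments() |> filter(metabolite == "proline"),
  true_label_ratio = 0.10, nat_background_ratio = 0.05,
  cv = 0.05, n_replicates = 6)
metabolite_label(iso$table, iso$control_samples) |>
  summarise(mean_percent = mean(percent_label))
#> # A tibble: 1 × 1
#>   mean_percent
#>          <dbl>
#> 1         9.63
```

For real data, start from `read_sample_metadata()`,
`read_protein_groups()` and `read_metabolite_table()`, or run everything
at once with `run_config()` + `run_pipeline()`, which writes per-stage
TSVs and a `report.yaml` of headline numbers.

## Documentation

The methods vignette (`vignettes/proteome-dynamics.Rmd`) describes the
kinetic model and its assumptions, the normalization and censoring
choices, what the synthetic generators do and do not emulate, and known
limitations.
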