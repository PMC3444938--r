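---
title: "Growth-corrected protein turnover and 13C label incorporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-corrected protein turnover and 13C label incorporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacdyn)
library(dplyr)
```

## The measurement model

In a pulsed-SILAC experiment a heavy amino acid (here ¹³C₆ arginine, fed to
an arginine-auxotrophic *Chlamydomonas reinhardtii* strain) is added at
time 0.  From that moment every newly synthesized protein molecule carries
heavy arginine, so for each protein the heavy/light intensity ratio
$R(t) = H/L$ reported by the search engine separates *de novo* synthesis
(heavy) from the pre-existing pool (light).

Three assumptions give the kinetic model used throughout this package:

1. **Exponential growth.** Biomass follows $P(t) = P_0\,2^{t/T_{double}}$.
   The cultures are deliberately slow-growing; a 1.3-fold increase in cell
   number over the 24 h pulse gives $T_{double} = 24/\log_2 1.3 = 63.4$ h
   and a dilution rate $k_{dil} = \ln 2 / T_{double} \approx 0.011\,h^{-1}$.
2. **Exponential decay of the light pool.** Pre-existing protein is lost
   at a rate $k_{loss} = k_{deg} + k_{dil}$: true proteolysis plus
   dilution by growth.
3. **Complete label incorporation.** New protein is fully heavy, so
   $R(t) = e^{k_{loss} t} - 1$.

A protein that is not degraded at all ($k_{deg} = 0$) is still synthesized
to keep pace with growth and reaches the *expected ratio*
$2^{t/T_{double}} - 1 = 0.30$ at 24 h.  Observed ratios above 0.3 indicate
turnover; ratios below it indicate synthesis slower than biomass increase.

## Fitting half-lives

Because $\ln(1 + R)$ is exactly linear in $t$ under the model, the loss
rate is estimated by least squares through the origin on
$y_i = \ln(1 + R_i)$:

$$\hat k_{loss} = \frac{\sum_i t_i y_i}{\sum_i t_i^2},$$

with the pulse start $(0, 0)$ as an implicit anchor (it contributes
nothing to either sum).  This is the "simplified linear regression"
through zero, made exact for large ratios by the log transform; a
raw-ratio variant (`use_linear_ratio = TRUE`) reproduces the small-ratio
linearization for comparison.  The default fit uses the 3, 8 and 24 h
points; the 1 h point is excluded by default because intracellular
arginine pools are still equilibrating shortly after the medium swap, and
replicate cultures are pooled into one regression per protein.

The degradation rate is $\hat k_{deg} = \hat k_{loss} - k_{dil}$ and the
half-life $T_{1/2} = \ln 2 / \hat k_{deg}$.  Noise can push $\hat k_{deg}$
to zero or below; such proteins are *censored*
(`censored_nonpositive_kdeg`) rather than being assigned huge or negative
half-lives, and the cohort median is computed over uncensored fits only.
The censoring threshold `epsilon = 1e-6` /h caps reportable half-lives
near $7\times10^5$ h; it is deliberately far below any biologically
interpretable rate so that it only removes sign flips caused by noise.

Quantification-confidence filters mirror standard practice: a protein
enters the fit in a sample only with an H/L ratio supported by at least 3
peptide ratio counts and identification by at least 2 unique peptides
(both configurable).

```{r turnover}
cfg <- sim_config(seed = 1, n_proteins = 710, times_h = c(0, 3, 8, 24))
d <- gen_turnover_dataset(cfg)
model <- growth_model(counts = unique(d$metadata[, c("time_h", "cell_count")]))
fits <- fit_turnover(d$proteins, d$metadata, model)
glance(fits)
```

## Relative abundance

The abundance index (AI) divides a protein's summed intensity by its
molecular mass, removing the trivial advantage of large proteins.  It is
an intra-sample relative measure comparable to emPAI
($10^{PAI} - 1$, with PAI the observed/observable peptide fraction), and
its ratio between two proteins estimates molar stoichiometry — the
package's schema carries a single summed-intensity column per sample, so
the AI always uses the total (heavy + light) signal.  The
generator's 48-protein dilution series (8 proteins per level, 6 levels
spanning 6 orders of magnitude) is the calibration check: with 10 %
intensity noise the within-level spread of $\log_{10}$ AI is
$\approx \log_{10}(e)\times 0.1 = 0.043$ and level means order perfectly.

## Cross-condition comparison under salt stress

Ratios measured under different NaCl concentrations are not directly
comparable: growth, global synthesis and the mild ratio underestimation
from metabolic labeling of proline and glutamate all scale whole
conditions.  The comparison therefore Z-normalizes the 24 h ratios within
each condition.  The Z-transform is applied to $\log_2 R$ (the ratio
distribution is strongly right-skewed, and a log-scale location/scale
adjustment absorbs exactly the multiplicative condition-wide biases; the
raw-scale variant is available via `log_scale = FALSE`).  Responders are
selected on the shift against the control, $\Delta z = z_{salt} -
z_{control}$: the `up` set is the intersection of the top 5 % by
$\Delta z$ in *every* stress condition, `down` analogously, with
lexicographic tie-breaking for reproducibility.  Spearman rank
concordance between the two salt conditions quantifies how similar the
two stress responses are.

## Metabolite label incorporation

For free metabolites the label readout is GC-MS fragment mass-isotopomer
pairs (e.g. proline 2TMS 142/146; glutamate 3TMS 84/85, 100/101, 156/157,
246/248).  The percent label of a fragment is

$$100\left(\frac{H}{L} - \frac{H_c}{L_c}\right),$$

the heavy/light intensity ratio minus the same ratio in unlabeled control
samples, which removes the natural ¹³C background.  Note the convention:
this is a ratio difference, not a heavy fraction — a pool whose molecules
are 9.09 % labeled reads as 10 %.  Metabolite-level values are unweighted
means across the declared fragments; per-fragment values are always
retained and a fragment spread above 5 percentage points flags discordant
fragments (e.g. a co-eluting contaminant on one mass).  Raw intensities
are normalized by internal-standard recovery and cell number before any
level comparison, and level fold changes are reported as log2 versus the
control.

```{r label}
iso <- gen_isotopomer_dataset(seed = 1,
  fragments = builtin_fragments() |> filter(metabolite == "proline"),
  true_label_ratio = 0.10, nat_background_ratio = 0.05,
  cv = 0.05, n_replicates = 6)
metabolite_label(iso$table, iso$control_samples) |>
  summarise(mean_percent = mean(percent_label))
```

## What the generators emulate — and what they do not

Every stage is testable without raw MS data because the generators draw
from the measurement model with known truth:

* **Turnover cohort**: half-lives log-normal (median 45 h, geometric
  SD 1.8 — a right-skewed shape typical of proteome-wide turnover
  measurements; the true dispersion in this alga is not known, so the
  geometric SD is a labeled modeling choice), doubling time 63.41 h,
  duplicate cultures at 0/1/3/8/24 h, multiplicative log-normal ratio
  noise with CV 15 %, shifted-Poisson ratio counts.  Salt conditions
  scale the dilution rate (slower growth) and apply a global synthesis
  factor; planted responders get per-protein multipliers.
* **Dilution series**: intensities proportional to concentration times
  mass, so true AI equals concentration exactly.
* **Isotopomer tables**: heavy intensity = light × (natural background +
  true label ratio) × noise; controls are generated unlabeled.

Noise is multiplicative log-normal with mean exactly 1
(`meanlog = -sdlog^2/2`), matching strictly positive intensities whose
errors scale with magnitude.  The generators do **not** simulate isotope
envelopes, peptide-level variation, missingness correlated with
abundance, arginine-to-proline interconversion (an optional global bias
term can probe the Z-normalization's robustness instead), or
chromatographic artifacts — so passing recovery tests demonstrates
estimator correctness under the stated model, not robustness to every
pathology of real LC-MS/GC-MS data.

## Numerical and design choices

* Strict TSV dialect for all tables ('.' decimals, no quoting, embedded
  tabs rejected, missing values as empty cells, `NaN` accepted on read):
  errors surface loudly instead of silently quoting, and write→read is
  the identity to 1e-12.
* Missing ratios are preserved as missing everywhere; a ratio with ratio
  count 0 is treated as unmeasured, never as 0.
* With more than two cell-count time points the growth factor comes from
  a log-linear least-squares fit; with exactly two it is the plain
  endpoint ratio (the classical calculation).
* A growth factor at or below 1 yields an infinite doubling time and zero
  dilution rate (flagged, not an error), so degradation equals loss.
* Doubling times are displayed rounded to whole hours; all computation
  keeps full precision.
* Control subtraction for percent label defaults to the mean over the
  user-specified unlabeled control samples; natural abundance is
  time-invariant, so pooled controls are the default recommendation.
* Problem sizes in the test-suite recovery runs (a 710-protein cohort,
  6-replicate label designs, 100-instance oracle comparisons) mirror the
  study-scale designs while keeping the default check runs fast.

## Known limitations

* One regression per protein: no peptide-level or Bayesian/ODE turnover
  modeling, and no correction for arginine pool equilibration kinetics.
* The AI is relative; absolute quantification is out of scope.
* Responder selection needs at least 20 proteins shared across all
  conditions.
* Real-data counts (numbers of identified or quantified proteins) depend
  on the original spectra and are not reproducible from synthetic data;
  the package reproduces the estimators, not the inventory.
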