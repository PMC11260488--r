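---
title: "Methods: noise quantification, selection simulation, and bulk-segregant mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noise quantification, selection simulation, and bulk-segregant mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisevolve)
```

`noisevolve` implements the quantitative chain of a forward-genetic screen
for gene-expression noise regulators in budding yeast: quantify noise from
dual-reporter flow cytometry, enrich high-noise mutants by iterated FACS
selection (simulated in silico), and map the causal mutation by
bulk-segregant analysis. Every wet-lab input is emulated by a seeded
synthetic-data generator with the statistical structure the analysis
assumes, so each stage can be validated against known ground truth.

## The reporter model and what it emulates

A cell's fluorescence in channel *ch* is modelled as

$$ X_{ch} = \mu_{ch} \cdot E \cdot I_{ch}, \qquad
   E \sim \mathrm{LogNormal}(0, \sigma_{ext}), \quad
   I_{ch} \sim \mathrm{LogNormal}(0, \sigma_{int,ch}), $$

with the extrinsic factor $E$ shared by both reporters within a cell and
the intrinsic factors independent. The multiplicative lognormal form
matches the log-scale analysis convention of flow cytometry and gives the
dual-reporter decomposition closed-form ground truth:
$\eta_{ext}^2 = e^{\sigma_{ext}^2} - 1$ and (for equal intrinsic sigmas)
$\eta_{int}^2 = e^{\sigma_{ext}^2}(e^{\sigma_{int}^2} - 1)$, both reducing
to $e^{\sigma^2}-1$ per component when the sigmas are small. The defaults
$\sigma_{ext} = 0.20$, $\sigma_{int} = 0.15$ keep the exact and
small-sigma expressions within about 4% of each other, so the 10%
parameter-recovery check in the test suite tests estimation error, not the
approximation. Scatter channels are lognormal with correlated log FSC-A /
log SSC-A ($\rho = 0.7$ by default); debris events sit below the FSC-A
trigger threshold with near-zero fluorescence; doublets are sums of two
singlet draws whose FSC-W is inflated by a Uniform(1.6, 2.2) multiplier,
guaranteeing separability from singlets without tuning a gate boundary.

The generator does **not** emulate spectral spillover, autofluorescence,
photomultiplier saturation, or noise-versus-abundance trends, so passing
tests demonstrate correctness of the estimators under the model's
assumptions, not robustness to every instrument artifact of real data.

## Gating and the Fano factor

The pipeline order is fixed: **trigger → doublet → contour → log**.

* `trigger_threshold()` drops events with FSC-A strictly below 2570 a.u.
  (small fluidic particles; equality is retained).
* `doublet_gate()` removes events above the 0.90 within-sample quantile of
  FSC-W. The boundary is data-driven because no absolute width cutoff
  transfers across instruments; as a consequence a second application
  re-quantiles the already-gated sample rather than being idempotent.
  An `NA` quantile in `gate_pipeline()` disables the gate — analyzer runs
  (as opposed to sorter runs) may use the contour gate alone.
* `density_contour_gate()` approximates proprietary instrument contour
  gating by a 64×64 2-D histogram on FSC-A vs SSC-A: bins are admitted in
  decreasing-count order (ties by row, then column index — deterministic)
  until at least 80% of events are covered. The retained fraction
  therefore lies in `[fraction, fraction + m/n]` with `m` the last
  admitted bin's count; at 64×64 on 10^5 smooth unimodal events the
  overshoot stays below one percentage point.
* `log_transform()` drops non-positive intensities (counted, warning above
  5%) and takes base-10 logs — the convention for cytometry data; the base
  is a parameter because the Fano factor is not scale-invariant.

Noise is summarized by the Fano factor $\sigma^2/\mu$ of the
log-transformed intensities (`fano()`, `sample_noise()`), computed with
sample variance (denominator $n-1$; at cytometry sample sizes the choice
is numerically immaterial but it is fixed so exact tests are possible).
The Fano factor is preferred over $CV^2$ because it is less sensitive to
shifts in mean abundance.

## Dual-reporter decomposition

`decompose()` rescales each channel to unit mean and applies the standard
two-reporter estimators with plain $1/n$ averages:

$$ \eta_{int}^2 = \frac{\langle (c-y)^2 \rangle}{2\langle c\rangle\langle y\rangle},\qquad
   \eta_{ext}^2 = \frac{\langle cy\rangle - \langle c\rangle\langle y\rangle}{\langle c\rangle\langle y\rangle},\qquad
   \eta_{tot}^2 = \frac{\langle c^2\rangle + \langle y^2\rangle - 2\langle c\rangle\langle y\rangle}{2\langle c\rangle\langle y\rangle}. $$

Design choices, made where the published description is silent:

* **Linear intensities** enter the decomposition (the cited dual-reporter
  framework uses relative linear intensities); the Fano pipeline uses log
  intensities. Unit-mean normalization makes the decomposition invariant
  to separate rescaling of either channel, which also removes any
  dependence on reporter brightness calibration.
* **Additivity by construction**: with $1/n$ averages the identity
  $\eta_{tot}^2 = \eta_{int}^2 + \eta_{ext}^2$ holds to machine precision
  for every input, and the suite asserts it at $10^{-10}$ relative.
* **Negative $\eta_{ext}^2$** sample estimates are reported as-is; clipping
  at zero would silently break the additivity identity.

## The selection-protocol simulator

Lineages are parameter vectors (channel means, noise sigmas, growth rate,
defect flags) with abundances — not genomes. One round of EMS mutagenesis
founds mutant lineages: a configurable fraction of cells is assigned to
effect classes (noise-up, general regulator, single-reporter defect,
mitochondrial defect, neutral), with effect sizes drawn per founded
lineage (noise-up multiplies all sigmas by Uniform(1.5, 2.5); general
regulators scale both means by a factor of 2–4, up or down).

Each sort step samples events from the lineage mixture, gates them, and
intersects two masks:

* `outermost_selection()` ranks events by **Mahalanobis distance** from
  the centroid in the (log GFP, log mCherry) plane and takes exactly
  `floor(0.10 n)` of them. The published protocol collects the cells
  outside an elliptical region holding 90% of the population; Mahalanobis
  ranking respects the elliptical geometry of lognormal clouds. Ties are
  broken by event index; a singular covariance (e.g. a constant channel)
  falls back to Euclidean ranking with a warning.
* `quadrant_mask()` splits the plane at the per-channel **medians**
  (robust and parameter-free; the published quadrants carry no printed
  coordinates), with boundary events assigned to the at/below side. The
  first sort of each round pools QII and QIV (one tube); the second sorts
  QI. The alternation counter-selects general activators/repressors (they
  travel along the diagonal) and broken reporters (they cannot reach QI).

Recovery is deterministic exponential growth for a fixed number of
wild-type generations (default 10, standing in for the 48 h glycerol
outgrowth, whose exact generation count is not printed) followed by
multinomial resampling to the target size; mitochondrially defective
lineages grow at 0.05× wild type in the non-fermentable medium and are
depleted to under 1% from 50% in one recovery. Agent-based division is
deliberately avoided: frequency dynamics only need expected growth plus
sampling noise.

**Scale.** The simulator defaults to 10^4 events per sort sample (the
bench protocol sorts 10^5 cells out of a much larger stream); frequency
dynamics are scale-free, so this preserves the studied behaviour. One
caveat: with a mutant lineage at frequency 10^-3, a 10^4-event sample
starts it at ~10 cells, where drift can extinguish it before selection
acts. The protocol-level enrichment test therefore samples 2×10^4 events
per sort — closer to the cell numbers the sorter actually surveys — and
observes enrichment in at least 9 of 10 seeded two-round runs.

## Bulk-segregant mapping

`gen_segregants()` simulates the F1 haploid cross: independent 1/2
inheritance at each chromosome's leftmost locus, Haldane recombination
$r = (1-e^{-2d/100})/2$ between adjacent loci (no interference — the
simplest standard map function), and replicate phenotype draws
(ancestral base Fano 1.0, causal-allele shift +1.0, Gaussian replicate
noise; the parental levels are free parameters of the synthetic cross —
the source figures print no numeric Fano values).

`classify_segregants()` calls a replicate evolved-like iff its Fano
exceeds the midpoint of the parental references and requires all
replicates to agree; disagreeing segregants are `inconsistent` and never
pooled. The midpoint rule is this package's own, replaceable choice — the
bench classification against parental distributions is not specified as a
formula. `build_pools()` draws 20 consistent segregants per class,
seeded. `gen_pool_reads()` samples reads per site as
Binomial(depth, $p(1-e) + (1-p)e$) with symmetric base error $e$ — a
single-parameter error model adequate for testing SNP-index robustness.

`snp_index()` is alt/(ref+alt) per bulk (alt = evolved-parent allele;
zero-depth sites are dropped and counted, never imputed);
`delta_and_filter()` takes delta = evolved − ancestral, keeps sites with
an index **strictly above 0.3** in at least one bulk, and calls causal
sites with delta **strictly above 0.8**. `clone_variant_filter()` applies
the evolved-clone variant filter: coverage strictly above 30 and allele
frequency strictly above 0.5. All four thresholds are strict per the
published "greater than" wording, and the suite pins the boundary cases
(30, 0.5, 0.3, 0.8 all excluded). With 20-segregant pools and a fully
penetrant phenotype the causal locus reaches delta = 1 exactly; under
binomial sampling with 0.5% base error it stays above the 0.8 calling
threshold in every seeded run, while unlinked neutral loci keep their
|delta| 99th percentile below 0.8 (binomial sampling noise of a
20-segregant pool at depth 200).

VCF input is parsed from per-sample AD fields via `vcfR`
(`read_bulk_vcf()`); multi-allelic sites are skipped (counted) or reduced
to the first alternate allele by flag. Positions stay 1-based; BED export
converts to 0-based half-open.

## Assay computations

* `ddct_fold_change()` — the 2^−ΔΔCt relative-quantification method; no
  amplification-efficiency correction (out of scope).
* `max_growth_rate()` — maximum OLS slope over every 20-point sliding
  window, ties to the earliest window. On a noiseless logistic curve
  sampled every 12 min with rate 0.005/min the windowed estimate is
  within 2% of the analytic maximum $rK/4$; the 5% test band leaves room
  for faster curves where the 228-min window flattens the peak.
* `pm_ratio()` — trapezoidal areas of baseline-subtracted absorbance over
  supplied peak boundaries; baseline = minimum within the boundary span
  (simplest defensible choice, reported for audit). Only the 80S peak
  forms the denominator; 40S/60S segments are ignored. Peak boundaries
  are supplied, not auto-detected — instrument software draws them on the
  bench.
* `competition_fitness()` — pointwise normalization of the
  mutant-to-reference ratio by the ancestral-to-reference ratio in the
  same condition, cancelling the marker-gene fitness effect.

## Reproducibility and numerical conventions

All generators and stochastic stages take explicit integer seeds; a
run-level seed yields per-stage seeds through `derive_seed(seed, offset)`
with fixed offsets, keeping stages decorrelated and everything
bit-reproducible. Quantiles use R's default type-7 definition. Degenerate
inputs fail loudly: empty post-gate populations, non-positive channel
means, zero-depth sites, insufficient consistent segregants, and
extinguished selections all raise informative errors rather than
returning numbers.

Problem sizes used by the test and acceptance runs — 10^5 events for
gating/decomposition checks, 100 segregants × 50 loci × depth 200 for
mapping, 10–100 seeded replicates for the stochastic properties — were
chosen as the smallest scales at which the binomial/multinomial error
bands in the assertions are meaningful.

## Known limitations

Lineages carry no genome, so the simulator cannot produce the clone
variant tables it filters (those come from the synthetic cross instead);
the contour gate is a histogram approximation of smooth instrument
contours; the SNP-index stage performs no sliding-window smoothing or
interval estimation (none is applied in the source procedure); and the
phenotype classifier is a midpoint rule standing in for expert judgment.
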