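# noisevolve

Quantitative toolkit for forward-genetic screens of **gene-expression
noise** in budding yeast. A screen of this kind measures cell-to-cell
variability of two fluorescent reporters by flow cytometry, enriches
high-noise mutants by repeatedly FACS-sorting the 10% outermost cells of
the two-reporter intensity distribution, and maps the causal mutation by
bulk-segregant analysis of an evolved × ancestral cross. `noisevolve`
implements that chain end to end, with a seeded synthetic-data module
standing in for every wet-lab input so each stage is testable against
known ground truth.

## What it computes

* **Gating** — FSC-A trigger threshold (< 2570 a.u. excluded), FSC-W
  quantile doublet gate, highest-density 2-D contour gate retaining 80%
  of events on FSC-A vs SSC-A, and base-10 log transform of the
  fluorescence channels.
* **Noise statistics** — the Fano factor σ²/μ of log-transformed
  intensities, CV², and the dual-reporter decomposition

  η²_int = ⟨(c−y)²⟩ / (2⟨c⟩⟨y⟩),  η²_ext = (⟨cy⟩−⟨c⟩⟨y⟩) / (⟨c⟩⟨y⟩),
  η²_tot = (⟨c²⟩+⟨y²⟩−2⟨c⟩⟨y⟩) / (2⟨c⟩⟨y⟩),

  computed on unit-mean-normalized linear intensities so that
  η²_tot = η²_int + η²_ext holds exactly.
* **Selection simulation** — EMS mutagenesis founding mutant lineages,
  alternating sorts of the 10% outermost cells (Mahalanobis distance in
  the log-GFP/log-mCherry plane) intersected with quadrant gates
  (QII ∪ QIV, then QI), and recovery growth in glycerol that depletes
  respiration-deficient lineages.
* **Bulk-segregant mapping** — F1 segregant simulation with Haldane
  recombination, replicate-consistent phenotype classification, 20-segregant
  pools, per-bulk SNP index alt/(ref+alt), ΔSNP index (evolved −
  ancestral), the index filter (> 0.3 in at least one bulk) and causal
  call (Δ > 0.8), plus the evolved-clone variant filter (coverage > 30,
  allele frequency > 0.5). VCF input via per-sample AD fields.
* **Assays** — 2^−ΔΔCt qPCR fold change, maximal growth rate (max OLS
  slope over 20-point windows), polysome-to-monosome ratio from A254
  peak areas, and marker-normalized competition fitness.

## Worked example

```r
library(noisevolve)

## synthetic dual-reporter sample, gated and log-transformed
ev    <- gen_events(reporter_model(f_debris = 0.02, f_doublet = 0.03),
                    50000, seed = 1)
gated <- gate_pipeline(ev)
sample_noise(gated, "GFP")
#> noise summary (GFP, log10): n = 35257, mean = 3, var = 0.0118,
#>   Fano = 0.003933, CV2 = 0.001311

## intrinsic/extrinsic decomposition on the linear intensities
decompose(10^gated$GFP, 10^gated$mCherry)
#> dual-reporter decomposition (n = 35257): eta_int2 = 0.02403,
#>   eta_ext2 = 0.04072, eta_tot2 = 0.06475

## map a causal noise locus in a simulated cross (100 segregants,
## 50 loci, 20-segregant bulks, depth 200, 0.5% base error)
des <- cross_design(n_loci = 50, causal_index = 25, n_segregants = 100,
                    phenotype_noise_sd = 0.05)
rec <- bsa_map(des, depth = 200, error_rate = 0.005, seed = 1)
rec[rec$called_causal, c("chrom", "pos", "snp_index_evolved",
                         "snp_index_ancestral", "delta_snp_index")]
#>    chrom pos snp_index_evolved snp_index_ancestral delta_snp_index
#> 25 chr25   1                 1               0.005           0.995
```

The gated sample keeps 35,257 of 50,000 events (trigger, doublet, and 80%
contour gates; `gate_report(gated)` itemizes each stage). The
decomposition recovers the generator's ground truth (η²_ext =
exp(0.2²)−1 ≈ 0.041, η²_int ≈ exp(0.15²)−1 ≈ 0.023). The mapping stage
flags the causal locus — and only it — with ΔSNP index 0.995, far above
the 0.8 calling threshold, while 49 neutral loci stay below it.

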