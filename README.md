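# divorseq

Genome-wide transcription-factor off-rate estimation from depletion
ChIP-seq time courses, in R.

## Science

Most measurements of transcription-factor binding are snapshots: a ChIP-seq
peak says *where* a factor binds, not *for how long*. When the nuclear pool
of a factor is abruptly removed (for example by anchor-away nuclear
depletion) and binding is re-measured at a series of time points, each site's
signal decays at a rate set by the factor's dissociation kinetics at that
site. For a site with dissociation rate constant `koff`, the expected ChIP
signal follows first-order decay

```
y(t) = yf + (y0 - yf) * exp(-koff * t)
```

where `y0` is the pre-depletion level and `yf` the residual plateau
(background plus rebinding floor). The mean **residence time** of the factor
at the site is `1 / koff`. Fitting this model independently at every
analyzable binding site turns a depletion time course into a genome-wide map
of binding stability, which can then be stratified against chromatin features
(nucleosome-free-region width, MNase footprint protection, Pol II stalling
upstream of the motif) and against transcriptional responses measured by
nascent-RNA time courses.

`divorseq` implements the full path from fragment BED files to residence-time
quartiles:

1. **genomic_io** — 0-based half-open interval tables, narrowPeak / bedGraph
   / wiggle / FASTA / chrom.sizes readers and writers, interval overlap.
2. **signal_quant** — fragment-midpoint coverage with a 101 bp boxcar,
   scaling to one million fragments, ±50 bp window sums at peak summits,
   background-fraction normalization, replicate outlier flagging (strict
   6× median-absolute-deviation rule).
3. **motif_scan** — additive position-weight-matrix scanning on both strands
   with a percent-of-maximum threshold and extraction of the base 8 bp
   5′ of the motif midpoint (the cross-linkability position).
4. **site_selection** — the filter cascade: fold enrichment ≥ 4, at least one
   motif match (≥ 85 % of the maximal score) with midpoint within 100 bp of
   the summit, G/C at −8 bp on *every* match, and telomere exclusion.
5. **decay_fit** — per-site nonlinear least squares on all replicate
   observations (variable projection over `log(koff)` plus an `nls`
   asymptotic-regression polish), pseudo-R², residence-time quartiles.
6. **chromatin_metrics** — motif-oriented aggregate profiles, NFR width by
   prominence-filtered peak calling, MNase protection ratios, Pol II
   roadblock indices, and the group-comparison statistics
   (ANOVA + Tukey HSD, t, Wilcoxon, Fisher).
7. **txn_dynamics** — nascent-RNA count normalization, responsive-gene
   selection, promoter assignment of binding sites, synthesis-decay fits.
8. **synthetic_data** — seeded generators for every input with known ground
   truth, so the whole method is testable offline.
9. **cli** — `inst/cli/divorseq`, a thin shell wrapper
   (`simulate`, `run-all`, `filter`).

## Worked example

Simulate a complete depletion experiment (30 sites with planted off-rates
and filter failures, 11 time points × 3 replicates, ~1 M fragments per
sample), then run the whole pipeline from files:

```r
library(divorseq)

dir <- tempfile()
sim <- simulate_chip_experiment(seed = 1, out_dir = file.path(dir, "in"))
cfg <- pipeline_config(paths = list(
  sample_sheet = sim$paths$sample_sheet, peaks = sim$paths$peaks,
  genome = sim$paths$genome, pfm = sim$paths$pfm,
  chrom_sizes = sim$paths$chrom_sizes, telomeres = sim$paths$telomeres))
res <- run_pipeline(cfg, file.path(dir, "out"))
#> [divorseq] site cascade: called=30 -> fold_enrichment=25 ->
#>            motif_and_minus8=18 -> non_telomeric=17

head(res$fits[, c("site_id", "koff", "residence_time_min", "r2", "quartile")], 5)
#>    site_id       koff residence_time_min        r2 quartile
#> 1 site_001 0.11813955           8.464566 0.9874860    short
#> 2 site_002 0.11683676           8.558950 0.9897613    short
#> 3 site_003 0.05196433          19.243969 0.9893025  longest
#> 4 site_005 0.17229520           5.803992 0.9895510 shortest
#> 5 site_007 0.15334404           6.521284 0.9912967 shortest
```

Against the planted truth, this run recovers off-rates with a median
relative error of **0.035**, a Spearman rank correlation of **0.988**, a
median fit R² of **0.989**, and residence times spanning **3.9 – 29.4
minutes**. The filter cascade (30 → 25 → 18 → 17) matches the planted site
classes exactly.

A single site can also be fit directly:

```r
f <- fit_decay(simulate_timecourse("demo", y0 = 500, yf = 50, koff = 0.12,
               noise = noise_model("lognormal", sd = 0.1), seed = 42))
f
#>   site_id       y0       yf      koff residence_time_min        r2 converged n_points
#> 1    demo 513.5151 55.05871 0.1258848           7.943773 0.9716367      TRUE       33
```

On noiseless curves the fit recovers the parameters to machine-level
accuracy (relative `koff` error below 1e-11 across 50 random draws); at the
extremes of the study's off-rate range (0.24 and 0.030 min⁻¹) the recovered
residence times are **4.2** and **33** minutes.

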