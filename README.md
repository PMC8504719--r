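# svrefine

Single-nucleotide refinement of read-depth structural-variant breakpoints
with a one-dimensional UNet.

## What problem does this solve?

Read-depth (RD) SV callers (CNVnator and relatives) find deletions (DEL)
and duplications (DUP) from binned coverage, so every breakpoint they
report is only accurate to the bin width — 50 bp at best, often worse.
`svrefine` post-processes such a callset to single-nucleotide resolution:

1. extract the base-wise depth vector over a screening window (default
   *l* = 400 bp) centred on each candidate breakpoint, z-normalised against
   background depth statistics sampled away from known SVs;
2. segment the window with a 1-D UNet into per-base SV-overlap marks
   *m&#x2097; ∈ {0,1}* — the network is trained on windows around validated
   breakpoints with a soft Dice loss,
   DSC = (2Σ m₉mₚ + ε)/(Σ m₉ + Σ mₚ + ε);
3. replace each breakpoint by the nearest boundary of the predicted mask
   runs (run starts for left boundaries, run ends for right), retaining the
   original call when the mask is empty or the refined SV would drop below
   the 50 bp minimum size.

The package also ships the full evaluation stack used to quantify the
effect — Jaccard matching against a gold standard (matched iff JS > 0.5),
precise-boundary summaries (a boundary is "precise" within 1 bp),
breakpoint distance change matrices, Dice and classification metrics — and
a seeded simulator that generates truthsets, haplotype-aware junction-
clipped read placements, and BAM/VCF fixtures, so the whole pipeline is
testable offline.

The intended users are people running RD-based CNV callers on short-read
WGS who need junction-grade coordinates: for training it expects a BAM and
a validated SV set (VCF/BED), for application a BAM and a candidate VCF.

## Worked example

Everything below runs in a couple of minutes on one CPU; no downloads.

```r
library(svrefine)

## a synthetic 1.2 Mb sample: truth SVs, reads, and a candidate callset
## degraded to a 50 bp bin grid (what an RD caller would report)
sim   <- simulate_sv_data(sim_config(genome_length = 1.2e6, n_svs = 120,
                                     mean_depth = 30, bin_size = 50,
                                     seed = 201))
paths <- write_fixtures(sim, "fixtures")   # reads.bam + truth.vcf + candidates.vcf

## background depth statistics for z-normalisation
bg <- estimate_background_stats(paths$bam, n_bins = 100, seed = 1,
                                exclude = sv_granges(read_svs(paths$candidate_vcf)))
bg
#> <depth_stats> mean = 30.182, sd = 5.479  (100 bins x 1000 bp, seed 1)

## train the segmentation UNet on a second, independent sample
tr  <- simulate_sv_data(sim_config(genome_length = 4e6, n_svs = 550,
                                   mean_depth = 30, seed = 1))
sts <- estimate_background_stats(tr$source, genome = tr$genome, n_bins = 200,
                                 seed = 1, exclude = sv_granges(tr$svs))
ts  <- build_training_set(tr$source, tr$svs, sts, tr$genome, l = 400, seed = 1)
fit <- train_model(build_unet(unet_config(400, base_filters = 8)), ts,
                   train_control(seed = 1, max_epochs = 40, patience = 8))
fit
#> <rd_unet> 1-D UNet, input 400 bp, 4 levels (widths 8-16-32-64 | 64)
#>   trained: 23 epochs, best validation DSC 0.5046

## enhance the degraded callset and measure the effect against the truth
enh <- enhance_callset(paths$candidate_vcf, fit, paths$bam, bg,
                       out_vcf = "enhanced.vcf", report = "enhancements.tsv")
ev  <- evaluate_enhancement(read_svs(paths$candidate_vcf), enh$svs, sim$svs)
ev$before$precise_proportion   # % of matched SVs with a precise boundary
#> [1] 10.08403
ev$after$precise_proportion
#> [1] 100
c(ev$bp_within5_before, ev$bp_within5_after)  # breakpoints within 5 bp of truth
#> [1]  47 221
```

Interpretation: before enhancement the candidate breakpoints sit on the
50 bp bin grid, so few land within 1 bp of the truth and only a handful
within 5 bp by rounding luck.  After segmentation-based refinement every
matched SV has at least one boundary exact to ≤1 bp and the large
majority of breakpoints sit within 5 bp of the true junction.  The
`enhancements.tsv` report records, per SV, the original and refined
coordinates and the per-side outcome (`updated`,
`multi-candidate-nearest`, `retained-no-candidate`,
`retained-size-guard`).

A command-line front-end wrapping the same functions lives in
`exec/svrefine` (`simulate` / `train` / `enhance` / `evaluate` / `run`),
and `run_pipeline()` orchestrates the whole in-sample or cross-sample flow
with a JSON run manifest.  See the vignette
(`vignettes/breakpoint-refinement.Rmd`) for the model, its assumptions,
and all tuning parameters.

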