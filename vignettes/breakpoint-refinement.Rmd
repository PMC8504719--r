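---
title: "Refining read-depth SV breakpoints with a 1-D UNet"
author: "svrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining read-depth SV breakpoints with a 1-D UNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrefine)
```

## The problem

Read-depth (RD) based structural-variant callers divide the genome into
fixed-width bins, smooth the per-base coverage into one value per bin, and
call deletions (DEL) and duplications (DUP) from abnormal bin-level depth.
The smoothing is what makes these callers robust, but it also caps the
precision of every reported breakpoint at the bin width: with a 50 bp bin,
a breakpoint is somewhere inside a 50 bp interval; with a 1,000 bp bin,
somewhere inside a kilobase.  Many downstream analyses — gene-disruption
calls, junction PCR design, comparison against split-read callsets — want
single-nucleotide coordinates.

The idea implemented here is that the *base-wise* depth signal around a
candidate breakpoint, although noisy, still carries enough information to
locate the true breakpoint, provided the pattern recognition is strong
enough.  The package treats breakpoint refinement as a 1-D segmentation
task: given the z-normalised depth vector
$X = (d_1, \dots, d_l)$ over a screening window of $l$ bp, predict the mask
$Y = (m_1, \dots, m_l)$, $m_i \in \{0, 1\}$, marking which bases of the
window overlap an SV.  The boundaries of the predicted mask runs are then
single-base breakpoint candidates, and a candidate callset's coordinates
are replaced by the candidate nearest the original call.

## The model

The segmentation network is a small one-dimensional UNet:

* an encoder of repeated blocks — convolution (kernel 3, same padding),
  ReLU, batch normalisation — with a 2x max-pool after every two blocks;
* a decoder that mirrors the encoder with 2x transposed convolutions,
  concatenating the same-resolution encoder feature map (skip connections)
  before two further conv–ReLU–BN blocks per level;
* a 1x1 convolution with a sigmoid producing per-base scores in (0, 1);
  a base is marked 1 when its score is strictly greater than 0.5.

There is no fully connected layer, so the output length always equals the
input length and the same weights apply to any window length divisible by
the total pooling factor ($2^{\text{levels}}$).  Channel widths double per
level from `base_filters`, capped at eight times the base (32 → 256 with
the defaults).

Training minimises one minus the Dice similarity coefficient,

$$\mathrm{DSC}(Y_{pred}, Y_{gold}) =
  \frac{2 \sum_i m_{gold,i}\, m_{pred,i} + \epsilon}
       {\sum_i m_{gold,i} + \sum_i m_{pred,i} + \epsilon},$$

with $\epsilon = 10^{-7}$, computed on the continuous sigmoid scores (soft
Dice) so the loss is differentiable, and optimised with Adam.  One
implementation detail matters: the loss sums run over the *whole
minibatch*, not per window.  Per-window soft Dice assigns an all-background
window a numerator of $\epsilon$ only, so its gradient all but vanishes and
false-positive marks on background windows are never penalised; pooling the
sums over the batch restores that signal.  All *evaluation* Dice values in
the package (the `DSC-ALL`/`DSC-BK` statistics of
`segmentation_metrics()`) remain strictly per-window on thresholded masks.

The whole network — forward pass, loss, and analytic backward pass — is
implemented in compiled code (RcppArmadillo); the test suite verifies the
gradients against central finite differences.  Training is bit-reproducible
on CPU given the `train_control()` seed, which drives weight
initialisation, the validation split, and shuffling.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `input_length` (l) | 400 bp | screening-window length; should cover at least four caller bins and a few read lengths |
| `pooling_levels` | 4 | pooling stages; bottleneck length is $l/2^4$ |
| `base_filters` | 32 | first-level channel width (capped doubling) |
| `threshold` | 0.5 | score cutoff for an SV-overlap mark (strict `>`) |
| `learning_rate` | 0.001 | Adam step size |
| `batch_size` | 64 | minibatch size |
| `min_epochs`/`max_epochs` | 10 / 100 | early-stopping bounds |
| `patience` | 10 | epochs without validation improvement tolerated |
| `validation_fraction` | 0.1 | held-out fraction monitored for early stopping |

Early stopping monitors the mean thresholded per-window Dice on the
validation split and restores the best weights.  The learning rate, batch
size and epoch bounds follow the standard configuration for this task; the
patience and validation fraction are this package's own choices.

## Training data construction

Positive windows are anchored on the breakpoints of known (validated) SVs:
both the start and the end of every DEL/DUP contribute one window whose
start is `breakpoint - delta` with `delta` drawn uniformly from the
integers `[10, l - 10]`, so breakpoints appear at variable in-window
offsets.  Windows whose anchor SV overlaps the window by fewer than 10 bp
are discarded — a sliver of overlap at the window edge is not a learnable
example.  Raw all-zero depth vectors are removed, an equal number of
negative windows is drawn from SV-free regions, and every window is
z-normalised with background statistics: the mean and standard deviation
of base-wise depth pooled over randomly sampled bins that avoid known SVs
and any supplied exclusion regions (e.g. low-mappability tracks).

At enhancement time the screening window is *centred* on each candidate
breakpoint (training uses the random offsets; application does not), each
side of the SV is segmented independently, and run boundaries become
candidates: run starts for the left boundary, one-past-run-ends for the
right, which preserves orientation.  A breakpoint updates to its single
candidate, to the nearest of several (ties toward the smaller coordinate),
or stays put when the mask is empty.  If the refined interval would be
shorter than 50 bp — the conventional minimum SV size — both original
boundaries are restored.

## What the simulator emulates — and what it does not

`simulate_sv_data()` generates a diploid-like sample: a truthset of
non-overlapping DELs and DUPs (sizes log-uniform on [50, 10000] bp, DEL
fraction 0.68 to match a DGV-derived mix, an even het/hom split, at least
twice the window length between events) and aligned read segments of fixed
length (125 bp) placed per haplotype at a Poisson rate of
$\lambda / (2\,\text{read length})$ per base.

Breakpoint sharpness is modelled deliberately.  On a haplotype carrying a
deletion, reads never start inside the deleted interval and reads spanning
a breakpoint are split the way an aligner maps junction reads — clipped at
the left breakpoint with the remainder mapped from the right breakpoint.
Carried duplications contribute an extra copy's worth of reads that wrap
around the tandem junction.  The expected depth is therefore *exactly*
piecewise constant — $\lambda$ in neutral sequence and $\lambda \times
\{0, 0.5, 1.5, 2\}$ inside hom-DEL/het-DEL/het-DUP/hom-DUP — with sharp
transitions at the true breakpoints, matching what aligned short-read data
look like around real SV junctions.  (An earlier design that merely thinned
read *starts* inside SVs produced read-length-wide linear ramps at every
breakpoint; single-base refinement is ill-posed on such ramps, and no
aligner produces them.)

The simulator does not model GC bias, mappability structure, sequencing
error, insert-size variation, imprecise or inconsistent truth annotations,
or tumour heterogeneity.  Real WGS data have all of these, and their expected consequence is that
segmentation accuracy drops by several points and the false-discovery rate
of window classification rises relative to clean simulation.  Passing the
synthetic checks here demonstrates that the machinery — labels, loss,
network, refinement arithmetic — is correct and that the method works under
its stated assumptions; it does not certify performance on any particular
real sample.

The same read placements back both the in-memory depth source and the BAM
fixture written by `write_fixtures()`, so tests can require exact equality
between simulated and extracted depth.  `degrade_candidates()` rounds the
truth breakpoints to the caller bin grid (default 50 bp), producing the
bin-resolution candidate VCF that enhancement is meant to fix.

## Problem sizes used by the tests and the acceptance script

All expensive checks run at a deliberately reduced scale chosen once as
this package's study conditions: training uses 2,000 windows of 400 bp at
30x depth with an 8-filter, 4-level UNet (about 75k parameters) and at most
40 epochs; held-out evaluation uses 500 windows from an independent
simulation; end-to-end enhancement uses a 1.2 Mb sample with 120 SVs
degraded to a 50 bp grid; the depth sweep trains at
$\lambda \in \{5, 15, 30, 60\}$ with 400 training windows each.  Under
these conditions the held-out SV-window Dice (`DSC-BK`) reaches ≈ 0.9 and
enhancement moves the large majority of matched breakpoints to within 5 bp
of the truth.

Two behaviours of the scaled-down configuration are worth knowing.  First,
the per-window Dice on *background* windows is an all-or-nothing statistic:
a single false-positive base zeroes it.  Whether the small network leaves
isolated marks on background windows varies noticeably between
initialisation seeds; on a noisy seed `DSC-ALL` sits far below `DSC-BK`
and window classification (positive iff any mark) over-calls positives
(high recall, elevated FDR), while on a clean seed both approach the
SV-window Dice.  SV-window segmentation (`DSC-BK`) is stable across seeds;
a full-width configuration (32 base filters) and larger training sets
reduce the variability.  Second, early stopping monitors exactly that
volatile all-window statistic, which is conservative: it never selects a
model whose background behaviour got worse.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF POS/END (1-based,
  inclusive END) are converted only at I/O boundaries, and round-trips are
  lossless.
* Windows overhanging a contig end are rejected, not clipped (the model
  needs fixed-length input); enhancement falls back to the original
  breakpoint with a warning.
* A score exactly equal to the threshold yields mark 0 (strict inequality).
* Two empty masks have Dice 1 by the $\epsilon$ limit; a background with
  zero depth variance raises a `degenerate_background` error rather than
  dividing by zero; normalising twice is an error rather than a silent
  no-op.
* Equidistant refinement candidates resolve to the smaller coordinate;
  matching to a gold standard is greedy one-to-one by descending Jaccard
  similarity with a strict 0.5 cutoff, and type-concordant (DEL with DEL,
  DUP with DUP).
* Batch normalisation uses biased batch variance and momentum-0.9 running
  statistics; prediction always uses the running statistics.

## Known limitations

* Only DELs and DUPs are refined — balanced events (INV) and insertions
  leave no copy-number footprint in depth and pass through untouched.
* A breakpoint farther than $l/2$ from the candidate coordinate is outside
  the screening window and cannot be recovered; with a caller bin size
  above $l/4$ this becomes the dominant failure mode (hence the four-bin
  warning).
* The 50 bp size guard restores *both* boundaries, so a good refinement on
  one side can be discarded because of a poor one on the other.
* Training windows from a validated SV set inherit its annotation errors;
  the simulator cannot emulate that, and cross-sample application assumes
  the samples share a sequencing platform.
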