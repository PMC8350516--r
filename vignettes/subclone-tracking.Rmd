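---
title: "Tracking an emerging tumour subclone from longitudinal low-pass WGS copy numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking an emerging tumour subclone from longitudinal low-pass WGS copy numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnatrace)
```

## The problem and the model

Serial liquid biopsies sequenced by low-pass whole-genome sequencing
(lpWGS, ~0.1-1x) yield, per sample, a genome-wide profile of
depth-based copy numbers but no usable B-allele frequencies and often
no matched normal.  cnatrace estimates, from such profiles alone, (i)
the tumour fraction ("purity") of each sample and (ii) the size of a
single emerging subclone over the series.

The model assumes three DNA sources in each sample $i$: normal cells
(copy number 2 everywhere), an ancestral tumour population with
per-segment integer copy number $C^{(A)}_j$, and one emerging subclone
with integer $C^{(S)}_j$.  With purity $p_i$ (fraction of
tumour-derived DNA) and subclonal ratio $r_i$ (fraction of the tumour
DNA from the subclone), the measured copy number of segment $j$ is

$$C_{ij} = 2 + p_i\left[(1-r_i)\,C^{(A)}_j + r_i\,C^{(S)}_j - 2\right] + \varepsilon_{ij}.$$

Segments are *clonal* ($C^{(A)}=C^{(S)}$), *subclonal*
($C^{(A)}\neq C^{(S)}$), or *unstable* (a time-dependent tumour copy
number $\zeta_{ij}$ independent of $r_i$ — unreliable measurement or
ongoing instability).  One designated *baseline* sample (e.g. taken
before therapy) is assumed to carry a negligible subclone fraction.

Estimation proceeds in three stages:

1. **Purity per sample.**  Clonal segments have integer tumour copy
   number, so segment copy numbers cluster at
   $\{2-p,\,2,\,2+p,\,2+2p,\dots\}$.  The estimate is the candidate
   purity whose expected peak grid best matches the peaks of a kernel
   density estimate of the segment values, aggregated over a range of
   smoothing bandwidths (details below).
2. **Subclonal segments and sample order.**  After purity correction
   ($\hat C^{(T)}_{ij} = (C_{ij}-2)/\hat p_i + 2$) the change versus
   baseline is $\Delta_{ij} \approx r_i\,(C^{(S)}_j - C^{(A)}_j)$:
   zero for clonal segments and proportional to $r_i$ for subclonal
   ones.  Low-spread segments are filtered as clonal; an exhaustive
   search over sample permutations (baseline fixed first) finds the
   order under which the most segments change *quasi-monotonically* —
   successive differences all above $-\varepsilon$ or all below
   $\varepsilon$ — and those segments are called subclonal, the rest
   unstable.
3. **Subclonal ratio.**  Since $C^{(S)}-C^{(A)}$ is a nonzero integer,
   subclonal $\Delta$ values live on the lattice
   $\{\dots,-2r_i,-r_i,r_i,2r_i,\dots\}$.  The absolute ratio is the
   shared mean parameter of a Gaussian mixture with means constrained
   to that lattice and a single shared variance.  Relative ratios
   (against the last sample of the optimal order, the one with the
   largest subclone) are medians of segment-wise ratios
   $\Delta_{ij}/\Delta_{Nj}$ and are more robust at low signal.

## The synthetic-data generator

`generate_truth()` / `render_bins()` emulate the statistical structure
of such longitudinal series and are the basis of all validation:

* 80 segments per dataset, lengths uniform in 120–800 bins of 50 kb
  (one pseudo-chromosome; coordinates only matter for length filters);
* ancestral copy numbers drawn from $\{1..5\}$ with weights
  $(1{:}4{:}2{:}1{:}1)/9$, subclonal offsets from $\{-2..2\}$ with
  weights $(1{:}2{:}8{:}2{:}1)/14$ — diploid/near-diploid states and
  "no change" dominate; the exact weights are unpublished for real
  tumours and are exposed as arguments;
* per-sample purity uniform in $(0.04, 0.45)$ and subclonal ratio in
  $(0.05, 0.8)$, baseline ratio below $0.04$; 2.5–15% of segments
  unstable, with $\zeta_{ij}$ uniform in $C^{(A)}_j \pm 1.5$ per
  sample;
* per-bin Gaussian noise with standard deviation
  $f(\sigma, C) = \sigma \cdot s_0 \cdot \sqrt{\max(C, 0.5)/2}$ —
  increasing in the local copy number (higher states have higher
  read-count variance), linear in the dimensionless noise level
  $\sigma$.  The calibration constant $s_0 = 0.4$ makes $\sigma = 1$
  correspond to a raw-bin standard deviation of 0.4 at diploid copy
  number, i.e. segment-level standard deviations of 0.014–0.037 over
  120–800 bins — the scatter typical of ~0.5–1x lpWGS profiles on
  50 kb bins.

What the generator does **not** emulate: GC/mappability artefacts and
wave bias, multi-chromosome karyotypes, segmentation errors by the
upstream caller (the rendered segmentation is the true one plus noise),
and read-level sampling.  Passing tests therefore demonstrate the
estimator's behaviour under the model's own noise assumptions, not
robustness to upstream artefacts; on real data those are handled by the
upstream caller's blacklists and by the curation step.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `ploidy_factor` | 1 (2 for diploid=1 callers) | multiplicative rescale so diploid sits at 2 |
| `min_length_bp` | 6 Mb | shortest retained ensemble segment |
| `trim` | 0.025/tail | raw-bin trimming before the segment-mean refit |
| `candidate_grid` | 0.05–1.00, step 0.005 | purity candidates; below ~5% peaks are unresolvable |
| `bw_multipliers` | 0.5–2.5 × base, step 0.25 | bandwidth sweep of the peak search |
| `purity_floor` | 0.10 | samples below are excluded (0.20 advisable at ~5M reads) |
| `epsilon` | 0.03 (0.02–0.05 sensible) | quasi-monotonicity tolerance, in CN units |
| `min_keep` | 10 | minimum segments retained by the clonal filter |
| `sd_grid` | 0.005–0.2, step 0.005 | candidate clonal-spread thresholds |
| `max_multiple` | 2 | largest modelled copy-number change (components ±r, ±2r) |

## Numerical and design choices

**Peak detection.**  Peaks are strict local maxima of a
length-weighted Gaussian KDE, parabolically interpolated between grid
points (2048-point grid), so peak locations are far more precise than
the grid spacing.  Long segments carry more evidence; weighting by
segment length keeps short noisy segments from seeding spurious peaks.

**Base bandwidth.**  The Sheather–Jones bandwidth adapts to the
multimodal cluster structure; Silverman's rule-of-thumb targets
unimodal densities and, on these data, over-smooths low-purity samples
until every peak merges.  Two guards apply: the base bandwidth is
capped at half the smallest candidate purity (a wider kernel cannot
resolve the grid whose spacing *is* the purity), and on heavily tied
(noise-free, discrete) data — where Sheather–Jones is unreliable — the
bandwidth is placed below the smallest gap between distinct values.

**Error aggregation.**  For each bandwidth, the candidate error is the
summed squared distance from each expected peak $2 + p(C-2)$,
$C \in \{1..5\}$, to the nearest observed peak, with the single worst
term dropped (`allow_missing = 1`): a genome simply lacking its
highest state must not penalise the candidate that generated every
other peak, which otherwise systematically favours the $p/2$
sub-harmonic.  Kernels resolving fewer than 3 peaks are excluded
(their error curves are degenerate and collapse towards the smallest
candidate), the median across the remaining bandwidths is taken
(robust to the residual degenerate curves, unlike the mean), and the
aggregate is divided by the squared candidate: the squared-distance
error is absolute-scale, so the densely packed expected grid of a
small candidate matches observed peaks by chance and otherwise drags
the argmin to the grid floor at high noise.

**Harmonic ties.**  A subclone at ratio $\approx 1/2$ places genuine
peaks on the half-lattice, making $p/2$, $p$ and $3p/2$ all exact peak
matches.  Candidates within a noise floor of the minimum
($\max(2\times\text{min}, 10^{-4})$ after normalisation) are treated
as tied and resolved by peak mass: under the true purity the
single-gain/loss positions $2 \pm p$ carry heavy clonal peaks, while
the harmonics place those states on light subclonal mass.  Exact
residual ties go to the larger purity.

**Refinement.**  The grid argmin is polished within one grid step by
minimising the error of the most concordant kernel (minimum across
informative bandwidths) — a fine scan of 201 points followed by a local
optimiser, since the objective is piecewise quadratic with several
local dips.  On noise-free data this recovers the purity to ~$10^{-5}$,
which matters because purity error propagates multiplicatively into
$\Delta$ and hence into the ratio estimates.

**Cross-sample consistency.**  A single-sample estimate can land on an
alias of the truth (e.g. $p/2$).  Jointly, such a sample betrays
itself: on clonal segments the purity-corrected deviation from
diploid must agree with the baseline's, so the robust slope of
$\hat C^{(T)}_i - 2$ against $\hat C^{(T)}_{\text{baseline}} - 2$
(segments with baseline deviation > 0.3; median of ratios) equals the
ratio of scale errors.  The baseline anchors the check because, with
no subclone, it offers no sub-lattice to alias to.  Purities are
rescaled by the slope when it is outside $[0.8, 1.25]$ *and* more than
three robust standard errors from 1 (the latter prevents false
triggers at high noise).  This correction, applied before the $\Delta$
computation, removes the dominant failure mode of downstream ratio
estimation.

**Clonal filter and order search.**  The spread threshold is chosen by
scanning a grid and maximising the proportion of retained segments
classified subclonal under the best order, subject to at least
`min_keep` retained; thresholds tie towards retaining more segments.
The quasi-monotone sequence starts at the baseline's implicit
$\Delta = 0$.  For a single non-baseline sample the spread across
samples is undefined and $|\Delta|$ is used instead.  Count ties among
permutations prefer orders along which the mean $|\Delta|$ of
subclonal segments increases (an *emerging* clone), then the order
closest to chronology (fewest inversions) — longitudinal series are
expected to evolve smoothly.

**Constrained mixture.**  The likelihood is maximised by an EM over
component weights and the shared variance nested in a grid search over
$r$ (0.01–1.00, step 0.005; the profile likelihood is multimodal),
followed by a continuous local refinement.  The shared standard
deviation is floored at $10^{-4}$ so noise-free lattice data keeps a
finite likelihood.  Convergence requires the EM tolerance
($10^{-8}$ within 500 iterations) and $r$ away from the grid edges.
The 95% interval is $r \pm 1.96\,\hat\sigma/\sqrt{m}$ with $m$ the
effective number of values in the $\pm r$ components — the simplest
reading of an interval "based on the shared variance"; it is validated
for reasonable coverage on simulation, not claimed to replicate any
particular prior construction.  Segments are weighted equally: each is
one alteration event, regardless of length.  When the direct fit fails
to converge for a sample, the two-step estimate (relative ratio times
the reference sample's fitted $r$) is reported instead, and the method
used is recorded per sample.

**Curation.**  The "mean of a normal distribution fitted to the
trimmed raw values" is the sample mean of the values inside the
2.5%/97.5% quantiles — the Gaussian maximum-likelihood mean — with a
fallback to the untrimmed mean below 10 usable bins.  The trim is per
tail; total-mass trimming would halve the nominal fraction.

**Degenerate inputs.**  All-equal segment values yield a single peak
and a flagged grid-floor purity; an all-diploid sample is flagged as
uninformative rather than assigned a fabricated purity; a baseline
below the purity floor is an error (every downstream quantity is
defined relative to it); two-sample series run with a prominent
warning since subclonal and unstable segments are then
indistinguishable.

## Known limitations

* Purities below ~5% are unresolvable by construction of the candidate
  grid; samples below the 10% floor are excluded, as their corrected
  values would inject large errors downstream.
* A subclone at ratio near 1/2 (or 1/3) with many private alterations
  creates a genuine half- (third-) lattice; the mass tie-break and the
  cross-sample check resolve most but not all such samples.
* At noise levels around $\sigma = 2$ (raw-bin sd 0.8 at diploid) the
  per-segment $\Delta$ noise after purity correction reaches the size
  of the subclonal signal itself; the sample order, and with it the
  reference for relative ratios, becomes unreliable, and relative
  errors in that regime are dominated by occasional wrong-reference
  datasets.  This is the regime the method's own guidance excludes
  (≥10M reads recommended).
* A single dominant subclone is assumed; concurrent subclones are not
  deconvolved, and the baseline's residual subclone fraction (up to
  0.04 in the generator) biases all ratios down by about that amount.

## Validation scale

The test suite validates recovery on 200 samples (40 datasets) for
purity at $\sigma \in \{0.5, 1\}$, a 120-dataset sweep over
$\sigma \in \{0, 0.5, 1, 2\}$ for ratio accuracy and noise
monotonicity, 100 random instances for the order-search oracle
equivalence, and 36 datasets for the sample-count effect.  The
acceptance script scales the purity check to 1000 samples.  These
sizes give stable medians and binomial margins of a few percent while
keeping a full run in minutes on one core.
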