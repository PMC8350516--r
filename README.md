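# cnatrace

Tracking an emerging tumour subclone from longitudinal low-pass WGS
copy-number profiles of cell-free DNA.

## What it does, and for whom

Serial liquid biopsies sequenced to ~0.1–1x give depth-based
copy-number profiles but no usable B-allele frequencies and usually no
matched normal. For groups monitoring treatment response or emerging
resistance from such data, cnatrace jointly analyses a patient's
longitudinal samples to estimate

* the **tumour fraction** (purity, $p_i$) of each sample, and
* the size of a single **emerging subclone** (subclonal ratio, $r_i$),
  together with the genomic segments that define it.

The measured copy number of segment $j$ in sample $i$ is modelled as a
three-population mixture of normal cells, ancestral tumour cells
(integer copy number $C^{(A)}_j$) and a subclone ($C^{(S)}_j$):

$$C_{ij} = 2 + p_i\left[(1-r_i)C^{(A)}_j + r_i C^{(S)}_j - 2\right] + \varepsilon_{ij}.$$

Purity is estimated per sample from the peaks of the segment
copy-number distribution (clonal integer states put peaks at
$2-p, 2, 2+p, 2+2p, \dots$), matched to that grid over a sweep of
kernel bandwidths. Purity-corrected changes versus a designated
baseline sample, $\Delta_{ij} \approx r_i (C^{(S)}_j - C^{(A)}_j)$,
separate clonal (≈0), subclonal (quasi-monotone along the sample order
that an exhaustive permutation search recovers) and unstable segments.
The subclonal ratio is then the constrained shared mean of a Gaussian
mixture with components at $\pm r, \pm 2r$ fitted to the subclonal
$\Delta$ values; relative ratios against the largest-subclone sample
(medians of segment-wise $\Delta$ ratios) are reported alongside, being
more robust at low signal.

A synthetic-data generator with the same statistical structure
(segment lattice, population mixing, copy-number-dependent noise) is
included and drives all validation.

## Worked example

```r
library(cnatrace)

ds <- simulate_dataset(sigma = 0.5, seed = 42, purity_range = c(0.1, 0.45))
ds$truth
#> <synthetic_truth> 80 segments x 5 samples (sigma = 0.5, seed = 42)
#>   purity: 0.117 0.166 0.444 0.215 0.160
#>   subclonal ratio: 0.029 0.064 0.305 0.072 0.700 (baseline first)
#>   segments: 54 clonal / 23 subclonal / 3 unstable

an <- analyze_cna(ds$profiles, baseline_id = "S1")
an
#> <cna_analysis>
#>   80 segments, baseline S1
#>   purity:
#>     S1  0.116
#>     S2  0.165
#>     S3  0.444
#>     S4  0.215
#>     S5  0.158
#>   order: S1 > S2 > S4 > S3 > S5
#>   subclonal ratios:
#>     S2  relative 0.033  absolute 0.034 [0.013-0.054] (direct)
#>     S3  relative 0.380  absolute 0.275 [0.216-0.334] (direct)
#>     S4  relative 0.094  absolute 0.061 [0.019-0.103] (direct)
#>     S5  relative 1.000  absolute 0.689 [0.605-0.773] (direct)
```

Reading the output: every purity lands within ~0.005 of the generating
value. The recovered order S2 → S4 → S3 → S5 sorts the non-baseline
samples by their true subclonal ratio, S5 (the largest subclone,
true $r = 0.70$) is the reference for the relative ratios, and the
absolute estimates track the true ratios net of the baseline's small
residual subclone (true $r_1 = 0.029$): e.g. S3's estimate 0.275
against $0.305 - 0.029 = 0.276$. The bracketed intervals are 95%
confidence bands from the constrained mixture; a `two_step` tag would
mark a sample whose direct mixture fit did not converge and whose
absolute value is instead the relative ratio times the reference's
fitted $r$.

`write_report(an, "out/")` writes the purity, segment-classification
and ratio tables as TSV plus an `order.json` with the permutation
search record and full parameter provenance.
`annotate_segments(an$segment_matrix, "genes.bed")` reports gene
overlaps of (subclonal) segments from a BED file. A command-line front
end with `simulate` / `run` / `benchmark` / `annotate` subcommands is
installed at `inst/cli/cnatrace.R`.

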