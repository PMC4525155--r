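---
title: "Quantitative ChIP-seq enrichment profiling with rertools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ChIP-seq enrichment profiling with rertools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rertools)
```

## The model

ChIP-seq measures where a chromatin protein sits on the genome by
sequencing immunoprecipitated DNA fragments alongside an input (no-IP)
control. `rertools` quantifies occupancy as the **relative enrichment
ratio (rER)**: on a fixed 10-bp bin grid, each aligned read contributes
one count to the bin holding the midpoint of its strand-aware extension
to the library fragment length (150 bp by default, the typical
sonication shear size). ChIP and input counts are smoothed with a
100-bp centered moving mean, bins whose smoothed input depth falls
below 20% of the genome-average input depth are masked, the ratio
smoothed-ChIP/smoothed-input is taken at unmasked bins, and the track
is divided by its unmasked mean so the genome-wide average rER is
exactly 1. An rER of 2 therefore means twice the genome-average
IP efficiency at that site, a scale that can be checked directly
against ChIP-qPCR percent-input measurements.

Where input sequencing is too shallow for a stable ratio (the typical
situation for large mammalian genomes), profiles are expressed instead
as the **normalized read intensity** `R_x = count * (1000/bin_size) *
(1e6/total mapped reads)`, a per-kilobase, per-million (modified RPKM)
intensity.

### Peak calling

Binding sites are maximal runs of unmasked bins exceeding a score
threshold: in rER mode, rER > `ethre` (2 for moderate, 5 for strong
enrichment) together with a relative ChIP-intensity floor `ithre`
(genome-mean units) that suppresses high-ratio calls supported by
almost no ChIP coverage; in intensity mode, `R_x > ipm` (7) together
with an input-exceedance guard (ChIP R_x must exceed twice the input
R_x) that removes pseudo-binding signals present in the input itself.
Runs separated by at most `merge_gap` (100 bp) of sub-threshold
*unmasked* bins are merged — masked bins never end up inside a peak —
and runs narrower than `min_width` (100 bp, one smoothing window) are
discarded. The summit is the leftmost bin attaining the maximum score,
so output is deterministic under ties.

The false discovery rate is estimated by **sample swap**: the identical
calling pipeline is run with ChIP and input exchanged, and the FDR
estimate is the swapped peak count over the forward peak count (a
`max(1, .)` denominator makes the no-peak case 0). `threshold_scan()`
walks an ascending `ipm` grid and picks the smallest threshold whose
swap FDR meets the target (5%).

### qPCR anchoring and cross-sample rescaling

Total-read normalization cannot compare samples whose global ChIP
efficiency differs (for example drug-treated versus untreated cells),
because the mean-1 constraint absorbs any genome-wide change. The
package therefore treats ChIP-qPCR percent-input values measured at a
panel of anchor amplicons as the external standard. The representative
rER of an amplicon is the **minimum** rER over its unmasked bins.
`fit_anchor_regression()` fits percent-input on representative rER by
zero-intercept least squares (`slope = sum(q*r)/sum(r^2)`):
a purely multiplicative rescaling can only superimpose regression
lines through the origin, so an intercept would make the alignment
target unattainable. `rescale_profile()` multiplies the non-reference
profile by `slope_other/slope_ref`, after which its anchor regression
line coincides with the reference sample's; the mean-1 property is
intentionally broken at this point and the profile is flagged
`externally_scaled`. Validation requires anchor correlation r >= 0.95
before a rescaling is trusted.

### Gene-centric analytics

TSSs and TTSs are inferred from CDS coordinates plus UTR lengths;
genes lacking UTR annotation fall back to genome-average UTR lengths
of 293 bp (5') and 430 bp (3'). Metagene profiles average a track
from 1 kb upstream of the TSS to 1 kb downstream of the TTS with every
gene body rescaled to a common number of positions
(fractional-overlap-weighted averaging of source bins; minus-strand
genes reversed; masked bins dropped per gene). The same per-gene
vectors, sorted by descending gene-body mean, form the enrichment
heat map. Peak-to-TSS distance is 0 when a TSS lies inside the peak
and otherwise the summit-to-nearest-TSS distance; the TSS-proximal
fraction uses a ±5-kb window, whose genome share is computed as a
merged interval union. CpG-island association compares the CGI-linked
fraction of peak-associated TSSs with that of all TSSs as an odds
ratio, and gene-set overlaps are tested with the one-sided
hypergeometric (Fisher) tail.

## The synthetic-data generator

Real genomes and read archives are deliberately out of scope; every
stage is instead exercised against a generator whose ground truth is
known exactly.

* **Occupancy.** Per-bin true occupancy is
  `basal + sum_g gain * expression_g * shape_g`, normalized to mean 1
  over mappable bins. In `yeast_tts` mode the shape ramps linearly from
  0 at the TSS to 1 at the TTS and decays over 300 bp beyond it —
  transcription-coupled occupancy that accumulates toward termination
  sites. In `human_tss` mode it is a triangular spike of 500-bp
  half-width at the TSS, the promoter-proximal pattern. The linear
  occupancy-versus-expression gain is an assumption of the generator,
  not an estimate: the quantitative occupancy–expression relationship
  is unknown, and linearity is the simplest shape consistent with
  expression-ranked binding.
* **Expression.** Mitotically active genes (a Bernoulli fraction,
  default 0.4) draw log-normal(0, 1) expression; the remainder are
  silent. In a mitotic arrest most genes carry essentially no
  polymerase, and without the silent class the low-expression stratum
  would still show a visible occupancy ramp, which would misrepresent
  the flat profile expected of poorly expressed genes.
* **Counts.** ChIP counts are Poisson with intensity
  `chip_depth * occupancy / n_bins`; input is uniform Poisson. Counts
  are drawn per bin rather than per read — equivalent under Poisson
  thinning and far cheaper; `reads_from_counts()` emits a read-level
  BED realization for I/O testing only.
* **Mappability.** Unmappable regions are contiguous blocks with
  geometric lengths (mean 500 bp), placed to hit the configured bin
  fraction exactly (default 2%, matching the few-percent of a compact
  genome typically lost to input coverage), so masking behaves like
  real mappability holes rather than salt-and-pepper dropout.
* **qPCR.** Anchor readouts are `qpcr_scale` times the true mean
  occupancy over the amplicon, with multiplicative Gaussian noise
  (s.d. 5%) drawn independently for two technical replicates.

Defaults describe a 2-Mb, 100-gene genome at 1e6/1e6 ChIP/input reads
— deep enough that a top-decile gene (>= 5-fold true enrichment) is
recovered essentially perfectly, which is what the recovery tests
assert. What passing tests show is that the *pipeline arithmetic* is
correct and that the caller recovers planted structure under Poisson
noise; they do not certify behavior under GC bias, fragment-size
artifacts, copy-number variation or antibody cross-reactivity, none of
which the generator models.

## Numerical and design choices

* **Smoothing before the ratio.** The 100-bp smoothing is applied to
  ChIP and input counts separately, then the ratio is taken. Smoothing
  the ratio itself would first require defining 0/0 bins; smoothing
  counts avoids division noise entirely, and for a window much wider
  than the bin the two orders differ negligibly.
* **No pseudocounts.** Zero-input bins are handled by the masking rule
  (the cutoff is strictly positive whenever any input exists), never by
  an additive constant, keeping rER a pure ratio.
* **Masking precedes normalization**, and the mean-1 constant is
  computed genome-wide over unmasked bins, not per chromosome.
* **Edge handling.** The moving mean shrinks at chromosome ends (mean
  over available bins); chromosomes never mix. Window widths round up
  to an odd number of bins so the window is centered.
* **Coordinates.** 0-based half-open everywhere internally (BED
  convention); GFF3 conversion happens only in the I/O layer.
* **Determinism.** Summit ties break leftmost; expression quartiles use
  greedy ceiling sizes (10 genes split 3/3/2/2) with ties broken by
  gene id; correlation-plot categories resolve overlaps by the fixed
  priority centromere > rDNA > tRNA.
* **Degenerate inputs** are errors, not silent results: all-masked
  profiles, zero-total tracks, fully masked amplicons or genes, fewer
  than 3 usable anchors, constant-rER anchor sets.

The property suite sizes are chosen to keep the full test run in tens
of seconds: oracle equivalence uses 200 random arrays of up to 1e4
bins, recovery and shape checks use the default 2-Mb genome, and the
exhaustive overlap-test oracle enumerates universes up to 15 genes.

## Limitations

* No local-lambda background model, broad/narrow dual calling or
  replicate IDR; the caller is a faithful threshold-contiguity scheme.
* No GC-bias correction and no fragment-level simulation; read
  placement enters only through the extended-fragment midpoint rule.
* The swap estimator is a global FDR summary, not a per-peak q-value.
* Expression values are inputs; the package does not quantify RNA-seq.
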