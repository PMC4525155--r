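# rertools

Quantitative ChIP-seq enrichment profiling for compact genomes, built
around the **relative enrichment ratio (rER)**: the smoothed per-bin
ratio of ChIP to input read density, normalized so its genome-wide
average over well-covered bins equals 1. The package was written for
studies that profile mitotic chromosomal proteins (condensin, RNA
polymerase II) and need profiles that are not merely shaped correctly
but *quantitatively* correct — validated against, and rescaled across
samples by, ChIP-qPCR percent-input measurements.

For a genome binned at width `b` with smoothed ChIP counts `c_i` and
smoothed input counts `n_i`, with bins masked where
`n_i < 0.2 * mean(n)`:

    rER_i = (c_i / n_i) / mean_{unmasked}(c / n)

Low-depth (human-style) profiles use the modified-RPKM intensity
`R_x = count * (1000/b) * (1e6/total reads)` instead. On top of these
tracks the package provides:

* threshold-contiguous **peak calling** (rER mode: `ethre`/`ithre`;
  intensity mode: `ipm` with an input-exceedance guard) with
  sample-swap FDR estimation and threshold scanning;
* **qPCR anchoring**: zero-intercept regression of percent-input on
  representative (minimum) amplicon rER, profile validation
  (r >= 0.95), and multiplicative cross-sample rescaling;
* **gene analytics**: TSS/TTS inference from CDS + UTR lengths
  (defaults 293/430 bp), length-scaled metagene profiles and heat
  maps, gene-level binding amounts, peak-to-TSS distances,
  genome-fraction of TSS windows, CpG-island association odds ratios,
  expression stratification and hypergeometric gene-set overlap tests,
  genome-wide track correlation;
* a **synthetic-data generator** with exact ground truth
  (expression-proportional occupancy with TTS-biased or TSS-spike
  shapes, Poisson counts, mappability dropouts, noisy qPCR anchors),
  so every stage is testable without external downloads;
* text-format I/O throughout: BED/SAM in; bedGraph, fixedStep wiggle,
  BED, GFF3, TSV and JSON out.

## Worked example

```r
library(rertools)

cfg <- sim_config(seed = 42)          # 2-Mb genome, 100 genes, 1e6/1e6 reads
ds  <- simulate_dataset(cfg)

profile <- compute_rer(ds$chip, ds$input)
profile
#> <rer_profile> 979925/980269 ChIP/input reads, window=100 bp,
#>               mask<20% input, 1.8% bins masked
mean(unmasked_values(profile$track))
#> [1] 1

peaks <- call_peaks_rer(profile, peak_config(ethre = 2, ithre = 2))
nrow(peaks)
#> [1] 35
head(peaks, 3)
#>   chrom start   end summit max_score mean_score mode
#> 1  chrI 24560 24710  24565     2.141      1.990  rer
#> 2  chrI 24820 25670  25355     4.256      2.990  rer
#> 3  chrI 80030 81920  81515     7.884      4.513  rer
estimate_fdr_swap(ds$chip, ds$input)$fdr
#> [1] 0

fit_anchor_regression(ds$anchors, profile)
#> <scaling_fit> slope=2.808 %input per rER, r=0.9998, n=12
```

The mean rER is 1 by construction (that is the normalization
contract). The 35 called peaks sit on the simulated high-expression
gene bodies; swapping ChIP and input calls nothing, so the estimated
FDR is 0. The anchor fit says one rER unit corresponds to 2.8%
input with near-perfect correlation, which is what licenses using the
slope as a cross-sample scaling constant. Gene-centric summaries of
the same run: the top-expression-decile metagene rises from a flank
level of 0.86 to a maximum of 20.4 near the gene 3' end (position
89/100 of the scaled body), and every called peak lies within 5 kb of
a TSS.

`run_pipeline(cfg, "outdir")` executes
simulate → profile → peaks → calibrate → analyze end to end and writes
all artifacts (tracks, mask, peaks, gene tables, anchor fit, reports,
provenance JSON) to a directory.

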