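# maccr — chromatin accessibility from MNase titration series

A single micrococcal nuclease (MNase) digest measures nucleosome
*occupancy* — how much of a locus is protected — but not *accessibility* —
how easily that protection is released. `maccr` implements the MACC (MNase
accessibility) approach: digest the same chromatin at several MNase amounts
(e.g. 1.5, 6.25, 25 and 100 U), sequence paired-end fragments from each
digest, and score every genomic bin by how its normalized fragment
frequency responds to digestion depth.

For bin *i* with normalized frequencies *y*<sub>ij</sub> at concentrations
*c*<sub>j</sub>, the MACC score is the least-squares slope

> MACC<sub>i</sub> = slope of *y*<sub>ij</sub> on *x*<sub>j</sub> = −ln *c*<sub>j</sub>

so loci whose yield grows as digestion gets **lighter** (fragile
nucleosomes, non-histone footprints — "open" chromatin) get positive
scores, and loci that need deep digestion to release fragments get negative
scores. Computing the score from whole-chromatin digests gives **c-MACC**;
from histone-ChIP-enriched digests, **h-MACC** (histone-mediated protection
only). Around this estimator the package provides the full analysis stack:

* fragment I/O (BAM / BEDPE / fragment BED), insert-size and
  anomalous-position filtering, midpoint binning, per-million ×
  genome-size normalization, pooled occupancy;
* `(1 − P)` significance weighting (Pearson or exact Mann–Kendall),
  LOWESS GC-bias correction (optionally CpG-island-stratified), median
  shifting;
* two-state Gaussian HMM segmentation into accessible / inaccessible
  domains (compiled Baum–Welch + Viterbi), with within-chromosome shuffling
  as the null for run statistics;
* strict local-maximum peak calling; classification of bins into
  **group 1** (high c-MACC, near-zero h-MACC: non-histone protein
  protection) and **group 2** (high c-MACC and h-MACC: accessible
  nucleosomes); ChIP Z-score site calling and randomized peak–site overlap;
  annotated-region enrichment;
* site-centered average profiles (linear interpolation + 40-bp smoothing),
  track correlations, UPGMA clustering of per-sample profiles;
* a synthetic titration simulator with known per-bin ground truth
  (response exponents, GC field, planted NHP and fragile-nucleosome loci,
  three pools: chromatin, histone-ChIP, ChIP-input).

It is aimed at epigenomics groups running MNase titrations who want
occupancy and accessibility from one assay, and at methods developers who
need a fully testable reference implementation.

## Worked example

Simulate a 10,000-bin titration with known truth, score it, and segment the
genome:

```r
library(maccr)

truth  <- simulate_genome(10000, seed = 1)
sim    <- simulate_titration(truth, depth = 50, seed = 2)
series <- build_series(sim$fragments$chromatin, sim$chrom_sizes,
                       sim$bin_size)
series
#> <titration_series> k = 4 points at 1.5/6.25/25/100 U; 10000 bins of 300 bp

cmacc <- median_shift(fit_macc(series))
cmacc
#> <macc_track> 2 chromosome(s), 10000 bins of 300 bp (macc_slope, normalized)
#>   defined bins: 10000; value range: [-1.271, 1.836]
#>   c-MACC, median-shifted

model <- fit_two_state_hmm(cmacc, n_restarts = 5, seed = 3)
model
#> <hmm_model> two-state Gaussian HMM
#>   accessible:   mean +0.7547, sd 0.3517, stay prob 0.9630
#>   inaccessible: mean -0.1397, sd 0.3013, stay prob 0.9916
#>   log-likelihood: -3097.421

viterbi_segment(model, cmacc)
#> <state_segmentation> 139 runs over 2 chromosome(s)
#>   accessible coverage: 18.7%; median run lengths (bins): accessible=25, inaccessible=91

hmacc <- median_shift(fit_macc(build_series(sim$fragments$histone_chip,
                                            sim$chrom_sizes, sim$bin_size),
                               provenance = "h-MACC"))
assign_groups(cmacc, hmacc)
#> <group_assignment> group1 (NHP-like): 200 bins; group2 (accessible nucleosome): 449 bins
#>   thresholds: c-MACC > 0.6819; h-MACC < 0.02564 | > 0.8702
```

Reading this output: the fitted MACC distribution splits into a sticky
accessible state (higher emission mean, ~19% of bins — accessibility is the
minority state) and an inaccessible state; the long median run lengths (25
and 91 bins, i.e. 7.5 and 27 kb) reflect domain-scale clustering of
accessibility. The 200 group-1 bins are exactly the simulator's planted
non-histone-protection loci — strong chromatin accessibility signal with no
histone-ChIP signal — and group 2 captures the planted fragile nucleosomes.

Real data enter through a YAML run configuration (sample table with file,
MNase amount, pool; genome sizes/FASTA/annotations; parameters) driving
`run_pipeline()`, or through the thin CLI in `inst/exec/macc`
(`macc simulate`, `macc run`). Outputs are bedGraph tracks, BED
segmentations/peaks/groups, TSV summaries and a JSON-lines log, each with a
provenance header (config hash, seed, version).

The methods vignette (`vignettes/macc-methods.Rmd`) documents the model,
the parameter defaults and the design decisions in detail.

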