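---
title: "Measuring chromatin accessibility from MNase titrations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromatin accessibility from MNase titrations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maccr)
```

## The measurement model

A single micrococcal nuclease (MNase) digest conflates two different
properties of chromatin: how much of a locus is protected (occupancy) and how
easily the protecting particle is released (accessibility). A titration
series — several digests of the same chromatin at increasing MNase amounts,
e.g. 1.5, 6.25, 25 and 100 U — separates them. Two opposite responses are
possible at a locus:

* **scenario 1 ("open")** — fragment yield is highest under the lightest
  digestion and falls as MNase increases: the protecting particles are
  accessible and are degraded by deeper digestion (fragile nucleosomes,
  non-histone protein footprints);
* **scenario 2 ("closed")** — yield rises with MNase amount: deep digestion
  is needed before the locus releases mononucleosome-sized fragments.

`maccr` quantifies this response per genomic bin as the **MACC score**: the
ordinary-least-squares slope of the normalized fragment frequency against
`x = -ln(concentration)`. The sign convention follows from the abscissa:
signal rising as MNase *decreases* (scenario 1) gives a positive slope, so
positive MACC means accessible. The log scale keeps an exponential titration
series evenly spaced. The one free constant in this construction — the log
base — only rescales every slope by `ln(new)/ln(old)`; we default to the
natural log and expose `log_base`.

Scores computed from whole-chromatin digests are called c-MACC; the same
computation on histone (H3/H4) ChIP-enriched digests gives h-MACC, which
responds only to histone-mediated protection. Comparing the two separates
nucleosomal from non-histone protection (below).

## From reads to tracks

Fragments are reconstructed from properly paired reads (one fragment per
pair, `[leftmost start, rightmost end)`), with insert sizes outside
50–500 bp discarded and, for alignment input, non-unique mappings removed by
a mapping-quality cutoff. Positions with tag counts above Z-score 7
(computed over positions carrying at least one tag; each fragment
contributes its two sequenced-tag endpoints) are treated as alignment
artifacts and the whole fragments touching them are removed. We resolve two
points the procedure leaves open: normalization uses the *post-filter*
retained library size, and anomalous positions remove whole fragments rather
than single tags (a fragment with one artifactual endpoint is itself
suspect).

Counts go into non-overlapping bins — 300 bp by default, 500 bp recommended
for mammalian genomes — by fragment **midpoint**: with mononucleosome-scale
fragments and 300-bp bins the midpoint is the least biased single-bin
assignment. Each titration point is normalized to fragments per million and
additionally by `genome size / 100 Mb` so tracks are comparable across
organisms. A bin is excluded only when it has zero reads at *every*
titration point (the stricter any-point rule is available via
`missing_rule = "any_zero"`). Replicates are pooled at the fragment level
before normalization.

The per-bin mean of the normalized frequencies over all titration points
(`pool_occupancy()`) approximates a conventional single-digest nucleosome
occupancy map and anchors the occupancy-vs-accessibility quadrant analysis
(`classify_occupancy_accessibility()`).

## Significance weighting and GC correction

With k = 4 points the per-bin fit is coarse; an optional adjustment
multiplies each score by `(1 - P)`, with P from either the Pearson
correlation t-test or the Mann–Kendall trend test (exact permutation null
for k ≤ 10 without ties, tie-corrected continuity-corrected normal
approximation otherwise). On simulated data at default depth the weighted
and unweighted tracks correlate at r > 0.99, so weighting is off by default;
n = 4 Pearson P values are coarse and should be read as ordering, not
calibrated probabilities.

MNase prefers AT-rich cleavage sites, which couples apparent accessibility
to base composition. The correction fits a LOWESS trend of MACC on per-bin
G+C fraction (span 0.3, fitted on a seed-controlled subsample of up to
10,000 bins and interpolated to the rest) and subtracts it, adding the
stratum's pre-correction mean back so the global level is preserved rather
than re-centered at zero. Two deliberate choices:

* **No robustifying iterations by default.** Robust LOWESS downweights
  large residuals, but in a MACC track the large residuals are the genuinely
  accessible and inaccessible bins. On simulated data with injected bias the
  robust fit underestimates the trend and leaves a residual score–GC
  correlation of ≈ 0.1, while the plain fit removes it to below 0.01;
  `iterations` remains configurable.
* **Correction at the score level**, not the count level: the bias model of
  interest is a GC-dependent distortion of the titration *response*, which
  lives on the slope scale.

For mammalian genomes, CpG islands have a qualitatively different sequence
composition; `stratify_cpg = TRUE` fits the correction separately inside and
outside islands. Strata with fewer than 100 defined bins are left
uncorrected with a warning.

Finally, c-MACC and h-MACC profiles are median-shifted so their genome-wide
medians are zero before any cross-profile comparison.

## Genome segmentation

Accessibility is spatially organized: bins with similar MACC cluster into
domains. A two-state hidden Markov model with one Gaussian emission per
state captures this; the state with the larger emission mean is "accessible".
Fitting is Baum–Welch EM over the maximal gap-free runs of defined bins,
treated as independent observation sequences — one genome-wide model, with
missing bins breaking sequences rather than being imputed, so no transition
is fabricated across unmappable regions. EM is initialized from a 2-means
split, run to a log-likelihood gain below 1e-6 (at most 500 iterations), and
the best of 10 restarts by likelihood is kept; everything is deterministic
given the seed. A single Gaussian per state is enough because MACC is a
continuous, roughly unimodal-per-state score. Decoding is by Viterbi; the
forward/backward/Viterbi recursions are compiled (Rcpp) with per-position
scaling.

Run-length statistics are compared against a null obtained by shuffling the
MACC profile within each chromosome (`shuffle_track()`), which preserves the
value distribution but destroys spatial clustering; observed runs longer
than shuffled runs indicate genuine domain structure.

## Peaks, group 1 and group 2

MACC peaks are bins whose c-MACC strictly exceeds both neighbors
(plateaus and bins adjacent to missing bins are ineligible). Bins are placed
into two sets using quantiles of the *positive*-score sub-distributions with
strict comparisons (inclusive linear-interpolation quantiles, R type 7):

* **group 1** — c-MACC above the 80th percentile of positive c-MACC scores
  and h-MACC below the 10th percentile of positive h-MACC scores: strong
  accessibility response without histone signal, the signature of
  non-histone protein (NHP) protection;
* **group 2** — the same c-MACC condition with h-MACC above the 90th
  percentile of positive h-MACC scores: accessible (fragile) nucleosomes.

A bin that is defined in c-MACC but received *no* histone-ChIP fragments at
any titration point has an undefined h-MACC under the exclusion rule; by
default such bins are treated as h-MACC = 0 (`missing_h = "zero"`), since
total absence of histone-protected fragments is the strongest form of the
low-h signature — exactly the situation at strong NHP footprints. The
alternative (`"drop"`) excludes them.

NHP-binding sites are derived from ChIP/input enrichment tracks transformed
to Z-scores with a threshold (bins with Z above it); when several profiles
exist for one protein, the one whose site counts vary least over Z in
2…5 (smallest coefficient of variation) is kept. Peak–site overlap is
evaluated on the bin grid (everything in this package lives on one grid, so
intersection is bin identity) against an expectation from re-placing the
same number of peaks uniformly over the defined bins, averaged over 10
randomizations. Genomic context uses a per-bin annotation with the priority
rule enhancer > promoter > 5'-gene > TES-proximal > gene body, strand-aware
1-kb TSS/TES windows (2 kb recommended for mammalian annotations), and
TSS-proximal regions overlapping other genes excluded.

## Profiles and clustering

Site-centered average profiles interpolate bin-center values linearly to
1-bp offsets, reverse minus-strand anchors, average over sites and smooth
with a 40-bp centered running mean truncated at the edges. Bin values are
anchored at bin centers — the natural choice for a quantity that is an
average over the bin — and the running window is unweighted. Correlations
between tracks (optionally within a region mask) are Pearson; heatmap cells
are `round(100 r)`. Per-sample profile matrices are clustered by UPGMA
(average linkage) on `1 - r`, with rows pre-sorted by label so leaf order is
deterministic under ties.

## The synthetic titration simulator

Every stage is validated against data with known truth, generated by
`simulate_genome()` + `simulate_titration()`. The genome model: domains with
geometric lengths (mean 20 bins) carry classes accessible / inaccessible /
neutral (fractions 0.2 / 0.2 / 0.6); each bin gets a response exponent
β — positive for accessible, negative for inaccessible, magnitude uniform in
[0.1, 0.3] — and a smooth GC field in [0.25, 0.75]. Small subsets of
accessible bins are flagged as NHP loci (2%) and fragile-nucleosome loci
(3%) with β in [0.3, 0.45]: the strongest responders, mirroring the fact
that group-1/2 sites are tail events (a few percent of bins). Expected yield
follows the log-linear model `λ = depth · exp(β (x − x̄))` with Poisson
counts — chosen because the MACC estimator is exactly the matched inference
for it, making parameter recovery a clean validation surface; over-digestion
loss is represented implicitly by the negative response, not mechanistically.
Mean-centering the abscissa keeps expected library sizes equal across points
for class-symmetric truths. Fragment lengths are N(150, 20²) truncated to
[50, 500] bp, N(110, 15²) at NHP loci (sub-nucleosomal footprints); the
histone-ChIP pool omits NHP-locus yield entirely, and the ChIP-input pool
mirrors chromatin.

GC bias is injected into the **response exponent**
(`β_eff = β + strength · 1.2 · (GC − 0.5)`), not as a per-bin level factor:
a factor constant across titration points would scale all four frequencies
equally and leave the score–GC correlation at zero, whereas sequence
preference in digestion manifests exactly as a composition-dependent
response to digestion depth — the bias the LOWESS step removes. At strength
1 this yields |r(MACC, GC)| ≈ 0.7 before correction.

Slope units: after per-million and genome/100 Mb scaling, a flat bin's
expected normalized level is `bin_size/100`, so for small β the fitted slope
estimates `(bin_size/100) · β`. Recovery analyses therefore divide fitted
slopes by `bin_size/100` to express them per unit relative yield; on that
scale the regression of fitted on planted β has slope ≈ 1.01 at depth 100
(the residual upward curvature of the exponential model over the 1.5–100 U
grid keeps it slightly above 1 for large |β|).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequence-level cleavage preference and read-level
error, overdispersion beyond Poisson, copy-number and mappability structure,
chromatin-state-specific fragment-length mixtures, and ChIP efficiency
variation. Defaults (depth 50 fragments/bin/point, 10,000 bins in the
bundled analyses) are desk-scale stand-ins for the ≥25 M read libraries of a
real titration.

## Numerical and degenerate-input conventions

* Zero-variance titration responses get slope 0 with P = 1.
* Quantile thresholds use inclusive linear interpolation (R type 7)
  throughout; partial terminal bins are retained in tracks but excluded from
  quantile computations.
* Anomalous-position Z statistics return "nothing flagged" under zero
  variance; ChIP Z-site calling warns and returns an empty set.
* HMM fitting refuses all-identical inputs and fewer than 100 defined bins;
  emission standard deviations are floored at 1e-6.
* Coordinates are 0-based half-open internally, BED conventions on output,
  1-based closed converted on GFF-style input.
* All randomness (EM restarts, shuffles, subsampling, randomized overlap,
  the simulator) flows from explicit integer seeds; reruns with the same
  configuration are bitwise reproducible for the deterministic stages.

## A compact example

```{r example, eval = FALSE}
truth <- simulate_genome(10000, seed = 1)
sim <- simulate_titration(truth, depth = 50, seed = 2)
series <- build_series(sim$fragments$chromatin, sim$chrom_sizes,
                       sim$bin_size)
cmacc <- median_shift(fit_macc(series))
model <- fit_two_state_hmm(cmacc, seed = 3)
segmentation <- viterbi_segment(model, cmacc)
segment_stats(segmentation)$coverage
```

## Known limitations

* P values at k = 4 are coarse; the `(1 - P)` weighting is a sensitivity
  check, not an inferential procedure.
* The two-state HMM imposes binary accessibility; gradients within domains
  are flattened into the state means.
* GC correction removes the *marginal* score–composition trend; a bias that
  interacts with accessibility class would be only partially removed.
* Group thresholds are distribution-relative (percentiles of positive
  scores); absolute group sizes are not comparable across datasets with very
  different signal-to-noise.
* The genome-size factor is the only cross-organism normalization; no
  attempt is made to calibrate absolute accessibility between species.
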