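---
title: "Permutation statistics and domain segmentation for insulator binding maps"
author: "insulatR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation statistics and domain segmentation for insulator binding maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulatR)
```

# Scope and model

`insulatR` analyses multi-factor genomic binding maps: per-factor site
interval sets, gene models with one or more transcription start sites
(TSS) per gene, probe-level signal tracks, CRM–target annotations and
genome sequence. Its statistical core is deliberately simple and
uniform: almost every question — "are sites enriched near TSS?", "do
they accumulate between divergent promoters?", "are they depleted
inside repressive domains?" — is answered by the same Monte-Carlo
recipe, so the assumptions are stated once here.

## Coordinates and the overlap criterion

Ranges are held in standard Bioconductor `GRanges` (1-based, closed);
conversion to and from the 0-based half-open BED/bedGraph conventions
happens only in the I/O layer. All *point* coordinates the package
reports — site midpoints, TSS, domain boundaries — are 0-based, so a
BED record `[100, 300)` has midpoint `floor((100+300)/2) = 200` and a
GFF gene `1001..2000(+)` has TSS 1000. Distances are identical under
either convention.

Two sites co-localise iff they lie on the same chromosome and their
midpoint distance is strictly below 250 bp. The midpoint of an
even-length interval is the floor — deterministic integer arithmetic.

## Single-linkage clustering

Multi-factor clusters are the connected components of the graph whose
edges are midpoint-overlap pairs, applied transitively. Because the
criterion is a 1-D distance, components are exactly the maximal runs of
sorted midpoints whose consecutive gaps are < 250 bp; the
implementation exploits this for linear-time clustering, and the test
suite checks it against an O(n²) union-find oracle. A factor occurring
twice in a component counts once in the cluster's signature.
Class assignment follows the signature: Class I iff it intersects
{BEAF-32, CP190, CTCF} without Su(Hw); Class II iff it contains Su(Hw)
without the trio; mixed signatures are reported as `both`, anything
else (e.g. GAF-only) as `other` — mixed clusters are reported, never
silently merged.

## The permutation null

The null hypothesis everywhere is uniform placement: per chromosome,
the observed number of sites is re-placed with midpoints uniform on
`[0, length)`, widths preserved, `n_sim` times (default 10,000;
tests and the pipeline typically use 1,000). For an observed count
statistic the package reports:

* `log2_enrichment = log2(observed / median(null))`, undefined
  (reported `NA`) when the null median is 0;
* a percentile interval from the 2.5 and 97.5 null percentiles, mapped
  to the log2 scale as `log2(observed / null_hi)` …
  `log2(observed / null_lo)` — the interval covers 0 exactly when the
  observation lies inside the central 95% of the null;
* two one-sided empirical p-values with a +1 pseudo-count,
  `p = (1 + #{null as-or-more extreme}) / (1 + n_sim)`. The minimal
  attainable p is `1/(1 + n_sim)` and no p can be 0 — a permutation
  scheme cannot justify smaller values.

**Discreteness.** Counting statistics are small integers, so ties
between the observed and null values are common and the reported
p-values are deliberately *conservative* (super-uniform): the
false-positive rate never exceeds the nominal level, but a raw
uniformity test (e.g. Kolmogorov–Smirnov) on these p-values will
reject even for a perfectly calibrated engine. Calibration checks in
the test suite therefore break ties uniformly (adding U(0,1) noise to
the integer counts before ranking), which restores exact
exchangeability; the reported p-values keep the conservative
convention. `PairEnrichment` objects retain their full null count
vector (`nullCounts()`) so users can run the same diagnostics.

## Feature selectors

* *Divergent promoters*: consecutive distinct TSS on opposite strands
  in divergent orientation (the minus-strand TSS left of the
  plus-strand TSS), 500–2,500 bp apart. "Between X and Y apart" is read
  inclusively throughout; convergent opposite-strand pairs do not
  qualify.
* *Adjacent promoters*: consecutive distinct TSS regardless of strand,
  1,500–20,000 bp apart; consecutiveness itself enforces "no
  intervening TSS".
* *Alternative promoters*: all pairs of distinct TSS of one gene.
* *Intervening counts* are strict: a site midpoint exactly on a pair
  endpoint is promoter-overlapping, not intervening.
* *Active promoters*: a TSS is active iff an H3K4me3 interval and a
  PolII interval overlap TSS ± 500 bp and at least one exon of the
  transcript overlaps an RNA interval. The ±500 bp window matches the
  package's promoter-proximal convention (the promoter split uses the
  TSS-to-500-bp-upstream interval, inclusive at both ends). Stratified
  pair analyses reuse the *same* permuted site sets across strata, so
  strata are directly comparable and the permutation cost is paid once.
* *CRM partition*: pairs are (CRM midpoint, nearest TSS of the target
  gene), (CRM midpoint, nearest other gene's TSS; equidistant ties
  resolve to the smaller coordinate) and adjacent CRM midpoints of the
  same gene.
* *Positional profiles* count each site once, at its nearest feature
  (not once per feature); the sign is flipped for minus-strand features
  so negative always means upstream in the feature's own orientation.
  Site category counts use midpoint precedence
  5′UTR > 3′UTR > exon > intron > intergenic, alongside the genomic
  base-pair fraction of each category for normalisation.

# Domain segmentation

The segmentation model is a Gaussian hidden Markov model, by default
with two states (background / domain):

* **Initialisation**: k-means on probe values (seeded, `nstart = 5`),
  uniform transitions with a 0.99 self-transition prior — broad domains
  imply sticky states — and states ordered by increasing mean.
* **Fitting**: Baum–Welch with scaled forward–backward recursions;
  the log-likelihood trace is exposed and is non-decreasing (an EM
  invariant the tests assert). Emission variances are floored at 1e-6
  of the data variance with a warning, which handles noiseless tracks.
* **Decoding**: Viterbi; maximal runs of the top-mean state become
  domains spanning first to last probe of the run; runs under
  `minLen = 1000` bp are dropped. Transitions are per *probe*, not per
  base pair — an approximation under irregular probe spacing that is
  exact for the evenly spaced tracks the generator emits.
* **Boundaries** are emitted at both domain edges, oriented so that
  signed distances are negative inside the domain; boundary/TSS
  co-occurrence is tested with Pearson's chi-squared on the 2×2 table
  over boundaries (site within 1 kb? TSS within 1 kb?), without
  continuity correction, reported as not computable when a marginal is
  zero. Syntenic-block analyses reuse the same three statistics with
  blocks as domains and internal block edges as boundaries.

# Meta-profiles and score summaries

Signal aggregation around midpoints uses 50-bp bins over ±3 kb and
averages over all (site, probe) pairs rather than per-site first: at
the uniform probe spacing the generator produces the two are
identical, and the pairwise form makes the promoter/non-promoter
partition exactly n-weighted-average-consistent with the whole-set
profile (a property test asserts this to 1e-9). Per-class conservation
summaries report the median and the *unscaled* median absolute
deviation (no 1.4826 consistency factor) of per-site mean scores.

# Motif statistics

* **Threshold from p-value**: the log2-odds score distribution of a
  random background sequence is computed exactly by column-wise
  convolution on a discrete score grid (resolution 1e-3 score units,
  configurable; the grid error is far below any realistic PWM
  precision). The returned threshold is the smallest *attainable* score
  whose upper tail is ≤ p; the threshold is applied per
  strand-position, and both strands are scanned (windows containing N
  are skipped, overlapping instances all reported). Zero-probability
  PWM cells are floored at 1e-4 before log-odds so scores stay finite.
* **Uniquely bound windows**: focal peak centres ≥ 1 kb (inclusive)
  from every other factor's centres, ± 100 bp, with excluded regions
  subtracted (windows are clipped; fully excluded windows vanish).
* **Hypergeometric enrichment** treats instance placements as draws of
  base pairs from the searchable universe, with region coverage as
  successes: the urn is base-pair coverage, an explicit design choice
  given instances are not naturally exchangeable units across regions
  of different size. Tails are exact (`phyper`), validated against
  factorial summation for all arguments ≤ 100.
* **Wilson ratio**: motif ranking uses the Wilson score interval at
  z = 1.5 — the lower bound of the bound-region fraction over the
  upper bound of the control fraction — so small-sample ratios are
  penalised; a zero control upper bound is flagged infinite rather
  than divided by.
* **Shuffled controls** are column-order permutations of the PWM
  (never the identity when width allows), preserving the per-column
  information content multiset exactly; shuffling acts on motifs, not
  on sequence.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
standard testbed (three 2-Mb chromosomes, 500 genes, four factors with
1,000 sites of 400 bp each, 20 domains of ~5 kb on 50-bp probes,
promoter activity probability 0.6). What it emulates, and how:

* **Gene geometry**: a binomial number of gene pairs are laid out
  divergently (TSS gap uniform in [500, 2500] bp); singles with random
  strand and 2–8 kb inter-unit gaps supply adjacent pairs in the
  1.5–20 kb range; each gene gains a second TSS (300–800 bp downstream
  of the first) with the configured probability. Two exons with a
  central intron and 150-bp terminal UTRs give the category annotator
  something to classify. Packing is left-to-right with explicit
  capacity errors when genes do not fit.
* **Sites**: fixed 400-bp width by default — real peak widths vary,
  but fixing the width isolates the statistical behaviour from width
  effects. Co-binding is planted by copying donor midpoints with ±100
  bp jitter, safely below the 250-bp criterion. Promoter bias places a
  Bernoulli fraction of sites within 500 bp upstream of random TSS.
  Pair enrichment of fold *f* places each remaining site inside a
  divergent gap with probability `min(1, f·a)` (with `a` the genomic
  fraction covered by the gaps) and uniformly outside otherwise, so the
  *expected* measured fold equals *f* exactly; the achieved fold is
  recorded in the ground truth since the realised fraction is binomial.
* **Domain tracks**: domain lengths uniform in [0.5, 1.5] × mean
  length, placed without overlap with slack distributed uniformly;
  probe values are Normal(mu_in, sigma) inside and Normal(mu_out,
  sigma) outside. The default separation (2 vs 0, sigma 0.5) is a
  4-sigma contrast typical of a clear broad mark.
* **Activity evidence**: activity is drawn per *gene* and shared by
  its TSS. Alternative promoters of one gene sit a few hundred bp
  apart and share exons, so no overlap-based caller can distinguish
  their activity states; per-gene labels keep the ground truth
  recoverable, and in the noiseless limit the conjunctive caller
  recovers 100% of labels by construction. Label noise flips a gene's
  emitted evidence, so accuracy degrades linearly with the noise rate.

What the generator does **not** emulate: array probe effects and
noise models, replicate structure, variable peak widths, sequence
composition bias, or correlated placement beyond the planted
structures. Passing tests therefore demonstrate statistical
correctness of the machinery — calibration under the null and recovery
of planted effects — not robustness to every artefact of real
tiling-array data.

# Determinism and problem sizes

Every stochastic routine takes a seed; scenario generation derives
per-component seeds by a stable string hash of (master seed, stage
name), so `generateScenario()` is byte-reproducible and pipeline stages
are independently reproducible. The test suite exercises: null
calibration over 200 independent uniform scenarios at n_sim = 1,000
(tie-randomised KS, CI coverage); 3-fold planted enrichment recovery
over 10 seeds (2,000 sites, 200 divergent pairs); co-binding detection
over 10 planted and 10 independent seeds; HMM recovery over 10 seeds
(20 domains, 50-bp probes, 4-sigma contrast); exact-oracle equivalence
on ≤ 500-site instances; and exhaustive enumeration for PWM widths up
to 8. These sizes were chosen to give stable pass/fail behaviour at
three-binomial-SD tolerances while keeping the suite comfortably fast
on a single CPU.

# Known limitations

* The HMM assumes Gaussian emissions and per-probe transitions; heavy
  tails or very irregular probe spacing would call for an emission or
  duration extension.
* The permutation null is uniform placement only — no GC,
  accessibility or probe-density matching.
* The hypergeometric urn (base-pair universe) is one of several
  defensible choices; matched instance-count controls would be needed
  for strongly size-confounded region sets.
* Empirical p-values are conservative at small counts by design; use
  the stored null counts for randomized-p diagnostics when uniformity
  matters.
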