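# insulatR

Statistical analysis of multi-factor insulator-protein binding maps.

Chromatin insulators (boundary elements) are DNA elements, bound by
proteins such as CTCF, CP190, BEAF-32, Su(Hw), Mod(mdg4) and GAF, that
partition the genome into regulatory domains. Genome-wide binding maps
for several such factors raise a recurring set of questions: which
factors co-occupy the same sites, where do sites fall relative to
promoters and gene structure, do they accumulate between functionally
distinct promoter pairs, do they mark the edges of repressive chromatin
domains, and what sequence motifs underlie them? `insulatR` implements
the full downstream analysis toolkit for these questions, together with
a synthetic-genome generator that plants known structure so every
statistic can be validated against ground truth.

The package is aimed at computational biologists analysing
multi-factor ChIP binding-site sets (BED), gene annotation (GFF3) and
probe-level signal tracks (bedGraph).

## What it computes

* **Co-binding and clustering.** Two sites overlap iff their midpoints
  are on the same chromosome and |m_A − m_B| < 250 bp (strict).
  Multi-factor clusters are the single-linkage connected components of
  this relation; each cluster gets a combination *signature* (the set of
  factors present) and a Class I (BEAF-32/CP190/CTCF) / Class II
  (Su(Hw)) assignment.
* **Permutation enrichment.** The universal null re-places each
  factor's *n* sites uniformly per chromosome (widths preserved),
  repeated `n_sim` times (10,000 by default). For a statistic *X*
  (binned distance-to-nearest-feature counts, or counts of sites
  strictly between feature pairs), the report is
  log2(X_obs / median X_null), a percentile interval from the 2.5/97.5
  null quantiles, and two one-sided empirical p-values
  p = (1 + #{X_null as-or-more extreme}) / (1 + n_sim).
* **Promoter-pair selectors.** Divergent (opposite strands, facing
  away, TSS 500–2,500 bp apart, inclusive), adjacent (any strand,
  1,500–20,000 bp, no intervening TSS) and alternative (distinct TSS of
  one gene) pairs; activity-stratified variants split pairs by whether
  their promoters differ in activity, where a promoter is called active
  iff H3K4me3 *and* PolII overlap TSS ± 500 bp *and* an exon overlaps
  RNA signal. CRM analyses partition pairs into CRM→target promoter,
  CRM→nearest non-target promoter, and CRM→CRM of the same gene.
* **Domain segmentation.** A 2-state Gaussian hidden Markov model
  (Baum–Welch, k-means initialisation, sticky transitions, Viterbi
  decoding) segments broad histone-mark signal (e.g. H3K27me3) into
  domains; boundary statistics include inside/outside enrichment,
  boundary distance profiles (negative = inside the domain), and a
  Pearson chi-squared test of whether site–boundary overlap is
  independent of TSS–boundary overlap. Syntenic blocks reuse the same
  machinery.
* **Signal meta-profiles.** Average probe signal in 50-bp bins over
  ±3 kb around site midpoints, a strand-aware promoter/non-promoter
  split (TSS to 500 bp upstream), and per-class median ± unscaled MAD
  score summaries.
* **Motif statistics.** Exact PWM score thresholds for a target
  p-value (dynamic programming over the discrete score distribution;
  the conventional stringency is p = 4⁻⁸), two-strand scanning,
  uniquely-bound ±100 bp windows (≥1 kb from any other factor's peak
  centre, exclusions removed), exact hypergeometric enrichment of
  instances in regions, and the conservative Wilson-ratio ranking
  statistic (z = 1.5) against column-shuffled control PWMs.

## Worked example

Plant 50% A→B co-binding and a promoter bias, then recover both:

```r
library(insulatR)

cb <- matrix(0, 2, 2, dimnames = list(c("A","B"), c("A","B")))
cb["A","B"] <- 0.5
cfg <- scenarioConfig(factors = c("A","B"), nSites = 1000L, cobind = cb,
                      promoterFrac = 0.3, seed = 11L)
scen <- generateScenario(cfg)

round(pairwiseOverlapFraction(scen$sites), 3)
#>       A     B
#> A 1.000 0.575
#> B 0.578 1.000

combinationSignificance(scen$sites, scen$genome, nSim = 1000L, seed = 4L)
#> CombinationTable: 3 signatures, 1000 simulations
#>   signature observed null_median  p_enriched  p_depleted
#> 3       A+B      498          77 0.000999001 1.000000000
#> 1         A      412         882 1.000000000 0.000999001
#> 2         B      398         882 1.000000000 0.000999001

pp <- selectPromoterPairs(scen$genes, "divergent")
interveningEnrichment(scen$sites$A, pp, scen$genome,
                      enrichmentConfig(nSim = 1000L, seed = 9L))
#> PairEnrichment 'pairs': observed 80, null median 16, log2 2.322
#>   [1.798, 3.152], p(enr) 0.000999, p(dep) 1
```

Half of A's sites were copied (±100 bp jitter) when placing B, and the
measured overlap fractions sit at 0.575/0.578 — the planted 0.5 plus
chance overlap. The A+B cluster signature (498 observed vs a null
median of 77) reaches the minimal attainable empirical p of
1/(1 + 1000). Because 30% of A's sites were planted promoter-proximal,
they also pile up between divergent promoters: 80 intervening sites
against a null median of 16, log2 enrichment 2.3.

`runFullPipeline(outDir, config, nSim, seed)` chains every stage
(clusters → positional profiles → promoter pairs → activity
stratification → CRM partition → domains → meta-profiles) and writes
per-stage TSVs with a manifest recording parameters and derived
per-stage seeds.

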