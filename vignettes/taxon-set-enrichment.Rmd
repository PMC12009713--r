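---
title: "Rank-based taxon set enrichment: model, assumptions and benchmark design"
author: "taxenrich"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Rank-based taxon set enrichment: model, assumptions and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxenrich)
```

## The problem

Differential abundance (DA) analysis reports one effect size per taxon
— typically a log2 fold change between two sample groups. Interpreting
hundreds of per-taxon effects is hard, and biologically related taxa
(butyrate producers, a disease signature) often shift coherently while
no single member passes a significance threshold. Taxon set enrichment
analysis asks a different question: *is the distribution of effect
sizes inside a predefined set of taxa different from the distribution
in the rest of the community?* This is the microbiome analogue of gene
set enrichment in transcriptomics, with taxon sets in place of gene
sets.

## The statistic

For a set with $m$ members detected in the input and $n = N - m$
remaining taxa, `taxenrich` compares the two groups of rank values with
the two-sample Kolmogorov–Smirnov statistic

$$D = \sup_x \left| F_m(x) - G_n(x) \right|,$$

where $F_m$ and $G_n$ are the empirical CDFs of the member and
non-member values. Members are compared against the *rest* of the
input, not against all taxa: the two samples must be disjoint for the
two-sample null distribution to apply. $D$ depends only on how the two
samples interleave when pooled and sorted, which has two consequences
that shape the whole package:

* **Distribution-freeness.** Under the null (members are an arbitrary
  subset, chosen independently of the values) every interleaving of
  $m$ and $n$ values is equally likely, whatever the value
  distribution.
* **Monotone invariance.** Any strictly increasing transform of all
  rank values leaves $D$, its p-value, the FDR and the result ordering
  bit-identical. This is the mechanism that makes enrichment calls
  robust to the choice of DA tool: different tools produce differently
  scaled effect estimates, but largely the same ordering.

### Exact and asymptotic p-values

With no ties, the null distribution of $D$ is the permutation
distribution over all $\binom{m+n}{m}$ interleavings. `ksTwoSample()`
computes it exactly by lattice-path counting: paths from $(0,0)$ to
$(m,n)$ whose ECDF gap stays below the observed $D$, with the
in-band test done on the integer quantity $|in - jm|$ so no
floating-point comparison is involved. The tail probability is
accumulated by first-exit decomposition — for each first out-of-band
cell, (in-band paths to its predecessor) × (unconstrained
continuations) — so every term is positive and p-values as small as
$10^{-56}$ are computed without the catastrophic cancellation that
$1 - P(\text{inside})$ would suffer.

The exact computation is used whenever $mn \le 250{,}000$, the largest
product for which the path counts stay inside double-precision range.
This threshold matters for calibration: the first-order asymptotic
Kolmogorov approximation $P(D \ge d) \approx 2\sum_{k\ge1} (-1)^{k-1}
e^{-2k^2 \lambda^2}$ with $\lambda = \sqrt{mn/(m+n)}\,d$ is measurably
conservative at community scale (a per-set null rejection rate near
0.040 at a nominal 0.05 for sets of 30–150 members against a
300-taxon background), while the exact permutation p is calibrated.
The asymptotic series is retained for larger problems and for tied
inputs.

**Ties.** When tied values occur across the pooled samples the
classical permutation null no longer holds, so the implementation
falls back to the asymptotic p and flags the result row
(`tie_flag = TRUE`) rather than jittering — deterministic output, no
hidden randomness. DA effect estimates are continuous, so ties are
rare in practice.

### Multiplicity and output

P-values are adjusted with the Benjamini–Hochberg step-up procedure
across exactly the *tested* sets — those surviving the detectability
filter — not the whole database; untested sets contribute no
hypothesis. Each result row reports the set, its category, the number
and identity of detected members, the median of the detected members'
rank values (`median_rank`; for even counts the mean of the two
central values), $D$, the p-value and the FDR. The sign of
`median_rank` relative to the background median indicates direction:
with log2 fold change input, negative means the set is depleted.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minSize` | 5 | minimum detected members for a set to be tested; smaller sets give the KS test too little resolution (the smallest attainable two-sided p for 4 vs 300 is already near 0.01) |
| `alpha` (screening) | 0.05 | FDR level above which a candidate null background is rejected in the benchmark |
| `detectionFdr` | 0.05 | FDR level at which an implanted set counts as recovered |
| `effectSize` | — | fold change $E$; implants draw from $\mathrm{Uniform}(\log_2 E/2,\, 3\log_2 E/2)$, whose median is exactly $\log_2 E$ |
| `sigma` | 0.5 | null background spread in log2 units |

All thresholds are user-settable; the defaults are the ones used
throughout the tests and the acceptance script.

## The synthetic data generators

Real benchmark backgrounds would come from DA runs on random splits of
healthy cohorts; this package instead generates them, so every test
runs offline and in seconds.

* `generateFixtureDB()` emulates a curated taxon-set database: sets
  drawn from a shared identifier universe in three size classes —
  small (2–9), medium (10–50), large (51–150) members. Sets overlap,
  as real metabolite-producer sets do (one species produces many
  metabolites).
* `generateNullBackground()` emulates enrichment-free DA output:
  i.i.d. normal(0, 0.5) log2 fold changes (Student-t optional for
  heavier tails), with identifiers from the same universe. The 0.5 SD
  keeps $|{\log_2 \mathrm{FC}}| > 1$ uncommon, as in DA comparisons of
  random healthy splits.

What the generators do **not** emulate: compositional coupling between
taxa (one taxon's gain is others' loss), correlated effect estimates
from shared sequencing depth, heavy-tailed or skewed per-taxon
variance, and phylogenetic correlation between set membership and
effect size. Passing benchmarks therefore demonstrate the statistical
machinery — calibration under the stated null, sensitivity under the
stated signal model — not performance on any particular real cohort.

## The signal-implantation benchmark

Sensitivity (true positive rate, TPR) is estimated per (size class ×
effect size) cell, `runBenchmark()`:

1. Draw a null background; run the full enrichment on it and **screen
   out** candidates with any pre-existing set at FDR < 0.05 (bounded
   redraws). Acceptance on truly null draws is high (~95%), so
   screening does not loop.
2. Pick a target set of the class uniformly at random. Eligible
   targets must have at least `minSize` detected members — a set below
   the detectability filter can never be declared significant, so
   including it would measure the filter, not the test. This only
   affects the small class (sets of 2–4 members are skipped).
3. **Replace** the detected members' values with
   $\mathrm{Uniform}(\log_2 E/2,\, 3\log_2 E/2)$ draws (negated for
   depletion signals). Replacement rather than shifting mirrors how a
   coherent group-level change overrides individual null noise; a
   `shift` mode exists for sensitivity analysis. At $E = 1$ the
   interval degenerates to $\{0\}$: the no-signal limit.
4. Re-run the enrichment and count a detection when the target's FDR
   falls below `detectionFdr`.

The whole procedure is a deterministic function of the seed.

Against these synthetic backgrounds the test is highly sensitive:
medium sets (10–50 detected members) at a 2.5-fold median implant are
recovered in >97% of replicates, TPR is non-decreasing in effect size,
and at a 2-fold implant the medium class is at least as sensitive as
the small and large classes. Absolute TPRs at low effect sizes are
*higher* than they would be against real-cohort backgrounds, whose
heavier tails and correlation structure dilute the signal; the
benchmark's claims are the ordering and the high-effect regime, not
the low-effect absolute numbers.

## Numerical and design choices

* **Members vs rest, two-sided.** The reference side excludes the
  set's own members (disjoint samples); the alternative is two-sided,
  with direction read off `median_rank`.
* **Exact-p cutoff** $mn \le 250{,}000$: bounded by double-precision
  range of $\binom{m+n}{m}$, see above; cross-checked against
  `stats::ks.test(exact = TRUE)` to a relative $10^{-12}$.
* **Degenerate inputs.** A set covering every input taxon has no
  background and is skipped with a warning; an input in which no set
  is testable yields an empty, well-formed table with a warning, not
  an error. Tiny exact p-values are floored at the smallest positive
  double so downstream $\log$ and BH stay defined.
* **Identifier matching is exact.** A genus-level input row does not
  match species-level set members; no lineage expansion is attempted.
  Name-to-taxid resolution is a separate, cacheable step
  (`namesToTaxids()`), and unresolved names are carried verbatim so
  they can still match name-keyed sets — dropping them would thin the
  background and bias $G_n$.
* **Problem sizes.** Tests and the acceptance script use 300-taxon
  backgrounds, a 45–50-set database and 200–1000 replicates per
  estimate — community-scale inputs at which every enrichment run
  takes tens of milliseconds, so full calibration and benchmark sweeps
  stay within minutes on one core.

## Known limitations

* Set quality bounds result quality: enrichment can only report on the
  sets it is given, and database coverage is strongly gut-biased in
  public sources.
* Exact identifier matching makes mixed-rank inputs (genus rows
  against species sets) silently non-overlapping; run the id-mapping
  step and check `n_detected` when results look empty.
* The KS statistic weights the whole distribution; a very large set
  whose complement is small loses power as the "background" stops
  being a background (visible as the large class's dip at moderate
  effects against real data).
* No per-sample scores and no over-representation testing: this
  package tests one ranked contrast at a time.

## A worked example

```{r example}
da <- readDaTable(system.file("extdata", "example_da.tsv",
                              package = "taxenrich"),
                  taxonCol = "taxon", rankCol = "log2FC")
cache <- readTaxidCache(system.file("extdata", "taxid_cache.json",
                                    package = "taxenrich"))
ranked <- translateTaxonIds(da, cache)
db <- readTaxonSets(system.file("extdata", "example_sets.json",
                                package = "taxenrich"))
runTaxonSetEnrichment(ranked, db)[, 1:7]
```

The butyrate-producer set is strongly depleted (negative
`median_rank`, complete separation $D = 1$), the dysbiosis bloom set
is enriched, and the two remaining metabolite sets are null — the
pattern the input table was constructed to carry.
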