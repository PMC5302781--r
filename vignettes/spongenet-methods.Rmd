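---
title: "spongenet: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spongenet: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

## The sponge-inference model

A competing endogenous RNA (ceRNA) sequesters miRNAs away from their mRNA
targets. When an mRNA *X* and a lncRNA *Y* are both repressed by the same
miRNA *Z*, fluctuations of *Z* induce co-expression of *X* and *Y* even
though the two never interact. `spongenet` quantifies this mediation with
the sensitivity correlation

$$S = \rho_{XY} - \rho_{XY|Z}, \qquad
\rho_{XY|Z} = \frac{\rho_{XY} - \rho_{XZ}\rho_{ZY}}
{\sqrt{1-\rho_{XZ}^2}\sqrt{1-\rho_{ZY}^2}},$$

the drop in the pair's Pearson correlation once the miRNA is linearly
conditioned away. The partial correlation is algebraically identical to the
correlation of the residuals of the two regressions of *X* on *Z* and *Y*
on *Z*; the test suite verifies this equivalence numerically at
$n = 10^5$. Two consequences of the closed form are worth keeping in mind:

* if $\rho_{XZ} = 0$ while $\rho_{ZY} \ne 0$ and $0 < \rho_{XY} < 1$, then
  $S < 0$ — mediation requires the miRNA to correlate with **both**
  profiles;
* $S \approx 0$ for a pair whose correlation stems from a shared
  transcriptional program rather than a shared miRNA, which is exactly the
  case the confounded pairs of the synthetic generator exercise.

### The four-stage pipeline

1. **Preprocessing.** Entities with strictly more than 10% missing values
   are dropped (the fraction is taken over all samples of the matrix, both
   conditions jointly — the per-condition alternative is not offered);
   mRNAs additionally require a 3'UTR of at least 500 nt (inclusive
   boundary, so a 500-nt UTR survives).
2. **Top-pair selection.** All mRNA-by-lncRNA Pearson correlations are
   computed on pairwise-complete observations; pairs strictly above the
   99th empirical percentile of that distribution are kept. The induced
   threshold (e.g. $\rho > 0.7$ on real breast-tissue data) is recorded in
   the network's provenance.
3. **Triplet scan.** For every retained pair and every miRNA, $S$ is
   computed; triplets with $S > 0.3$ pass. A zero-variance miRNA yields an
   undefined (NA) column, excluded from selection rather than treated as 0.
4. **Seed-match enrichment.** The 6-mer seed is positions 2–7 of the mature
   miRNA; its reverse complement (DNA alphabet) is the match site. All
   overlapping occurrences are counted, sliding one position at a time,
   because no exclusion rule is warranted for a minimal 6-mer pairing
   requirement; `N` never matches. The hypergeometric universe — nowhere
   fully specified in the ceRNA literature — is a declared convention of
   this package: the population is all 6-mer windows over every indexed
   transcript ($N$, a transcript of length $L$ offering $\max(L-5,0)$
   windows), successes are the miRNA's total site occurrences ($K$), the
   sample is the candidate pair's combined windows ($n$), and the observed
   successes its combined site count ($k$); the p-value is the upper tail
   $P(\ge k)$. Edges require $p < 0.01$ (strict) and at least one site in
   each transcript.

All thresholds (percentile 99, $S > 0.3$, $p < 0.01$, t-test $\alpha =
0.05$, UTR $\ge$ 500 nt, missing $\le$ 10%) are configuration values with
the published operating point as defaults; comparisons are strict as
printed. No multiple-testing correction is applied to enrichment p-values —
the method's published form uses a raw 0.01 cut, and we keep that contract
(flagged here deliberately).

The resulting network is an undirected multigraph: competition is
symmetric, one edge per (pair, miRNA), parallel edges between the same pair
kept distinct and counted separately in degrees. This matches the
convention under which a hub's edge count exceeds its neighbour count.
Hub ranking breaks degree ties lexicographically by node id so results are
reproducible.

## The isoform titration analysis

The sponge mechanism is concentration-sensitive: a sponge isoform works
while its abundance is comparable to its miRNA's, and saturates when the
miRNA vastly outnumbers it. The toolkit implements:

* **Paired Student's t-test filtering** (`filter_isoforms()`), two-sided on
  per-patient differences. The design is matched pairs, so the paired test
  is the default; an unpaired switch exists for sensitivity checks.
  Degenerate inputs follow the statistic's limits: all differences zero
  gives $p = 1$, identical non-zero differences give $p = 0$.
* **Abundance shares** per condition: each isoform's mean FPKM as a
  percentage of the summed means; shares sum to 100 by construction.
* **The variation matrix**: entry $(i, p)$ is isoform $i$'s
  cancer-minus-normal FPKM difference in patient $p$. "Variation" is the
  per-patient difference, not the difference of condition means — forced by
  the convention that the PCA's variables are the patients.
* **Covariance PCA** (`pca_variation()`): columns (patients) are
  mean-centred, no scaling to unit variance. Correlation-based PCA would
  change the explained-variance fractions and is not offered. Eigenvalues
  descend; `factors` (variables × components) is orthonormal; `scores` =
  centred data × factors. Component signs are indeterminate in any
  eigen-decomposition, so each factor column is flipped to make its
  largest-magnitude loading positive — score plots are then reproducible.
  By default the pipeline's PCA runs on the t-test-filtered isoforms; both
  entry points are exposed because filtering-then-decomposing and
  decomposing everything answer slightly different questions, and the
  toolkit does not resolve that choice for the user.
* **Isoform/miRNA ratios** (`ratio_to_mirna()`): mean isoform FPKM over
  mean miRNA FPKM per condition, with the per-patient ratio distributions
  and a paired t-test between them. Fold changes are ratios of condition
  means with no pseudo-count: a zero denominator is an explicit undefined
  signal, never a silently distorted number.
* **Exon-usage comparison**: per-exon cancer/normal fold of mean normalised
  counts plus a paired t-test; exons with fold > 1 and $p < 0.05$ are
  flagged. Counts are accepted as normalised upstream — the comparison is
  distributional, not a GLM exon model.

## The synthetic-data generator

`simulate_sponge_dataset()` emulates the statistical structure the
inference assumes, with every planted feature recorded as ground truth:

* **Planted triplets**: $\tilde z \sim N(0,1)$ per patient;
  $Z = e^{\mu_z + s_z \tilde z}$,
  $X = a\,e^{-\gamma \tilde z + \sigma \varepsilon_1}$,
  $Y = b\,e^{-\gamma \tilde z + \sigma \varepsilon_2}$. All pairwise
  raw-scale Pearson correlations then have closed forms (log-normal
  moments), exposed in `expected_triplet_correlations()` and checked
  empirically at $n = 10^5$ in the tests.
* **Confounded pairs**: a shared latent factor drives both members with no
  miRNA involvement — high $\rho_{XY}$, $S \approx 0$. These exist to test
  that the pipeline does not mistake co-regulation for sponging.
* **Background entities**: independent log-normal noise.
* **Sequences**: uniform-random DNA, with the mediating miRNA's match site
  planted (default 5 copies) into both members of each sponge pair on a
  non-overlapping grid; nothing is planted for confounded pairs.
* **Conditions**: 72 matched patients by default; in cancer the miRNAs rise
  by a uniform 4–8-fold factor, the sponge gene by 2-fold, and miRNA
  mediation is switched off (`cancer_mediation = FALSE`), producing the
  normal-to-cancer rewiring the comparison stage measures. A
  `super_sponge` mode routes all planted triplets through one lncRNA and
  one miRNA to plant a hub.

**Choice of dispersion regime.** The inference correlates raw FPKM values
(a `log_transform` switch is deliberately not the default, matching the
method's published form). Under a multiplicative model, raw-scale Pearson
correlation transmits the mediation signal faithfully only while log-scale
dispersions are small — for large dispersions the exponential link makes
the miRNA–target relation strongly non-linear and the linear partial
correlation can no longer remove it, driving $S$ toward 0 even under
perfect mediation. The defaults ($\gamma = 0.15$, $\sigma = 0.03$,
$s_z = 0.05$) therefore sit in the quasi-linear regime, giving a planted
population sensitivity of $S \approx 0.63$ — comfortably past the 0.3
selection threshold at $n = 72$ without being degenerate. This is a real
limitation worth knowing: on heavy-tailed real data the sensitivity
statistic on raw FPKM is conservative, and the log-transform switch is the
remedy.

`simulate_isoform_titration()` plants ten isoforms: a dominant site-free
isoform (~50% normal share) that absorbs a 2-fold increase of the total, a
site-bearing isoform (~15% share) changing only 1.3-fold, and null
low-abundance isoforms, against a reference miRNA rising 4–8-fold. Holding
the other isoforms null while doubling the total necessarily pushes the
dominant isoform's cancer share above its normal share; the generator
follows its stated contract (total fold and per-isoform folds) rather than
pinning both conditions' shares. The site isoform's miRNA ratio then
collapses in cancer by construction while its own abundance barely moves —
the titration signature. `simulate_exon_counts()` draws
negative-binomial counts (size 20, mean 200) and doubles cancer means for
exons past a breakpoint (default: after exon 5 of 9).

### What the generator does not emulate

Real FPKM data are heavy-tailed across entities and samples, zero-inflated,
and library-size coupled; miRNA regulation is many-to-many with varying
site efficacy; sequences have composition bias and paralogy. Passing tests
on this generator therefore demonstrate the pipeline's *logic* — formula
fidelity, filter semantics, ground-truth recovery under the stated model —
not its power on real tissue data.

## Numerical conventions and degenerate inputs

* Correlations need at least 3 pairwise-complete observations; zero
  variance yields an explicit NA ("undefined"), distinct from 0.
* Percentile thresholds use the empirical quantile; selection is strict
  (`>`), so an all-ties distribution selects nothing.
* Internal genomic intervals are 0-based half-open; GTF I/O converts at the
  boundary (a GTF exon 11–20 becomes (10, 20], length 10). Strand is
  recorded but sequences are assumed sense-strand; no reverse complementing
  on input.
* All stored transcript sequences use the DNA alphabet (U→T on input);
  mature miRNAs are stored as RNA (T→U). Seed matching happens in DNA
  space.
* Filters that empty a dataset raise a classed error
  (`spongenet_empty`) naming the stage, never return a silent empty
  result.
* Each pipeline run echoes its thresholds into the output manifest, and
  generators are pure functions of their parameter object including the
  seed.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full pipeline on the
default generator conditions (72 patients, 50 sponge triplets, 50
confounded pairs, 50 background entities per role) over 10 seeds, the
titration generator over 20 seeds, oracle comparisons over 1000 random
(sequence, site) pairs and 100 hypergeometric instances, and the
regression-residual equivalence at $n = 10^5$. These sizes were chosen so
the whole suite completes in about a minute while every stochastic claim is
averaged over enough replicates to be stable.

## Known limitations

* The hypergeometric universe is this package's convention; other window
  definitions (per-transcript tests, nucleotide-level universes) would give
  different p-values.
* The sensitivity statistic is a first-order linear mediation measure: it
  cannot distinguish mediation from certain confounding topologies and is
  conservative on strongly non-linear (heavy-tailed raw-scale) data.
* No 7mer/8mer site classes, pairing thermodynamics or conservation
  filtering: the 6-mer minimal pairing requirement only.
* lncRNA scanning uses spliced cDNA sequences only; genomic scanning is not
  offered.
* Degree is the only centrality; no community detection or layout.
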