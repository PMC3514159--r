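---
title: "Interactor catalogs and direct/indirect enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactor catalogs and direct/indirect enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedenrich)
```

## The problem

A proteome-wide yeast two-hybrid (Y2H) screen tests one bait protein
pairwise against an ORFeome library in two orientations: bait fused to the
Gal4 DNA-binding domain against AD-ORF preys (`DB`), and the reverse
(`AD`).  The product is two hit lists over the same tested universe.
Downstream questions are (i) bookkeeping — how many distinct partners, how
many found in both orientations, how many validated orthogonally, where in
the cell the interactions occur (by bimolecular fluorescence
complementation, BiFC); and (ii) function — whether the partner set is
enriched for annotation terms or pathways, either directly or through the
partners' own interactors in a reference protein–protein interaction (PPI)
network.

`seedenrich` implements this pipeline end to end, together with a
synthetic-data generator that plants known enrichment so every stage can be
benchmarked without any external database.

## The catalog model

A catalog is a set of interactor records keyed by Entrez Gene ID (symbols
carry aliases and typographic marks, so they are unsuitable keys).  Each
record holds the set of screen configurations in which the partner was
found, a previously-described flag (the `*` mark in printed tables), an
orthogonal-validation status (affinity co-purification, Y/N), and a BiFC
localization call.  Localization calls have exactly three variants:

* a *pattern* — a non-empty subset of {nuclear, cytoplasmic, vesicular};
* *no signal* (`/` in table cells) — assayed, no fluorescence;
* *not determined* (`n.d.`).

The cell-string tokenizer treats commas and the word "and" identically and
ignores repeated tokens, because printed tables freely mix "Nuclear and
cytoplasmic" with "Nuclear, vesicular, cytoplasmic".

Merging the two configuration lists unions records by gene ID and unions
their configuration sets; the shared annotation fields must agree, and a
disagreement is an error rather than a silent overwrite.  The
"both-configurations" flag is always derived from the merged configuration
sets.  Printed tables mark it with `§`; the reader keeps that mark as a
claim and validates it against the derived flag, never the other way
round.

### Counting conventions

Published screen reports mix two conventions: the headline partner count
excludes the bait's homodimer record, while validation and BiFC counts
include it.  With the packaged fixtures, the merged catalog has 60 distinct
proteins: 59 partners plus the bait homodimer.  `summarize_counts()`
therefore exposes `include_bait_self` explicitly instead of hard-coding
either convention:

```{r}
demo <- demo_catalog()
demo$counts_excl_bait   # 59 partners, homodimer excluded
demo$counts_incl_bait   # 45 confirmed / 41 BiFC-positive include it
demo$tally              # 31 partners with a nuclear component
```

One known discrepancy is documented rather than reconciled: counting the
printed BiFC cells gives 18 exclusively-nuclear partners (homodimer
excluded), while the accompanying narrative arrives at 16 exclusive and 15
mixed.  `tally_localization()` reports the table-derived values.

## Direct enrichment

For seeds $S$ (the direct interactors), a term $T$, and the tested universe
$U$ (the ORFeome — only genes that could have been found), the 2×2 table is

$$a = |S \cap T \cap U|,\quad b = |S \cap U| - a,\quad
  c = |T \cap U| - a,\quad d = |U| - a - b - c.$$

The test is the one-sided Fisher exact test: the upper-tail hypergeometric
probability $P(X \ge a)$ with population $N = |U|$, $K = a + c$ annotated
genes and $n = a + b$ draws.  Only over-representation is tested; the
published reports never test depletion.  The odds ratio is the sample odds
ratio $ad/bc$ with the Haldane–Anscombe correction (0.5 added to every
cell) when a cell is zero; the original reports' exact odds-ratio recipe is
not recoverable from their printed values, so odds ratios here are verified
by formula properties, not against published numbers.

### The correction dialect

The corrected p-values in published screen tables follow
$\tilde p_i = \min(1,\; p_i \, m / r_i)$ with $r_i$ the rank of $p_i$ in
ascending order — the Benjamini–Hochberg quotient *without* the step-up
cumulative minimum.  The fingerprint is that corrected values are not
monotone in rank (in the packaged reference table, the rank-5 corrected
value exceeds the rank-6 one).  The implicit test count $m$ is never
printed but is recoverable: the ratio `corrected/raw × rank` is constant
across the top-ranked rows (329 for the packaged GO table).
`multiple_test_correct()` implements this dialect as `paper_simple` (the
default, for reproduction) and the standard step-up as `standard_bh` (for
correct practice); `infer_test_count()` recovers $m$ from printed pairs.

$m$ defaults to the number of terms with at least one annotated universe
gene; whether the original 329-term space was restricted further is not
stated anywhere recoverable, so callers may pin $m$ explicitly.  Terms are
reported only when at least `min_obs = 2` seeds are annotated, matching the
published filtering rule; ranks are assigned before that filter.  Ties in
$p$ are ranked stably by term ID so ranks are reproducible.

## Indirect enrichment

Second-degree (indirect) interactors are the union of network neighbors of
all in-network seeds, minus the seeds themselves and minus the bait;
self-loops contribute nothing.  Excluding seeds and bait is a documented
convention — the source procedure is silent on it — and both exclusions are
applied identically to observed and null expansions, which is what matters
for the test's validity.

Significance comes from a seed-randomization null: `n_trials` (default
100,000) random seed sets of the same size are drawn from the network's
node set, each expanded the same way, and each pathway's count of distinct
indirect members is accumulated.  The *empirical FDR* of a pathway is the
exceedance proportion — the fraction of trials with a count at least the
observed one.  It is a permutation p-value in all but name; the term
follows the field's usage.  With `smoothing = "none"` (the default and the
literal published rule) it can be exactly 0; `add_one` gives
$(r+1)/(N+1)$ for log-scale use.

Null seed sets are drawn from the network node set, not the full ORFeome:
this keeps neighborhood sizes comparable and matches "the identity of the
direct targets was randomized".  Uniform sampling ignores hub bias, so a
`degree_matched` mode is provided that replaces each true seed with a node
from the same log2-degree bin.

The FDRs are Bonferroni-corrected *per source collection* (e.g. NCI-Nature,
KEGG, Reactome), with $m$ the number of pathways of that source with at
least one network member.  The per-source choice is forced by the published
corrected/raw ratios, which are internally consistent only under per-source
multipliers (120, 150 and 628 in the packaged pathway table), not a global
one.  A pathway is significant when its corrected FDR is below
$\alpha = 0.05$ *and* at least `min_obs = 2` indirect targets were
observed.

The observed/null counting loop is compiled (Rcpp); the test suite verifies
the kernel against a per-trial composition of `second_degree()` and
`observed_pathway_counts()` and against exhaustive enumeration of all
$\binom{n}{k}$ seed sets on small networks.

## The synthetic-data generator

The generator emulates the screen's shape: a universe of 10,214 genes
(defaults), ~59 seeds, a sparse undirected network (Erdős–Rényi with mean
degree 8 by default; a truncated power-law configuration model for
heavy-tailed degrees, because hub effects are exactly what degree-matched
sampling must be tested against), and gene-set collections with
heterogeneous sizes (30–60 by default).  Two planting operations create
recoverable signal:

* `plant_direct()` draws a fraction `direct_q` of the seeds from one term —
  the signal the Fisher stage must recover;
* `plant_indirect()` adds `indirect_k_links` edges per seed into one
  pathway — the signal the permutation stage must recover.  Because seeds
  are excluded from the second-degree set, the planted pathway should be a
  different set from the direct-planted term; `simulate_inputs()` plants
  them into sets 1 and 2 respectively.

Every generator call consumes its own RNG stream derived from
`(rng_seed, call label)`, so adding one call to a script never shifts
another call's draws, and everything is a pure function of the
configuration.

What the generator does *not* emulate: Y2H false-positive/negative
processes, annotation incompleteness, correlated pathway membership, and
literature bias in real PPI networks.  Passing benchmarks on synthetic data
therefore demonstrate correctness of the statistics, not robustness to
those real-data pathologies.

## Numerical choices and benchmark sizes

* Hypergeometric tails come from `stats::phyper`; the test suite checks
  them against explicit enumeration for every table with $N \le 20$ at
  1e-12.
* Result tables are written with decimal points at full stored precision
  (probability 1 is written `1.0`); published-table inputs with decimal
  commas are handled by `parse_decimal()`.
* Benchmarks used by the test suite and the acceptance script, chosen as
  the smallest sizes at which the statistical properties are sharp:
  null calibration on a 2,000-node network with 40 pathways, 10,000 trials
  and 200 replicates (the fraction of pathway tests with empirical FDR
  ≤ 0.05 stays below 0.07; the test is conservative because the exceedance
  proportion is discrete); direct recovery with a planted 50-gene term,
  30 seeds at `direct_q = 0.5` in a 1,000-gene universe (rank 1 in ≥95 of
  100 replicates); indirect recovery with 20 seeds × 2 planted links on a
  2,000-node network at 10,000 trials (significant in ≥90% of 50
  replicates); and a full 100,000-trial run on 2,000 nodes with 50
  pathways as the scale check.

## Known limitations

* No GO-graph propagation: annotation sets are flat.  Whether the original
  analyses propagated annotations up the ontology is not recoverable, and
  graph-aware (elim/conditional) testing is out of scope.
* No identifier mapping: collections, universes and networks must share one
  namespace; the packaged fixtures use Entrez IDs, synthetic data uses
  generated symbols.
* Published odds ratios and raw permutation FDRs depend on 2008–2009
  database versions and an external PPI network and are not reproduction
  targets; the machinery around them is verified by oracle equivalence and
  planted-signal recovery instead.
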