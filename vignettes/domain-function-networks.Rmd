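---
title: "Predicting protein function from domain-function associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from domain-function associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trifun)
```

## The model

`trifun` rests on a single structural assumption: if a domain and a
function repeatedly occur on the same proteins, the domain is predictive
of the function. The data structure is a tripartite network whose middle
layer (proteins) connects a domain layer to a function layer. Only
proteins annotated in **both** layers enter the network — a protein with
domains but no known function (or vice versa) contributes no
co-occurrence evidence — and the protein count `nT` refers to this dually
annotated set. Repeated mentions of a feature on one protein are collapsed
to set membership, because all downstream quantities are functions of the
neighbour *sets* `Np(D)` and `Np(F)`.

### Association indices

Four indices score a (domain, function) pair from `|Np(D)|`, `|Np(F)|`,
their overlap and `nT`; only pairs sharing at least one protein are
materialized (zero-overlap pairs carry no signal, and the full
cross-product would be quadratic — downstream code treats absent pairs as
"no association").

* **Jaccard** `|∩|/|∪|`: symmetric overlap, penalized by either side's
  exclusive proteins.
* **Simpson** `|∩|/min(|Np(D)|, |Np(F)|)`: normalizes by the
  less-connected node. Domain and function neighbourhoods differ in size
  by orders of magnitude in real annotation corpora; Simpson is the index
  least distorted by that asymmetry, which is why it is the package
  default in the pipeline.
* **PCC**: the Pearson correlation of the two binary protein-membership
  profiles (the phi coefficient),
  `(|∩|·nT − |Np(D)|·|Np(F)|) / sqrt(|Np(D)|·|Np(F)|·(nT−|Np(D)|)·(nT−|Np(F)|))`.
  It is undefined when a node is connected to every protein; such pairs
  are dropped with a warning rather than given an arbitrary value.
* **HyI**: `−log10` of the upper-tail hypergeometric probability of an
  overlap at least as large as observed — an over-representation test
  statistic. The tail is evaluated in log space (`phyper(..., log.p =
  TRUE)`), so small probabilities do not underflow; a tail that still
  underflows to zero is capped at a configurable `HyI = 300` (~the
  smallest double's magnitude in log10 units) with a warning, so no
  infinities propagate.

### From associations to protein scores

Jaccard/Simpson/PCC tables are standardized to z-scores using the mean and
**population** standard deviation of the whole table: the table is the
complete population of associations for that network and metric, not a
sample from a larger one. Standardization is per table (one metric × one
network), so scores are never mixed across annotation sources. PCC is
signed; its values are combined by magnitude, so `standardizeTable(...,
takeAbsolute = TRUE)` takes absolute values *before* recomputing the
moments. A table with zero spread cannot be standardized and raises an
error rather than emitting NaNs.

For a query protein, each candidate function's per-domain values are
combined:

* **Stouffer** for z-scores: `Z = Σ zᵢ / sqrt(k)`.
* **Fisher** for HyI-derived p-values (`p = 10^−HyI`):
  `X = −2 Σ ln pᵢ ~ χ²` with `2k` degrees of freedom.

`k` counts the domains actually contributing a value for that function,
not all domains of the protein: domains without an association record for
the function contribute no term to either sum, so counting them in `k`
would deflate every score by a constant that carries no evidence. This is
the one place where two readings of the combination formulas exist; the
per-function reading is the only one consistent with the sums' index
sets, and it is what the package implements.

### Range normalization

Benchmark submission formats require scores in (0, 1]. The Stouffer path
re-standardizes the run's combined scores, clips to ±2 (sign-preserving —
a one-sided clip could never reach values below 0.5 after the affine
map), divides by the clipped range (4) and adds 0.5; the Fisher path
reports `1 − p`. Scores below 0.001 are then removed as spurious, which
also resolves the boundary case `z = −2 → 0.0` that would otherwise fall
outside (0, 1]. The clip-and-shift map is monotone, so within-run ranking
is preserved up to ties created at the clip boundaries.

Re-standardization is over the *prediction run* (the pooled combined
scores of the queried proteins), not over the training association
distribution: the clip quantiles then adapt to the query set, and a run
consisting only of strong predictions still spreads over the full range.
A run with zero spread maps everything to 0.5 with a warning instead of
failing, since downstream evaluation can still rank ties.

A protein whose every prediction falls below the 0.001 filter belongs to
neither the predicted set nor the no-domains/no-associations categories;
it is recorded with the distinct reason `below-threshold` so that
`|predicted| + |unpredictable| = |queried|` holds unconditionally. This
bookkeeping identity is what makes reported coverage exact.

## Ontology handling

The OBO reader keeps the subset of OBO 1.2 that evaluation needs: `is_a`
and `relationship: part_of` parent edges (the relations conventionally
used for annotation propagation; `regulates`-type edges are ignored),
namespaces, `alt_id` aliases and `is_obsolete` flags. Edges to unknown
parents are dropped with a warning; cycles are a fatal error (checked by
Kahn peeling at parse time).

Annotation sets are propagated to ancestor closure before evaluation, and
namespace roots are excluded (every protein trivially has them).
Prediction sets are propagated by default too, each ancestor inheriting
the maximum score of its predicted descendants; a flag disables this for
callers whose predictions are already consistent.

Smin weights terms by **information accretion**:
`ia(t) = −log2 P(t | parents(t))`, estimated from a propagated corpus as
the count of proteins with `t` over the count of proteins with all of
`t`'s parents, in bits (log base 2, the convention for this quantity).
Roots get 0. A term never seen in the corpus gets the pseudo-count value
`−log2(pc / (n_parents + pc))` with `pc = 1` by default; terms absent
from the table entirely fall back to `−log2(pc / (n_proteins + pc))`
with a warning. These fallbacks only matter when predictions name terms
outside the training corpus, and they err on the side of penalizing such
predictions.

## Evaluation

Protein-centric precision/recall at threshold τ averages per-protein
precision over proteins with ≥1 prediction at τ and per-protein recall
over all benchmark proteins (**full** mode, penalizing non-predictions)
or over covered proteins only (**partial** mode). Fmax sweeps
τ = 0.01, …, 1.00 (step 0.01, the protein-centric benchmarking
convention; the grid is built as `(1:100)/100` so each point is the same
double as a score rounded to two decimals, and comparisons carry a 1e−9
slack — without this, binary floating point makes `0.29 < 0.29` "true"
and the sweep silently misses thresholds). Among tied thresholds the
*largest* τ is reported: the most confident threshold attaining the
maximum, and the convention under which the worked instance
(truth {A, B}, predictions {A: 0.9, C: 0.8}) reports its Fmax of 2/3 at
τ = 0.9 rather than at the bottom of the tie interval (0.80, 0.90].
Because every grid threshold realizes the predicted set of some exact
score threshold, the grid maximum can only equal or fall below the exact
maximum; when scores lie on the 0.01 lattice — the precision at which
predictions are serialized — the two coincide exactly, which is how the
suite checks the sweep against a brute-force oracle.

Smin minimizes `sqrt(ru² + mi²)` over the same grid, `ru` being the
average accretion of missed true terms and `mi` of wrong predictions.

The pooled self-prediction procedure (pathway-prediction-performance
style) requires no ontology: all (protein, function, score) records are
pooled, labelled by literal membership in the protein's original
annotation (ancestor-propagated matching is available behind a flag, but
literal matching is the default since pathway vocabularies have no DAG),
and summarized by a ranked precision-recall curve, its step-interpolated
area, and its maximum F-measure. The frequency naive baseline scores
every training term by its training prevalence for every query protein.

## Synthetic study conditions

The generator plants a map from domains to functions, draws 1–3 domains
per protein uniformly, and annotates each protein with the union of its
domains' planted functions. Its defaults — 500 proteins, 50 domains, 20
functions, no noise — are the package's reference conditions; two
corruption knobs emulate real-data pathologies:

* `noiseRate`: each planted (protein, function) edge is independently
  replaced by a uniformly random function. At 0.3 this leaves planted
  signal dominant but visibly degrades recovery.
* `fractionDomainless`: a protein receives no domain annotation (it still
  draws 1–3 random functions, mirroring benchmark proteins that have
  functions but no domain data and are therefore unpredictable).

Under zero noise every planted pair has Simpson index exactly 1
(`Np(D) ⊆ Np(F)` by construction), so end-to-end recovery is a sharp
correctness check rather than a statistical one: the reference run
reaches pooled-PR Fmax ≥ 0.95, and raising `noiseRate` to 0.3 strictly
lowers it. What these conditions do **not** emulate: the heavy-tailed
degree distributions of real domain families, inter-function correlation
induced by ontology structure, annotation incompleteness bias, or
evidence-code quality strata. Passing tests therefore demonstrate
algorithmic correctness and seeded reproducibility, not expected
performance on real proteomes.

A single integer seed drives each generator call (restored RNG state via
`withr`), so identical specifications yield byte-identical pair files;
the train/benchmark split withholds an exact `round(f · n)` protein
subset's function annotations while keeping their domains.

## Problem sizes and runtime choices

The test suite runs oracle equivalence on 200 random networks of at most
20 proteins (where the hypergeometric tail can be enumerated exhaustively
with `choose()`), Fmax equivalence on 100 random instances of 2–6
proteins, and end-to-end recovery at the 500-protein reference
conditions; the whole suite and the acceptance script each complete in
about a minute on one core. These sizes were chosen so that every
brute-force oracle is exact, not approximate.

## Known limitations

* Domain annotation is an input; the package does no homology search or
  HMM scanning, so query proteins without supplied domains are
  unpredictable by design.
* Only the four indices above are implemented, and only Fisher/Stouffer
  combination — no Brown-style dependent-p combination, although
  per-domain association values for one function are plainly not
  independent.
* Identifiers are opaque case-sensitive strings; no normalization across
  GO/KEGG/Reactome syntaxes is attempted.
* The OBO reader covers the propagation-relevant subset of the format
  only; it is not a general ontology toolkit.

```{r session}
sessionInfo()
```
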