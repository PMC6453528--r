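---
title: "Ranking candidate biomarker genes by factorizing literature-mined interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate biomarker genes by factorizing literature-mined interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnetmf)
```

## The problem

Pharmacodynamic biomarkers — genes whose measurable change indicates that a
drug has engaged its target pathway — are usually nominated by experts who
read the literature around a drug target such as Bruton's tyrosine kinase
(BTK). Text-mining systems can extract directed gene–gene assertions from
abstracts at scale: triples of an *agent* gene, a canonical *relation*
(phosphorylation, positive/negative regulation, binding, ...), and a *theme*
gene, each supported by some number of articles. The resulting directed
network is sparse and incomplete: absence of an edge mostly means nobody has
written the sentence yet, not that the relationship is absent in biology.

`litnetmf` treats candidate nomination as a link-prediction problem on this
network. Genes that act on similar sets of partners tend to share pathway
membership; a low-rank factorization of the interaction matrix captures that
shared structure and scores unobserved ordered pairs by how consistent they
would be with it. Ranking every gene by its score for the relationship
"downstream of the target" turns the network into a prioritized hypothesis
list, which can then be filtered, evaluated against an expert gold standard,
and explained gene by gene.

## The model

Let `M` be the set of agent genes and `N` the set of theme genes — in this
package a single shared universe, every gene observed anywhere in the
triples, so any gene can in principle be scored downstream of any other. The
interaction matrix holds, in cell `(i, j)`, the total number of articles
supporting any relation with agent `i` and theme `j` (non-directional
relations such as binding contribute to both orientations; all relation
types for an ordered pair collapse into one cell). Its binary view `X` has
`X[i, j] = 1` iff the count is positive.

The factorization is the implicit-feedback alternating-least-squares model
(the Hu–Koren–Volinsky formulation): every cell carries a binary
*preference* $p_{ij} = \mathbf{1}[x_{ij} > 0]$ and a *confidence*
$c_{ij} = 1 + \alpha\, x_{ij}$, and we minimize

$$
\sum_{i,j} c_{ij}\,\bigl(p_{ij} - \mathbf{w}_i^\top \mathbf{h}_j\bigr)^2
 + \lambda\bigl(\lVert W\rVert^2 + \lVert H\rVert^2\bigr),
$$

the sum running over **all** cells, observed and not. Zero cells are weak
evidence of absence (confidence 1); repeatedly co-reported pairs anchor the
fit in proportion to their article counts. Each sweep solves every row of
`W` exactly by ridge regression given `H`, then every column of `H` given
`W`; because each half-step is an exact minimizer, the objective is
non-increasing across sweeps, which the test suite verifies on random
matrices. The reconstructed value $\mathbf{w}_a^\top \mathbf{h}_b$ is the
*consistency score* of the ordered pair $a \to b$.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `rank` | 20 | latent dimensionality of `W` (genes × k) and `H` (k × genes) |
| `iterations` | 20 | full alternating sweeps |
| `lambda` | 0.1 | ridge weight; any positive value keeps the per-row normal equations positive-definite |
| `alpha` | 0.1 | confidence slope on article counts |
| `seed` | 1 | factor initialization; fits are bitwise deterministic given it |
| `init_scale` | 0.01 | magnitude of the uniform initial factors |

`alpha = 0.1` is low by recommender-system standards (confidences for
single-article edges are only 1.1), which makes the fit conservative: the
popularity structure of the network dominates over individual noisy edges.
It is kept as the default because the surrounding pipeline was designed
around it. Whether the counts or a strict 0/1 matrix drive confidence is
switchable (`use_counts`); counts are the default since per-cell article
numbers carry real information about how established a relationship is.

### Initialization and numerics

Factors start at seeded uniform values scaled by `init_scale = 0.01`. A
small-magnitude start keeps early normal equations dominated by the
`lambda` ridge and therefore well-conditioned; the per-row systems are
solved by Cholesky factorization, and the test suite checks every half-step
against normal equations formed explicitly with a generic dense solver. Ties
in ranked output are broken lexicographically by gene symbol so that runs
are reproducible to the byte.

## Ranking, leave-one-out scoring, and the direct-interactor filter

For a target `t`, one factorization of the full matrix suffices to rank all
novel candidates: their cells are already zero, so nothing needs masking.
`rank_relation` scores every gene `g ≠ t` with the reconstructed value at
`(t, g)` (downstream) or `(g, t)` (upstream), flags genes with an existing
direct edge as *known*, and assigns ranks and percentiles.

Scoring a relationship that is *already in the literature* requires masking,
otherwise its own cell dominates its reconstruction: `consistency_score`
zeroes the focal cell, refits, and compares the focal score's position
against a background population built by applying the same zero–refit–score
procedure to sampled existing relationships. The background defaults to 200
sampled nonzero cells — enough for a stable percentile while bounding the
number of refits.

Direct interactors of the target reflect transient, proximal effects of
target inhibition; distal biomarker discovery wants what lies beyond them.
`remove_direct` therefore drops every gene with a direct edge to or from the
target — both orientations, since a reported edge in either direction makes
the gene a direct interactor — and re-ranks the remainder. Known pairs are
otherwise ranked in place by default (`include_known = TRUE`), with a
novel-only mode available.

## Evaluation conventions

`roc_auc` is the rank-sum AUC: the probability that a random gold-standard
gene outranks a random non-gold gene, tied pairs counted half. It is tested
to equal brute-force pair counting exactly, to equal trapezoidal integration
of the stepwise ROC curve, and to complement itself under ranking reversal.
On the bundled expert table of 13 biomarker ranks among 13,595 genes it
evaluates to 0.829.

`recall_at_percentile` defaults to *nearest-percent* rounding: a gene at
percentile 20.41% rounds to 20% and counts as "top 20%". This matches how
such tables are read — the bundled expert table has a gene at rank 2775 of
13,595 (20.41%) that is counted among the top-20% hits — while a strict
`rank ≤ floor(0.20 · n)` mode is retained for transparency.

The co-occurrence baseline ranks genes by how many abstracts mention them
with the target, under competition ranking (tied counts share the rank
`1 + #{strictly greater}`). Half the genes in a typical gold set have zero
co-occurrence with the target, which forces them into one huge tie at the
bottom; the resulting AUC depends strongly on tie treatment, so the package
reports the mid-rank (half-credit) value as a diagnostic rather than
asserting any particular number.

Gold symbols that do not resolve against the ranked universe are excluded
from both numerator and denominator, with a warning: silently keeping them
would deflate the AUC by an unverifiable amount.

## Explaining predictions

A prediction for gene `X` is explained by analogy: find genes whose overall
connection pattern resembles `X`'s and which already carry the predicted
relationship with the target. "Connections" are the undirected union of in-
and out-neighbors in the binary view — a single total per gene, the number
such explanation tables print. For each candidate similar gene the package
forms the 2×2 contingency table over the partner universe (all genes except
the query and the candidate, to avoid self-connection artifacts): connected
to the query? × connected to the candidate? The 1-df chi-squared statistic
without continuity correction measures departure from independence, and its
upper-tail p-value orders the list; a Yates-corrected variant is available
behind a flag. Because the chi-squared is two-sided, genes sharing *fewer*
partners than chance also get small p-values; those are anti-similar, so
genes at or above their expected overlap always sort first. On synthetic
data where one gene duplicates a known downstream gene's row, the
explanation names the duplicate with `carries_connection = TRUE`, which the
test suite checks constructively.

## The synthetic generator

Real literature networks cannot be redistributed with the package, so every
pipeline stage is exercised on generated networks that emulate their
statistical shape:

- **Planted low-rank structure.** Genes draw non-negative latent factors
  (gamma, shape 0.15 — sharply peaked at zero, so communities are distinct
  and sparsely overlapping, the regime in which shared connection patterns
  identify pathway co-membership). Edge probability is proportional to
  factor inner products, rescaled — after clipping at 1 — so the realized
  edge count matches the requested density in expectation.
- **Heavy-tailed article counts.** Each edge's count is 1 plus a geometric
  excess with mean `count_dispersion` (default 1.5): most pairs have one or
  two supporting articles, a few have many.
- **A well-embedded target.** The target symbol is assigned to the gene at
  the 90th percentile of latent row norm. A drug target is by construction
  a connected pathway node; an arbitrary gene can have a near-zero latent
  row, leaving nothing for any method to recover.
- **Held-out positives that are not direct neighbors.** The target's
  strongest planted downstream partners are split at random into a known
  set (direct edges kept) and a held-out set whose edges to *and from* the
  target are deleted. This mirrors the validation situation for expert
  biomarker lists, which mostly contain genes that are not one literature
  step from the target, and it guarantees the held-out genes survive the
  direct-interactor filter.
- **Noise as rewiring.** `noise_edge_fraction` of edges move to uniformly
  random empty cells, progressively destroying the latent structure;
  recovery AUC degrades monotonically with it and reaches chance near 90%
  rewiring.

Defaults (500 genes, rank 2, density 0.02, 20 known / 10 held out, no
noise) were fixed by oracle runs at generator design time; under them the
full pipeline recovers held-out positives at mean AUC ≈ 0.85–0.92 over
5 replicates. What the generator does **not** emulate: extraction errors
with systematic structure (mis-normalized gene symbols, aliasing),
publication-date dynamics, relation-type semantics beyond directionality,
and the extreme hub skew of real literature (where a handful of genes
appear in thousands of abstracts). Passing tests on synthetic data
therefore demonstrate that the machinery recovers planted indirect
structure under literature-like sparsity — not that any particular real
network meets the model's assumptions.

## Problem sizes and determinism

The shipped tests run factorizations up to 500 genes at rank 20 and
property checks on matrices from 3×3 to 8×8 against dense oracles, sizes
chosen to give each property a meaningful instance while keeping the whole
suite fast to iterate on. All randomness — initialization, generator,
background sampling — flows through explicit integer seeds, and identical
configurations produce byte-identical ranked output, which the pipeline
tests assert literally.

## Known limitations

- Absence of evidence is treated as weak evidence of absence; heavily
  studied genes accrue higher scores for reasons partly sociological.
  Scores are relative consistencies, not probabilities.
- One factorization serves all candidates of a target; the leave-one-out
  refit is reserved for auditing existing edges and costs one fit per
  background sample.
- The chi-squared explanation assumes partner connections are independent
  across genes; for very high-degree queries the asymptotic p-values are
  conservative orderings, not calibrated error rates.
- The package deliberately performs no entity normalization and no
  identifier mapping: triples arrive symbol-clean, and garbage symbols
  propagate as distinct genes.
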