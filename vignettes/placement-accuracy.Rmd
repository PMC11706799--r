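---
title: "Benchmarking DNA-barcode phylogenetic placement with barcodeplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking DNA-barcode phylogenetic placement with barcodeplace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeplace)
```

## The question the package addresses

Phylogenetic placement grafts query sequences onto a fixed reference
("backbone") phylogeny instead of re-estimating the whole tree. For
DNA barcodes — the short (~660 bp) COI fragment available for hundreds of
thousands of animal species — placement is an attractive route to very
large trees: a multigene backbone provides the scaffold, and each
barcode-only species is attached independently at its maximum-likelihood
(or least-squares) position.

How reliable is that route? Placement accuracy plausibly depends on how
*complete* the backbone is (what fraction of species it already
contains), on how the backbone species are *chosen* (at random, spread
across higher taxa, or biased the way real databases are biased), and on
the placement *method* (likelihood versus distance). `barcodeplace`
implements the full factorial experiment: simulate a known truth, thin
the backbone under controlled sampling designs, place the missing
species from their COI sequence alone, score each placement against the
truth, and analyze the resulting accuracy metrics with a nonparametric
factorial ANOVA.

Everything runs at desk scale on synthetic data, so every stage is
testable against a known answer.

## Synthetic truth

`truth_bundle()` produces the study system:

* **Tree.** A birth--death backbone over families, each family tip
  expanded into its own birth--death subtree (`ape::rphylo` both times),
  so families are monophyletic by construction. Default: 20 families and
  200 species, with heavy-tailed family sizes (1 + negative binomial,
  dispersion 0.9) spanning species-poor (< 5) through species-rich
  families — the skew that makes stratified sampling interesting. The
  tree is rescaled to a root-to-tip height of 0.5 expected substitutions
  per site at unit rate, a typical depth for a vertebrate class.
* **Alignment.** Five partitions evolved under per-partition GTR+Γ
  models: a 660-column COI partition with a fast relative rate (1.5), a
  transition-biased exchangeability profile, AT-rich composition and
  strong rate heterogeneity (Γ shape 0.45, four discrete categories —
  the codon-position signature of mitochondrial protein genes), plus
  four nuclear-style partitions (400–1200 columns, relative rates
  0.5–1.0, milder heterogeneity, shape 0.8). Site categories are drawn
  once per site and shared across the tree; the root is drawn from the
  stationary frequencies. The rate matrix is normalized so branch
  lengths are expected substitutions per site, and the discrete-Γ
  category rates (equal-probability, mean-of-interval) average 1.
* **Missing genes.** Real multigene matrices are patchy. Each species
  keeps COI plus a random subset of the other genes (presence
  probability 0.55, redrawn until at least three genes survive),
  mirroring a minimum-three-genes-including-COI inclusion rule.

What the generator deliberately does **not** emulate: indel evolution
(gaps arise only from masks and planted artifacts), alignment error,
model misspecification between simulation and inference (the placement
engines are handed the generating model), contamination, introgression
or other gene-tree/species-tree discordance, and non-monophyletic
families. Passing benchmarks on these data therefore demonstrate
*algorithmic* correctness and the *relative* behavior of designs and
engines under clean conditions; absolute accuracy on real data will be
lower, and the gap between engines can change when every model is wrong.

## Quality control

`qc_filter()` applies three rules, in order: cells containing an
internal gap run strictly longer than 150 columns are blanked; cells
with strictly fewer than 100 non-gap characters are blanked; species
left with fewer than 3 genes, or without COI, are dropped. Thresholds
are strict inequalities. Terminal gap runs are treated as
incompleteness rather than internal gaps by default (`include_terminal
= TRUE` counts them too; sequences truncated at the 5' end are then
caught by the gap rule rather than only by the length rule).
`inject_artifacts()` plants violations with a manifest so the filters
can be audited cell-for-cell; a planted gap always leaves at least 100
residues so no cell ever trips both rules at once.

## Completeness series

All designs emit *nested* series: the 80% backbone is a subset of the
99% backbone, and so on down to 20%, so level effects are not
confounded with species identity within a replicate (this nesting is
also why the downstream ANOVA treats replicate as a block).

* `random_series()` samples uniformly; sizes are `round_half_up(level%
  × n)` clamped so at least one species is always missing.
* `stratified_series()` samples within families: `max(1,
  round_half_up(level% × n_f))` per family, and families under 5
  species keep all members at every level, so no family is ever lost.
  At 99% on 200 species every family rounds to full retention; one
  species of the largest family is then forced out (and stays out at
  lower levels) so the placement stage always has a query.
* `biased_series()` applies per-family missing fractions. The shipped
  default profile spans 0.95 down to 0.72 (assigned by ascending family
  size), landing near 20% overall completeness — inside the 14–28%
  window seen when real checklists are compared against sequence
  databases. `biased_retention_from_counts()` derives a profile from an
  actual complete-versus-observed count table instead.

## The likelihood engine

`epa_place()` evaluates **every** backbone edge. The machinery is the
standard two-pass Felsenstein scheme: a postorder pass gives each
node's conditional likelihoods, a preorder pass gives, for every edge,
the conditional likelihood of everything *outside* the edge's subtree
(reversibility lets transitions be read in either direction). Attaching
a query at distance *a* from an edge's child end with pendant length
*p* then costs one 4×4 transition per category, and the per-edge
log-likelihood is maximized over *p* by golden-section search (absolute
tolerance 1e-6, search interval [0, 2 × tree height], with the *p* = 0
boundary probed explicitly since an interior-point search cannot land
on it). Partial likelihoods are rescaled per node and site, so trees
with hundreds of taxa do not underflow.

By default the attachment point is the branch midpoint. With `optimize
= TRUE` — the pipeline default — the ten best-scoring edges are then
re-optimized jointly over attachment point and pendant length (nested
golden sections; a coarse pendant tolerance while searching, a final
full-precision pass at the optimum). Refining a shortlist rather than
every edge is the same economy the production likelihood placers use:
the midpoint scan ranks edges accurately, and the refinement only needs
to settle the winner among the leaders. Two consequences are worth
knowing: unrefined edges keep their midpoint-attachment likelihoods, so
their weight ratios are very slightly understated; and every reported
likelihood is *exact for its recorded attachment* — grafting the query
at the recorded distal/pendant and re-running full pruning reproduces
the reported value to numerical precision (this identity is asserted in
the test suite).

The likelihood weight ratio (LWR) of an edge is its attachment
likelihood normalized over all edges. Columns where the query carries
no data multiply every edge's likelihood by the same factor and are
skipped; reported likelihoods are therefore over the query's
informative columns. Ties in the best edge break to the lowest edge
number. Placement confidence (the `CP` metric below) counts placements
with LWR strictly above 0.9.

## The distance engine

`apples_place()` is a least-squares placer in the APPLES mold. For a
query with corrected distance δ_i to each backbone leaf, every edge is
scored by the weighted least-squares objective

  Q(x, t) = Σ_i w_i (t + d_i(x) − δ_i)²,

where x is the attachment point along the edge, t the pendant length,
d_i(x) the path length from the attachment to leaf i, and w_i = 1/δ_i²
(Fitch–Margoliash, default) or 1 (OLS). Because d_i(x) is linear in x
with slope ±1, the minimizer is a closed-form 2×2 solve per edge;
box constraints (x within the edge, t ≥ 0) are handled by evaluating
the clamped candidate solutions and keeping the best. On noise-free
additive distances the true edge is recovered with zero residual — the
test suite checks this exactly. No confidence value is produced:
least-squares residuals are not comparable across queries the way
likelihood weights are.

Two distance corrections are available. `"jc"` is the classical
Jukes–Cantor formula d = −(3/4)·ln(1 − 4p/3). `"ml"`
(`ml_pairwise_distances()`) estimates each pairwise distance by maximum
likelihood under a supplied GTR+Γ model, evaluated on a shared
log-spaced grid with quadratic refinement. The pipeline defaults to
`"ml"`, and the reason is instructive: on data that evolved under
GTR+Γ, JC distances are increasingly compressed with depth, which drags
every placement rootward. Under the sister-clade correctness rule
(below) a too-deep placement is structurally unfalsifiable — its sister
group is an exact reference clade — so the JC engine's accuracy is
*overstated* by the metric even as its exact-edge recovery collapses.
Model-matched distances keep the engine's errors visible to the metric
and the engine comparison meaningful.

## Scoring a placement: PCP, CP, PCP-CP

`build_placement_tree()` grafts every query's best candidate onto the
backbone (queries sharing an edge are grafted in descending distal
order, ties broken by name — the result is order-invariant). For each
placed species, `assess_placement()`:

1. takes its sister group S on the placement tree (other grafted
   queries included);
2. finds the clade C on the reference tree — the MRCA of S
   (`sister_mrca` mode) or of S plus the query itself
   (`sister_plus_query_mrca` mode);
3. forms the difference list D = (C \\ S) \\ {query};
4. calls the placement **correct** iff no member of D is a backbone
   species (every difference species is itself missing).

A note on the clade rule: described as the "most inclusive" clade
containing the sister group, taken literally that is always the root
and discriminates nothing; the only reading that yields a usable metric
is the *least* inclusive such clade (the MRCA), which is what both
modes implement. `sister_mrca` is the closest transcription of the
rule, but it has a blind spot: whenever the sister group is itself an
exact reference clade — including every singleton sister — the
difference list is empty and the verdict is automatically correct, no
matter where that clade sits. `sister_plus_query_mrca` anchors the
MRCA with the query itself, closing the singleton loophole, and is the
stricter default used by the experiment pipeline. Deep placements
(ancestral to the true position) remain forgiven in both modes — their
difference lists contain only missing species — which is exactly the
asymmetry that makes the JC-distance engine look spuriously good (see
above).

`summarize_accuracy()` aggregates: **PCP** (percent of placed queries
correct), **CP** (percent with LWR strictly above 0.9; absent for the
distance engine), **PCP-CP** (percent correct within the confident
subset; undefined — not zero — when nothing is confident).

The identity property anchors the whole metric: restoring every
missing species at its true position (`restore_missing()`, a sequential
inverse pruning that also handles species attaching above the backbone
root) reproduces the reference tree and scores PCP = 100 in both modes,
on arbitrary trees and missing sets.

## Rank-based factorial analysis

`art_anova()` implements the aligned rank transform: for each effect
(completeness level, sampling strategy, their interaction), subtract
every *other* estimated effect from each observation, mid-rank the
aligned values, and run a standard fixed-effects ANOVA on the ranks,
reporting only the aligned effect. Effect estimates come from cell and
marginal means; replicate enters as an additive block term — a
deliberate simplification of the full repeated-measures structure
induced by the nested subsampling (a mixed-model ART is out of scope;
with 3–10 replicates the block term captures the dominant pairing).
`art_contrasts()` fits the same linear model on the aligned ranks and
tests pairwise level differences with pooled-variance t statistics,
Holm-adjusted by default — chosen over Tukey's HSD for exactness
without studentized-range machinery; with `adjust = "none"` a
two-level contrast reproduces the corresponding ANOVA p exactly, a
consistency the tests assert. Alpha is reported at 0.05. Type-I
control of the whole chain is verified by simulation (1000 null
datasets of the 5×2×3 design) in the acceptance suite.

## Numerical and design choices

* Edge numbering is depth-first postorder, children in stored order,
  starting at 0 — fixed here because the jplace standard leaves it
  tool-defined. Numbers are dense and deterministic; pruning and
  grafting invalidate them (renumber explicitly).
* Branch lengths serialize with the shortest decimal representation
  (≤ 17 significant digits) that round-trips the double exactly; jplace
  numerics are written at 17 significant digits, so read-back is
  bit-for-bit.
* Ties everywhere break deterministically: best edge by lowest edge
  number, multi-graft order by descending distal then query name.
* Per-stage seeds derive from the master seed as `(seed + 10007·k) mod
  (2^31 − 1)`; every stage is independently reproducible and reruns are
  bit-identical.
* Rounding of sampling counts is round-half-up (0.5 away from zero),
  not banker's rounding.
* Degenerate inputs are rejected loudly: mixed branch-length
  annotation, negative lengths, duplicate labels, non-covering
  partitions, saturated JC distances (p ≥ 0.75 → the query-leaf pair is
  dropped; a query with fewer than 4 usable distances is reported as
  unplaced, not guessed).

## Problem sizes

The default experiment — 200 species, five levels, two strategies, two
engines, three replicates — is sized to run in minutes on one core:
roughly 2400 likelihood placements against backbones of 40–200 leaves.
The test suite uses smaller bundles (36 species) for engine unit tests
and the full default only in the end-to-end acceptance checks. All
scales are configuration, not constants.

## A short tour

```{r tour, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_experiment(cfg)
report_table(res$summary)

d <- design_table(res$summary, engine = "likelihood", metric = "pcp")
art_anova(d)
art_contrasts(d, "strategy", within = 80)
```

## Known limitations

* The engines are desk-scale reimplementations of the likelihood and
  distance placement *algorithms*, not wrappers of EPA-ng or APPLES;
  absolute accuracy values are not comparable to published numbers from
  those tools, only the qualitative contrasts are.
* The likelihood engine assumes the query shares the reference
  coordinate system (no alignment step) and is handed the substitution
  model rather than estimating it.
* The sister-clade metric is asymmetric (deep errors are forgiven);
  results should be read with that in mind, and topological distances
  would make a useful complementary diagnostic.
* Polytomies are tolerated in the tree structures but sister groups
  require a binary parent; simulated trees are binary throughout.
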