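---
title: "Homology-based GO term prediction and its assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based GO term prediction and its assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOmology)
```

## The problem

Most proteins have no experimentally verified functional annotation.  The
cheapest family of predictors transfers Gene Ontology (GO) terms from
experimentally annotated homologs: run PSI-BLAST against an annotated
database, look at the best hits, and copy (parts of) their annotations onto
the query, with a reliability score per term.  `GOmology` implements a
complete stack of such nearest-neighbour transfer methods, the reference
baselines they must beat, a linear meta-combiner, and the recall-precision
machinery needed to assess any of them — including a leaf-based measure
that scores only the most specific predicted terms.

Everything operates on plain tabular inputs: an ontology edge list (or
minimal OBO), a protein-to-term annotation table with evidence codes, and
BLAST-tabular hit files.  The package never runs PSI-BLAST itself; hit
tables are inputs, and the "iterations" option of a predictor merely
selects which caller-provided hit file is consumed.

## The ontology and the propagation algebra

GO namespaces (here MFO/BPO-style labels) are rooted DAGs whose edges
point from specific to general, i.e. toward the root.  All methods operate
on *propagated* term sets: a set extended with every ancestor up to the
root.  Scores propagate by one of two rules:

* **maximum rule** (`propagateMax`): a parent takes the maximum score of
  its scored descendants; idempotent, order-free, and it preserves
  monotonicity (a parent never scores below a scored child);
* **cumulative rule** (`propagateCumulative`): a term's value is its own
  raw count plus the raw counts of its *distinct* descendants, then all
  values are divided by the maximum (attained at the root).  A descendant
  reachable along several paths is counted once — a depth-first traversal
  that re-visits shared subgraphs would inflate diamond motifs, and the
  once-only rule keeps the root equal to the total raw count, which makes
  the normalization interpretable as "fraction of all transferred
  annotation mass".

Depth is the length of the *longest* path to the root, matching
path-table semantics; "deepest" tie-breaks (lowest common ancestor,
deepest-leaf selection) are resolved lexicographically on the term
identifier so that every run is reproducible.  Relation labels (`is_a`,
`part_of`) are carried through loading but not distinguished during
propagation.  The root itself is uninformative ("has a molecular
function") and is stripped from every emitted prediction and every
evaluation count.

## The three transfer predictors

All three start from the same place: a hit table filtered by a strict
E-value cutoff, with self-hits removed (a benchmark target must not
inherit its own annotation) and hits to unannotated subjects dropped —
the search database consists of annotated proteins only, so a subject
that loses all records under an evidence filter effectively leaves the
database.

**Method A (unanimity voting, `predictStudentA`).**  Takes the best N
hits (default 6; 1/5/9 on the option grid).  A term found in the
propagated annotation of *all* retained hits scores 1.0, every other
transferred term 0.5 (membership is tested against propagated hit
annotations — otherwise a general term annotated at different depths in
different hits could never be unanimous).  The propagation of these
scores is reduced to its leaves and de-redundified: leaf branches are
clustered by single linkage at pairwise overlap ≥ 0.10 — which guarantees
that branches in different clusters overlap below 10% — and only the
deepest leaf per cluster survives.  Because that filter can discard
well-supported cores, any pre-clustering branch pair overlapping above
90% has its deepest common term restored, scored with the larger of the
two leaf scores (the rule is silent on this score; the maximum is the
choice consistent with max-propagation).

**Method B (log-E-value weighting, `predictStudentB`).**  Two scores are
multiplied.  The *template quality score* (TQS) summarises the whole hit
list: the mean of ln E over all retained hits plus twice their sample
standard deviation, percentile-normalized against a background of such
raw scores ("beaten by 90% of the background" maps to 0.1).  The
background is compiled by `compileBackground` over the hit tables the
caller provides (optionally a seeded sample) — the original precompiled
database-wide percentiles are not portable, so the background is a
corpus-level input here.  The *combined leaf score* of each leaf of the
pooled propagated annotation is the mean, over the leaf and its non-root
ancestors, of the term *support*: the fraction of total ln-E mass carried
by hits containing the term.  The root is excluded from the average
because its support is identically 1 and it is discarded everywhere else;
including it would only inflate every leaf uniformly.  Natural logarithms
are used throughout; support ratios are base-invariant, but the choice is
documented for reproducibility.  E-values are clamped into
[1e-180, 0.999] before any logarithm so every log is finite and strictly
negative, keeping supports in (0, 1].

**Method C (count propagation, `predictStudentC`).**  Counts how often
each term occurs among the hits' direct annotations, propagates the
counts cumulatively, and multiplies each term's normalized count by the
best percent positives (or percent identity, on the option grid) among
the hits whose propagated annotation contains the term.  By default only
the branch of the highest-scoring leaf is emitted — a deliberate
commitment to one specific function — with an all-branches option.

Unpredicted targets (no hits after filtering) yield empty predictions,
which the evaluation counts as recall 0 without touching precision.

## Baselines

* `predictPriors`: every target gets every database term, scored by the
  fraction of database proteins whose propagated annotation contains the
  term (document frequency over proteins, not over annotation records —
  the score should read as "probability that a random protein carries
  this term").
* `predictPriorsRandom`: the propagated annotation of one uniformly drawn
  database protein per target, scored by the same frequencies.  For a
  term of frequency p, picking it *and* it being true co-occur with
  probability p² under independence — `simulatePriorsCoincidence`
  verifies this analytic argument by Monte Carlo (p = 0.15 gives ≈ 0.0225,
  i.e. about 2%), which explains why always-predict priors dominate
  random-neighbour priors under set-based measures.
* `predictBlastBaseline`: max percent identity over the hits carrying the
  term.
* `predictGotcha`: the I-score Σ(−ln E) over hits carrying the term,
  normalized per target by the root I-score so thresholds in [0, 1]
  apply; whether the historical baseline normalized per target or
  globally is unrecorded, and per-target root normalization is the
  convention adopted here.

## Assessment measures

All three measures macro-average per-target recall and precision with the
same asymmetry: recall over *all* targets (an unpredicted target
contributes 0), precision only over targets that predicted something at
the operating point.

* **top-20** (`top20Curve`): for k = 1..20, keep the terms in the k
  highest *distinct* reliability values of each target.  Tiers are score
  classes, not single terms: two terms sharing the top score form one
  tier of size two.
* **threshold** (`thresholdCurve`): sweep t = 1.00 → 0.00 in 0.01 steps,
  keep terms scoring ≥ t.  A 1e-9 tolerance on ≥ makes boundary scores
  written with 3 decimals stable.
* **leaf threshold** (`leafThresholdCurve`): reduce both truth and
  prediction to their leaf terms first, then sweep the threshold over the
  predicted leaves.  Over-general predictions (up to "predict the whole
  ontology") collapse under this measure because true leaves buried as
  internal nodes never count.

`fmax` condenses a curve to its maximum F1 over points with defined
precision, and `rankMethods` orders methods by Fmax with ties sharing the
better rank.

## Re-parameterization and the meta-combiner

`enumerateGrid` builds the documented option grids (36, 54 and 72
settings for methods A, B, C), and `optimizeParams` picks the
threshold-Fmax argmax on a hold-out set, ties resolved by enumeration
order.  `twoFoldPredictions` implements the role-switching protocol: a
seeded half-split (floor/ceil for odd sizes), optimization on one half,
prediction of the other, then the reverse, so each target is predicted
exactly once per method by a model that never saw it.

`fitMeta` trains the combiner x·A + y·B + z·C + i = p on one row per
(target, candidate term), candidate terms being the union of the three
methods' predictions (a method that skipped a term contributes 0).  The
regression is *weighted* least squares; since candidate rows are
overwhelmingly negative, the default weights are inverse class
frequencies (positives and negatives contribute equal total weight), with
uniform weighting available.  A rank-deficient design (e.g. constant
scores) falls back to the minimum-norm pseudoinverse solution and is
flagged on the model object.  `predictMeta` clamps the combined score
into [0, 1] and max-propagates, so every evaluation threshold applies.
One model serves a namespace; MFO and BPO are evaluated separately
throughout, and per-namespace models are simply separate fits.

## The synthetic benchmark generator

`genBenchmark` fabricates everything the stack consumes: a layered random
DAG with configurable depth, branching and diamond (multi-parent) rate; a
protein database annotated with 1..k ontology leaves under a configurable
evidence-code mix; and per-target hit tables whose statistics correlate
with annotation overlap.  Hits are generated directly as tabular records
— E-values log-uniform in a configurable range, scaled down for subjects
whose annotation overlaps the target's truth, percent positives rising
with overlap plus Gaussian noise, identity bounded by positives — because
the predictors consume only these statistics; simulating actual sequence
evolution would add nothing testable.  Templates and targets are disjoint
(a logical stand-in for the temporal template/target split of real
benchmarks; no dates are modelled), and a few templates per target are
re-annotated as exact homology "clones" (disjoint host blocks, so clones
stay exact) to guarantee that faithful hits exist at fidelity 1.

The `fidelity` dial interpolates between uniform subject draws (0) and
draws from the best-matching templates (1).  At fidelity 1 with zero
identity noise and single-leaf annotations, every predictor provably
recovers each target's exact truth — method A because unanimity holds,
method B up to its template quality factor, method C because the single
best leaf is the true one — and the test suite asserts threshold-Fmax
1.0 for all three under exactly those conditions.  Multi-leaf truths are
deliberately not part of that assertion: method C's default single-branch
output and method A's redundancy filter both trade recall for precision
there, which is behaviour, not error.

What the generator does *not* emulate: realistic E-value distributions,
annotation biases of curated databases, term co-occurrence structure, or
ontology-scale term counts.  Passing tests therefore demonstrate
correctness of the algorithms under controlled conditions, not
performance on real proteomes.

## Numerical and design choices

* E-value cutoffs are strict (`evalue < cutoff`); truncation to the hit
  budget happens after the cutoff, and E = 0 is floored to 1e-180.
* Scores are serialized with 3 decimals (2 is traditional; 3 reduces tie
  artifacts in the 0.01-step threshold sweep), and one namespace is
  processed per invocation.
* Problem sizes in the tests and examples are deliberately small —
  ontologies of 25–60 terms, databases of 30–100 proteins, 100,000
  Monte-Carlo draws — chosen so the full stack (including two-fold grid
  optimization, 162 settings per fold pair) is exercised end-to-end in
  seconds while every property under test is already non-trivial at that
  scale.
* All randomness (generators, splits, samples) flows through explicit
  seeds and restores the caller's RNG state.

## Known limitations

Support of OBO is minimal (`id`, `is_a`, `relationship: part_of`,
`namespace`); cross-namespace edges and obsolete terms are out of scope.
The background distribution of method B is only as representative as the
hit tables supplied to `compileBackground`.  Headline numbers from
full-scale benchmarks (database-wide Fmax values and method rankings on
historical data) require the original multi-thousand-protein datasets
and are not reproducible at this scale; what the package reproduces
instead are the worked single-target examples, the combinatorial grid
counts, the analytic coincidence rate, and the behavioural properties
asserted in the test suite.
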