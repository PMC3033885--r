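---
title: "Hyper-box enclosure classification: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyper-box enclosure classification: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperbox)
```

## The model

A hyper-box classifier represents each tumor class by one or more
axis-aligned boxes in scaled expression space: per-gene intervals
`[L_m, U_m]` carrying a class label. The appeal for expression panels is
interpretability — a box *is* a set of per-gene reference ranges — and the
absence of per-dataset tuning parameters: the same pipeline is run unchanged
on every dataset.

All training data are min–max scaled per gene, `x' = (x − x_min)/(x_max −
x_min)`, using training extrema only. Test samples are scaled with the same
parameters and may land outside `[0, 1]`; they are deliberately not clamped,
because clamping would silently move unseen samples onto box boundaries.
Genes constant in training map to 0 with a warning: the division is
undefined there and a constant gene carries no class information either way.

Training has five stages.

**Class bounds and problematic samples.** Each class's bounding box is the
componentwise extrema of its samples. A sample inside a foreign class's box
is *problematic*: no assignment of one box per class can separate it. The
marking is refined (default 2 rounds): bounds are refit on the currently
non-problematic samples and all samples re-marked against the refitted
boxes. Because refitted bounds are subsets of the previous ones, the
problematic set shrinks monotonically and the iteration reaches a fixpoint
quickly; the refinement exists to keep the downstream optimization small.

**Seed finding.** For each class one representative sample (the *seed*) is
fixed before the main optimization. Seed quality is an explicit integer
program: sample `s` of class `k` has cost
`Σ_{j∈k} d(s,j) − (1/|out|)·Σ_{j∉k} d(s,j)` with Euclidean `d`, and the
model picks the cost-minimizing sample per class. The "one seed per class"
constraint matrix is an interval matrix over disjoint blocks — totally
unimodular — so every basic optimum of the LP relaxation is integral and the
IP decomposes into independent per-class minimizations. `find_seeds()`
exploits the decomposition; `check_lp_integrality()` verifies the
total-unimodularity consequence on any instance by solving the relaxation
with an independent simplex routine (`boot::simplex`) and comparing value
and integrality against the IP. Ties break to the lowest sample index.

**Box construction (MILP).** The problematic samples plus the seeds enter a
mixed-integer model: binaries `x[i,b]` (sample-to-box), `z[b,k]`
(box-to-class), `u[b]` (box used), `y[i,k]` (misclassification), continuous
bounds `L, U ∈ [0,1]`; constraints give every sample exactly one box, every
used box exactly one class, tie bounds to assigned samples via big-M = 1
(valid because the data are scaled), and fix each seed into a designated box
of its class. The objective is `Σ y + λ·Σ u` (default `λ = 1`; any
`0 < λ ≤ 1` keeps misclassification lexicographically dominant when the box
budget is at most the sample count). The box pool is `classes ×
max_boxes_per_class` (default budget 2).

Cross-class overlap is *not* forbidden at this stage; it is resolved
afterwards. That staging has a structural consequence worth stating plainly:
since every class always has its seed box available, every sample can be
assigned to a box of its own class, so the optimum has zero
misclassifications and exactly one box per class — the model's value lies in
fixing the optimal grouping, and the geometric separation work happens in
the elimination stage. It also makes the model fully decomposable: bounds
never bind (a used box can always take exactly its members' extrema), and
given the `z` configuration each sample independently chooses a cheapest
box. `build_boxes_milp()` is therefore an exact solver that enumerates the
free-box class configurations — a deliberate design, documented here
because no general MILP library is involved: the enumeration *is* provably
optimal for this model, and `box_search_bruteforce()` (full enumeration of
configurations × assignments) independently confirms the optimum in the
test suite. The formulation reconstructs a narrative model description
whose exact algebra is not published; it is labeled as a reconstruction.

**Enclosure of non-problematic samples.** Each class's non-problematic
samples (excluding seeds, which already sit in MILP boxes — membership must
stay disjoint) form one *defined* box at their extrema.

**Intersection elimination.** While any two boxes of different classes
overlap (closed intervals: boundary contact counts, keeping prediction
containment unambiguous), the offending pair is chosen deterministically —
pairs with a defined/split box first, then lowest class index, then largest
overlap volume, then box order — and the pair's defined/split box sheds the
members lying inside the other box into a new *split* box; if none lie
inside, it sheds the single member nearest the overlap region. Two cases are
not covered by that base rule and are resolved as follows: if the preferred
box cannot strictly shrink (it is a point box, or *all* members would
leave), the roles swap to the other box; a box whose members all lie inside
the other sheds all but its lowest-index member. If neither box can shrink,
both are point boxes at identical coordinates with different labels — the
data are inconsistent, and fitting stops with an error naming the samples.
Every step moves at least one member from a multi-member box into a new
nonempty box, so the box count strictly grows toward its (finite) member
bound and the loop terminates.

**Prediction.** A query inside a box takes the box's class; otherwise the
nearest box wins (componentwise distance to the interval, then the norm).
Ties go to the smaller box volume (volumes compared at 12 significant
digits to absorb floating-point dust), then the earlier class, then box
order.

## Gene ranking

Three standard filters initialize gene selection:

* **Information gain** `IG = H(Y) − H(Y|X)` in bits, with expression
  discretized by Fayyad–Irani MDL recursive partitioning (equal-width
  binning, default 10 bins, is available for comparisons, and `"none"`
  treats values as already discrete). MDL was chosen because expression is
  continuous and the criterion needs no bin-count parameter.
* **ReliefF** with `k = 10` neighbors capped at the smallest class size
  minus one, Manhattan per-gene differences on range-normalized values, all
  samples as probes by default (sub-sampling probes is seeded). Scores land
  in `[−1, 1]`; label-independent genes converge to 0.
* **CFS**: merit `k·r̄_cf / √(k + k(k−1)·r̄_ff)` with both association
  terms computed as symmetrical uncertainty on MDL-discretized values —
  the canonical instantiation that keeps both terms in `[0, 1]` — explored
  by forward best-first search stopping after 5 stale expansions. For
  ranking purposes the selected subset comes first and the remaining genes
  follow by individual association, so a requested `top_n` larger than the
  subset stays meaningful.

Ties everywhere break by ascending gene index, for determinism.

## The variance-ratio search

For gene `g` and class `k`, `X = Var_all(g)/Var_k(g)` is large when the
gene is tight inside the class but variable overall. The score is the F CDF
of `X` at `(N−1, n_k−1)` degrees of freedom (sample variances; raw counts
are available as an option), the per-gene summary is the max over classes.
The published description of this quantity is ambiguous about direction: it
names the score "1 − FCDF" yet calls values *close to 1* most informative,
while `1 − FCDF(X)` of an informative gene tends to 0. This package follows
the stated *orientation* (informative ⇒ near 1), i.e. it reports
`FCDF(X)` = one minus the upper-tail p-value; the convention lives in a
single internal function (`fcdf_informativeness`) so flipping it cannot
touch the search logic. A within-class variance of zero would make `X`
undefined; it is floored at a machine-epsilon-scaled value with a warning,
which sends the score to 1 — the limit behavior of an infinitely tight
class.

The search itself is the published greedy heuristic, implemented as such
(global optimality is explicitly not claimed): swap the lowest-summary gene
of the current set for the highest-summary unused pool gene, evaluate by
stratified cross-validation (default 10-fold — CV rather than training
accuracy, because point boxes make training accuracy trivially optimistic),
record, repeat up to `max_iter` (default 20) or pool exhaustion.
Swapped-out genes retire from the pool, which rules out cycling and bounds
the search by the pool size. The pool is pre-filtered so no kept gene has
absolute Pearson correlation above 0.9 (configurable) with an earlier one.
The best set is the recorded maximum, ties to the earliest iteration; the
initial set is always recorded, so the result is never worse than the
starting point. The initial set size is not fixed by the method; 10 is the
default, matching the size range in which published gene panels fall (4–10).

## Evaluation protocols

`evaluate_test` (train/test), `cross_validate` (repeated stratified
k-fold), and `loocv` (= `cross_validate` with `k = n`, whose sd is flagged
undefined) all share one harness. Two protocol choices deserve their own
paragraph:

* **Mean ± sd.** Published accuracy tables of this form rarely state what
  the "±" spans. The default here is 5 repeats with the sd over repeat
  means, which matches the small printed spreads far better than
  fold-to-fold variation; `sd_over = "folds"` switches to fold-level sd so
  both readings are auditable.
* **Selection inside folds.** Whether gene selection belongs inside or
  outside the CV loop is likewise often unstated. The honest default is
  inside (selection and scaling refit per training fold); `selection =
  "outside"` mimics the legacy protocol and is labeled in the result
  object. The test suite demonstrates the leak: on pure-noise data with
  many genes, outside-fold selection inflates accuracy above chance while
  the inside protocol stays at chance level.

Stratification is the default for k-fold because the targeted datasets have
classes as small as 8; folds are dealt per class in load order so fold
sizes differ by at most one globally and per class. A majority-class dummy
classifier plugs into the same harness as a sanity baseline.

## Synthetic data

The generators make every stage testable without external downloads, and
their defaults are the package's study conditions:

* `make_fig2_scenario`: four Gaussian blobs on two attributes (sd 0.06
  around centers on a unit square), with an `overlap_fraction` (default
  0.2) of each class re-drawn inside a neighboring class's bounding region
  to guarantee problematic samples.
* `make_microarray`: 500 genes, 60 samples, 3 classes, 5 planted markers by
  default. Noise genes are log-normal positive intensities (right-skewed,
  microarray-like; a Gaussian alternative exists), identical across
  classes; planted genes take class-specific log-scale shifts spaced 3
  within-class standard deviations apart — a strong, clean marker signal.
  Ground truth is returned beside the data, never encoded in gene ids.
* `make_separable`: every gene gives each class a dedicated interval with a
  guaranteed margin (default 0.2, class order rotating across genes); the
  generator asserts pairwise-disjoint class boxes before returning. The
  class structure is placed on every gene because per-gene min–max scaling
  rescales any "low-amplitude noise" gene back to full range — a noise
  gene would re-introduce spurious nearest-box ambiguity that the
  separable guarantee is meant to exclude.

What passing on these generators does *not* show: robustness to batch
effects, probe-level artifacts, missing values, heavy-tailed outliers, or
markers weaker than the planted effect size — none of which the generators
emulate.

## Numerical and scale choices

Box overlap and containment use closed intervals with a `1e-12` tolerance;
LP integrality is judged at `1e-7`; oracle equality at `1e-9`. The
verification scales — 100 random instances for the seed IP and LP checks,
50 for the MILP oracle, 200 fitted models for the geometry sweep, 20 seeds
for the recovery study (10-fold CV, information-gain top-10 start) — keep
the full suite around two minutes on one CPU while exercising 2–4 classes,
2–5 genes, and class sizes 2–6, the regime where exhaustive oracles are
affordable.

## Known limitations

* The box MILP, by design of its published staging, never trades
  misclassification against box count in practice (see above); datasets
  whose difficulty lies in heavy class interleaving are handled almost
  entirely by intersection elimination, which can produce many small boxes
  (up to one per sample in the worst case).
* Identical expression vectors with different labels are unrepresentable
  and raise an inconsistent-data error rather than a soft misclassification
  flag.
* The elimination order rule is a deterministic choice among several
  defensible ones; different orders can yield different (all valid,
  non-overlapping) box sets.
* ARFF support covers numeric attributes plus one nominal class attribute
  only.
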