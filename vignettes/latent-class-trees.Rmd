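---
title: "Latent class trees: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class trees: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standard latent class (LC) analysis clusters respondents from categorical
survey items by fitting a finite mixture of product-multinomial
distributions. On large datasets, information criteria routinely favor
models with many classes whose pairwise differences are hard to interpret,
and different criteria disagree on how many classes to keep. A latent
class *tree* (LCT) replaces the flat solution with a divisive hierarchy:
a small, interpretable model at the root, refined by recursively splitting
classes into subclasses. Every split can be read conditionally on its
parent, so a nine-leaf tree stays interpretable where a flat nine-class
model would not be.

`lctree` implements this procedure for two likelihoods: ordinary
categorical indicators, and a discrete-choice model for items where each
respondent gives a first and a second choice among a set of alternatives.

## Model and estimation

For responses $y_{ij}$ of case $i$ on item $j$, the $K$-class model is

$$P(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J} P(y_{ij} \mid X = k),$$

with local independence within class. At any node of the tree the same
model is fitted to the full dataset reweighted by the node's case
weights, maximizing the weighted log-likelihood
$\sum_i w_i \log P(y_i)$. Estimation is EM:

* **E-step**: posterior class memberships by Bayes' rule.
* **M-step**: closed-form weighted updates of the class proportions and
  the class-conditional response probabilities.

The M-step has a closed form for indicators; for the ranking model the
class-specific logits are updated by BFGS on the aggregated pair counts
(see below).

**Starts.** EM is run from `n_starts = 16` independent random soft
assignments by default and the best final log-likelihood is kept.
Mixture likelihoods are multimodal; 16 starts is a practical default for
the ten-to-twenty item problems the package targets, and every
convergence failure is flagged on the returned object rather than hidden.

**Convergence.** A start stops when the relative change in the weighted
log-likelihood falls below `tol = 1e-8`, or after `max_iter = 1000`
iterations. Within a start the log-likelihood is monotone non-decreasing
(a property the test suite checks directly).

**Boundary protection.** After each M-step, response probabilities are
floored at `prob_floor = 1e-6` and renormalized. Without the floor,
weighted subsamples regularly drive cells to exact zero and a later
E-step would take `log(0)`. The floor is far below anything
substantively interpretable and configurable where a boundary solution
is wanted.

**Seeds.** A single master seed deterministically generates
per-start (and, in the tree, per-node) seeds, so any fit, table, tree,
or simulation study is bit-reproducible from one integer. The global RNG
state of the session is restored afterwards.

**Missing data** are rejected at construction with the offending row and
column named. Weighted-likelihood EM with missingness raises questions
(MAR assumptions, per-item weights) the package does not answer in this
version.

## Growing the tree

The root is split into `root_K` classes; every case is then carried into
each child with weight equal to its posterior membership probability
(*proportional assignment* — no case is ever hard-assigned), so a weight
at depth $d$ is a product of $d$ posteriors and the per-case weights
across the leaves always sum to one. Each new node is tested
breadth-first with a binary split and split as long as the criterion
accepts; children within a split are ordered by size, largest first, and
labeled by digit paths ("21" is the second child of root child "2").

A split at a node is accepted when the BIC of the two-class model on the
node-weighted data is below that of the one-class model (AIC is
available as a more liberal gate: it produces the same splits plus
possibly more). Two conventions exist for the $N$ in the BIC penalty at
a non-root node, and they genuinely differ: the total (root) sample
size, or the node's effective size (sum of its weights). The package
defaults to the total sample size — the form in which the criterion is
conventionally printed — and exposes `ic_n = "effective"` for the
statistically natural alternative; at the root they coincide, and the
choice only shifts split decisions near the acceptance boundary.

Safeguards: growth stops at `max_depth = 10`; nodes whose effective size
is below 1% of $N$ (configurable) are not tested; a node with fewer
effective cases than the split model has parameters is auto-rejected
with a warning. Exact size ties between children are broken by
lexicographic comparison of the class profiles so labeling is
deterministic.

## Sizing the root: relative improvement of fit

Binary splits can be structurally wrong at the root — e.g. three
mutually distinct classes force the first binary split to shear one
class across both children. The package therefore sizes the root with
the *relative improvement* measure

$$RI_{K,K+1} = \frac{\log L_{K+1} - \log L_K}{\log L_2 - \log L_1},$$

the fit gain of adding a class beyond $K$, relative to the gain of the
first split (for BIC/AIC the improvement is the decrease). The selected
root size is the smallest $K \ge 2$ with $RI_{K,K+1}$ below a threshold,
defaulting to 0.10: in the benchmark configurations below, layouts where
a binary root suffices produce values well under 0.10 while a genuinely
ternary layout produces values several times larger, so 0.10 sits in the
gap. The full RI table is always reported — the measure is meant to aid
judgment, not replace it; `RI_{1,2} = 1` by construction and is printed
as a sanity row.

Two caveats are deliberate. The measure is not mathematically bounded by
1 — a later split can improve fit more than the first — and such values
are reported with a warning, never clamped. And RI values recomputed
from *rounded, printed* fit columns can differ in the third decimal from
values computed on unrounded fits; the package computes on unrounded
values and rounds only for display (3 decimals for RI, integers for
BIC/AIC).

## The top-2 ranking model

For items where a respondent picks a first and a (different) second
choice among $A_j$ alternatives, each class $k$ holds per-item utilities
$\tau_{ak} = e^{\beta_{ak}}$ and

$$P(a_1, a_2 \mid k) =
  \frac{\tau_{a_1 k}}{\sum_a \tau_{ak}} \cdot
  \frac{\tau_{a_2 k}}{\sum_{a \neq a_1} \tau_{ak}},$$

a top-2 exploded logit: the second choice is a standard logit over the
non-selected alternatives, with utilities shared between the two choice
stages (this sharing is a substantive assumption of the model and is
hard-coded). Effects coding ($\sum_a \beta_{ak} = 0$ within item and
class) identifies the logits and is enforced *by construction* — the
optimizer works on $A_j - 1$ free logits per item and class, with the
last equal to minus their sum — so the constraint holds exactly at every
step rather than approximately via a penalty. Per item and class the
M-step objective depends on the data only through the $A_j(A_j-1)$
weighted ordered-pair counts, which makes the inner BFGS (analytic
gradient, tolerance `1e-9`) cheap at any sample size. The model plugs
into `fit_table()` and `grow_tree()` through the same adapter interface
as the indicator model, so trees on ranking data need no special code
path. Parameter count: $(K-1) + K\sum_j (A_j - 1)$.

## What the synthetic generators emulate

`simulate_lc()` draws class labels from the class proportions and item
responses independently given class — exactly the data-generating
process the model assumes. `config_profiles()` provides three frozen
benchmark layouts on 10 binary items with equal class sizes and 1,000
cases, emulating the canonical situations for root sizing:

* **A** — one distinct class (0.8 on all items) and two fairly similar
  classes averaging 0.2 (0.3/0.1 on complementary halves). A binary root
  works: the first split isolates the distinct class, the next split
  separates the similar pair. $RI_{2,3}$ stays far below 0.10.
* **B** — three mutually distinct classes (0.8 throughout; 0.2
  throughout; 0.8/0.2 by half). A binary root is structurally wrong and
  $RI_{2,3}$ is large in every replication.
* **C** — four classes in two macro-clusters (pair means 0.8 and 0.2)
  with within-pair differences of 0.35 on disjoint five-item subsets.
  The binary root separates the macro-clusters and two further binary
  splits recover all four classes; $RI_{2,3}$ is small for most
  replications, with more sampling spread than A.

The exact probability values are package constants, chosen once so that
each layout actually exhibits the qualitative behavior that defines it —
in particular, the within-pair separations in A and C are large enough
that the second-level BIC splits succeed at $n = 1000$, and small enough
(in A) that the root-level RI stays low. They are documented in
`?config_profiles` and versioned with the package so tests are stable.

What these generators do *not* emulate about real survey data: local
dependencies between items within a class (e.g. near-duplicate items),
unbalanced class sizes, item-level missingness, and measurement drift.
A passing simulation study therefore shows the machinery is correct
under the model's own assumptions — not that any particular real
dataset has classes.

`run_ri_study()` repeats simulate-then-fit over replications and
collects $RI_{2,3}$ (and $RI_{3,4}$ where fitted). The default is 20
replications — enough to see the qualitative separation between the
configurations, which is the study's point — with the full 100 available
by argument.

## Problem sizes used by the tests

The test suite fits tiny instances against independent oracles
(brute-force class enumeration; a dense grid search over the full
parameter space of a two-class two-item model, polished by Nelder-Mead),
runs the three-configuration study at 20 replications of $n = 1000$, and
checks parameter recovery at $n = 5000$ (response probabilities within
0.03; ranking logits within 0.15 after class matching). Tree-growing
tests use 6 EM starts rather than 16: the splits involved are well
separated and insensitive to the number of starts.

## Known limitations

* Nonbinary splits are automated only at the root; deeper nodes default
  to binary with a per-node manual override (`k_split_overrides`). An
  RI-style rule for interior nodes would need a within-branch baseline
  and is left open.
* The BIC gate tests one split at a time; it does not correct for the
  sequence of tests performed while growing.
* No covariates, no ordinal restrictions, no within-class item
  dependencies, no missing data.
* Rankings deeper than first-plus-second choice are out of scope; the
  pair model is not a general Plackett-Luce implementation.
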