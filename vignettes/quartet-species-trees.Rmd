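---
title: "Quartet-score species trees: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet-score species trees: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstree)
```

## The model and the score

Under the multispecies coalescent (MSC), gene lineages coalesce within the
branches of a species tree; when an internal branch is short (in coalescent
units, time divided by 2Ne generations), lineages may fail to coalesce within
it and the resulting gene tree can disagree with the species tree
(incomplete lineage sorting). For any four species around an internal branch
of length $d$, the gene tree displays the species-tree pairing with
probability $1 - \tfrac{2}{3}e^{-d}$ and each alternative pairing with
probability $\tfrac{1}{3}e^{-d}$. Because the species pairing is always the
most probable one, the species tree can be estimated consistently by
maximizing the **quartet support score**: the (weighted) number of
four-species subtrees on which the candidate tree agrees with the gene
trees. `qstree` computes this score exactly, searches for its maximizer, and
annotates the result — all of it testable against synthetic data from the
bundled simulator.

### Exact scoring by anchored tripartition counting

A resolved quartet $ab|cd$ induced by a gene tree has a unique internal
path; its endpoints are the gene-tree nodes where $\{a,b\}$ and $\{c,d\}$
merge. The same is true in a binary species tree. `qstree` counts each
agreeing quartet at its **two species-tree anchors**: the gain of an
internal node with tripartition $(A,B,C)$ is the weighted number of
quartets with one species in $A$, one in $B$ and a (distinct-species) pair
in $C$ (plus the two block rotations) that the gene trees display
identically. Summing gains over all $n-2$ internal nodes counts every
agreeing quartet exactly twice, so the score is half the total. This makes
the gains additive per node — exactly what the constrained dynamic program
needs — while remaining equal to the brute-force enumeration.

On the gene-tree side, the kernel enumerates ordered pairs $(p,q)$ of
internal nodes and multiplies per-component taxon masses: the pair split at
$p$ away from $q$, the pair merged at $q$ away from $p$. Polytomies need no
special casing (a node of degree $m$ simply has $m$ components), and the
count is $O(I_g^2)$ per gene tree with $I_g$ internal nodes — polynomial in
$n$ and linear in the number of trees $k$, with no quartet enumeration or
subsampling. The brute-force route (`quartet_score(..., method = "brute")`)
instead iterates all $\binom{n}{4}$ quadruples using edge bipartition masks;
the two routes share no counting code, and their agreement — exact in unit
mode, $10^{-9}$ relative in weighted modes — is enforced on hundreds of
random instances with polytomies, missing taxa and multiple individuals in
the test suite.

### Weighting schemes

* **unit** — each resolved quartet counts 1.
* **support** — each quartet counts the product of the supports of the
  internal branches on the path connecting its two pairs in the gene tree.
  Supports live on $[0,1]$; a branch without a support counts
  `default_missing_support` (default 1). If any support in an input set
  exceeds 1 the whole set is treated as percent-scale (bootstrap
  convention) and divided by 100; `support_scale` overrides the detection.
* **hybrid** — the support weight times $e^{-L}$, where $L$ is the sum of
  the four terminal path lengths of the induced quartet subtree. Long
  terminal branches mean more substitutions and more gene-tree estimation
  error for that quartet, so such quartets are discounted. The exact
  weighting formulas of the weighted-score literature live behind the
  `weight_scheme` abstraction and can be swapped without touching the
  scorer.

*Design choice (uncapped length factor).* An earlier design capped the
length penalty at $e^{-\min(L, 20)}$. The cap breaks the factorization of
$e^{-L}$ into per-leaf terms $e^{-\mathrm{dist}(x, \text{anchor})}$ that the
tripartition kernel relies on, and would introduce discrepancies between the
fast and brute routes of up to $2\times10^{-9}$ per quartet — violating the
equality contract for no benefit, since $e^{-L}$ cannot underflow to zero
for any realistic $L$ in double precision. `qstree` therefore uses
$e^{-L}$ uncapped; the factor stays in $(0,1]$, and trees without branch
lengths get factor 1 (missing lengths contribute 0 to $L$).

### Missing data, normalization, multiple individuals

A species absent from a gene tree simply contributes no quartets for that
tree (no imputation). Quartets unresolved in a gene tree (polytomies)
contribute to neither the numerator nor the normalization denominator —
matching the workflow where poorly supported gene-tree branches are
contracted before scoring (`contract_low_support`). The denominator is the
total weight of all resolved quartets co-present in the gene tree and the
species tree, so `normalized` is in $[0,1]$ and equals 1 exactly when every
resolved gene-tree quartet agrees. Species present in the gene trees but
not in the (possibly partial) species tree are excluded from both sides;
this convention is what makes stepwise-placement scoring and supertree
inputs well defined.

With multiple individuals per species (a `taxon_map`), each quadruple's
contribution is averaged over all choices of one individual per species.
The kernel implements this exactly by giving each leaf multiplicity
$1/n_s$ ($n_s$ = individuals of its species in that tree), which turns the
average into a factorized product of per-component masses; the same-species
corrections (a pair must be two *different* species) use an
inclusion–exclusion step that vanishes automatically for single-individual
data.

## The search

1. **Stepwise placement.** For each of `n_init` (default 4) uniformly random
   species orders, start from a star on the first three species and attach
   each next species to the edge maximizing the score restricted to the
   placed taxa. The paper behind this strategy fixes neither the number of
   initial trees nor the order rule; both are exposed in `search_config`.
2. **NNI hill climbing.** Full sweeps over all $2(n-3)$ neighbors,
   best-improvement, accepting only strict gains, at most
   `nni_max_rounds` (default 50) sweeps. The returned score never drops.
3. **Constrained DP.** Clusters are the bipartition sides not containing the
   reference taxon (the lexicographically smallest species). The constraint
   set is the union of all input-tree bipartitions, all trivial clusters,
   and one closure round adding pairwise intersections and differences —
   a bounded-cost enrichment of the search space. `best(A)` maximizes over
   splits of $A$ into two constituent clusters plus the tripartition gain of
   $(A_1, A_2, \overline{A})$; the result is provably optimal within the
   set and at least as good as every input tree. With
   `full_constraint_set()` (all $2^{n-1}-1$ clusters) the DP is an exact
   global optimizer, which the tests verify against exhaustive enumeration
   of all 105 (n=6) and 945 (n=7) unrooted binary trees.

**Tie-breaking.** Placement ties choose the edge with the smallest
canonical (sorted child-side) key; NNI ties the smallest canonical Newick;
the DP scans clusters in a fixed (size, bitmask) order and keeps the first
strict maximum. All three are deterministic, so identical seed and input
give byte-identical output — asserted at the CLI level in the tests.

**Limits.** Cluster bitmasks use native integers: constrained search
handles at most 31 species. Scoring, annotation and simulation have no such
limit. The divide-and-conquer acceleration of the original C++
implementation is intentionally out of scope.

## Branch annotation

Every internal branch of a binary species tree defines a quadripartition
$(A,B\,|\,C,D)$. Accumulating weighted gene-tree masses for the three
pairings gives frequencies $(q_1, q_2, q_3)$ (species-tree pairing first)
and the effective count $n$ (only quadruples co-present in a gene tree are
counted). From these:

* **Coalescent length** $d = -\ln(1.5\,(1 - q_1))$, the inversion of the
  MSC matching probability; $q_1 \le 1/3$ gives $d = 0$ and
  $q_1 \ge 1 - 10^{-6}$ is capped at $D_{\max} = 10$ (at $q_1 = 1$ the
  estimate is infinite; 10 coalescent units is already indistinguishable
  from complete sorting).
* **Local posterior probability**: posterior that pairing 1 is the species
  pairing under a uniform prior over the three pairings, an exponential(1)
  prior on $d$, and per-observation MSC probabilities
  $(1 - \tfrac23 e^{-d}, \tfrac13 e^{-d}, \tfrac13 e^{-d})$. The integral
  over $d$ uses a fixed 201-point log-spaced trapezoid grid on
  $[10^{-6}, 20]$, evaluated in log space; the tests check agreement with a
  4001-point grid to $10^{-6}$ and the analytic symmetry/monotonicity
  properties.

Annotations are serialized as internal-node labels
`q1=..;q2=..;q3=..;pp=..;n=..` with $d$ as the branch length. Because `;`
terminates a Newick statement, such labels are single-quoted on output and
the parser reads quoted labels back; `label_mode = "pp"` or `"support"`
emit a single scalar for strict downstream consumers.

## The simulator and what a green test establishes

`simulate_gene_tree` implements the standard coalescent-within-species-tree
algorithm: within each branch, from the tips rootward, lineage pairs merge
after exponential waits at rate $j(j-1)/2$, truncated at the branch length
(in coalescent units); remaining lineages coalesce above the root. Missing
terminal lengths default to 1 coalescent unit. The error model adds, per
gene tree: one uniform random NNI with probability `nni_prob`; species
dropped independently with probability `p_miss` (never below 4 leaves); and
synthetic supports — Beta(20,1) (median ≈ 0.97) on branches agreeing with
the pre-error tree, Beta(2,2) on perturbed branches — emulating
approximate-Bayes supports, where high thresholds (≈0.9) are the
recommended contraction level.

The generator's defaults state the simulated world of the acceptance tests:
5-taxon (consistency) and 8-taxon (weighting benefit) caterpillars with
0.5-coalescent-unit internal branches and unit terminal branches; $k=1000$
gene trees for consistency, $k=50$ with `nni_prob = 0.3` for the weighting
comparison. The simulator emulates topology-generating coalescent noise and
support-correlated gene-tree error. It does **not** emulate alignment or
sequence-level estimation error, gene flow or hybridization (for which the
quartet-matching theorem can fail), paralogy, or non-ultrametric species
trees (tips are placed at height 0). A green consistency test therefore
establishes correct behavior under the MSC with ILS and simple gene-tree
error — not robustness to those excluded processes.

## Numerical conventions

* Unit-mode scores are integer-exact (double accumulation of integers far
  below $2^{53}$); weighted comparisons use $10^{-9}$ relative tolerance.
* Score ties during search are resolved with a $10^{-9}$ relative band and
  the canonical orders above.
* Branch supports are normalized once per input set (percent-scale
  auto-detection across the whole file, not per tree) so that a file mixing
  scales is treated consistently; `quartet_weight` on a standalone tree
  auto-detects within that tree.
* Absent branch lengths are stored as missing, never as 0; unary nodes are
  suppressed at parse time with lengths summed; degree-2 roots are
  suppressed for all scoring, merging the two root branches (lengths
  summed, the surviving support label kept).
* Gene trees with fewer than two internal nodes (stars with fewer than 2
  resolved splits, tiny trees) contribute zero to every score, by
  construction of the pair enumeration.

## Known limitations

Single-copy gene trees only; no multi-copy paralog tagging. The local
posterior treats quartet observations as independent, as is standard, which
overstates confidence for correlated quartets sharing branches. The
weighted-mode formulas are deliberate stand-ins behind `weight_scheme`
(see above). Constrained search is limited to 31 species. The simulator's
species trees are treated as ultrametric for gene-tree branch lengths;
topologies are unaffected.
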