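---
title: "Common refinement of rooted trees on a shared leaf set: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common refinement of rooted trees on a shared leaf set: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincr)
```

## The problem

A rooted phylogenetic tree on a taxon set $L$ is equivalent to its
*hierarchy* of clusters $\mathcal{H}(T) = \{L(T(v)) : v \in V(T)\}$: the
set system containing $L$, every singleton, and one cluster per inner
vertex, any two of which are nested or disjoint.  When several trees
$T_1,\dots,T_k$ on the *same* leaf set are produced — say, partially
resolved gene trees inferred from different data types for the same taxa —
the natural reconciliation question is whether a single tree displays all
of them.  For a common leaf set, "$T$ displays $T_i$" reduces to
$\mathcal{H}(T_i) \subseteq \mathcal{H}(T)$, so a common refinement exists
iff $\mathcal{H} := \bigcup_i \mathcal{H}(T_i)$ is itself a hierarchy, and
the inclusion-minimal witness is the unique tree $T$ with
$\mathcal{H}(T) = \mathcal{H}$.  That tree is *least resolved*: contracting
any inner edge of $T$ removes a cluster that some input tree requires.

`lincr()` decides existence and builds $T$ in $O(k\,|L|)$ time.
`refine_by_union()` is the same mathematical object computed the
definitional (quadratic) way, and `build_from_triples()` reaches it through
a third formalism — Aho's BUILD applied to the pooled rooted triples of the
inputs.  All three must agree everywhere; the test suite enforces this on
an exhaustive catalogue of small trees and on simulated instances.

## The bottom-up construction

The algorithm never materializes $\mathcal{H}$.  It grows the parent
function of the candidate tree $T$ upward from the leaves, maintaining for
each discovered vertex $v$:

* $J(v)$ — the indices of the input trees containing a vertex with
  cluster $L(T(v))$ (never empty; all of $1..k$ for leaves and the root);
* $p_i(v)$ — the lowest vertex of $T_i$ weakly above $v$, i.e. the vertex
  whose cluster is the inclusion-minimal cluster of $T_i$ containing
  $L(T(v))$.  By construction $p_i(v) = v$ exactly when $i \in J(v)$;
* a bidirectional correspondence between $v$ and its copies in the $T_i$.

When $v$ is dequeued, its parent in $T$ is the minimum, in the ancestor
order of $T$, over one candidate per tree: $\mathrm{parent}_{T_i}(v)$ for
$i \in J(v)$, and $p_i(v)$ otherwise.  Two facts make this cheap.  First,
all candidates are ancestors of $v$ in $T$ and hence pairwise comparable.
Second, among comparable vertices of a phylogenetic forest, ancestry is
equivalent to comparing subtree leaf counts, which are precomputed per
input tree by the postorder recursion (`leaf_counts()`): 1 at leaves, sum
over children otherwise.  The minimum is therefore a scan of $k$ integers;
the trees attaining it form $J(u)$ of the parent $u$ (the running "list of
equalities" is re-initialized whenever a strictly smaller candidate
appears), and $p_i(u)$ follows by a three-case recursion: $u$'s own copy
for $i \in J(u)$; the tree-$i$ parent of $v$'s copy for $i \in J(v)$; and
$p_i(v)$ unchanged when $i$ is in neither.

Processing order is a FIFO queue initialized with the leaves.  A parent
may be reported by several children, possibly after it was already
dequeued, so enqueue-deduplication must consult the set of vertices *ever*
enqueued, not the current queue content.  `queue_trace()` replays exactly
this discipline on a single tree and shows the difference: on
`(a,(b,c)v1)v2;` with initial queue `(a,b,c)`, testing only the live queue
enqueues the root twice, while the ever-enqueued set admits it once.  In
the full algorithm the root never enters the queue at all: a candidate
whose leaf count equals $|L|$ is the shared root of all inputs and is
materialized directly with $J = \{1..k\}$.

## Verification

The construction above is only guaranteed to be meaningful when a common
refinement exists; on arbitrary inputs the equal-cardinality
identification may merge vertices with different clusters.  Three guards
make the verdict sound without ever computing set inclusions:

1. **Vertex budget.** A phylogenetic tree on $|L|$ leaves has at most
   $|L|-2$ inner non-root vertices, so at most $2|L|-2$ distinct vertices
   may ever be enqueued; exceeding the budget aborts with
   `vertex_budget_exceeded`.
2. **Strict growth.** Each assigned parent must have a strictly larger
   leaf count than its child (`parent_not_strictly_larger` otherwise);
   with the budget this forces the parent function to define a tree.
3. **Display checks.** The assembled tree must be phylogenetic
   (`not_phylogenetic`), and for every input $T_i$, contracting every edge
   of (a copy of) $T$ whose child vertex lacks $i$ in $J$ must reproduce
   $T_i$ *vertex by vertex* under the maintained correspondence
   (`display_check_failed`).  The contraction is implemented implicitly:
   each kept vertex is matched against its nearest kept ancestor, in
   $O(|L|)$ per tree.

The failure reason reports which guard tripped first; it is a diagnostic
label, not a classification of the input (the same incompatible instance
may trip different guards depending on processing order).  On
incompatibility no partial tree is returned — no natural unique partial
object exists, and consumers wanting a consensus-style fallback should use
a loose-consensus construction instead, which is outside this package's
scope.

`verify = FALSE` skips stage 3 (the budget and growth checks are
inherent to the construction and always on).  It exists for pipelines
whose inputs are compatible by construction — e.g. the simulator below —
and is unsafe otherwise; the default always verifies.

## Parameters and defaults

* `lincr(trees, verify = TRUE)` — `verify` as above.  No other tuning:
  the algorithm is exact and parameter-free.
* `make_instance(n_leaves, k, p_contract, seed)` — the evaluation
  protocol.  `n_leaves` $\ge 2$; `k` $\ge 1$ input trees; `p_contract`
  $\in [0,1]$ is the independent contraction probability per inner edge,
  with $p = 0$ duplicating the base tree and $p = 1$ producing stars.
  The canonical evaluation grid pairs $k \in \{2, 8, 32\}$ with
  $p \in \{0.1, 0.5, 0.9\}$; tests and the acceptance script sample
  $k \in \{2, 8\}$ over all three $p$ values.
* `make_incompatible_instance(n_leaves, k, max_tries = 20)` — rejection
  sampling of independent random trees until their cluster union fails
  the hierarchy test; after `max_tries` failures a deterministic
  overlapping-cherry pair is substituted, so the function always returns
  an incompatible instance.

## What the simulator does and does not emulate

`random_tree()` grows a tree by repeatedly choosing a vertex uniformly at
random from the *current vertex set*: a chosen leaf receives two children,
a chosen inner vertex one more child, so the leaf count rises by exactly
one per step and the result is phylogenetic but generally multifurcating.
Uniform choice over all vertices is a modelling decision — the protocol
only requires "a randomly chosen vertex" — and is documented here once;
it biases toward broader multifurcations than, say, a Yule process.
Contraction candidates are exactly the *inner* edges: contracting a leaf
edge would delete a taxon and change $L$, which the problem forbids.

Consequently the instances are compatible by construction (every input is
displayed by the base tree $T^*$), but $T^*$ is in general strictly more
resolved than the least-resolved refinement, so correctness checks always
compare against the cluster union of the inputs and never against $T^*$.
The simulator emulates tree *shape* only: no branch lengths, no model of
inference error (contractions are independent and unbiased, whereas real
polytomies concentrate at short branches), no label-dependent structure.
Passing tests therefore certify the combinatorial algorithm, not the
behaviour of any inference pipeline feeding it.

A single-vertex tree ($|L| = 1$) is rejected: the growth procedure is
ill-defined there and a one-leaf "tree" has no inner structure to refine.

## Numerical and representational choices

* **Vertex identity.**  Trees use opaque integer vertex ids with explicit
  parent and ordered-children maps (`rtree`), so cross-tree
  correspondence tables are unambiguous.  Newick reading and writing is
  delegated to `ape` with converters in both directions; branch lengths
  are accepted and discarded, inner labels preserved, child order kept
  but never semantically meaningful.
* **Tree equality** is cluster-set equality — valid because all
  comparisons happen on a fixed leaf set — which avoids any need for a
  rooted-isomorphism routine.
* **Tie handling.**  Equal-cardinality parent candidates are identified
  as a single merged vertex.  Among the pairwise-comparable candidate
  sets arising from compatible inputs this is exact (equal cardinality
  implies equal cluster); on incompatible inputs it can be wrong, which
  is precisely what the verification stage catches.
* **Determinism.**  FIFO queue, leaves enqueued in the leaf order of the
  first input tree, children attached in discovery order: the output
  Newick is reproducible run to run, although only its cluster set is
  contractually meaningful.
* **State layout.**  The merge keeps its bookkeeping ($p_i$, $J$, leaf
  counts, correspondence, queue) in flat preallocated arrays of size
  $2|L|-1$.  The reference step functions (`compute_parent`,
  `update_pmaps`) operate on a shared state environment and are what the
  unit tests exercise; the production loop in `merge_trees` applies the
  same recursions to local copies of those arrays so that element writes
  update in place rather than triggering R's copy-on-modify on every
  assignment.  The two are held together by tests that compare the merge
  against both oracles on every catalogued small-tree pair.
* **Binary shortcut.**  A binary input ($|V(T_i)| = 2|L|-1$) would allow
  returning $T_i$ itself after display checks; the bookkeeping ($J$,
  correspondence) is needed regardless, so the package takes no special
  path and the general sweep handles this case at the same asymptotic
  cost.  `k = 1` returns the input's own cluster tree immediately via the
  same machinery.
* **BUILD.**  The oracle recursion uses an explicit work stack and
  rebuilds the Aho graph per level with a hand-rolled union–find over the
  current label subset — deterministic component numbering, quadratic
  overall, which is acceptable for its role as a cross-check.
  `representative_triples()` encodes a tree compactly for BUILD: for each
  inner non-root vertex, representative leaves of its children are
  chained with an outgroup from a sibling subtree, giving
  $\sum_v (\mathrm{deg}(v) - 1)$ triples — equal to the number of inner
  edges on binary trees.  The encoding is closure-exact (BUILD
  reconstructs the tree); no minimal-cardinality claim is made.

## Problem sizes exercised

The test suite and acceptance script work at sizes chosen to make the
combinatorial guarantees sharp rather than to benchmark: exhaustive
catalogues of all phylogenetic trees on 3–5 leaves (4, 26 and 236 trees)
taken pairwise against both oracles; 300 simulated instances with
$|L| \in [5, 50]$ over the $k \times p$ grid; 100-instance batches for
the triple-oracle, least-resolved and display contracts; 500 draws for
the simulator limits; and a runtime-doubling measurement at
$|L| = 250$ versus $500$ with $k = 4$, whose median ratio near 2 is a
smoke check of near-linear scaling, not a timing claim.

## Limitations

* Inputs must share one leaf set exactly; the general supertree problem
  (differing leaf sets) is a different algorithmic regime and out of
  scope.
* On incompatible inputs only a verdict and a reason code are produced;
  extracting a maximum consistent substructure is NP-hard territory and
  not attempted.
* Branch lengths and nested-taxa (inner-label) semantics are ignored.
* The `lca()` helper is intentionally naive (ancestor-path intersection);
  it is a definitional oracle for tests, not a query structure.
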