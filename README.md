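# lincr — linear-time common refinement of rooted phylogenetic trees

`lincr` answers a recurring question in mathematical phylogenetics: given
rooted phylogenetic trees *T₁, …, T_k* that all carry the **same** leaf set
*L* — typically incompletely resolved trees for the same taxa produced by
different methods or data types — is there a single tree that displays all
of them, and what is the *least resolved* such tree?

Writing ℋ(T) for the cluster set of *T* (the sets *L(T(v))* of leaves below
each vertex *v*), a common refinement exists if and only if
ℋ(T₁) ∪ … ∪ ℋ(T_k) is a hierarchy (any two pooled clusters nested or
disjoint), and in that case there is a unique tree *T* with

> ℋ(T) = ℋ(T₁) ∪ ℋ(T₂) ∪ … ∪ ℋ(T_k),

which every other common refinement refines. The package constructs this
tree in *O(k·|L|)* time with a bottom-up sweep that builds the parent
function of *T* directly: starting from the leaves, the parent of each
discovered vertex is the minimum — by subtree leaf count — over one
candidate per input tree (the parent of *v* in tree *i* when tree *i*
contains *v*, otherwise the lowest vertex of tree *i* weakly above *v*);
equal-cardinality candidates are identified as one vertex of *T*. The
candidate tree is then verified (vertex budget 2|L|−2, strict cluster
growth, phylogenetic property, and an exact display check against every
input), so incompatible inputs are always detected.

Alongside the core algorithm the package ships:

* **Independent oracles** — `refine_by_union()` (pool the clusters, test
  the hierarchy property, build the Hasse diagram) and
  `build_from_triples()` (Aho's BUILD on rooted triples), used to
  cross-check every verdict;
* **Newick I/O** (`parse_newick()`, `write_newick()`, `as_phylo()` /
  `as_rtree()` for `ape` interoperability);
* **A simulator** (`make_instance()`) reproducing the standard evaluation
  protocol: a random phylogenetic tree grown by stepwise leaf attachment,
  and *k* inputs derived by contracting each inner edge independently with
  probability *p*;
* **A command line** (`refine`, `simulate`, `check` subcommands; see
  `?run_cli`).

## Worked example

```r
library(lincr)
t1 <- parse_newick("((a,b),c,d,e);")
t2 <- parse_newick("(a,b,((c,d),e));")
res <- lincr(list(t1, t2))
res
#> Common refinement found:
#>   ((a,b),(e,(c,d)));
res$stats$n_merged_nonroot
#> [1] 8
res$J[[res$tree$root]]
#> [1] 1 2
```

The refined tree carries every cluster of both inputs — `{a,b}` from the
first, `{c,d}` and `{c,d,e}` from the second — and nothing else; `J` maps
each output vertex to the input trees that contain its cluster (the root,
cluster `{a,…,e}`, is in both). The eight non-root vertices respect the
2·5−2 bound. Adding a third tree with the conflicting cluster `{a,c}`
flips the verdict:

```r
lincr(list(t1, t2, parse_newick("((a,c),b,d,e);")))
#> No common refinement (not_phylogenetic)
```

(the failure reason names the verification stage that rejected the
candidate). Simulated instances are compatible by construction:

```r
inst <- make_instance(n_leaves = 8, k = 3, p_contract = 0.5, seed = 42)
sapply(inst$trees, write_newick)
#> [1] "((L5,L6),L1,L7,L8,L2,L3,L4);"   "((L5,L6),L1,(L7,L8),L2,L3,L4);"
#> [3] "(L5,L6,L1,(L7,L8),L2,L3,L4);"
write_newick(lincr(inst$trees)$tree)
#> [1] "(L1,L2,L3,L4,(L5,L6),(L7,L8));"
```

Note the result is the *least* resolved tree covering all input clusters —
not the (generally more resolved) base tree the simulator contracted.

The same pipeline from a shell:

```sh
lincr simulate --n 8 --k 3 --p 0.5 --seed 42 --outdir inst_dir
lincr refine inst_dir/input_*.nwk          # prints the refined Newick
lincr refine --algorithm union --verify inst_dir/input_*.nwk
```

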