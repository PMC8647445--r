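#' Random phylogenetic tree by stepwise leaf attachment
#'
#' Grows a tree from a single vertex: at each step a vertex `v` is drawn
#' uniformly at random from the current vertex set; if `v` is a leaf it
#' receives two children (so it becomes an inner vertex and the leaf count
#' rises by one), otherwise it receives one additional child leaf.  The
#' procedure stops when `n_leaves` leaves exist.  The result is always
#' phylogenetic but in general not binary.  Leaves are labelled `L1`,
#' `L2`, ... in vertex-id order.  Randomness comes from R's global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param n_leaves number of leaves, at least 2.
#' @return An [rtree].
#' @export
random_tree <- function(n_leaves) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 2L)
    stop_input("n_leaves must be an integer >= 2")
  cap <- 2L * n_leaves             # loose upper bound on vertex count
  parent <- rep(NA_integer_, cap)
  children <- vector("list", cap)
  is_leaf <- logical(cap)
  nv <- 1L
  is_leaf[1L] <- TRUE
  children[[1L]] <- integer(0)
  nl <- 1L
  while (nl < n_leaves) {
    v <- if (nv == 1L) 1L else sample.int(nv, 1L)
    if (is_leaf[v]) {
      for (j in 1:2) {
        nv <- nv + 1L
        parent[nv] <- v
        children[[nv]] <- integer(0)
        is_leaf[nv] <- TRUE
        children[[v]] <- c(children[[v]], nv)
      }
      is_leaf[v] <- FALSE
    } else {
      nv <- nv + 1L
      parent[nv] <- v
      children[[nv]] <- integer(0)
      is_leaf[nv] <- TRUE
      children[[v]] <- c(children[[v]], nv)
    }
    nl <- nl + 1L
  }
  labels <- rep(NA_character_, nv)
  labels[is_leaf[seq_len(nv)]] <- paste0("L", seq_len(nl))
  rtree(parent[seq_len(nv)], children[seq_len(nv)], labels)
}

#' Randomly contract inner edges of a tree
#'
#' Each inner edge (an edge whose lower endpoint is an inner, non-root
#' vertex) is considered independently and contracted with probability
#' `p`.  Leaf edges are never touched, so the leaf set is unchanged and
#' the input tree displays the output by construction.  At `p = 0` the
#' output is cluster-identical to the input; at `p = 1` it is the star
#' tree.
#'
#' @param tree a phylogenetic [rtree].
#' @param p contraction probability in `[0, 1]`.
#' @return An [rtree] that the input tree displays.
#' @export
contract_random_inner_edges <- function(tree, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_input("p must be a probability in [0, 1]")
  inner_nonroot <- which(lengths(tree$children) > 0L &
                           seq_along(tree$parent) != tree$root)
  if (length(inner_nonroot) == 0L) return(tree)
  pick <- inner_nonroot[stats::runif(length(inner_nonroot)) < p]
  contract_edges(tree, pick)
}

#' Simulate a compatible common-refinement instance
#'
#' Draws one random tree `T*` on `n_leaves` leaves and derives `k` input
#' trees by independent random contraction of its inner edges with
#' probability `p_contract`.  Every input is displayed by `T*`, so a
#' common refinement exists by construction — but `T*` itself is in
#' general strictly more resolved than the least-resolved refinement, so
#' correctness checks must compare against the cluster union of the
#' inputs, not against `T*`.
#'
#' @param n_leaves leaves of the base tree (>= 2).
#' @param k number of derived input trees (>= 1).
#' @param p_contract inner-edge contraction probability.
#' @param seed optional integer seed applied via [set.seed()].
#' @return A list with `t_star` (the base [rtree]) and `trees` (list of
#'   `k` contracted input trees).
#' @examples
#' inst <- make_instance(8, k = 2, p_contract = 0.5, seed = 1)
#' lincr(inst$trees)$status
#' @export
make_instance <- function(n_leaves, k, p_contract, seed = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_input("k must be an integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  t_star <- random_tree(n_leaves)
  trees <- lapply(seq_len(k),
                  function(i) contract_random_inner_edges(t_star, p_contract))
  list(t_star = t_star, trees = trees)
}

#' Sample an instance without a common refinement
#'
#' Draws `k` independent random trees on a shared label set and keeps the
#' draw if their cluster union fails to be a hierarchy, retrying up to
#' `max_tries` times (independent trees are usually incompatible, but need
#' not be).  If every retry happens to be compatible, a deterministic
#' incompatible pair is substituted: two trees whose first cherries
#' `\{L1, L2\}` and `\{L1, L3\}` overlap without nesting, padded with star
#' trees for `k > 2`.
#'
#' @param n_leaves leaves per tree (>= 3).
#' @param k number of trees (>= 2).
#' @param max_tries rejection-sampling budget.
#' @return A list of `k` [rtree]s whose cluster union is not a hierarchy.
#' @export
make_incompatible_instance <- function(n_leaves, k, max_tries = 20L) {
  n_leaves <- as.integer(n_leaves)
  k <- as.integer(k)
  if (is.na(n_leaves) || n_leaves < 3L) stop_input("n_leaves must be >= 3")
  if (is.na(k) || k < 2L) stop_input("k must be >= 2")
  for (try in seq_len(max_tries)) {
    trees <- lapply(seq_len(k), function(i) random_tree(n_leaves))
    all_cl <- unlist(lapply(trees, vertex_clusters), recursive = FALSE)
    cs <- cluster_system(all_cl, leaf_labels(trees[[1L]]))
    if (!is_hierarchy(cs)) return(trees)
  }
  labs <- paste0("L", seq_len(n_leaves))
  mk <- function(a, b) {
    outside <- paste(setdiff(labs, c(a, b)), collapse = ",")
    parse_newick(paste0("((", a, ",", b, "),", outside, ");"))
  }
  t1 <- mk(labs[1], labs[2])      # cluster {L1, L2}
  t2 <- mk(labs[1], labs[3])      # cluster {L1, L3}: overlap without nesting
  star <- parse_newick(paste0("(", paste(labs, collapse = ","), ");"))
  c(list(t1, t2), rep(list(star), k - 2L))
}
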