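#' Subtree leaf counts
#'
#' Computes, in one postorder traversal, the number of leaves below every
#' vertex: 1 for leaves, the sum over children otherwise.  These counts
#' stand in for cluster-inclusion comparisons during the bottom-up merge:
#' among the pairwise comparable parent candidates of a vertex, the strictly
#' lower vertex is exactly the one with the strictly smaller leaf count.
#'
#' @param tree an [rtree].
#' @return Integer vector indexed by vertex id.
#' @examples
#' leaf_counts(parse_newick("(a,(b,c)v1)v2;"))
#' @export
leaf_counts <- function(tree) {
  nv <- n_vertices(tree)
  lc <- integer(nv)
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    lc[v] <- if (length(kids) == 0L) 1L else sum(lc[kids])
  }
  lc
}

# ---------------------------------------------------------------------------
# Bottom-up merge.  State layout (preallocated; N = 2|L|-1 slots):
#   pmap  k x N : pmap[i, v] = vertex of tree i that is the lowest vertex of
#                 tree i weakly above merged vertex v (p_i(v))
#   Jm    k x N : Jm[i, v] = TRUE iff tree i contains a vertex whose cluster
#                 equals the cluster of merged vertex v (i in J(v))
#   lsz       N : cluster cardinality of each merged vertex
#   parent_out N: parent function of the candidate refinement (NA at root)
#   corr  list  : per tree, vertex-of-tree-i -> merged id (0 = unset); the
#                 cross-tree correspondence table, doubling as the seen-set
#                 test ("u already found in tree i" iff its pointer is set)
# Leaves occupy ids 1..n; inner merged vertices are appended as discovered;
# the root is materialized when a parent candidate attains the full leaf
# count and is never enqueued, so at most 2|L|-2 ids ever enter the queue.
# ---------------------------------------------------------------------------

init_merge_state <- function(trees) {
  if (length(trees) < 1L) stop_input("at least one input tree is required")
  for (tr in trees) {
    if (!inherits(tr, "rtree")) stop_input("inputs must be rtree objects")
    if (!is_phylogenetic(tr)) stop_input("input trees must be phylogenetic")
  }
  k <- length(trees)
  lab1 <- leaf_labels(trees[[1L]])
  if (anyDuplicated(lab1)) stop_input("duplicate leaf labels")
  for (i in seq_len(k)) {
    if (!setequal(leaf_labels(trees[[i]]), lab1))
      stop_input("input trees must share an identical leaf-label set")
  }
  n <- length(lab1)
  if (n < 2L) stop_input("trees must have at least two leaves")
  cap <- 2L * n - 1L
  st <- new.env(parent = emptyenv())
  st$trees <- trees
  st$k <- k
  st$n <- n
  st$labels <- lab1                       # merged leaf ids follow tree-1 leaf order
  st$lc <- lapply(trees, leaf_counts)
  st$par <- lapply(trees, function(t) t$parent)
  st$pmap <- matrix(NA_integer_, k, cap)
  st$Jm <- matrix(FALSE, k, cap)
  st$lsz <- integer(cap)
  st$parent_out <- rep(NA_integer_, cap)
  st$corr <- lapply(trees, function(t) integer(n_vertices(t)))
  st$queue <- integer(cap)
  st$qh <- 1L
  st$qt <- 0L
  st$n_vertices <- n                      # merged ids in use
  st$n_nonroot <- n                       # enqueued ids (leaves count)
  st$root_id <- NA_integer_
  st$lsz[seq_len(n)] <- 1L
  for (i in seq_len(k)) {
    vi <- match(lab1, trees[[i]]$labels)      # leaf j of the merge -> tree i
    st$pmap[i, seq_len(n)] <- vi
    st$Jm[i, seq_len(n)] <- TRUE
    st$corr[[i]][vi] <- seq_len(n)
  }
  st$queue[seq_len(n)] <- seq_len(n)
  st$qt <- n
  st
}

# Parent candidates of merged vertex v: for i in J(v) the parent of v in
# tree i, otherwise p_i(v).  Returns the candidate vertices, their leaf
# counts, and the index set attaining the minimum, or a root signal when
# the minimum sits at the full leaf count.
compute_parent <- function(st, v) {
  k <- st$k
  cand <- integer(k)
  lcand <- integer(k)
  for (i in seq_len(k)) {
    ci <- if (st$Jm[i, v]) st$par[[i]][st$pmap[i, v]] else st$pmap[i, v]
    if (is.na(ci)) return(list(status = "root"))
    cand[i] <- ci
    lcand[i] <- st$lc[[i]][ci]
  }
  lmin <- min(lcand)
  if (st$lsz[v] >= lmin) return(list(status = "not_larger"))
  list(status = if (lmin == st$n) "root_candidate" else "ok",
       cand = cand, lmin = lmin, J_new = which(lcand == lmin))
}

# Set p_i(u) for a freshly created merged vertex u = parent(v):
#   p_i(u) = u's own tree-i vertex          if i in J(u)
#          = parent in tree i of p_i(v)      if i in J(v)
#          = p_i(v)                          otherwise
update_pmaps <- function(st, u, v, cand, J_new) {
  for (i in seq_len(st$k)) {
    if (i %in% J_new) {
      st$pmap[i, u] <- cand[i]
      st$Jm[i, u] <- TRUE
    } else if (st$Jm[i, v]) {
      st$pmap[i, u] <- cand[i]          # parent of v in tree i
    } else {
      st$pmap[i, u] <- st$pmap[i, v]
    }
  }
  invisible(st)
}

# Bottom-up construction of the parent function of the candidate common
# refinement.  Returns the completed state or an incompatibility record.
#
# The loop body re-states the step functions compute_parent() and
# update_pmaps() on local copies of the state: writes into vectors bound in
# an environment trigger R's copy-on-modify and would cost O(|L|) each, so
# the hot loop works on locals (modified in place) and writes the state
# back once at the end.  The step functions remain the reference mechanics
# and the unit tests hold the two in agreement.
merge_trees <- function(trees) {
  st <- init_merge_state(trees)
  k <- st$k
  n <- st$n
  budget <- 2L * n - 2L
  par_i <- st$par
  lc_i <- st$lc
  pmap <- st$pmap
  Jm <- st$Jm
  lsz <- st$lsz
  parent_out <- st$parent_out
  corr <- st$corr
  queue <- st$queue
  qh <- 1L
  qt <- st$qt
  nv <- st$n_vertices
  n_nonroot <- st$n_nonroot
  root_id <- NA_integer_
  cand <- integer(k)
  lcand <- integer(k)
  fail <- NULL
  while (qh <= qt) {
    v <- queue[qh]
    qh <- qh + 1L
    # parent candidates: parent in tree i for i in J(v), p_i(v) otherwise
    for (i in seq_len(k)) {
      ci <- if (Jm[i, v]) par_i[[i]][pmap[i, v]] else pmap[i, v]
      cand[i] <- ci
      lcand[i] <- lc_i[[i]][ci]
    }
    lmin <- min(lcand)
    if (lsz[v] >= lmin) {
      fail <- "parent_not_strictly_larger"
      break
    }
    if (lmin == n) {
      # the parent is the root, shared by all trees; materialize it once
      # and never enqueue it
      if (is.na(root_id)) {
        nv <- nv + 1L
        root_id <- nv
        lsz[root_id] <- n
        for (i in seq_len(k)) {
          ri <- trees[[i]]$root
          pmap[i, root_id] <- ri
          Jm[i, root_id] <- TRUE
          corr[[i]][ri] <- root_id
        }
      }
      parent_out[v] <- root_id
      next
    }
    J_new <- which(lcand == lmin)
    # find-or-create the merged vertex u among the minimum attainers
    u <- 0L
    for (i in J_new) {
      hit <- corr[[i]][cand[i]]
      if (hit > 0L) { u <- hit; break }
    }
    if (u == 0L) {
      if (n_nonroot + 1L > budget) {
        fail <- "vertex_budget_exceeded"
        break
      }
      nv <- nv + 1L
      n_nonroot <- n_nonroot + 1L
      u <- nv
      lsz[u] <- lmin
      # p_i(u): own vertex for the attainers, parent of v in tree i when
      # i in J(v), inherited p_i(v) otherwise
      in_new <- logical(k)
      in_new[J_new] <- TRUE
      for (i in seq_len(k)) {
        pmap[i, u] <- if (in_new[i] || Jm[i, v]) cand[i] else pmap[i, v]
        if (in_new[i]) Jm[i, u] <- TRUE
      }
      qt <- qt + 1L
      queue[qt] <- u
    }
    # record the correspondence for every tree attaining the minimum; an
    # already-set pointer identifies u as previously seen and is kept
    for (i in J_new) {
      if (corr[[i]][cand[i]] == 0L) {
        corr[[i]][cand[i]] <- u
        Jm[i, u] <- TRUE
        pmap[i, u] <- cand[i]
      }
    }
    parent_out[v] <- u
  }
  if (is.null(fail) && is.na(root_id)) fail <- "parent_not_strictly_larger"
  if (!is.null(fail)) {
    return(list(status = "incompatible", failure_reason = fail))
  }
  st$pmap <- pmap
  st$Jm <- Jm
  st$lsz <- lsz
  st$parent_out <- parent_out
  st$corr <- corr
  st$queue <- queue
  st$qh <- qh
  st$qt <- qt
  st$n_vertices <- nv
  st$n_nonroot <- n_nonroot
  st$root_id <- root_id
  list(status = "merged", state = st)
}

# Assemble the candidate rtree from the merged parent function.  Children
# are attached in order of increasing child id (= discovery order).
tree_from_state <- function(st) {
  nv <- st$n_vertices
  parent <- st$parent_out[seq_len(nv)]
  children <- children_from_parent(parent)
  labels <- rep(NA_character_, nv)
  labels[seq_len(st$n)] <- st$labels
  rtree(parent, children, labels)
}

verify_phylogenetic <- function(tree) {
  is_phylogenetic(tree)
}

# Check that the candidate refinement displays input tree i: contract every
# edge whose child vertex u has i outside J(u) (equivalently, keep exactly
# the merged vertices with a tree-i counterpart) and compare the contracted
# parent relation with tree i under the maintained correspondence.
verify_displays <- function(st, i) {
  nv <- st$n_vertices
  ti <- st$trees[[i]]
  nvi <- n_vertices(ti)
  kept <- st$Jm[i, seq_len(nv)]
  if (sum(kept) != nvi) return(FALSE)
  if (any(st$corr[[i]] == 0L)) return(FALSE)  # some tree-i vertex never matched
  # nearest kept strict ancestor of every merged vertex; parents have
  # strictly larger clusters, so process in decreasing cluster size
  anc <- integer(nv)
  ord <- order(st$lsz[seq_len(nv)], decreasing = TRUE)
  for (v in ord) {
    p <- st$parent_out[v]
    if (is.na(p)) next                    # root
    anc[v] <- if (kept[p]) p else anc[p]
  }
  for (w in seq_len(nvi)) {
    m <- st$corr[[i]][w]
    if (!kept[m]) return(FALSE)
    pw <- ti$parent[w]
    if (is.na(pw)) {
      if (m != st$root_id) return(FALSE)
    } else {
      if (anc[m] != st$corr[[i]][pw]) return(FALSE)
    }
  }
  TRUE
}

#' Common refinement of rooted trees on a shared leaf set
#'
#' Decides whether the input trees admit a common refinement — a tree whose
#' cluster set is the union of the inputs' cluster sets — and constructs it
#' when it exists.  The union is a hierarchy exactly in the positive case,
#' and the refinement is then unique and least resolved: contracting any of
#' its inner edges loses a cluster of some input.
#'
#' The construction is bottom-up: starting from the leaves, the parent of
#' each discovered vertex is found as the minimum, by subtree leaf count,
#' over one parent candidate per input tree; vertices of different input
#' trees with equal-cardinality candidate clusters are identified on the
#' fly.  The procedure runs in `O(k |L|)` time.  Since the identification
#' is only valid when a refinement exists, the candidate is verified: the
#' number of discovered non-root vertices may never exceed `2|L| - 2`, each
#' parent must have a strictly larger cluster, the result must be
#' phylogenetic, and contracting back to every input tree must reproduce it
#' exactly.  With `verify = FALSE` the last two checks are skipped; this is
#' only safe when the inputs are known to be compatible.
#'
#' @param trees a list of phylogenetic [rtree]s on one leaf-label set
#'   (k >= 1).
#' @param verify run the phylogenetic and per-tree display checks
#'   (default `TRUE`).
#' @return An object of class `refinement`: a list with
#'   \describe{
#'     \item{status}{`"refined"` or `"incompatible"`.}
#'     \item{tree}{the least-resolved common refinement (if refined).}
#'     \item{J}{per output vertex, the indices of the input trees containing
#'       a vertex with that cluster (if refined).}
#'     \item{failure_reason}{one of `"vertex_budget_exceeded"`,
#'       `"parent_not_strictly_larger"`, `"not_phylogenetic"`,
#'       `"display_check_failed"` (if incompatible).}
#'     \item{stats}{bookkeeping: `n_merged_nonroot`, the number of distinct
#'       non-root vertices discovered (at most `2|L| - 2`).}
#'   }
#' @examples
#' t1 <- parse_newick("((a,b),c,d);")
#' t2 <- parse_newick("(a,b,(c,d));")
#' res <- lincr(list(t1, t2))
#' res$status
#' write_newick(res$tree)
#' @export
lincr <- function(trees, verify = TRUE) {
  if (inherits(trees, "rtree")) trees <- list(trees)
  m <- merge_trees(trees)
  if (m$status == "incompatible") {
    return(structure(list(status = "incompatible",
                          failure_reason = m$failure_reason,
                          stats = list(n_merged_nonroot = NA_integer_)),
                     class = "refinement"))
  }
  st <- m$state
  tree <- tree_from_state(st)
  stats <- list(n_merged_nonroot = st$n_nonroot)
  incompatible <- function(reason) {
    structure(list(status = "incompatible", failure_reason = reason,
                   stats = stats), class = "refinement")
  }
  if (verify) {
    if (!verify_phylogenetic(tree)) return(incompatible("not_phylogenetic"))
    for (i in seq_len(st$k)) {
      if (!verify_displays(st, i)) return(incompatible("display_check_failed"))
    }
  }
  J <- lapply(seq_len(st$n_vertices),
              function(v) which(st$Jm[, v, drop = TRUE]))
  structure(list(status = "refined", tree = tree, J = J, stats = stats),
            class = "refinement")
}

#' @export
print.refinement <- function(x, ...) {
  if (x$status == "refined") {
    cat("Common refinement found:\n ", write_newick(x$tree), "\n")
  } else {
    cat("No common refinement (", x$failure_reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Replay the bottom-up queue discipline on a single tree
#'
#' A diagnostic replay of the queue mechanics of the bottom-up merge on one
#' tree whose parent function is already known.  Starting from the leaves,
#' each dequeued vertex reports its parent, which is enqueued unless the
#' duplicate test rejects it.  With `use_seen_set = TRUE` the test is
#' membership in the set of all vertices ever enqueued; with `FALSE` it is
#' only membership in the current queue, which lets a vertex re-enter after
#' it has been dequeued.  The returned enqueue counts demonstrate why the
#' seen-set is required for the linear-time bound: e.g. on
#' `(a,(b,c)v1)v2;` with initial queue `(a, b, c)`, the root `v2` is
#' enqueued twice without the seen-set but only once with it.
#'
#' @param tree an [rtree].
#' @param use_seen_set track all vertices ever enqueued (`TRUE`) or only
#'   test the current queue (`FALSE`).
#' @return Named integer vector of enqueue counts per vertex (named by
#'   label where present, otherwise `#<id>`), in vertex-id order.
#' @export
queue_trace <- function(tree, use_seen_set = TRUE) {
  nv <- n_vertices(tree)
  counts <- integer(nv)
  lf <- leaves(tree)
  queue <- lf
  counts[lf] <- 1L
  seen <- rep(FALSE, nv)
  seen[lf] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    u <- tree$parent[v]
    if (is.na(u)) next
    dup <- if (use_seen_set) seen[u] else u %in% queue
    if (!dup) {
      queue <- c(queue, u)
      counts[u] <- counts[u] + 1L
      seen[u] <- TRUE
    }
  }
  nm <- tree$labels
  nm[is.na(nm)] <- paste0("#", which(is.na(nm)))
  names(counts) <- nm
  counts
}
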