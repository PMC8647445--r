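#' Brute-force common refinement via the cluster-hierarchy union
#'
#' The definitional construction: pool the cluster sets of all input trees,
#' test whether the union is a hierarchy, and if so return the tree given
#' by its Hasse diagram.  Quadratic in the number of clusters; it exists as
#' an independent correctness oracle for [lincr()], with which it must
#' agree on verdict and (when compatible) on the output cluster set.
#'
#' @param trees a list of phylogenetic [rtree]s on one leaf-label set.
#' @return An object of class `refinement` (see [lincr()]); the
#'   `failure_reason` on incompatible inputs is `"union_not_hierarchy"`.
#' @export
refine_by_union <- function(trees) {
  if (inherits(trees, "rtree")) trees <- list(trees)
  if (length(trees) < 1L) stop_input("at least one input tree is required")
  lab1 <- leaf_labels(trees[[1L]])
  for (tr in trees) {
    if (!is_phylogenetic(tr)) stop_input("input trees must be phylogenetic")
    if (!setequal(leaf_labels(tr), lab1))
      stop_input("input trees must share an identical leaf-label set")
  }
  all_cl <- unlist(lapply(trees, vertex_clusters), recursive = FALSE)
  cs <- cluster_system(all_cl, lab1)
  if (!is_hierarchy(cs)) {
    return(structure(list(status = "incompatible",
                          failure_reason = "union_not_hierarchy"),
                     class = "refinement"))
  }
  structure(list(status = "refined", tree = tree_from_hierarchy(cs)),
            class = "refinement")
}

#' Aho's BUILD algorithm on a set of rooted triples
#'
#' Recursively partitions the label set into the connected components of
#' the Aho graph — labels as vertices, one edge `{x, y}` for every triple
#' `xy|z` whose three labels lie in the current set — and recurses into
#' each component.  A single component of size greater than one means the
#' triple set is inconsistent.  The returned tree displays every input
#' triple and is least resolved with respect to the triple set.  When the
#' triples are the pooled displayed triples of trees on a common leaf set,
#' BUILD returns exactly their least-resolved common refinement, which
#' makes it a second, independent oracle for [lincr()].
#'
#' @param R a three-column character matrix of triples (`x`, `y`, `z`) as
#'   returned by [triples()]; zero rows allowed.
#' @param L character vector of leaf labels (must contain every label
#'   occurring in `R`).
#' @return A list with `status` (`"consistent"` / `"inconsistent"`) and,
#'   when consistent, `tree`, the [rtree] built from the triples.
#' @export
build_from_triples <- function(R, L) {
  L <- sort(unique(as.character(L)))
  if (length(L) < 1L) stop_input("label set must be non-empty")
  if (is.null(dim(R))) R <- matrix(R, ncol = 3L)
  if (nrow(R) > 0L && !all(R %in% L))
    stop_input("triple contains labels outside L")
  n_total <- 0L
  parent <- integer(0)
  labels <- character(0)
  new_vertex <- function(par, lab) {
    n_total <<- n_total + 1L
    parent[n_total] <<- par
    labels[n_total] <<- lab
    n_total
  }
  root <- new_vertex(NA_integer_, NA_character_)
  # explicit work stack of (label subset, parent vertex id)
  work <- list(list(set = L, par = root))
  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    S <- item$set
    if (length(S) == 1L) {
      labels[item$par] <- S          # singleton: parent slot becomes the leaf
      next
    }
    comp <- aho_components(R, S)
    if (max(comp) == 1L) return(list(status = "inconsistent"))
    for (cid in seq_len(max(comp))) {
      sub <- S[comp == cid]
      v <- new_vertex(item$par, NA_character_)
      work[[length(work) + 1L]] <- list(set = sub, par = v)
    }
  }
  children <- vector("list", n_total)
  for (v in seq_len(n_total)) children[[v]] <- integer(0)
  for (v in seq_len(n_total)) {
    if (!is.na(parent[v])) children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  list(status = "consistent",
       tree = rtree(parent, children, labels))
}

# Connected components of the Aho graph on label set S, by union-find over
# the positions of S (deterministic: components numbered by first member).
aho_components <- function(R, S) {
  m <- length(S)
  uf <- seq_len(m)
  find <- function(x) {
    while (uf[x] != x) {
      uf[x] <<- uf[uf[x]]
      x <- uf[x]
    }
    x
  }
  if (nrow(R) > 0L) {
    xi <- match(R[, 1L], S)
    yi <- match(R[, 2L], S)
    zi <- match(R[, 3L], S)
    act <- !is.na(xi) & !is.na(yi) & !is.na(zi)
    for (r in which(act)) {
      a <- find(xi[r]); b <- find(yi[r])
      if (a != b) uf[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(m), find, 0L)
  match(roots, unique(roots))
}

#' Representative triples of a tree
#'
#' Returns a triple set whose BUILD closure is the tree itself: for every
#' inner non-root vertex `v`, one representative leaf is picked from each
#' child of `v` and linked in a chain `x1 x2 | z`, `x2 x3 | z`, ...,
#' with the outgroup `z` a representative leaf of a sibling of `v`.  This
#' gives `sum over inner non-root v of (deg(v) - 1)` triples — equal to the
#' number of inner edges for binary trees, and `O(|L|)` in general — and
#' `build_from_triples(representative_triples(T), L)` reconstructs `T`.
#' (The pooled full triple sets are exact but quadratic per tree; the
#' representative sets keep the BUILD oracle cheap on larger instances.)
#'
#' @param tree a phylogenetic [rtree].
#' @return A three-column character matrix of triples (possibly zero rows,
#'   e.g. for a star tree).
#' @export
representative_triples <- function(tree) {
  if (!is_phylogenetic(tree)) stop_contract("requires a phylogenetic tree")
  nv <- n_vertices(tree)
  rep_leaf <- character(nv)             # one representative leaf per vertex
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    rep_leaf[v] <- if (length(kids) == 0L) tree$labels[v] else rep_leaf[kids[1L]]
  }
  out <- list()
  for (v in seq_len(nv)) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L || is.na(tree$parent[v])) next
    sibs <- setdiff(tree$children[[tree$parent[v]]], v)
    z <- rep_leaf[sibs[1L]]
    reps <- rep_leaf[kids]
    for (j in seq_len(length(reps) - 1L)) {
      xy <- sort(c(reps[j], reps[j + 1L]))
      out[[length(out) + 1L]] <- c(xy, z)
    }
  }
  mat <- if (length(out) == 0L) matrix(character(0), 0L, 3L)
         else do.call(rbind, out)
  colnames(mat) <- c("x", "y", "z")
  mat
}
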