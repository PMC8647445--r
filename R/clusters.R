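#' Cluster systems on a fixed leaf-label set
#'
#' A cluster is a non-empty set of leaf labels; for a tree vertex `v` it is
#' the label set of the subtree below `v`.  A `cluster_system` bundles a set
#' of clusters with its ground set.  Clusters are stored as sorted character
#' vectors; two clusters are equal iff they contain the same labels.
#'
#' @param clusters a list of character vectors (duplicates are removed).
#' @param ground_set character vector of all leaf labels.
#' @return An object of class `cluster_system` with elements `clusters`
#'   (list of sorted label vectors) and `ground_set`.
#' @export
cluster_system <- function(clusters, ground_set) {
  ground_set <- sort(unique(as.character(ground_set)))
  cl <- lapply(clusters, function(x) sort(unique(as.character(x))))
  if (any(lengths(cl) == 0L)) stop_input("clusters must be non-empty")
  if (!all(unlist(cl) %in% ground_set))
    stop_input("cluster contains labels outside the ground set")
  keys <- vapply(cl, paste, "", collapse = "\x1f")
  cl <- cl[!duplicated(keys)]
  structure(list(clusters = cl, ground_set = ground_set),
            class = "cluster_system")
}

#' @export
print.cluster_system <- function(x, ...) {
  cat(sprintf("Cluster system: %d clusters on %d labels\n",
              length(x$clusters), length(x$ground_set)))
  invisible(x)
}

cluster_keys <- function(cs) {
  vapply(cs$clusters, paste, "", collapse = "\x1f")
}

#' Cluster set of a tree
#'
#' Computes `H(T)`, the set of clusters `L(T(v))` over all vertices `v`.
#' For a phylogenetic tree the clusters are pairwise distinct, so
#' `|H(T)| = |V(T)|`; the system always contains every singleton and the
#' full leaf set.
#'
#' @param tree an [rtree].
#' @return A [cluster_system]; attribute `vertex` gives, for each cluster,
#'   one vertex realizing it.
#' @examples
#' clusters(parse_newick("(a,(b,c)v1)v2;"))
#' @export
clusters <- function(tree) {
  cl <- vertex_clusters(tree)
  cs <- cluster_system(cl, tree$labels[leaves(tree)])
  keys <- vapply(lapply(cl, sort), paste, "", collapse = "\x1f")
  attr(cs, "vertex") <- match(cluster_keys(cs), keys)
  cs
}

# list of label vectors, one per vertex, indexed by vertex id
vertex_clusters <- function(tree) {
  nv <- n_vertices(tree)
  cl <- vector("list", nv)
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    cl[[v]] <- if (length(kids) == 0L) tree$labels[v]
               else unlist(cl[kids], use.names = FALSE)
  }
  cl
}

#' Test whether a cluster system is a hierarchy
#'
#' A hierarchy on `L` contains `L` itself and every singleton, and any two
#' of its clusters are nested or disjoint.  Hierarchies on `L` are in
#' bijection with rooted phylogenetic trees on `L`.
#'
#' @param cs a [cluster_system].
#' @return `TRUE` or `FALSE`.
#' @export
is_hierarchy <- function(cs) {
  stopifnot(inherits(cs, "cluster_system"))
  keys <- cluster_keys(cs)
  if (!(paste(cs$ground_set, collapse = "\x1f") %in% keys)) return(FALSE)
  if (!all(cs$ground_set %in% keys[lengths(cs$clusters) == 1L])) return(FALSE)
  m <- length(cs$clusters)
  if (m < 2L) return(TRUE)
  ord <- order(lengths(cs$clusters))
  cl <- cs$clusters[ord]
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      ov <- sum(cl[[i]] %in% cl[[j]])
      if (ov != 0L && ov != length(cl[[i]])) return(FALSE)
    }
  }
  TRUE
}

#' Tree corresponding to a hierarchy
#'
#' Builds the Hasse diagram of the clusters with respect to set inclusion:
#' each cluster becomes a vertex whose parent is the inclusion-minimal
#' cluster properly containing it.  This realizes the bijection between
#' hierarchies and rooted phylogenetic trees and serves as the brute-force
#' construction of a common refinement from a cluster union.
#'
#' @param cs a [cluster_system] with `is_hierarchy(cs) == TRUE`.
#' @return An [rtree] `T` with `clusters(T)` equal to `cs`.
#' @export
tree_from_hierarchy <- function(cs) {
  if (!is_hierarchy(cs)) stop_contract("input cluster system is not a hierarchy")
  ord <- order(lengths(cs$clusters), decreasing = TRUE)
  cl <- cs$clusters[ord]                    # root first
  m <- length(cl)
  parent <- rep(NA_integer_, m)
  for (i in seq_len(m)[-1L]) {
    # smallest cluster strictly containing cl[[i]]; scan larger clusters
    # from the smallest upwards
    for (j in rev(seq_len(i - 1L))) {
      if (length(cl[[j]]) > length(cl[[i]]) && all(cl[[i]] %in% cl[[j]])) {
        parent[i] <- j
        break
      }
    }
    if (is.na(parent[i])) stop_contract("hierarchy has no containing cluster")
  }
  children <- vector("list", m)
  for (v in seq_len(m)) children[[v]] <- integer(0)
  for (i in seq_len(m)[-1L]) children[[parent[i]]] <- c(children[[parent[i]]], i)
  labels <- rep(NA_character_, m)
  lv <- lengths(cl) == 1L
  labels[lv] <- unlist(cl[lv])
  rtree(parent, children, labels)
}

#' Last common ancestor of a set of leaf labels
#'
#' Returns the unique lowest vertex weakly above all the given leaves,
#' i.e. the vertex whose cluster is the inclusion-minimal cluster
#' containing the labels.  Implemented naively by ancestor-path
#' intersection; it serves as a definition-level oracle in tests and is not
#' on the hot path of the refinement algorithm.
#'
#' @param tree an [rtree].
#' @param labels non-empty character vector of leaf labels of `tree`.
#' @return An integer vertex id.
#' @export
lca <- function(tree, labels) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0L) stop_input("lca of an empty label set is undefined")
  v <- match(labels, tree$labels)
  if (anyNA(v)) stop_input(paste("unknown leaf label:",
                                 paste(labels[is.na(v)], collapse = ", ")))
  path <- function(x) {
    p <- x
    while (!is.na(tree$parent[x])) {
      x <- tree$parent[x]
      p <- c(p, x)
    }
    p
  }
  common <- Reduce(intersect, lapply(v, path))
  common[1L]  # paths are bottom-up, first common vertex is the lowest
}

#' Rooted triples displayed by a tree
#'
#' A tree displays the triple `xy|z` when some cluster contains `x` and `y`
#' but not `z`.  The full displayed set is returned as a three-column
#' character matrix (`x`, `y`, `z`, with `x < y`); intended for small trees
#' and the BUILD oracle, it enumerates over all clusters.
#'
#' @param tree a phylogenetic [rtree].
#' @return A character matrix with columns `x`, `y`, `z`; zero rows when no
#'   triple is displayed (e.g. a star tree).
#' @export
triples <- function(tree) {
  if (!is_phylogenetic(tree)) stop_contract("triples require a phylogenetic tree")
  ground <- sort(leaf_labels(tree))
  seen <- new.env(parent = emptyenv())
  out <- vector("list", 64L)
  cnt <- 0L
  for (cl in vertex_clusters(tree)) {
    if (length(cl) < 2L || length(cl) == length(ground)) next
    cl <- sort(cl)
    zs <- setdiff(ground, cl)
    for (i in seq_len(length(cl) - 1L)) {
      for (j in seq.int(i + 1L, length(cl))) {
        for (z in zs) {
          key <- paste(cl[i], cl[j], z, sep = "\x1f")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            cnt <- cnt + 1L
            if (cnt > length(out)) out <- c(out, vector("list", length(out)))
            out[[cnt]] <- c(cl[i], cl[j], z)
          }
        }
      }
    }
  }
  mat <- if (cnt == 0L) matrix(character(0), 0L, 3L)
         else do.call(rbind, out[seq_len(cnt)])
  colnames(mat) <- c("x", "y", "z")
  mat
}

#' Does one tree display another on the same leaf set?
#'
#' For trees on an identical leaf set, `T` displays `Tp` exactly when
#' `clusters(Tp)` is a subset of `clusters(T)`, i.e. when `T` is a
#' refinement of `Tp`.
#'
#' @param tree,other [rtree]s on the same leaf-label set.
#' @return `TRUE` or `FALSE`.
#' @export
displays_tree <- function(tree, other) {
  if (!setequal(leaf_labels(tree), leaf_labels(other)))
    stop_input("trees must have identical leaf-label sets")
  all(cluster_keys(clusters(other)) %in% cluster_keys(clusters(tree)))
}

# cluster-set identity; the package's working notion of tree equality for
# trees on a common leaf set (child order and vertex numbering ignored)
same_tree <- function(a, b) {
  setequal(leaf_labels(a), leaf_labels(b)) &&
    setequal(cluster_keys(clusters(a)), cluster_keys(clusters(b)))
}

#' Contract inner edges
#'
#' `contract_edge()` removes the edge between `child_vertex` and its parent
#' by splicing the children of `child_vertex` into the parent's child list
#' at its position; exactly one cluster disappears from the cluster set.
#' `contract_edges()` contracts a set of inner edges simultaneously.
#'
#' @param tree an [rtree].
#' @param child_vertex an inner, non-root vertex id.
#' @param child_vertices integer vector of inner, non-root vertex ids.
#' @return An [rtree] with the edge(s) contracted; vertex ids are
#'   renumbered, labels are preserved.
#' @export
contract_edge <- function(tree, child_vertex) {
  contract_edges(tree, child_vertex)
}

#' @rdname contract_edge
#' @export
contract_edges <- function(tree, child_vertices) {
  child_vertices <- unique(as.integer(child_vertices))
  if (length(child_vertices) == 0L) return(tree)
  lv <- is_leaf_vertex(tree)
  if (any(lv[child_vertices]) || tree$root %in% child_vertices)
    stop_contract("only edges above inner non-root vertices can be contracted")
  drop <- rep(FALSE, n_vertices(tree))
  drop[child_vertices] <- TRUE
  # splice bottom-up so that children lists cascade through dropped vertices
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) next
    new_kids <- integer(0)
    for (u in kids) {
      new_kids <- if (drop[u]) c(new_kids, tree$children[[u]]) else c(new_kids, u)
    }
    tree$children[[v]] <- new_kids
    for (u in new_kids) tree$parent[u] <- v
  }
  keep <- which(!drop)
  remap <- integer(n_vertices(tree))
  remap[keep] <- seq_along(keep)
  rtree(parent = ifelse(is.na(tree$parent[keep]), NA_integer_,
                        remap[tree$parent[keep]]),
        children = lapply(tree$children[keep], function(k) remap[k]),
        labels = tree$labels[keep])
}
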