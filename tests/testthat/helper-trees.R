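# Shared fixtures: exhaustive tree catalogues (built in code) and small
# convenience wrappers around package internals used as test oracles.

trees_equal <- function(a, b) lincr:::same_tree(a, b)

cluster_keyset <- function(tree) {
  sort(vapply(clusters(tree)$clusters, paste, "", collapse = "|"))
}

# All set partitions of a character vector.
set_partitions <- function(x) {
  if (length(x) == 1L) return(list(list(x)))
  rest <- set_partitions(x[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(x[1L]), p)
  }
  out
}

# Newick strings of every phylogenetic tree on the given labels (the root's
# child clusters partition the label set into >= 2 blocks; recurse per block).
all_trees_newick <- function(labs) {
  if (length(labs) == 1L) return(labs)
  out <- character(0)
  for (p in Filter(function(q) length(q) >= 2L, set_partitions(labs))) {
    subs <- lapply(p, all_trees_newick)
    grid <- expand.grid(lapply(subs, seq_along))
    for (r in seq_len(nrow(grid))) {
      parts <- vapply(seq_along(p), function(j) subs[[j]][grid[r, j]], "")
      out <- c(out, paste0("(", paste(parts, collapse = ","), ")"))
    }
  }
  out
}

tree_catalogue <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      nwk <- all_trees_newick(letters[seq_len(n)])
      cache[[key]] <<- lapply(paste0(nwk, ";"), parse_newick)
    }
    cache[[key]]
  }
})

# A random rooted binary tree on n leaves (via ape), as an rtree.
random_binary_tree <- function(n) {
  phy <- ape::rtree(n, rooted = TRUE, br = NULL)
  parse_newick(ape::write.tree(phy))
}

# Definition-level triple oracle: enumerate 3-subsets and apply the
# lca-based display condition directly.
triples_by_lca <- function(tree) {
  labs <- sort(leaf_labels(tree))
  strictly_below <- function(a, b) {           # a strictly below b
    while (!is.na(tree$parent[a])) {
      a <- tree$parent[a]
      if (a == b) return(TRUE)
    }
    FALSE
  }
  out <- list()
  cmb <- utils::combn(labs, 3L)
  for (col in seq_len(ncol(cmb))) {
    trio <- cmb[, col]
    for (z_pos in 1:3) {
      z <- trio[z_pos]
      xy <- sort(trio[-z_pos])
      l_xy <- lca(tree, xy)
      l_xz <- lca(tree, c(xy[1L], z))
      l_yz <- lca(tree, c(xy[2L], z))
      if (l_xz == l_yz && l_xy != l_xz && strictly_below(l_xy, l_xz)) {
        out[[length(out) + 1L]] <- c(xy, z)
      }
    }
  }
  if (length(out) == 0L) return(matrix(character(0), 0L, 3L))
  do.call(rbind, out)
}

triple_keys <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  sort(apply(mat, 1L, paste, collapse = "|"))
}
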