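#' Rooted phylogenetic trees with stable vertex identities
#'
#' An `rtree` stores a rooted tree as an explicit parent map, ordered child
#' lists and a label vector, all indexed by integer vertex ids `1..n`.
#' Vertex ids are stable handles: they never change under traversal and they
#' are what cross-tree correspondence tables refer to.  Leaves are exactly
#' the vertices without children and carry unique labels; inner vertices may
#' optionally be labelled.
#'
#' @param parent integer vector; `parent[v]` is the parent of vertex `v`,
#'   `NA` exactly at the root.
#' @param children list of integer vectors; `children[[v]]` are the children
#'   of `v` in order.
#' @param labels character vector; leaf labels (mandatory, unique) and
#'   optional inner labels, `NA` where absent.
#' @param validate if `TRUE`, check structural invariants.
#'
#' @return An object of class `rtree`.
#' @seealso [parse_newick()], [write_newick()], [as_phylo()]
#' @export
rtree <- function(parent, children, labels = rep(NA_character_, length(parent)),
                  validate = TRUE) {
  x <- structure(list(parent = as.integer(parent),
                      children = lapply(children, as.integer),
                      labels = as.character(labels),
                      root = which(is.na(parent))[1L]),
                 class = "rtree")
  if (validate) validate_rtree(x)
  x
}

validate_rtree <- function(x) {
  nv <- length(x$parent)
  if (length(x$children) != nv || length(x$labels) != nv)
    stop_contract("parent, children and labels must have equal length")
  if (sum(is.na(x$parent)) != 1L)
    stop_contract("exactly one root (one NA in parent) is required")
  # parent/children mutual consistency
  for (v in seq_len(nv)) {
    for (u in x$children[[v]]) {
      if (is.na(x$parent[u]) || x$parent[u] != v)
        stop_contract("children and parent maps are inconsistent")
    }
  }
  kid_count <- lengths(x$children)
  if (sum(kid_count) != nv - 1L)
    stop_contract("tree must have exactly n - 1 edges")
  # connectivity: every vertex reaches the root
  depth <- rep(NA_integer_, nv)
  depth[x$root] <- 0L
  frontier <- x$root
  while (length(frontier)) {
    nxt <- unlist(x$children[frontier], use.names = FALSE)
    depth[nxt] <- 1L
    frontier <- nxt
  }
  if (anyNA(depth))
    stop_contract("tree is not connected")
  lv <- kid_count == 0L
  if (any(is.na(x$labels[lv])))
    stop_contract("every leaf must be labelled")
  if (anyDuplicated(x$labels[lv]))
    stop_input("duplicate leaf labels")
  invisible(x)
}

#' @export
print.rtree <- function(x, ...) {
  cat(sprintf("Rooted tree with %d leaves and %d inner vertices\n",
              n_leaves(x), sum(lengths(x$children) > 0L)))
  cat(write_newick(x), "\n")
  invisible(x)
}

n_vertices <- function(tree) length(tree$parent)

is_leaf_vertex <- function(tree) lengths(tree$children) == 0L

#' Leaf vertices and leaf labels
#'
#' `leaves()` returns the integer ids of the leaf vertices (in vertex-id
#' order); `leaf_labels()` their labels; `n_leaves()` their number.
#'
#' @param tree an [rtree].
#' @return Integer vector, character vector, or a count.
#' @export
leaves <- function(tree) which(is_leaf_vertex(tree))

#' @rdname leaves
#' @export
leaf_labels <- function(tree) tree$labels[leaves(tree)]

#' @rdname leaves
#' @export
n_leaves <- function(tree) sum(is_leaf_vertex(tree))

#' Test the phylogenetic property
#'
#' A rooted tree is phylogenetic if every inner vertex has at least two
#' children.  Trees with unary vertices can be represented (they arise
#' transiently during verification) but most operations require the
#' phylogenetic property.
#'
#' @param tree an [rtree].
#' @return `TRUE` or `FALSE`.
#' @export
is_phylogenetic <- function(tree) {
  k <- lengths(tree$children)
  !any(k == 1L)
}

# Ordered child lists from a parent vector (children sorted by vertex id).
children_from_parent <- function(parent) {
  nv <- length(parent)
  kids <- split(seq_len(nv)[!is.na(parent)], factor(parent[!is.na(parent)],
                                                    levels = seq_len(nv)))
  lapply(kids, as.integer)
}

# Vertices in preorder (parents before children, siblings in child order).
preorder <- function(tree) {
  nv <- n_vertices(tree)
  out <- integer(nv)
  stack <- integer(nv)
  stack[1L] <- tree$root
  sp <- 1L
  pos <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    pos <- pos + 1L
    out[pos] <- v
    kids <- tree$children[[v]]
    for (u in rev(kids)) {
      sp <- sp + 1L
      stack[sp] <- u
    }
  }
  out
}

# Vertices in postorder (children before parents).
postorder <- function(tree) rev(preorder(tree))

#' Convert between rtree and ape's phylo representation
#'
#' `as_phylo()` renumbers vertices into ape's convention (tips first, then
#' inner vertices starting at the root); `as_rtree()` does the reverse.
#' Branch lengths are never produced and are discarded on conversion.
#'
#' @param x an [rtree] or an [ape::read.tree()] `phylo` object.
#' @return A `phylo`, respectively an [rtree].
#' @export
as_phylo <- function(x) {
  stopifnot(inherits(x, "rtree"))
  nv <- n_vertices(x)
  lv <- is_leaf_vertex(x)
  n <- sum(lv)
  if (nv < 3L) stop_contract("ape's phylo requires at least two leaves plus root")
  pre <- preorder(x)
  tip_ids <- pre[lv[pre]]        # tips in preorder, ape-style
  inner_ids <- pre[!lv[pre]]     # root first
  new_id <- integer(nv)
  new_id[tip_ids] <- seq_len(n)
  new_id[inner_ids] <- n + seq_along(inner_ids)
  edge <- matrix(0L, nv - 1L, 2L)
  r <- 0L
  for (v in pre) {
    for (u in x$children[[v]]) {
      r <- r + 1L
      edge[r, ] <- c(new_id[v], new_id[u])
    }
  }
  node_lab <- x$labels[inner_ids]
  phy <- list(edge = edge, Nnode = nv - n, tip.label = x$labels[tip_ids])
  if (!all(is.na(node_lab))) {
    node_lab[is.na(node_lab)] <- ""
    phy$node.label <- node_lab
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' @rdname as_phylo
#' @export
as_rtree <- function(x) {
  stopifnot(inherits(x, "phylo"))
  n <- length(x$tip.label)
  nv <- n + x$Nnode
  parent <- rep(NA_integer_, nv)
  children <- vector("list", nv)
  for (v in seq_len(nv)) children[[v]] <- integer(0)
  for (r in seq_len(nrow(x$edge))) {
    p <- x$edge[r, 1L]; c_ <- x$edge[r, 2L]
    parent[c_] <- p
    children[[p]] <- c(children[[p]], c_)
  }
  labels <- rep(NA_character_, nv)
  labels[seq_len(n)] <- x$tip.label
  if (!is.null(x$node.label)) {
    nl <- x$node.label
    nl[!nzchar(nl)] <- NA_character_
    labels[n + seq_len(x$Nnode)] <- nl
  }
  rtree(parent, children, labels)
}

#' Read a rooted tree from a Newick string
#'
#' Accepts the standard rooted Newick dialect: multifurcations, optional
#' inner-vertex labels, optional branch lengths (parsed and discarded) and
#' an optional trailing semicolon.  Leaf labels must be unique.  Unary
#' (single-child) vertices are rejected unless `allow_unary = TRUE`, since
#' phylogenetic trees do not contain them.
#'
#' @param text a Newick string.
#' @param allow_unary admit non-phylogenetic trees with unary vertices.
#' @return An [rtree].
#' @examples
#' tr <- parse_newick("(a,(b,c)v1)v2;")
#' n_leaves(tr)
#' @export
parse_newick <- function(text, allow_unary = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop_parse("empty Newick string")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  no <- sum(strsplit(text, "")[[1]] == "(")
  nc <- sum(strsplit(text, "")[[1]] == ")")
  if (no != nc) stop_parse("unbalanced parentheses in Newick string")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop_parse(conditionMessage(e)))
  if (is.null(phy)) stop_parse("could not parse Newick string")
  if (anyDuplicated(phy$tip.label)) stop_input("duplicate leaf labels")
  tr <- as_rtree(phy)
  if (!allow_unary && !is_phylogenetic(tr))
    stop_input("tree has unary vertices; use allow_unary = TRUE to accept")
  tr
}

#' Write a rooted tree as a Newick string
#'
#' The inverse of [parse_newick()] up to child order: re-parsing the output
#' yields a tree with the same cluster set and the same labels.
#'
#' @param tree an [rtree].
#' @return A Newick string terminated by a semicolon.
#' @export
write_newick <- function(tree) {
  ape::write.tree(as_phylo(tree))
}
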