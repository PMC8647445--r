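test_that("Newick parsing recovers vertices, labels and structure", {
  tr <- parse_newick("(a,(b,c)v1)v2;")
  expect_equal(length(tr$parent), 5L)
  expect_equal(sort(leaf_labels(tr)), c("a", "b", "c"))
  expect_equal(tr$labels[tr$root], "v2")
  v1 <- lca(tr, c("b", "c"))
  expect_equal(tr$labels[v1], "v1")
  expect_setequal(tr$labels[tr$children[[v1]]], c("b", "c"))

  cherry <- parse_newick("(a,b);")
  expect_equal(n_leaves(cherry), 2L)
  expect_equal(sort(cherry$labels[cherry$children[[cherry$root]]]), c("a", "b"))

  # branch lengths tolerated and discarded; trailing semicolon optional
  expect_true(trees_equal(parse_newick("(a:1,(b:2,c:0.5)v1:3)v2;"), tr))
  expect_true(trees_equal(parse_newick("((a,b),c)"), parse_newick("((a,b),c);")))

  expect_error(parse_newick("((a,b,c);"), class = "lincr_parse_error")
  expect_error(parse_newick("(a,(b,a));"), class = "lincr_input_error")
  expect_error(parse_newick("((a)u,b);"), class = "lincr_input_error")
  expect_silent(tr_un <- parse_newick("((a)u,b);", allow_unary = TRUE))
  expect_false(is_phylogenetic(tr_un))
})

test_that("Newick writing round-trips cluster sets", {
  for (nwk in c("(a,b);", "((a,b),c);", "(a,(b,c)v1)v2;", "(a,b,c,d);",
                "((a,b),(c,d),e);")) {
    tr <- parse_newick(nwk)
    expect_true(trees_equal(parse_newick(write_newick(tr)), tr))
  }
  reparsed <- parse_newick(write_newick(parse_newick("(a,(b,c)v1)v2;")))
  expect_setequal(cluster_keyset(reparsed), c("a", "b", "c", "b|c", "a|b|c"))
})

test_that("cluster sets match subtree enumeration and hierarchy tests work", {
  expect_setequal(cluster_keyset(parse_newick("(a,b,c);")),
                  c("a", "b", "c", "a|b|c"))
  expect_setequal(cluster_keyset(parse_newick("((a,b),c);")),
                  c("a", "b", "c", "a|b", "a|b|c"))
  cs <- clusters(parse_newick("(a,(b,c)v1)v2;"))
  expect_equal(length(cs$clusters), 5L)    # one distinct cluster per vertex

  expect_true(is_hierarchy(clusters(parse_newick("((a,b),(c,d),e);"))))
  bad <- cluster_system(list("a", "b", "c", c("a", "b"), c("b", "c"),
                             c("a", "b", "c")), c("a", "b", "c"))
  expect_false(is_hierarchy(bad))
  expect_true(is_hierarchy(cluster_system(list("a", "b", c("a", "b")),
                                          c("a", "b"))))
  # missing singleton or ground set disqualifies
  expect_false(is_hierarchy(cluster_system(list("a", c("a", "b")), c("a", "b"))))
  expect_false(is_hierarchy(cluster_system(list("a", "b"), c("a", "b"))))
})

test_that("Hasse diagram reconstruction inverts the cluster map", {
  cs <- cluster_system(list("a", "b", "c", c("a", "b"), c("a", "b", "c")),
                       c("a", "b", "c"))
  expect_true(trees_equal(tree_from_hierarchy(cs), parse_newick("((a,b),c);")))

  star_cs <- cluster_system(list("a", "b", "c", "d", letters[1:4]), letters[1:4])
  expect_true(trees_equal(tree_from_hierarchy(star_cs),
                          parse_newick("(a,b,c,d);")))

  expect_error(tree_from_hierarchy(cluster_system(
    list("a", "b", "c", c("a", "b"), c("b", "c"), c("a", "b", "c")),
    c("a", "b", "c"))), class = "lincr_contract_error")

  set.seed(7)
  for (rep in 1:20) {
    tr <- random_tree(sample(3:12, 1L))
    back <- tree_from_hierarchy(clusters(tr))
    expect_true(trees_equal(back, tr))
    expect_true(is_phylogenetic(back))
  }
})

test_that("lca returns the inclusion-minimal cluster vertex", {
  tr <- parse_newick("(a,(b,c)v1)v2;")
  expect_equal(tr$labels[lca(tr, c("b", "c"))], "v1")
  expect_equal(lca(tr, c("a", "b", "c")), tr$root)
  t2 <- parse_newick("((a,b),(c,d));")
  expect_equal(lca(t2, c("a", "c")), t2$root)
  expect_equal(lca(t2, "a"), which(t2$labels == "a"))
  expect_error(lca(tr, c("a", "zz")), class = "lincr_input_error")
})

test_that("displayed triples match the lca-based definition", {
  expect_equal(triple_keys(triples(parse_newick("((a,b),c);"))), "a|b|c")
  expect_equal(nrow(triples(parse_newick("(a,b,c);"))), 0L)
  expect_setequal(triple_keys(triples(parse_newick("((a,b),(c,d));"))),
                  c("a|b|c", "a|b|d", "c|d|a", "c|d|b"))
  set.seed(11)
  for (rep in 1:10) {
    tr <- random_tree(sample(4:8, 1L))
    expect_equal(triple_keys(triples(tr)), triple_keys(triples_by_lca(tr)))
  }
})

test_that("the display relation is cluster containment", {
  t_res <- parse_newick("((a,b),(c,d));")
  t_loose <- parse_newick("((a,b),c,d);")
  expect_true(displays_tree(t_res, t_res))
  expect_true(displays_tree(t_res, t_loose))
  expect_false(displays_tree(t_loose, t_res))
  expect_false(displays_tree(parse_newick("((a,b),c);"),
                             parse_newick("((a,c),b);")))
  expect_error(displays_tree(parse_newick("(a,b);"), parse_newick("(a,c);")),
               class = "lincr_input_error")
})

test_that("edge contraction removes exactly the chosen clusters", {
  tr <- parse_newick("(a,(b,c)v1)v2;")
  v1 <- lca(tr, c("b", "c"))
  expect_true(trees_equal(contract_edge(tr, v1), parse_newick("(a,b,c);")))
  expect_error(contract_edge(tr, tr$root), class = "lincr_contract_error")
  expect_error(contract_edge(tr, which(tr$labels == "a")),
               class = "lincr_contract_error")

  set.seed(3)
  for (rep in 1:15) {
    tr <- random_tree(sample(4:12, 1L))
    inner <- setdiff(which(lengths(tr$children) > 0L), tr$root)
    if (length(inner) == 0L) next
    v <- sample(inner, 1L)
    before <- cluster_keyset(tr)
    after <- cluster_keyset(contract_edge(tr, v))
    expect_equal(length(setdiff(before, after)), 1L)
    expect_true(all(after %in% before))
    # contracting everything gives the star
    expect_setequal(cluster_keyset(contract_edges(tr, inner)),
                    c(sort(leaf_labels(tr)),
                      paste(sort(leaf_labels(tr)), collapse = "|")))
  }
})

test_that("cluster count equals vertex count, bounded by 2|L| - 1", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:20, 1L)
    tr <- random_tree(n)
    m <- length(clusters(tr)$clusters)
    expect_equal(m, length(tr$parent))
    expect_lte(m, 2L * n - 1L)
  }
  bin <- random_binary_tree(9)
  expect_equal(length(clusters(bin)$clusters), 2L * 9L - 1L)
})

test_that("display is a partial order on trees over a fixed leaf set", {
  for (n in 3:5) {
    cat_trees <- tree_catalogue(n)
    keysets <- lapply(cat_trees, cluster_keyset)
    m <- length(cat_trees)
    disp <- matrix(FALSE, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      disp[i, j] <- all(keysets[[j]] %in% keysets[[i]])
    }
    expect_true(all(diag(disp)))                          # reflexive
    sym <- disp & t(disp)
    expect_true(all(sym == diag(TRUE, m)))                # antisymmetric
    closure <- (disp %*% disp) > 0
    expect_true(all(disp[closure]))                       # transitive
    # the matrix really is the displays_tree relation (spot checks)
    set.seed(n)
    for (s in 1:25) {
      i <- sample(m, 1L); j <- sample(m, 1L)
      expect_equal(displays_tree(cat_trees[[i]], cat_trees[[j]]), disp[i, j])
    }
  }
})

test_that("phylo conversion round-trips through ape", {
  set.seed(9)
  for (rep in 1:10) {
    tr <- random_tree(sample(3:15, 1L))
    phy <- as_phylo(tr)
    expect_s3_class(phy, "phylo")
    expect_true(trees_equal(as_rtree(phy), tr))
  }
})
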