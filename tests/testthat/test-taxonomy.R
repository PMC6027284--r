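test_that("taxdump parsing builds the tree and keeps synonym names", {
  paths <- write_tiny_taxdump(
    nodes_lines = c(dmp_line(1, 1, "no rank"),
                    dmp_line(2, 1, "order")),
    names_lines = c(dmp_line(1, "root", "", "scientific name"),
                    dmp_line(2, "Primates", "", "scientific name"),
                    dmp_line(2, "primate group", "", "synonym")))
  tree <- load_taxdump(paths[["nodes"]], paths[["names"]])
  expect_equal(nrow(tree$nodes), 2)
  expect_equal(tree$root, 1L)
  expect_equal(taxon_name(tree, 2L), "Primates")
  # both classes resolve; scientific name wins when both exist
  expect_equal(resolve_taxon(tree, "Primates"), 2L)
  expect_equal(resolve_taxon(tree, "primate group"), 2L)
  expect_equal(resolve_taxon(tree, "PRIMATES"), 2L)
})

test_that("malformed and structurally broken taxdumps raise errors", {
  paths <- write_tiny_taxdump(
    nodes_lines = c(dmp_line(1, 1, "no rank"), "2\t|\t1"),
    names_lines = dmp_line(1, "root", "", "scientific name"))
  expect_error(load_taxdump(paths[["nodes"]], paths[["names"]]),
               "line 2")
  paths2 <- write_tiny_taxdump(
    nodes_lines = c(dmp_line(1, 1, "no rank"),
                    dmp_line(2, 99, "genus")),
    names_lines = dmp_line(1, "root", "", "scientific name"))
  expect_error(load_taxdump(paths2[["nodes"]], paths2[["names"]]),
               "structural error.*99")
})

test_that("taxon resolution handles ids, unknown names and homonyms", {
  tree <- binary_tree()
  expect_error(resolve_taxon(tree, 4710), "not found")
  expect_equal(resolve_taxon(tree, 3L), 3L)
  expect_error(resolve_taxon(tree, "Notaxon"), "not found")
  homonym <- tax_tree(
    data.frame(taxid = 1:3, parent_taxid = c(1L, 1L, 1L),
               rank = c("order", "genus", "genus"),
               name = c("Root", "Dupe", "Dupe"), stringsAsFactors = FALSE))
  expect_error(resolve_taxon(homonym, "Dupe"), "ambiguous.*2, 3")
})

test_that("descendant enumeration is preorder and matches recursion", {
  tree <- binary_tree()
  expect_equal(descendants(tree, 4L), integer(0))
  expect_equal(descendants(tree, 1L), c(2L, 4L, 5L, 3L, 6L, 7L))
  # independent oracle: plain recursive enumeration
  recurse <- function(v) {
    kids <- sort(tree$nodes$taxid[tree$nodes$parent_taxid == v &
                                    tree$nodes$taxid != v])
    unlist(lapply(kids, function(k) c(k, recurse(k))))
  }
  expect_equal(descendants(tree, 1L), as.integer(recurse(1L)))
  expect_error(descendants(tree, 42L), "not found")
  for (seed in 1:5) {
    rt <- random_tax_tree(40, seed)
    d <- descendants(rt, rt$root)
    expect_equal(sort(d), 2:40) # all non-root ids exactly once
  }
})

test_that("ancestor_at_rank walks to the nearest ranked ancestor", {
  tree <- binary_tree()
  expect_equal(ancestor_at_rank(tree, 4L, "genus"), 2L)
  expect_equal(ancestor_at_rank(tree, 2L, "genus"), 2L) # self counts
  expect_equal(ancestor_at_rank(tree, 1L, "genus"), NA_integer_)
  expect_equal(ancestor_at_rank(tree, 6L, "order"), 1L)
})

test_that("small subtrees become one unit; oversized roots are split", {
  tree <- binary_tree()
  counts <- stats::setNames(rep(2L, 4), as.character(4:7))
  units <- partition_clades(tree, counts) # defaults 50000/100000
  expect_length(units, 1)
  expect_equal(units[[1]]$kind, "subtree")
  expect_equal(units[[1]]$taxid, 1L)
  expect_setequal(units[[1]]$member_taxids, 1:7)

  # root over limit, children fit: two subtree units + paraphyletic pool
  counts2 <- stats::setNames(c(2L, rep(3L, 4)), as.character(c(1L, 4:7)))
  units2 <- partition_clades(tree, counts2, max_seqs = 8)
  kinds <- vapply(units2, `[[`, "", "kind")
  expect_equal(sort(kinds), c("paraphyletic", "subtree", "subtree"))
  para <- units2[[which(kinds == "paraphyletic")]]
  expect_equal(para$member_taxids, 1L)
  expect_equal(para$n_seqs, 2L)

  expect_length(partition_clades(tree, stats::setNames(integer(0),
                                                       character(0))), 0)
})

test_that("partition covers sequence-bearing taxa once and obeys limits", {
  for (seed in 1:15) {
    tree <- random_tax_tree(30 + (seed %% 3) * 60, seed)
    set.seed(seed + 1000)
    n <- nrow(tree$nodes)
    bearing <- sample(tree$nodes$taxid, max(2, n %/% 3))
    counts <- stats::setNames(sample(0:20, length(bearing), replace = TRUE),
                              as.character(bearing))
    max_seqs <- sample(c(10, 30, 100), 1)
    max_nodes <- sample(c(15, 60, 1000), 1)
    units <- suppressWarnings(
      partition_clades(tree, counts, max_seqs, max_nodes))
    bearing_ids <- as.integer(names(counts)[counts > 0])
    covered <- unlist(lapply(units, `[[`, "member_taxids"))
    expect_true(all(bearing_ids %in% covered))
    expect_equal(anyDuplicated(covered), 0L)
    # subtree units obey both limits vs the brute-force oracle
    sums <- brute_subtree_sums(tree, counts)
    for (u in units) {
      if (u$kind != "subtree" || length(u$member_taxids) == 1) next
      at <- match(u$taxid, tree$nodes$taxid)
      expect_lte(sums["seqs", at], max_seqs)
      expect_lte(sums["nodes", at], max_nodes)
    }
    # determinism
    units_again <- suppressWarnings(
      partition_clades(tree, counts, max_seqs, max_nodes))
    expect_identical(units, units_again)
  }
})
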