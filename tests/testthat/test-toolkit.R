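test_that("MAD closed forms and properties hold", {
  expect_equal(mad_score(c(500, 500, 500)), 1)
  expect_equal(mad_score(c(100, 100, 50)), 250 / 300)
  expect_equal(mad_score(1234), 1)
  expect_error(mad_score(numeric(0)), "empty")
  set.seed(7)
  for (trial in 1:200) {
    lens <- sample(50:2000, sample(2:30, 1), replace = TRUE)
    m <- mad_score(lens)
    expect_gt(m, 0)
    expect_lte(m, 1)
    expect_equal(m == 1, length(unique(lens)) == 1)
    # shrinking a member without changing the maximum strictly lowers it
    cand <- which(lens < max(lens) | duplicated(lens))
    if (length(cand) > 0) {
      i <- cand[[sample.int(length(cand), 1)]]
      lens2 <- lens
      lens2[[i]] <- max(1, lens2[[i]] - sample(1:40, 1))
      if (max(lens2) == max(lens)) expect_lt(mad_score(lens2), m)
    }
  }
})

test_that("GC ratio and ambiguity proportion handle degenerate input", {
  expect_equal(gc_ratio("GGCC"), 1)
  expect_equal(ambiguous_prop("GGCC"), 0)
  expect_equal(ambiguous_prop("ATATNNNN"), 0.5)
  expect_equal(gc_ratio("ATATNNNN"), 0) # over unambiguous bases only
  expect_equal(gc_ratio("acgt"), 0.5)
  gc_n <- gc_ratio("NNNN")
  expect_equal(as.numeric(gc_n), 0)
  expect_true(attr(gc_n, "degenerate"))
  expect_error(gc_ratio(""), "empty")
  expect_error(ambiguous_prop(""), "empty")
})

test_that("informativeness and MAD filters keep the right clusters", {
  tree <- binary_tree()
  # clusters with 3, 5 and 12 member taxids (wrapping the 4 leaf species
  # is fine for the count: taxids repeat across segments)
  members <- list(paste0("a", 1:3), paste0("b", 1:5), paste0("c", 1:12))
  taxids <- c(4:6, c(4L, 5L, 6L, 7L, 101L), 101:112)
  homonym_tree <- tax_tree(data.frame(
    taxid = c(1L, 4:7, 101:112), parent_taxid = 1L,
    rank = c("order", rep("species", 16)),
    name = paste0("t", c(1L, 4:7, 101:112)), stringsAsFactors = FALSE))
  cset <- toy_cluster_set(members, taxids, tree = homonym_tree)
  kept <- filter_clusters(cset, min_taxa = 5)
  expect_setequal(vapply(kept$clusters, `[[`, 0L, "cluster_id"), c(1L, 2L))

  # MAD filter: lengths (1000,100,100) give 0.4 < 0.75
  cset2 <- toy_cluster_set(list(paste0("m", 1:3), paste0("n", 1:3)),
                           c(4:6, 4:6),
                           lengths = c(1000L, 100L, 100L, 500L, 500L, 500L),
                           tree = homonym_tree)
  kept2 <- filter_clusters(cset2, min_mad = 0.75)
  expect_equal(vapply(kept2$clusters, `[[`, 0L, "cluster_id"), 1L)

  # top_k larger than the pool keeps everything
  kept3 <- filter_clusters(cset, top_k = 10)
  expect_length(kept3$clusters, 3)
  expect_error(filter_clusters(cset, nonsense_filter = 1),
               "unknown predicate")
})

test_that("per-rank representative selection keeps the best segments", {
  tree <- binary_tree()
  # 7 segments in one genus (taxids 4/5 both under genus 2)
  ids <- paste0("r", 1:7)
  lens <- c(300L, 500L, 450L, 500L, 200L, 350L, 400L)
  resid <- vapply(seq_along(ids), function(i) {
    n_amb <- c(5L, 0L, 0L, 3L, 0L, 8L, 1L)[i]
    paste0(strrep("N", n_amb), strrep("ACGT", 200))
  }, "")
  resid <- substr(resid, 1, lens)
  cset <- toy_cluster_set(list(ids), rep(c(4L, 5L), length.out = 7),
                          lengths = lens, tree = tree, residues = resid)
  out <- representatives_per_rank(cset, tree, rank = "genus",
                                  n_per_group = 2)
  # oracle: explicit sort by (ambiguity asc, length desc) -> r2 then r3
  expect_equal(out$clusters[[1]]$segment_ids, c("r2", "r3"))

  single <- toy_cluster_set(list("solo"), 4L, lengths = 400L, tree = tree)
  out2 <- representatives_per_rank(single, tree, rank = "genus",
                                   n_per_group = 2)
  expect_equal(out2$clusters[[1]]$segment_ids, "solo")

  # members with no ancestor at the rank drop out; empty clusters vanish
  rootonly <- toy_cluster_set(list(c("q1", "q2")), c(1L, 1L), tree = tree)
  out3 <- representatives_per_rank(rootonly, tree, rank = "genus",
                                   n_per_group = 2)
  expect_length(out3$clusters, 0)
})

test_that("presence/absence matrices tabulate rank coverage", {
  tree <- binary_tree()
  # cluster 0 spans both genera, cluster 1 only genus 2
  cset <- toy_cluster_set(list(c("x1", "x2"), c("y1", "y2")),
                          c(4L, 6L, 4L, 5L), tree = tree)
  m <- presence_absence(cset, tree, rank = "genus")
  expect_equal(dim(m), c(2, 2))
  expect_equal(unname(m[, "0"]), c(1L, 1L))
  expect_equal(unname(m[, "1"]), c(1L, 0L))
  expect_equal(rownames(m), c("GenusA", "GenusB"))
  # row sums cross-check against per-cluster group counts
  expect_equal(unname(colSums(m)),
               vapply(cset$clusters, function(cl)
                 orthoclust:::n_rank_groups(cset, tree, "genus",
                                            cl$cluster_id), 0L))
  empty <- toy_cluster_set(list(), integer(0), lengths = integer(0),
                           residues = character(0),
                           definitions = character(0), tree = tree)
  expect_equal(dim(presence_absence(empty, tree, "genus")), c(0, 0))
})

test_that("export writes tables plus FASTA and round-trips", {
  tree <- binary_tree()
  cset <- toy_cluster_set(list(c("e1", "e2", "e3"), c("f1", "f2", "f3")),
                          c(4L, 5L, 6L, 4L, 6L, 7L), tree = tree)
  d <- withr_tempdir()
  paths <- export_clusters(cset, d, tree = tree)
  expect_true(file.exists(file.path(d, "clusters.tsv")))
  expect_true(file.exists(file.path(d, "cluster_seqs.tsv")))
  expect_true(file.exists(file.path(d, "taxa.tsv")))
  expect_true(file.exists(file.path(d, "cluster_0.fasta")))
  expect_true(file.exists(file.path(d, "cluster_1.fasta")))
  ctab <- read.delim(file.path(d, "clusters.tsv"))
  stab <- read.delim(file.path(d, "cluster_seqs.tsv"))
  expect_equal(nrow(ctab), 2)
  expect_equal(nrow(stab), 6)
  expect_equal(nrow(read.delim(file.path(d, "taxa.tsv"))), 7)
  # FASTA wraps at 70 columns
  fa_lines <- readLines(file.path(d, "cluster_0.fasta"))
  expect_true(all(nchar(fa_lines[!startsWith(fa_lines, ">")]) <= 70))

  back <- import_clusters(d)
  expect_equal(length(back$clusters), length(cset$clusters))
  expect_identical(lapply(back$clusters, `[[`, "segment_ids"),
                   lapply(cset$clusters, `[[`, "segment_ids"))
  expect_identical(lapply(back$clusters, `[[`, "kind"),
                   lapply(cset$clusters, `[[`, "kind"))
  expect_equal(back$segments$residues[match(cset$segments$segment_id,
                                            back$segments$segment_id)],
               cset$segments$residues)

  empty <- toy_cluster_set(list(), integer(0), lengths = integer(0),
                           residues = character(0),
                           definitions = character(0), tree = tree)
  d2 <- withr_tempdir()
  export_clusters(empty, d2, tree = tree)
  expect_equal(readLines(file.path(d2, "clusters.tsv")),
               "cluster_id\tkind\ttaxid\tn_seqs\tn_taxa\tseed_id\tmad")
})
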