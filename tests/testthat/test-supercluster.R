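# Build a cluster_set holding one gene family artificially split across
# two clade units (plus an unrelated family), so seed-vs-seed search is
# the only way the halves can reunite.
split_family_cset <- function(seed = 4) {
  segs <- two_family_segments(n_per = 6, len = 500, divergence = 0.05,
                              seed = seed)
  fam1 <- segs[substr(segs$segment_id, 1, 2) == "F1", ]
  fam2 <- segs[substr(segs$segment_id, 1, 2) == "F2", ]
  halves <- list(fam1[1:3, ], fam1[4:6, ])
  params <- search_params()
  mk <- function(s, kind = "subtree", taxid = 1L) {
    hits <- filter_hits(all_vs_all(s, params), params)
    edges <- symmetrize_edges(hits)
    lens <- stats::setNames(s$length, s$segment_id)
    orthoclust:::new_cluster(kind = kind, taxid = taxid,
                             segment_ids = sort(s$segment_id,
                                                method = "radix"),
                             seed_id = seed_of(s$segment_id, edges, lens))
  }
  clusters <- list(mk(halves[[1]], taxid = 2L), mk(halves[[2]], taxid = 3L),
                   mk(fam2, taxid = 1L))
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i - 1L
  structure(list(clusters = clusters,
                 segments = segs[, c("segment_id", "taxid", "length",
                                     "definition", "residues")],
                 metadata = list()),
            class = "cluster_set")
}

test_that("a family split across units is merged back into one cluster", {
  cset <- split_family_cset()
  out <- merge_clusters(cset)
  merged <- Filter(function(cl) cl$kind == "merged", out$clusters)
  expect_length(merged, 1)
  mc <- merged[[1]]
  expect_equal(mc$parent_cluster_ids, c(0L, 1L))
  parents <- lapply(mc$parent_cluster_ids, orthoclust:::cluster_by_id,
                    cset = cset)
  expect_equal(mc$segment_ids,
               sort(unique(unlist(lapply(parents, `[[`, "segment_ids"))),
                    method = "radix"))
  expect_true(mc$seed_id %in% vapply(parents, `[[`, "", "seed_id"))
  # parents are retained and flagged; the unrelated family is untouched
  expect_equal(out$clusters[[1]]$merged_into, mc$cluster_id)
  expect_equal(out$clusters[[2]]$merged_into, mc$cluster_id)
  expect_true(is.na(out$clusters[[3]]$merged_into))
})

test_that("merge groups are invariant under cluster input order", {
  cset <- split_family_cset()
  out1 <- merge_clusters(cset)
  cset_rev <- cset
  cset_rev$clusters <- rev(cset$clusters)
  out2 <- merge_clusters(cset_rev)
  groups_of <- function(out) {
    merged <- Filter(function(cl) cl$kind == "merged", out$clusters)
    lapply(merged, function(m) sort(m$parent_cluster_ids))
  }
  expect_identical(groups_of(out1), groups_of(out2))
  members_of <- function(out) {
    merged <- Filter(function(cl) cl$kind == "merged", out$clusters)
    lapply(merged, `[[`, "segment_ids")
  }
  expect_identical(members_of(out1), members_of(out2))
})

test_that("merging is idempotent when seed relations are unchanged", {
  cset <- split_family_cset()
  once <- merge_clusters(cset)
  twice <- merge_clusters(once)
  expect_equal(length(twice$clusters), length(once$clusters))
  expect_identical(lapply(twice$clusters, `[[`, "segment_ids"),
                   lapply(once$clusters, `[[`, "segment_ids"))
})

test_that("unrelated clusters are passed through with no merge", {
  segs <- two_family_segments(n_per = 4, len = 500, seed = 12)
  params <- search_params()
  mk_cluster <- function(s, id) {
    edges <- symmetrize_edges(filter_hits(all_vs_all(s, params), params))
    orthoclust:::new_cluster(kind = "subtree", taxid = 1L,
                             segment_ids = sort(s$segment_id,
                                                method = "radix"),
                             seed_id = seed_of(s$segment_id, edges),
                             cluster_id = id)
  }
  fam1 <- segs[substr(segs$segment_id, 1, 2) == "F1", ]
  fam2 <- segs[substr(segs$segment_id, 1, 2) == "F2", ]
  cset <- structure(list(
    clusters = list(mk_cluster(fam1, 0L), mk_cluster(fam2, 1L)),
    segments = segs[, c("segment_id", "taxid", "length", "definition",
                        "residues")],
    metadata = list()), class = "cluster_set")
  out <- merge_clusters(cset)
  expect_length(Filter(function(cl) cl$kind == "merged", out$clusters), 0)
  expect_length(out$metadata$merge_log, 1)
  expect_length(out$metadata$merge_log[[1]]$groups, 0)
})

test_that("chained seed hits merge all three clusters", {
  set.seed(31)
  root <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    for (i in which(runif(length(ch)) < p)) {
      ch[[i]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[i]]), 1)
    }
    paste(ch, collapse = "")
  }
  seqs <- c(A = mutate(root, 0.03), B = root, C = mutate(root, 0.03))
  segs <- do.call(rbind, lapply(names(seqs), function(nm)
    data.frame(segment_id = nm, taxid = 1L, length = 500L,
               definition = "", residues = seqs[[nm]],
               stringsAsFactors = FALSE)))
  clusters <- lapply(seq_along(seqs), function(i)
    orthoclust:::new_cluster(kind = "subtree", taxid = 1L,
                             segment_ids = names(seqs)[i],
                             seed_id = names(seqs)[i],
                             cluster_id = i - 1L))
  cset <- structure(list(clusters = clusters, segments = segs,
                         metadata = list()), class = "cluster_set")
  out <- merge_clusters(cset)
  merged <- Filter(function(cl) cl$kind == "merged", out$clusters)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$parent_cluster_ids, c(0L, 1L, 2L))
  expect_equal(merged[[1]]$segment_ids, c("A", "B", "C"))
})
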