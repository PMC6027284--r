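make_record <- function(acc = "AB000001.1", taxid = 9L, len = 600,
                        features = NULL, seed = 1) {
  set.seed(seed)
  res <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  seq_record(acc, taxid, res, definition = paste(acc, "test sequence"),
             features = features %||% orthoclust:::empty_features())
}

test_that("annotated FASTA and GenBank dialects round-trip records", {
  feats <- data.frame(kind = c("gene", "CDS"), start = c(10L, 200L),
                      end = c(150L, 420L), strand = c("+", "-"),
                      label = c("geneA", "geneB"), stringsAsFactors = FALSE)
  recs <- list(make_record("AA000001.1", 5L, 500, feats, seed = 2),
               make_record("AA000002.1", 6L, 320, seed = 3))
  d <- withr_tempdir()
  fa <- file.path(d, "r.fasta")
  gb <- file.path(d, "r.gb")
  orthoclust:::write_annotated_fasta(recs, fa)
  orthoclust:::write_genbank(recs, gb)
  for (src in list(fasta_source(fa), genbank_source(gb))) {
    back <- fetch_records(src, c(5L, 6L))
    expect_length(back, 2)
    for (i in 1:2) {
      expect_equal(back[[i]]$accession, recs[[i]]$accession)
      expect_equal(back[[i]]$taxid, recs[[i]]$taxid)
      expect_equal(back[[i]]$residues, recs[[i]]$residues)
      expect_equal(back[[i]]$definition, recs[[i]]$definition)
      expect_equal(back[[i]]$features[, c("kind", "start", "end", "strand")],
                   recs[[i]]$features[, c("kind", "start", "end", "strand")])
    }
  }
})

test_that("fetch filters by taxid, is ordered, and repeats identically", {
  recs <- lapply(1:5, function(i)
    make_record(sprintf("Z%07d.1", 6 - i), taxid = c(7L, 7L, 7L, 8L, 8L)[i],
                len = 300, seed = i))
  src <- memory_source(recs)
  got <- fetch_records(src, c(7L, 8L))
  expect_length(got, 5)
  accs <- vapply(got, `[[`, "", "accession")
  expect_equal(accs, sort(accs, method = "radix"))
  expect_length(fetch_records(src, 999L), 0)
  expect_identical(fetch_records(src, c(7L, 8L)), got)
})

test_that("length filtering partitions inclusively at the bounds", {
  recs <- list(make_record("A.1", 1L, 100), make_record("B.1", 1L, 300),
               make_record("C.1", 1L, 9000))
  parts <- length_filter(recs, 250, 3000)
  expect_equal(vapply(parts$kept, `[[`, "", "accession"), "B.1")
  expect_equal(vapply(parts$too_short, `[[`, "", "accession"), "A.1")
  expect_equal(vapply(parts$too_long, `[[`, "", "accession"), "C.1")
  exact <- length_filter(recs[2], 300, 300)
  expect_length(exact$kept, 1)
  expect_length(exact$too_long, 0)
  expect_length(exact$too_short, 0)
})

test_that("feature splitting slices exactly, dedups, and flags bad spans", {
  feats <- data.frame(kind = rep("gene", 3),
                      start = c(1000L, 5000L, 12000L),
                      end = c(2000L, 6000L, 13000L),
                      strand = "+", label = paste0("g", 1:3),
                      stringsAsFactors = FALSE)
  rec <- make_record("LONG1.1", 3L, 20000, feats, seed = 4)
  segs <- split_by_features(rec, 250, 3000)
  expect_equal(nrow(segs), 3)
  # oracle: manual slicing of the fixture string
  for (i in 1:3) {
    expect_equal(segs$residues[[i]],
                 substr(rec$residues, feats$start[[i]] + 1, feats$end[[i]]))
    expect_equal(segs$segment_id[[i]],
                 paste0("LONG1.1/", feats$start[[i]], "-", feats$end[[i]]))
  }
  expect_equal(unique(segs$taxid), 3L)

  no_feat <- make_record("LONG2.1", 3L, 20000, seed = 5)
  expect_equal(nrow(split_by_features(no_feat, 250, 3000)), 0)

  dup <- make_record("LONG3.1", 3L, 20000,
                     feats[c(1, 1), , drop = FALSE], seed = 6)
  expect_equal(nrow(split_by_features(dup, 250, 3000)), 1)

  bad <- make_record("LONG4.1", 3L, 20000,
                     data.frame(kind = "gene", start = 19500L, end = 20500L,
                                strand = "+", label = "g",
                                stringsAsFactors = FALSE), seed = 7)
  expect_warning(out <- split_by_features(bad, 250, 3000), "outside")
  expect_equal(nrow(out), 0)
})

test_that("reverse-strand slices are reverse-complemented and suffixed", {
  feats <- data.frame(kind = "gene", start = 100L, end = 600L, strand = "-",
                      label = "g", stringsAsFactors = FALSE)
  rec <- make_record("RC1.1", 2L, 5000, feats, seed = 8)
  segs <- split_by_features(rec, 250, 3000)
  expect_equal(segs$segment_id, "RC1.1/100-600:rc")
  fwd <- substr(rec$residues, 101, 600)
  expect_equal(segs$residues,
               orthoclust:::reverse_complement(fwd))
})

test_that("segment slices always reconstruct from their parents", {
  set.seed(42)
  for (trial in 1:10) {
    n_feat <- sample(1:4, 1)
    len <- sample(4000:9000, 1)
    starts <- sort(sample(seq(0, len - 800, by = 50), n_feat))
    feats <- data.frame(kind = "gene", start = starts,
                        end = pmin(starts + sample(300:800, n_feat,
                                                   replace = TRUE), len),
                        strand = sample(c("+", "-"), n_feat, replace = TRUE),
                        label = "g", stringsAsFactors = FALSE)
    rec <- make_record("P1.1", 1L, len, feats, seed = trial + 100)
    segs <- prepare_segments(list(rec), 250, 3000)
    expect_true(all(segs$length >= 250 & segs$length <= 3000))
    for (i in seq_len(nrow(segs))) {
      slice <- substr(rec$residues, segs$start[[i]] + 1, segs$end[[i]])
      if (segs$strand[[i]] == "-") {
        slice <- orthoclust:::reverse_complement(slice)
      }
      expect_equal(segs$residues[[i]], slice)
    }
  }
})

test_that("per-taxon subsampling caps reproducibly", {
  recs <- lapply(1:60, function(i)
    make_record(sprintf("S%06d.1", i), taxid = if (i <= 50) 1L else 2L,
                len = 300, seed = i))
  segs <- prepare_segments(recs, 250, 3000)
  capped <- subsample_per_taxon(segs, cap = 10, rng_seed = 5)
  expect_equal(sum(capped$taxid == 1L), 10)
  expect_equal(sum(capped$taxid == 2L), 10) # under cap: untouched
  expect_true(all(capped$segment_id %in% segs$segment_id))
  expect_identical(capped, subsample_per_taxon(segs, cap = 10, rng_seed = 5))
  other <- subsample_per_taxon(segs, cap = 10, rng_seed = 6)
  expect_false(identical(capped$segment_id, other$segment_id))
})
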