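# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# Minimal taxdump files: returns paths of (nodes.dmp, names.dmp).
write_tiny_taxdump <- function(dir = withr_tempdir(),
                               nodes_lines, names_lines) {
  np <- file.path(dir, "nodes.dmp")
  mp <- file.path(dir, "names.dmp")
  writeLines(nodes_lines, np)
  writeLines(names_lines, mp)
  c(nodes = np, names = mp)
}

withr_tempdir <- function() {
  d <- tempfile("fixture_")
  dir.create(d)
  d
}

dmp_line <- function(...) paste0(paste(..., sep = "\t|\t"), "\t|")

# Balanced 3-level binary taxonomy: root 1; 2,3; 4,5 under 2; 6,7 under 3.
binary_tree <- function() {
  tax_tree(data.frame(
    taxid = 1:7,
    parent_taxid = c(1L, 1L, 1L, 2L, 2L, 3L, 3L),
    rank = c("order", "genus", "genus", "species", "species", "species",
             "species"),
    name = c("Root", "GenusA", "GenusB", "GenusA sp1", "GenusA sp2",
             "GenusB sp1", "GenusB sp2"),
    stringsAsFactors = FALSE
  ))
}

# Random taxonomy of n nodes: parent of node k drawn among 1..k-1.
random_tax_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(k) sample.int(k - 1L, 1), integer(1)))
  tax_tree(data.frame(
    taxid = seq_len(n), parent_taxid = parent,
    rank = rep(c("family", "tribe", "genus", "species"), length.out = n),
    name = paste0("node", seq_len(n)), stringsAsFactors = FALSE
  ))
}

# Brute-force subtree sequence/node totals for the partition oracle.
brute_subtree_sums <- function(tree, counts) {
  all_ids <- tree$nodes$taxid
  sapply(all_ids, function(v) {
    sub <- c(v, descendants(tree, v))
    c(seqs = sum(counts[as.character(sub)], na.rm = TRUE),
      nodes = length(sub))
  })
}

# Brute-force connected components by repeated transitive closure over an
# adjacency matrix; the independent oracle for single-linkage clustering.
brute_components <- function(ids, edges) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(ids, ids)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      adj[edges$a[[r]], edges$b[[r]]] <- TRUE
      adj[edges$b[[r]], edges$a[[r]]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comps <- unique(lapply(seq_len(n), function(i) {
    sort(ids[adj[i, ]], method = "radix")
  }))
  first <- vapply(comps, `[[`, "", 1)
  comps[order(-lengths(comps), first, method = "radix")]
}

# A toy two-family corpus: `n_per` related sequences per family, built by
# mutating a family root at `divergence` substitutions/site per tip.
two_family_segments <- function(n_per = 5, len = 500, divergence = 0.05,
                                seed = 1) {
  set.seed(seed)
  mk_root <- function() paste(sample(c("A", "C", "G", "T"), len,
                                     replace = TRUE), collapse = "")
  mutate <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < p)
    for (i in hit) ch[[i]] <- sample(setdiff(c("A", "C", "G", "T"),
                                             ch[[i]]), 1)
    paste(ch, collapse = "")
  }
  roots <- list(mk_root(), mk_root())
  rows <- list()
  for (f in 1:2) {
    for (k in seq_len(n_per)) {
      acc <- sprintf("F%dS%02d.1", f, k)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = paste0(acc, "/0-", len), parent_accession = acc,
        taxid = 100L + k, start = 0L, end = len, strand = "+",
        residues = mutate(roots[[f]], divergence), source_kind = "whole",
        definition = sprintf("family %d member %d", f, k), length = len,
        stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, rows)
  segs[order(segs$segment_id, method = "radix"), , drop = FALSE]
}

# Build a cluster_set directly from a membership list; segments get
# constant-composition residues unless supplied.
toy_cluster_set <- function(members, taxids, lengths = NULL, tree = NULL,
                            definitions = NULL, residues = NULL) {
  all_ids <- unlist(members, use.names = FALSE)
  lengths <- lengths %||% rep(400L, length(all_ids))
  residues <- residues %||% vapply(lengths, function(n)
    paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = ""), "")
  definitions <- definitions %||% rep("synthetic segment", length(all_ids))
  segs <- data.frame(segment_id = all_ids, taxid = taxids,
                     length = lengths, definition = definitions,
                     residues = residues, stringsAsFactors = FALSE)
  clusters <- lapply(seq_along(members), function(i) {
    ids <- sort(members[[i]], method = "radix")
    orthoclust:::new_cluster(kind = "subtree", taxid = 1L,
                             segment_ids = ids, seed_id = ids[[1]],
                             cluster_id = i - 1L)
  })
  structure(list(clusters = clusters, segments = segs,
                 metadata = list(tree = tree)),
            class = "cluster_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
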