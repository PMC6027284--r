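#' Maximum alignment density (MAD) of a cluster
#'
#' Operationalized as `sum(lengths) / (n * max(lengths))`: the fraction of
#' a gapless alignment of width equal to the longest member that the
#' members would occupy. Equals 1 exactly when all lengths are equal and
#' strictly decreases as any member shrinks below the maximum. Clusters of
#' very uneven lengths (a long genomic record among short markers) score
#' low and are poor alignment candidates.
#'
#' @param lengths Positive integer vector of member sequence lengths.
#' @return A value in (0, 1].
#' @export
mad_score <- function(lengths) {
  if (length(lengths) == 0) {
    stop("mad_score: empty length vector", call. = FALSE)
  }
  stopifnot(all(lengths > 0))
  sum(lengths) / (length(lengths) * max(lengths))
}

#' GC ratio of a nucleotide sequence
#'
#' Computed over unambiguous (A/C/G/T) bases only, case-insensitively. A
#' sequence with no unambiguous base has no defined GC ratio; it is
#' reported as 0 with a `degenerate` attribute set, keeping batch
#' statistics total.
#'
#' @param residues Nonempty nucleotide string.
#' @return A fraction in \[0, 1\] (possibly with attribute `degenerate`).
#' @export
gc_ratio <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1)
  if (nchar(residues) == 0) stop("gc_ratio: empty sequence", call. = FALSE)
  s <- toupper(residues)
  counts <- base_counts(s)
  unamb <- sum(counts[c("A", "C", "G", "T")])
  if (unamb == 0) {
    return(structure(0, degenerate = TRUE))
  }
  unname(sum(counts[c("G", "C")]) / unamb)
}

#' Proportion of ambiguous nucleotides
#'
#' The fraction of residues that are not A, C, G or T (i.e., IUPAC
#' ambiguity codes such as N, R, Y), case-insensitively.
#'
#' @param residues Nonempty nucleotide string.
#' @return A fraction in \[0, 1\].
#' @export
ambiguous_prop <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1)
  n <- nchar(residues)
  if (n == 0) stop("ambiguous_prop: empty sequence", call. = FALSE)
  counts <- base_counts(toupper(residues))
  unname(1 - sum(counts[c("A", "C", "G", "T")]) / n)
}

base_counts <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  tab <- table(chars)
  for (b in names(counts)) {
    if (b %in% names(tab)) counts[[b]] <- tab[[b]]
  }
  counts
}

#' Per-cluster summary statistics
#'
#' @param cset A `cluster_set`.
#' @param tree Optional `tax_tree` (defaults to `cset$metadata$tree`);
#'   needed for the genus tally.
#' @param include_below_threshold Include clusters flagged below the
#'   reporting threshold (default `FALSE`).
#' @return Data frame with one row per cluster: `cluster_id`, `kind`,
#'   `taxid`, `n_segments`, `n_unique_taxids`, `n_genera`, `mad`,
#'   `length_min`, `length_median`, `length_max`, `gc_median`,
#'   `ambig_median`.
#' @export
cluster_stats <- function(cset, tree = NULL,
                          include_below_threshold = FALSE) {
  tree <- tree %||% cset$metadata$tree
  cls <- reported_clusters(cset, include_below_threshold)
  seg <- cset$segments
  rows <- lapply(cls, function(cl) {
    at <- match(cl$segment_ids, seg$segment_id)
    lens <- seg$length[at]
    taxids <- seg$taxid[at]
    genera <- if (!is.null(tree)) {
      g <- vapply(unique(taxids), function(t)
        ancestor_at_rank(tree, t, "genus"), integer(1))
      length(unique(g[!is.na(g)]))
    } else NA_integer_
    gcs <- vapply(seg$residues[at], function(r) as.numeric(gc_ratio(r)),
                  numeric(1), USE.NAMES = FALSE)
    ambs <- vapply(seg$residues[at], ambiguous_prop, numeric(1),
                   USE.NAMES = FALSE)
    data.frame(cluster_id = cl$cluster_id, kind = cl$kind, taxid = cl$taxid,
               n_segments = length(at), n_unique_taxids = length(unique(taxids)),
               n_genera = genera, mad = mad_score(lens),
               length_min = min(lens), length_median = stats::median(lens),
               length_max = max(lens), gc_median = stats::median(gcs),
               ambig_median = stats::median(ambs), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(cluster_id = integer(0), kind = character(0),
                      taxid = integer(0), n_segments = integer(0),
                      n_unique_taxids = integer(0), n_genera = integer(0),
                      mad = numeric(0), length_min = numeric(0),
                      length_median = numeric(0), length_max = numeric(0),
                      gc_median = numeric(0), ambig_median = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

reported_clusters <- function(cset, include_below_threshold = FALSE) {
  Filter(function(cl) {
    include_below_threshold || !isTRUE(cl$below_threshold)
  }, cset$clusters)
}

#' Select clusters by quality and informativeness predicates
#'
#' Applies the post-pipeline selection filters. A typical demonstration
#' selection keeps phylogenetically informative clusters (more than four
#' unique taxids, i.e. `min_taxa = 5`), drops clusters with MAD below
#' 0.75, and keeps the top ten by number of genus-level groups. `top_k`
#' is always applied last, with ties broken by (statistic descending,
#' cluster id ascending).
#'
#' @param cset A `cluster_set`.
#' @param min_taxa Minimum number of unique taxids.
#' @param min_mad Minimum MAD score.
#' @param max_ambig Maximum median ambiguous-nucleotide proportion.
#' @param min_len,max_len Bounds on the median member length (nt).
#' @param def_regex Keep clusters where at least one member definition
#'   matches this regular expression.
#' @param top_k Keep only the best `top_k` clusters by `top_by`.
#' @param top_by Statistic for `top_k`: a `cluster_stats` column, or
#'   `"n_rank_groups"` together with `rank`.
#' @param rank Rank used when `top_by = "n_rank_groups"` (e.g.
#'   `"genus"`, `"tribe"`).
#' @param tree Optional `tax_tree` (defaults to the one in metadata).
#' @param ... Unknown predicate names are a configuration error.
#' @return A `cluster_set` containing the surviving clusters.
#' @export
filter_clusters <- function(cset, min_taxa = NULL, min_mad = NULL,
                            max_ambig = NULL, min_len = NULL, max_len = NULL,
                            def_regex = NULL, top_k = NULL,
                            top_by = "n_unique_taxids", rank = "genus",
                            tree = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("configuration error: unknown predicate(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  tree <- tree %||% cset$metadata$tree
  stats <- cluster_stats(cset, tree)
  keep <- rep(TRUE, nrow(stats))
  if (!is.null(min_taxa)) keep <- keep & stats$n_unique_taxids >= min_taxa
  if (!is.null(min_mad)) keep <- keep & stats$mad >= min_mad
  if (!is.null(max_ambig)) keep <- keep & stats$ambig_median <= max_ambig
  if (!is.null(min_len)) keep <- keep & stats$length_median >= min_len
  if (!is.null(max_len)) keep <- keep & stats$length_median <= max_len
  if (!is.null(def_regex)) {
    seg <- cset$segments
    keep <- keep & vapply(stats$cluster_id, function(id) {
      cl <- cluster_by_id(cset, id)
      any(grepl(def_regex, seg$definition[match(cl$segment_ids,
                                                seg$segment_id)]))
    }, logical(1))
  }
  stats <- stats[keep, , drop = FALSE]
  if (!is.null(top_k) && nrow(stats) > top_k) {
    val <- if (top_by == "n_rank_groups") {
      if (is.null(tree)) {
        stop("configuration error: top_by = 'n_rank_groups' needs a taxonomy",
             call. = FALSE)
      }
      vapply(stats$cluster_id, function(id)
        n_rank_groups(cset, tree, rank, id), integer(1))
    } else {
      if (!top_by %in% colnames(stats)) {
        stop("configuration error: unknown top_by statistic '", top_by, "'",
             call. = FALSE)
      }
      stats[[top_by]]
    }
    ord <- order(-val, stats$cluster_id)
    stats <- stats[ord[seq_len(top_k)], , drop = FALSE]
  }
  subset_cluster_set(cset, stats$cluster_id)
}

n_rank_groups <- function(cset, tree, rank, cluster_id) {
  cl <- cluster_by_id(cset, cluster_id)
  taxids <- cset$segments$taxid[match(cl$segment_ids,
                                      cset$segments$segment_id)]
  g <- vapply(unique(taxids), function(t) ancestor_at_rank(tree, t, rank),
              integer(1))
  length(unique(g[!is.na(g)]))
}

subset_cluster_set <- function(cset, cluster_ids) {
  keep <- vapply(cset$clusters, function(cl)
    cl$cluster_id %in% cluster_ids, logical(1))
  out <- cset
  out$clusters <- cset$clusters[keep]
  out
}

#' Reduce clusters to representative sequences per rank group
#'
#' Within each cluster, segments are grouped by their nearest ancestor at
#' `rank`; each group keeps its best `n_per_group` segments (fewest
#' ambiguous nucleotides, then longest — or a seeded random draw with
#' `ranking = "random"`). Segments with no ancestor at the rank are
#' dropped, and clusters left empty are removed. Keeping two
#' representatives rather than one lets downstream tree checks confirm
#' that same-group sequences come out as sisters.
#'
#' @param cset A `cluster_set`.
#' @param tree A `tax_tree`.
#' @param rank Rank to reduce to (e.g. `"genus"`, `"tribe"`).
#' @param n_per_group Representatives per rank group (default 2).
#' @param rng_seed Seed for `ranking = "random"`.
#' @param ranking `"quality"` (default) or `"random"`.
#' @return A reduced `cluster_set`.
#' @export
representatives_per_rank <- function(cset, tree = NULL, rank = "genus",
                                     n_per_group = 2, rng_seed = 1,
                                     ranking = c("quality", "random")) {
  stopifnot(n_per_group >= 1)
  ranking <- match.arg(ranking)
  tree <- tree %||% cset$metadata$tree
  seg <- cset$segments
  out <- cset
  kept_clusters <- list()
  for (cl in out$clusters) {
    at <- match(cl$segment_ids, seg$segment_id)
    group <- vapply(seg$taxid[at], function(t)
      ancestor_at_rank(tree, t, rank), integer(1))
    ids <- cl$segment_ids[!is.na(group)]
    grp <- group[!is.na(group)]
    if (length(ids) == 0) {
      log_event(NULL, "representatives",
                paste0("cluster ", cl$cluster_id, " dropped: no member has ",
                       "an ancestor at rank '", rank, "'"))
      next
    }
    keep_ids <- character(0)
    for (g in sort(unique(grp))) {
      gids <- ids[grp == g]
      if (length(gids) > n_per_group) {
        if (ranking == "quality") {
          gat <- match(gids, seg$segment_id)
          amb <- vapply(seg$residues[gat], ambiguous_prop, numeric(1),
                        USE.NAMES = FALSE)
          ord <- order_c(amb, -seg$length[gat], gids)
          gids <- gids[ord[seq_len(n_per_group)]]
        } else {
          gids <- with_seed(rng_seed + g, sort_c(sample(gids, n_per_group)))
        }
      }
      keep_ids <- c(keep_ids, gids)
    }
    cl$segment_ids <- sort_c(keep_ids)
    if (!cl$seed_id %in% cl$segment_ids) cl$seed_id <- cl$segment_ids[[1]]
    kept_clusters[[length(kept_clusters) + 1L]] <- cl
  }
  out$clusters <- kept_clusters
  out
}

#' Presence/absence matrix of rank groups across clusters
#'
#' @param cset A `cluster_set`.
#' @param tree A `tax_tree`.
#' @param rank Grouping rank (e.g. `"tribe"`, `"genus"`).
#' @return Binary matrix, rows = rank groups (named by taxon, ordered by
#'   taxid), columns = cluster ids (ascending); cell 1 when the cluster
#'   holds at least one segment from the group.
#' @export
presence_absence <- function(cset, tree = NULL, rank = "genus") {
  tree <- tree %||% cset$metadata$tree
  cls <- cset$clusters
  if (length(cls) == 0) {
    return(matrix(0L, nrow = 0, ncol = 0))
  }
  seg <- cset$segments
  groups_per_cluster <- lapply(cls, function(cl) {
    taxids <- unique(seg$taxid[match(cl$segment_ids, seg$segment_id)])
    g <- vapply(taxids, function(t) ancestor_at_rank(tree, t, rank),
                integer(1))
    unique(g[!is.na(g)])
  })
  all_groups <- sort(unique(unlist(groups_per_cluster)))
  ids <- vapply(cls, `[[`, 0L, "cluster_id")
  ord <- order(ids)
  m <- matrix(0L, nrow = length(all_groups), ncol = length(cls),
              dimnames = list(taxon_name(tree, all_groups),
                              as.character(ids[ord])))
  for (k in seq_along(ord)) {
    g <- groups_per_cluster[[ord[[k]]]]
    m[match(g, all_groups), k] <- 1L
  }
  m
}

#' Export a cluster set as PhyLoTa-style tables and FASTA files
#'
#' Writes three tab-separated tables — `clusters.tsv` (cluster id, kind,
#' owning taxid, sizes, seed, MAD), `cluster_seqs.tsv` (cluster-to-segment
#' membership with lengths and definitions) and `taxa.tsv` (the taxonomy
#' slice) — plus one wrapped FASTA file per cluster
#' (`cluster_<id>.fasta`, headers `><segment_id> taxid=<taxid>
#' def=<definition>`). All writes are atomic (temp file then rename).
#'
#' @param cset A `cluster_set`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "fasta")`.
#' @param tree Optional `tax_tree` for `taxa.tsv` (defaults to metadata).
#' @param include_below_threshold Export below-threshold clusters too.
#' @return Invisibly, the paths written.
#' @export
export_clusters <- function(cset, out_dir, formats = c("tsv", "fasta"),
                            tree = NULL, include_below_threshold = FALSE) {
  tree <- tree %||% cset$metadata$tree
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  cls <- reported_clusters(cset, include_below_threshold)
  seg <- cset$segments
  paths <- character(0)
  if ("tsv" %in% formats) {
    stats_rows <- lapply(cls, function(cl) {
      at <- match(cl$segment_ids, seg$segment_id)
      data.frame(cluster_id = cl$cluster_id, kind = cl$kind,
                 taxid = cl$taxid, n_seqs = length(at),
                 n_taxa = length(unique(seg$taxid[at])),
                 seed_id = cl$seed_id,
                 mad = mad_score(seg$length[at]), stringsAsFactors = FALSE)
    })
    clusters_tab <- if (length(stats_rows) > 0) do.call(rbind, stats_rows) else
      data.frame(cluster_id = integer(0), kind = character(0),
                 taxid = integer(0), n_seqs = integer(0), n_taxa = integer(0),
                 seed_id = character(0), mad = numeric(0))
    seq_rows <- lapply(cls, function(cl) {
      at <- match(cl$segment_ids, seg$segment_id)
      data.frame(cluster_id = cl$cluster_id, segment_id = cl$segment_ids,
                 taxid = seg$taxid[at], length = seg$length[at],
                 definition = seg$definition[at], stringsAsFactors = FALSE)
    })
    seqs_tab <- if (length(seq_rows) > 0) do.call(rbind, seq_rows) else
      data.frame(cluster_id = integer(0), segment_id = character(0),
                 taxid = integer(0), length = integer(0),
                 definition = character(0))
    taxa_tab <- if (!is.null(tree)) {
      data.frame(taxid = tree$nodes$taxid, parent = tree$nodes$parent_taxid,
                 rank = tree$nodes$rank, name = tree$nodes$name,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(taxid = sort(unique(seg$taxid)), parent = NA_integer_,
                 rank = "", name = "", stringsAsFactors = FALSE)
    }
    p1 <- file.path(out_dir, "clusters.tsv")
    p2 <- file.path(out_dir, "cluster_seqs.tsv")
    p3 <- file.path(out_dir, "taxa.tsv")
    write_tsv_atomic(clusters_tab, p1)
    write_tsv_atomic(seqs_tab, p2)
    write_tsv_atomic(taxa_tab, p3)
    paths <- c(paths, p1, p2, p3)
  }
  if ("fasta" %in% formats) {
    for (cl in cls) {
      at <- match(cl$segment_ids, seg$segment_id)
      p <- file.path(out_dir, paste0("cluster_", cl$cluster_id, ".fasta"))
      write_fasta_atomic(
        paste0(cl$segment_ids, " taxid=", seg$taxid[at],
               " def=", seg$definition[at]),
        seg$residues[at], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Re-import an exported cluster set
#'
#' Rebuilds a `cluster_set` from the tables and FASTA files written by
#' [export_clusters()] (run metadata is not round-tripped).
#'
#' @param dir Directory holding the export.
#' @return A `cluster_set`.
#' @export
import_clusters <- function(dir) {
  clusters_tab <- read_tsv_plain(file.path(dir, "clusters.tsv"))
  seqs_tab <- read_tsv_plain(file.path(dir, "cluster_seqs.tsv"))
  residues <- character(0)
  for (id in clusters_tab$cluster_id) {
    fa <- file.path(dir, paste0("cluster_", id, ".fasta"))
    if (!file.exists(fa)) next
    dna <- Biostrings::readDNAStringSet(fa)
    ids <- vapply(strsplit(names(dna), "[[:space:]]+"), `[[`, "", 1)
    residues[ids] <- as.character(dna)
  }
  segments <- unique(seqs_tab[, c("segment_id", "taxid", "length",
                                  "definition")])
  segments$residues <- unname(residues[segments$segment_id])
  segments$residues[is.na(segments$residues)] <- ""
  segments <- segments[order_c(segments$segment_id), , drop = FALSE]
  rownames(segments) <- NULL
  clusters <- lapply(seq_len(nrow(clusters_tab)), function(i) {
    row <- clusters_tab[i, ]
    members <- sort_c(seqs_tab$segment_id[seqs_tab$cluster_id ==
                                            row$cluster_id])
    new_cluster(kind = row$kind, taxid = row$taxid, segment_ids = members,
                seed_id = row$seed_id, cluster_id = as.integer(row$cluster_id))
  })
  structure(list(clusters = clusters, segments = segments,
                 metadata = list()), class = "cluster_set")
}
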