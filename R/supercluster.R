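#' Merge clusters across clade units by seed-vs-seed search
#'
#' Each cluster is represented by its seed (most connected) sequence
#' only; an all-vs-all search over the seeds is run, hits are filtered
#' with the same thresholds as the within-unit stage, and a passing hit
#' between the seeds of two different clusters draws an edge between the
#' clusters. Connected components of two or more clusters become new
#' clusters of kind `"merged"` whose membership is the exact union of
#' their parents; parents are retained, flagged with the id of the merged
#' cluster they joined. All other clusters pass through unchanged, so
#' merged and non-merged clusters are reported together.
#'
#' Only subtree, paraphyletic and previously merged clusters participate;
#' direct clusters are restrictions of subtree clusters and would merge
#' trivially with their parents. Clusters already absorbed into a merged
#' cluster are skipped, which makes a second merge pass a no-op when seed
#' relations are unchanged. The merged cluster's seed is the parent seed
#' with the highest degree among the seed-level edges (ties as in
#' [seed_of()]); its owning taxon is the most recent common ancestor of
#' the parents when a taxonomy is available, else the smallest parent
#' taxid.
#'
#' @param cset A `cluster_set` from the cluster stage.
#' @param params A [search_params()] object.
#' @param backend A search backend.
#' @param tree Optional `tax_tree` for MRCA computation (taken from
#'   `cset$metadata$tree` when present).
#' @param fixpoint If `TRUE`, repeat merging until no new merged cluster
#'   appears (off by default: one round matches the pipeline design).
#' @return A `cluster_set` with merged clusters appended and a
#'   `merge_log` entry in its metadata.
#' @export
merge_clusters <- function(cset, params = search_params(),
                           backend = builtin_backend(), tree = NULL,
                           fixpoint = FALSE) {
  stopifnot(inherits(cset, "cluster_set"))
  tree <- tree %||% cset$metadata$tree
  repeat {
    before <- length(cset$clusters)
    cset <- merge_round(cset, params, backend, tree)
    if (!fixpoint || length(cset$clusters) == before) break
  }
  cset
}

merge_round <- function(cset, params, backend, tree) {
  eligible <- Filter(function(cl) {
    cl$kind %in% c("subtree", "paraphyletic", "merged") &&
      is.na(cl$merged_into)
  }, cset$clusters)
  if (length(eligible) < 2) {
    cset$metadata$merge_log <- c(cset$metadata$merge_log, list(list(
      groups = list(), n_candidates = length(eligible))))
    return(cset)
  }
  seed_ids <- vapply(eligible, `[[`, "", "seed_id")
  owner <- vapply(eligible, `[[`, 0L, "cluster_id")
  seg <- cset$segments
  seed_segs <- seg[match(unique(seed_ids), seg$segment_id), , drop = FALSE]
  seed_segs$segment_id <- seed_segs$segment_id # keep original ids
  hits <- if (nrow(seed_segs) >= 2) {
    filter_hits(all_vs_all(seed_segs, params, backend), params)
  } else empty_hits()
  edges <- symmetrize_edges(hits)

  # seed-segment edges -> cluster-id edges (a seed may represent several
  # clusters; all owner pairs are connected)
  owners_of <- split(owner, seed_ids)
  cl_edges <- list()
  add_edge <- function(x, y) {
    cl_edges[[length(cl_edges) + 1L]] <<- c(min(x, y), max(x, y))
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      for (x in owners_of[[edges$a[[r]]]]) {
        for (y in owners_of[[edges$b[[r]]]]) if (x != y) add_edge(x, y)
      }
    }
  }
  for (os in owners_of) { # shared seed implies relation
    if (length(os) > 1) {
      for (x in os[-1]) add_edge(os[[1]], x)
    }
  }
  cl_edge_df <- if (length(cl_edges) > 0) {
    m <- unique(do.call(rbind, cl_edges))
    data.frame(a = as.character(m[, 1]), b = as.character(m[, 2]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
  }
  comps <- connected_clusters(as.character(owner), cl_edge_df)
  groups <- Filter(function(g) length(g) >= 2, comps)
  # deterministic group order by smallest parent id
  groups <- groups[order_c(vapply(groups, function(g)
    min(as.integer(g)), 0L))]

  next_id <- if (length(cset$clusters) > 0) {
    max(vapply(cset$clusters, `[[`, 0L, "cluster_id")) + 1L
  } else 0L
  seg_lens <- stats::setNames(seg$length, seg$segment_id)
  merged_list <- list()
  for (g in groups) {
    gids <- sort(as.integer(g))
    parents <- lapply(gids, function(id) cluster_by_id(cset, id))
    members <- sort_c(unique(unlist(lapply(parents, `[[`, "segment_ids"))))
    parent_seeds <- sort_c(unique(vapply(parents, `[[`, "", "seed_id")))
    seed <- seed_of(parent_seeds, edges, seg_lens)
    taxids <- vapply(parents, `[[`, 0L, "taxid")
    own_tax <- if (!is.null(tree)) mrca(tree, taxids) else min(taxids)
    mc <- new_cluster(kind = "merged", taxid = own_tax,
                      segment_ids = members, seed_id = seed,
                      parent_cluster_ids = gids,
                      below_threshold = length(members) < 3,
                      cluster_id = next_id)
    merged_list[[length(merged_list) + 1L]] <- mc
    for (i in seq_along(cset$clusters)) {
      if (cset$clusters[[i]]$cluster_id %in% gids) {
        cset$clusters[[i]]$merged_into <- next_id
      }
    }
    next_id <- next_id + 1L
  }
  cset$clusters <- c(cset$clusters, merged_list)
  cset$metadata$merge_log <- c(cset$metadata$merge_log, list(list(
    groups = groups, n_candidates = length(eligible))))
  cset
}
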