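#' Single-linkage clusters as connected components
#'
#' Clusters are the connected components of the undirected, filtered hit
#' graph (single linkage: one passing hit suffices to join two segments).
#' Implemented with a union-find structure. Singletons are included.
#' Output is fully deterministic: components ordered by size (descending)
#' then smallest member id, members in lexicographic order.
#'
#' @param segment_ids Character vector of all segment ids in scope.
#' @param edges Data frame with columns `a`, `b` naming undirected edges
#'   (see [symmetrize_edges()]).
#' @return List of character vectors (one per component).
#' @export
connected_clusters <- function(segment_ids, edges) {
  segment_ids <- as.character(segment_ids)
  n <- length(segment_ids)
  if (n == 0) return(list())
  idx <- stats::setNames(seq_len(n), segment_ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]] # path halving
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0) {
    ai <- idx[as.character(edges$a)]
    bi <- idx[as.character(edges$b)]
    if (anyNA(ai) || anyNA(bi)) {
      bad <- c(edges$a[is.na(ai)], edges$b[is.na(bi)])[1]
      stop("structural error: edge names unknown segment '", bad, "'",
           call. = FALSE)
    }
    for (e in seq_along(ai)) {
      ra <- find(ai[[e]]); rb <- find(bi[[e]])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(segment_ids, roots)
  comps <- lapply(comps, sort_c)
  first <- vapply(comps, `[[`, "", 1)
  comps <- comps[order_c(-lengths(comps), first)]
  names(comps) <- NULL
  comps
}

#' Seed sequence of a component
#'
#' The seed is the most connected member of the component's hit graph:
#' highest degree, ties broken by greater summed bitscore of incident
#' edges, then by longer segment, then by lexicographically smaller id.
#'
#' @param component Character vector of member segment ids (nonempty).
#' @param edges Edge data frame (`a`, `b`, optional `bitscore`).
#' @param lengths Optional named vector of segment lengths for the length
#'   tie-break.
#' @return A single segment id.
#' @export
seed_of <- function(component, edges, lengths = NULL) {
  stopifnot(length(component) > 0)
  if (length(component) == 1) return(component[[1]])
  inside <- edges$a %in% component & edges$b %in% component
  e <- edges[inside, , drop = FALSE]
  if (is.null(e$bitscore)) e$bitscore <- rep(0, nrow(e))
  deg <- stats::setNames(numeric(length(component)), component)
  bs <- deg
  for (v in c(e$a, e$b)) deg[[v]] <- deg[[v]] + 1
  if (nrow(e) > 0) {
    for (r in seq_len(nrow(e))) {
      bs[[e$a[[r]]]] <- bs[[e$a[[r]]]] + e$bitscore[[r]]
      bs[[e$b[[r]]]] <- bs[[e$b[[r]]]] + e$bitscore[[r]]
    }
  }
  len <- if (is.null(lengths)) stats::setNames(numeric(length(component)),
                                               component)
         else lengths[component]
  ord <- order_c(-deg, -bs, -as.numeric(len), component)
  component[[ord[[1]]]]
}

#' Cluster the segments of one clade unit
#'
#' Builds single-linkage clusters from the unit's filtered hits. For a
#' subtree unit the resulting clusters have kind `"subtree"`, and in
#' addition, for every taxid holding segments inside the unit, each
#' subtree cluster's members restricted to that taxid are recorded as a
#' `"direct"` cluster (same edge evidence, no extra search). Paraphyletic
#' units yield `"paraphyletic"` clusters only. Components smaller than
#' `min_cluster_seqs` are retained but flagged `below_threshold` so that
#' default reporting can exclude them without losing auditability.
#'
#' @param unit A `clade_unit` from [partition_clades()].
#' @param segments Segment data frame restricted to the unit's taxa.
#' @param hits Filtered directed hits among those segments.
#' @param min_cluster_seqs Reporting threshold (default 3).
#' @return List of cluster objects (fields `cluster_id` — unset here —,
#'   `kind`, `taxid`, `segment_ids`, `seed_id`, `parent_cluster_ids`,
#'   `below_threshold`).
#' @export
cluster_unit <- function(unit, segments, hits, min_cluster_seqs = 3) {
  stopifnot(all(segments$taxid %in% unit$member_taxids))
  edges <- symmetrize_edges(hits)
  comps <- connected_clusters(segments$segment_id, edges)
  lens <- stats::setNames(segments$length, segments$segment_id)
  taxid_of <- stats::setNames(segments$taxid, segments$segment_id)
  primary_kind <- if (unit$kind == "subtree") "subtree" else "paraphyletic"
  clusters <- lapply(comps, function(cp) {
    new_cluster(kind = primary_kind, taxid = unit$taxid, segment_ids = cp,
                seed_id = seed_of(cp, edges, lens),
                below_threshold = length(cp) < min_cluster_seqs)
  })
  if (unit$kind == "subtree") {
    for (t in sort_c(unique(segments$taxid))) {
      own <- names(taxid_of)[taxid_of == t]
      for (cp in comps) {
        sub <- sort_c(intersect(cp, own))
        if (length(sub) == 0) next
        clusters[[length(clusters) + 1L]] <- new_cluster(
          kind = "direct", taxid = t, segment_ids = sub,
          seed_id = seed_of(sub, edges, lens),
          below_threshold = length(sub) < min_cluster_seqs)
      }
    }
  }
  clusters
}

new_cluster <- function(kind, taxid, segment_ids, seed_id,
                        parent_cluster_ids = integer(0),
                        below_threshold = FALSE, cluster_id = NA_integer_) {
  stopifnot(length(segment_ids) > 0, seed_id %in% segment_ids)
  structure(list(cluster_id = cluster_id, kind = kind,
                 taxid = as.integer(taxid), segment_ids = segment_ids,
                 seed_id = seed_id, parent_cluster_ids = parent_cluster_ids,
                 below_threshold = below_threshold,
                 merged_into = NA_integer_),
            class = "ortho_cluster")
}

#' @export
print.ortho_cluster <- function(x, ...) {
  cat("<cluster ", x$cluster_id, "> ", x$kind, " @taxid ", x$taxid, ": ",
      length(x$segment_ids), " segments, seed ", x$seed_id,
      if (isTRUE(x$below_threshold)) " [below threshold]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Assemble clusters from all units into a cluster set
#'
#' Assigns run-unique integer ids (units in ascending owning-taxid order,
#' primary clusters before direct clusters, in the deterministic order
#' produced by [cluster_unit()]) and attaches the segment index and run
#' metadata.
#'
#' @param unit_clusters List of cluster lists, one per clade unit.
#' @param segments Segment data frame for the whole run.
#' @param metadata Named list of run provenance (root taxid, parameters,
#'   timestamps); stored as-is.
#' @return A `cluster_set`.
#' @export
cluster_set <- function(unit_clusters, segments, metadata = list()) {
  clusters <- unlist(unit_clusters, recursive = FALSE)
  if (length(clusters) > 0) {
    for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i - 1L
  }
  seg_index <- segments[, c("segment_id", "taxid", "length", "definition",
                            "residues")]
  structure(list(clusters = clusters, segments = seg_index,
                 metadata = metadata),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  kinds <- vapply(x$clusters, `[[`, "", "kind")
  cat("<cluster_set> ", length(x$clusters), " clusters (",
      paste(names(table(kinds)), as.integer(table(kinds)),
            sep = ":", collapse = ", "),
      "), ", nrow(x$segments), " indexed segments\n", sep = "")
  invisible(x)
}

cluster_by_id <- function(cset, id) {
  ids <- vapply(cset$clusters, `[[`, 0L, "cluster_id")
  cset$clusters[[which(ids == id)]]
}
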