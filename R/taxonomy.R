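#' Load an NCBI-taxdump-style taxonomy
#'
#' Parses `nodes.dmp` / `names.dmp` in the NCBI taxdump dialect (fields
#' separated by `"\t|\t"`, lines terminated by `"\t|"`). Only the columns
#' the pipeline needs are used: taxid, parent taxid and rank from
#' `nodes.dmp`; taxid, name and name class from `names.dmp`. Both
#' `"scientific name"` and `"synonym"` entries are retained so that either
#' can be resolved, with scientific names preferred.
#'
#' @param nodes_path Path to a `nodes.dmp`-dialect file.
#' @param names_path Path to a `names.dmp`-dialect file.
#' @return A `tax_tree` object: a rooted, rank-annotated taxonomy with
#'   parent pointers and a name table.
#' @examples
#' paths <- system.file(package = "orthoclust") # see vignette for a worked run
#' @export
load_taxdump <- function(nodes_path, names_path) {
  nodes_raw <- parse_dmp(nodes_path, min_fields = 3)
  names_raw <- parse_dmp(names_path, min_fields = 4)
  nodes <- data.frame(
    taxid = as.integer(vapply(nodes_raw, `[[`, "", 1)),
    parent_taxid = as.integer(vapply(nodes_raw, `[[`, "", 2)),
    rank = vapply(nodes_raw, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  if (anyNA(nodes$taxid) || anyNA(nodes$parent_taxid)) {
    bad <- which(is.na(nodes$taxid) | is.na(nodes$parent_taxid))[1]
    stop("parse error in ", nodes_path, " line ", bad,
         ": non-integer taxid", call. = FALSE)
  }
  name_tab <- data.frame(
    taxid = as.integer(vapply(names_raw, `[[`, "", 1)),
    name = vapply(names_raw, `[[`, "", 2),
    class = vapply(names_raw, `[[`, "", 4),
    stringsAsFactors = FALSE
  )
  sci <- name_tab[name_tab$class == "scientific name", ]
  sci_name <- sci$name[match(nodes$taxid, sci$taxid)]
  nodes$name <- ifelse(is.na(sci_name), "", sci_name)
  tax_tree(nodes, name_tab)
}

# Split one taxdump-dialect file into per-line field lists.
parse_dmp <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  # strip the "\t|" line terminator, then split on "\t|\t"
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < min_fields)) {
    bad <- which(n_fields < min_fields)[1]
    stop("parse error in ", path, " line ", bad, ": expected at least ",
         min_fields, " fields, found ", n_fields[bad], call. = FALSE)
  }
  fields
}

#' Construct a taxonomy tree from node and name tables
#'
#' @param nodes A data frame with columns `taxid`, `parent_taxid`, `rank`
#'   and optionally `name` (scientific name).
#' @param name_tab Optional long-format name table with columns `taxid`,
#'   `name`, `class`; defaults to the scientific names in `nodes`.
#' @return A `tax_tree` object.
#' @export
tax_tree <- function(nodes, name_tab = NULL) {
  stopifnot(all(c("taxid", "parent_taxid", "rank") %in% colnames(nodes)))
  if (is.null(nodes$name)) nodes$name <- ""
  if (anyDuplicated(nodes$taxid)) {
    stop("structural error: duplicated taxid ",
         nodes$taxid[duplicated(nodes$taxid)][1], call. = FALSE)
  }
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1) {
    stop("structural error: expected exactly one self-parent root, found ",
         length(root), call. = FALSE)
  }
  dangling <- setdiff(nodes$parent_taxid, nodes$taxid)
  if (length(dangling) > 0) {
    stop("structural error: parent taxid ", dangling[1],
         " not present in node table", call. = FALSE)
  }
  nodes <- nodes[order_c(nodes$taxid), , drop = FALSE]
  rownames(nodes) <- NULL
  # children index, each child vector sorted ascending for determinism
  non_root <- nodes$taxid != root
  children <- split(nodes$taxid[non_root], nodes$parent_taxid[non_root])
  children <- lapply(children, sort_c)
  tree <- structure(
    list(nodes = nodes, root = root, children = children,
         name_tab = if (is.null(name_tab)) {
           data.frame(taxid = nodes$taxid, name = nodes$name,
                      class = "scientific name", stringsAsFactors = FALSE)
         } else name_tab),
    class = "tax_tree"
  )
  check_acyclic(tree)
  tree
}

check_acyclic <- function(tree) {
  # every node must reach the root; a cycle leaves nodes unvisited
  seen <- descendants(tree, tree$root)
  n_reached <- length(seen) + 1L
  if (n_reached != nrow(tree$nodes)) {
    stop("structural error: ", nrow(tree$nodes) - n_reached,
         " node(s) unreachable from root (cycle or disconnected subtree)",
         call. = FALSE)
  }
  invisible(tree)
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("<tax_tree> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      " (", taxon_name(x, x$root), ")\n", sep = "")
  invisible(x)
}

tax_index <- function(tree, taxids) {
  idx <- match(taxids, tree$nodes$taxid)
  if (anyNA(idx)) {
    stop("taxid not found: ", taxids[is.na(idx)][1], call. = FALSE)
  }
  idx
}

taxon_name <- function(tree, taxids) {
  tree$nodes$name[tax_index(tree, taxids)]
}

taxon_rank <- function(tree, taxids) {
  tree$nodes$rank[tax_index(tree, taxids)]
}

taxon_parent <- function(tree, taxids) {
  tree$nodes$parent_taxid[tax_index(tree, taxids)]
}

#' Resolve a taxon name or id to a taxid
#'
#' Name matching is case-insensitive and exact. Scientific names are
#' preferred over synonyms; a name attached to more than one node at the
#' preferred class is a homonym and raises an error listing the candidate
#' taxids rather than silently picking one.
#'
#' @param tree A `tax_tree`.
#' @param query A taxon name (character) or taxid (integer).
#' @return A single taxid.
#' @export
resolve_taxon <- function(tree, query) {
  if (is.numeric(query)) {
    taxid <- as.integer(query)
    tax_index(tree, taxid) # errors if absent
    return(taxid)
  }
  stopifnot(is.character(query), length(query) == 1)
  tab <- tree$name_tab
  hit <- tab[tolower(tab$name) == tolower(query), , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("taxon name not found: '", query, "'", call. = FALSE)
  }
  sci <- hit[hit$class == "scientific name", , drop = FALSE]
  use <- if (nrow(sci) > 0) sci else hit
  ids <- sort_c(unique(use$taxid))
  if (length(ids) > 1) {
    stop("ambiguous taxon name '", query, "': candidate taxids ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Enumerate all strict descendants of a taxon
#'
#' Returns a preorder (depth-first, children visited in ascending taxid
#' order) list of every taxid below `taxid`, excluding `taxid` itself.
#' The order is fully deterministic.
#'
#' @param tree A `tax_tree`.
#' @param taxid Taxid whose subtree to enumerate.
#' @return Integer vector of descendant taxids (empty for a leaf).
#' @export
descendants <- function(tree, taxid) {
  tax_index(tree, taxid)
  out <- integer(0)
  stack <- rev(tree$children[[as.character(taxid)]] %||% integer(0))
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out[[length(out) + 1L]] <- v
    kids <- tree$children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, rev(kids))
  }
  out
}

#' Nearest ancestor (including self) at a given rank
#'
#' Walks from `taxid` toward the root and returns the first node whose
#' rank equals `rank`, or `NA` if no ancestor carries that rank.
#'
#' @param tree A `tax_tree`.
#' @param taxid Starting taxid.
#' @param rank Rank string, e.g. `"genus"`.
#' @return A taxid, or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  v <- taxid
  tax_index(tree, v)
  repeat {
    if (taxon_rank(tree, v) == rank) return(v)
    p <- taxon_parent(tree, v)
    if (p == v) return(NA_integer_)
    v <- p
  }
}

# Most recent common ancestor of a set of taxids.
mrca <- function(tree, taxids) {
  stopifnot(length(taxids) >= 1)
  path_to_root <- function(v) {
    path <- v
    repeat {
      p <- taxon_parent(tree, v)
      if (p == v) break
      path <- c(path, p)
      v <- p
    }
    path
  }
  common <- path_to_root(taxids[[1]])
  for (t in taxids[-1]) {
    common <- common[common %in% path_to_root(t)]
  }
  common[[1]]
}

#' Partition a taxonomy into clade work units
#'
#' Recursively descends from the root: a node whose whole subtree holds no
#' more than `max_seqs` sequences and `max_nodes` taxonomy nodes becomes a
#' single subtree work unit; larger subtrees are split into their children.
#' When a node is split, its directly-assigned sequences — together with
#' any child subtrees too small to stand alone (fewer than `min_unit_seqs`
#' sequences) — are pooled into one paraphyletic unit owned by the split
#' node, so that no sequence is dropped. Every sequence-bearing taxid ends
#' up in exactly one unit.
#'
#' A single node whose direct count alone exceeds `max_seqs` cannot be
#' split further; it is emitted as a unit with a warning.
#'
#' @param tree A `tax_tree`.
#' @param seq_counts Named integer vector: direct (node-assigned) sequence
#'   tallies, names are taxids. Taxids absent from the vector count as 0.
#' @param max_seqs Maximum sequences per unit (default 50000).
#' @param max_nodes Maximum taxonomy nodes per unit (default 100000).
#' @param min_unit_seqs Minimum sequences for a clade to stand alone
#'   (default 3); smaller clades are pooled paraphyletically.
#' @return List of `clade_unit` objects, each with fields `taxid`,
#'   `member_taxids`, `kind` (`"subtree"` or `"paraphyletic"`) and
#'   `n_seqs`.
#' @export
partition_clades <- function(tree, seq_counts, max_seqs = 50000,
                             max_nodes = 100000, min_unit_seqs = 3) {
  stopifnot(max_seqs > 0, max_nodes > 0, min_unit_seqs >= 1)
  counts <- direct_counts(tree, seq_counts)
  sums <- subtree_sums(tree, counts)
  units <- list()
  emit <- function(u) units[[length(units) + 1L]] <<- u

  make_unit <- function(taxid, members, kind, n) {
    structure(list(taxid = taxid, member_taxids = members, kind = kind,
                   n_seqs = n), class = "clade_unit")
  }

  recurse <- function(v) {
    key <- as.character(v)
    if (sums$seqs[[key]] == 0) return(invisible(NULL))
    if (sums$seqs[[key]] <= max_seqs && sums$nodes[[key]] <= max_nodes) {
      emit(make_unit(v, c(v, descendants(tree, v)), "subtree",
                     sums$seqs[[key]]))
      return(invisible(NULL))
    }
    kids <- tree$children[[key]] %||% integer(0)
    if (length(kids) == 0) {
      warning("taxid ", v, " holds ", sums$seqs[[key]],
              " sequences, above max_seqs = ", max_seqs,
              " and cannot be split further", call. = FALSE)
      emit(make_unit(v, v, "subtree", sums$seqs[[key]]))
      return(invisible(NULL))
    }
    # pool: the split node's own sequences + too-small child subtrees
    pool_taxids <- if (counts[[key]] > 0) v else integer(0)
    pool_n <- counts[[key]]
    for (k in kids) {
      ks <- as.character(k)
      n_k <- sums$seqs[[ks]]
      if (n_k == 0) next
      if (n_k < min_unit_seqs) {
        pool_taxids <- c(pool_taxids, k, descendants(tree, k))
        pool_n <- pool_n + n_k
      } else {
        recurse(k)
      }
    }
    if (pool_n > 0) {
      for (u in chunk_pool(tree, v, pool_taxids, counts, max_seqs)) emit(u)
    }
    invisible(NULL)
  }

  recurse(tree$root)
  units
}

# Split a paraphyletic pool into units each within max_seqs where possible;
# a single taxid above max_seqs is emitted alone with a warning.
chunk_pool <- function(tree, owner, pool_taxids, counts, max_seqs) {
  pool_taxids <- sort_c(unique(pool_taxids))
  n_each <- counts[as.character(pool_taxids)]
  total <- sum(n_each)
  if (total <= max_seqs) {
    return(list(structure(
      list(taxid = owner, member_taxids = pool_taxids, kind = "paraphyletic",
           n_seqs = total), class = "clade_unit")))
  }
  units <- list()
  cur <- integer(0)
  cur_n <- 0
  flush <- function() {
    if (length(cur) > 0) {
      units[[length(units) + 1L]] <<- structure(
        list(taxid = owner, member_taxids = cur, kind = "paraphyletic",
             n_seqs = cur_n), class = "clade_unit")
    }
    cur <<- integer(0); cur_n <<- 0
  }
  for (i in seq_along(pool_taxids)) {
    if (n_each[[i]] > max_seqs) {
      flush()
      warning("taxid ", pool_taxids[[i]], " holds ", n_each[[i]],
              " sequences, above max_seqs = ", max_seqs, call. = FALSE)
      cur <- pool_taxids[[i]]; cur_n <- n_each[[i]]
      flush()
    } else if (cur_n + n_each[[i]] > max_seqs) {
      flush()
      cur <- pool_taxids[[i]]; cur_n <- n_each[[i]]
    } else {
      cur <- c(cur, pool_taxids[[i]]); cur_n <- cur_n + n_each[[i]]
    }
  }
  flush()
  units
}

direct_counts <- function(tree, seq_counts) {
  counts <- stats::setNames(integer(nrow(tree$nodes)),
                            as.character(tree$nodes$taxid))
  if (length(seq_counts) > 0) {
    if (is.null(names(seq_counts))) {
      stop("seq_counts must be a named vector (names are taxids)",
           call. = FALSE)
    }
    ids <- as.integer(names(seq_counts))
    tax_index(tree, ids)
    counts[names(seq_counts)] <- as.integer(seq_counts)
  }
  counts
}

# Per-node subtree totals (sequence counts and node counts) in one
# bottom-up pass over the preorder.
subtree_sums <- function(tree, counts) {
  ord <- c(tree$root, descendants(tree, tree$root)) # preorder
  seqs <- counts[as.character(ord)]
  nodes <- stats::setNames(rep(1L, length(ord)), as.character(ord))
  parents <- taxon_parent(tree, ord)
  for (i in rev(seq_along(ord))) {
    v <- ord[[i]]; p <- parents[[i]]
    if (p != v) {
      seqs[[as.character(p)]] <- seqs[[as.character(p)]] + seqs[[as.character(v)]]
      nodes[[as.character(p)]] <- nodes[[as.character(p)]] + nodes[[as.character(v)]]
    }
  }
  list(seqs = seqs, nodes = nodes)
}

#' @export
print.clade_unit <- function(x, ...) {
  cat("<clade_unit> ", x$kind, " unit at taxid ", x$taxid, ": ",
      length(x$member_taxids), " taxa, ", x$n_seqs, " sequences\n", sep = "")
  invisible(x)
}
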