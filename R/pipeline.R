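PIPELINE_STAGES <- c("taxise", "download", "cluster", "cluster2")

#' Run configuration
#'
#' Collects every parameter of a pipeline run. The effective configuration
#' is persisted as YAML in the working directory so a halted run can be
#' restarted with identical settings, and every parameter is logged before
#' the first stage that uses it.
#'
#' @param root_taxon Taxon name or taxid at which to root the run.
#' @param wd Working directory for caches, logs and results.
#' @param nodes_path,names_path Taxdump-dialect taxonomy files.
#' @param records_path Record corpus: annotated FASTA (`.fasta`/`.fa`) or
#'   GenBank flat file (`.gb`/`.gbk`/`.genbank`).
#' @param stages Stages to run, in pipeline order; any prefix or single
#'   stage of taxise, download, cluster, cluster2.
#' @param backend `"builtin"` or `"blast"`.
#' @param min_len,max_len Sequence length window (nt); defaults 250/3000.
#' @param max_seqs,max_nodes Clade-unit limits; defaults 50000/100000.
#' @param min_unit_seqs Minimum sequences for a clade to stand alone.
#' @param min_cluster_seqs Cluster reporting threshold.
#' @param cap Per-taxon segment cap (model-organism subsampling).
#' @param evalue_max,coverage_min,identity_min,word_size Search thresholds
#'   (see [search_params()]).
#' @param seed Run RNG seed; all stochastic steps derive from it.
#' @param retries Record-source retry count.
#' @return A `run_config` object.
#' @export
run_config <- function(root_taxon, wd, nodes_path, names_path, records_path,
                       stages = PIPELINE_STAGES, backend = "builtin",
                       min_len = 250, max_len = 3000,
                       max_seqs = 50000, max_nodes = 100000,
                       min_unit_seqs = 3, min_cluster_seqs = 3, cap = 100,
                       evalue_max = 1e-10, coverage_min = 0.5,
                       identity_min = 0, word_size = 11,
                       seed = 1, retries = 3) {
  stages <- match_stages(stages)
  if (!backend %in% c("builtin", "blast")) {
    stop("config error: backend must be 'builtin' or 'blast'", call. = FALSE)
  }
  cfg <- list(root_taxon = root_taxon, wd = wd, nodes_path = nodes_path,
              names_path = names_path, records_path = records_path,
              stages = stages, backend = backend,
              min_len = min_len, max_len = max_len, max_seqs = max_seqs,
              max_nodes = max_nodes, min_unit_seqs = min_unit_seqs,
              min_cluster_seqs = min_cluster_seqs, cap = cap,
              evalue_max = evalue_max, coverage_min = coverage_min,
              identity_min = identity_min, word_size = word_size,
              seed = seed, retries = retries)
  structure(cfg, class = "run_config")
}

match_stages <- function(stages) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
}

cfg_params <- function(cfg) {
  search_params(cfg$evalue_max, cfg$coverage_min, cfg$identity_min,
                cfg$word_size)
}

cfg_backend <- function(cfg) {
  if (cfg$backend == "blast") blast_backend() else builtin_backend()
}

cfg_source <- function(cfg) {
  if (grepl("\\.(gb|gbk|genbank)$", cfg$records_path)) {
    genbank_source(cfg$records_path)
  } else {
    fasta_source(cfg$records_path)
  }
}

# ---- logging ------------------------------------------------------------

# The active run log path, if any; run_logged()/log_event() from any
# module append to it when a pipeline run is in progress.
the_log <- new.env(parent = emptyenv())
the_log$path <- NULL

log_event <- function(path, stage, message) {
  path <- path %||% the_log$path
  if (is.null(path)) return(invisible(NULL))
  line <- sprintf("[%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), stage, message)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}

config_fingerprint <- function(cfg, fields) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[fields], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

# ---- caching ------------------------------------------------------------

cache_path <- function(wd, ...) file.path(wd, "cache", ...)

cache_write <- function(obj, path, fingerprint) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  saveRDS(list(fingerprint = fingerprint, value = obj), tmp, version = 2)
  file.rename(tmp, path)
  invisible(path)
}

cache_read <- function(path, fingerprint) {
  if (!file.exists(path)) return(NULL)
  entry <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(entry) || !identical(entry$fingerprint, fingerprint)) {
    if (!is.null(entry)) {
      warning("cache entry ", basename(path),
              " was written under different parameters; recomputing",
              call. = FALSE)
    } else if (file.exists(path)) {
      warning("corrupted cache entry ", basename(path), " discarded",
              call. = FALSE)
    }
    unlink(path)
    return(NULL)
  }
  entry["value"]
}

# ---- stages -------------------------------------------------------------

#' Run the pipeline
#'
#' Executes the requested stages in order — taxise (taxonomy loading and
#' clade-unit partitioning), download (record retrieval, length
#' filtering, feature splitting, per-taxon subsampling), cluster
#' (within-unit all-vs-all search and single-linkage clustering) and
#' cluster2 (seed-vs-seed cluster merging) — with per-unit caching so an
#' interrupted run resumes without repeating completed work. After the
#' cluster stages the cluster set is serialized and PhyLoTa-style tables
#' plus per-cluster FASTA files are exported under `<wd>/results`. A run
#' summary is printed and logged.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress the console summary.
#' @return The final `cluster_set` (invisibly), when a cluster stage ran.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$wd, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$wd, "config.yaml"))
  the_log$path <- file.path(cfg$wd, "log.txt")
  on.exit(the_log$path <- NULL, add = TRUE)
  log_event(NULL, "run", paste0("stages requested: ",
                                paste(cfg$stages, collapse = ",")))
  log_event(NULL, "run", paste0("parameters fingerprint: ",
                                config_fingerprint(cfg, names(unclass(cfg)))))
  result <- NULL
  for (stage in cfg$stages) {
    check_predecessor(cfg, stage)
    log_event(NULL, stage, "stage start")
    result <- switch(stage,
                     taxise = stage_taxise(cfg),
                     download = stage_download(cfg),
                     cluster = stage_cluster(cfg),
                     cluster2 = stage_cluster2(cfg))
    log_event(NULL, stage, "stage done")
  }
  final <- last_cluster_set(cfg$wd)
  if (!is.null(final)) {
    export_clusters(final, file.path(cfg$wd, "results"),
                    tree = final$metadata$tree)
    if (!quiet) print_summary(final)
  }
  invisible(final %||% result)
}

check_predecessor <- function(cfg, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  if (idx == 1) return(invisible(NULL))
  pred <- PIPELINE_STAGES[[idx - 1L]]
  if (pred %in% cfg$stages) return(invisible(NULL)) # will run first
  marker <- switch(pred,
                   taxise = cache_path(cfg$wd, "taxise.rds"),
                   download = cache_path(cfg$wd, "download"),
                   cluster = cache_path(cfg$wd, "cluster"))
  if (!file.exists(marker)) {
    stop("stage error: '", stage, "' needs the cached output of '", pred,
         "'; run stage '", pred, "' first", call. = FALSE)
  }
  invisible(NULL)
}

taxise_fields <- c("root_taxon", "nodes_path", "names_path", "records_path",
                   "max_seqs", "max_nodes", "min_unit_seqs")
download_fields <- c(taxise_fields, "min_len", "max_len", "cap", "seed")
cluster_fields <- c(download_fields, "backend", "evalue_max", "coverage_min",
                    "identity_min", "word_size", "min_cluster_seqs")

stage_taxise <- function(cfg) {
  fp <- config_fingerprint(cfg, taxise_fields)
  path <- cache_path(cfg$wd, "taxise.rds")
  hit <- cache_read(path, fp)
  if (!is.null(hit)) {
    log_event(NULL, "taxise", "cached")
    return(invisible(hit$value))
  }
  tree <- load_taxdump(cfg$nodes_path, cfg$names_path)
  root <- resolve_taxon(tree, cfg$root_taxon)
  log_event(NULL, "taxise", paste0("root resolved to taxid ", root, " (",
                                   taxon_name(tree, root), ")"))
  # restrict the tree to the root's subtree
  scope <- c(root, descendants(tree, root))
  nodes <- tree$nodes[tree$nodes$taxid %in% scope, , drop = FALSE]
  nodes$parent_taxid[nodes$taxid == root] <- root
  subtree <- tax_tree(nodes, tree$name_tab[tree$name_tab$taxid %in% scope, ,
                                           drop = FALSE])
  counts <- count_by_taxon(cfg_source(cfg))
  counts <- counts[as.integer(names(counts)) %in% scope]
  units <- partition_clades(subtree, counts, cfg$max_seqs, cfg$max_nodes,
                            cfg$min_unit_seqs)
  log_event(NULL, "taxise", paste0(length(scope), " taxa in scope, ",
                                   length(units), " clade unit(s)"))
  value <- list(tree = subtree, root = root, units = units)
  cache_write(value, path, fp)
  invisible(value)
}

stage_download <- function(cfg) {
  tx <- cache_read(cache_path(cfg$wd, "taxise.rds"),
                   config_fingerprint(cfg, taxise_fields))
  if (is.null(tx)) {
    stop("stage error: 'download' needs the cached output of 'taxise'; ",
         "run stage 'taxise' first", call. = FALSE)
  }
  tx <- tx$value
  fp <- config_fingerprint(cfg, download_fields)
  source <- cfg_source(cfg)
  segs_by_unit <- list()
  for (i in seq_along(tx$units)) {
    unit <- tx$units[[i]]
    path <- cache_path(cfg$wd, "download", sprintf("unit_%03d.rds", i))
    hit <- cache_read(path, fp)
    if (!is.null(hit)) {
      log_event(NULL, "download", paste0("unit ", i, " cached"))
      segs_by_unit[[i]] <- hit$value
      next
    }
    records <- fetch_records(source, unit$member_taxids, cfg$retries)
    segs <- prepare_segments(records, cfg$min_len, cfg$max_len)
    segs <- subsample_per_taxon(segs, cfg$cap, rng_seed = cfg$seed + i)
    log_event(NULL, "download", paste0("unit ", i, ": ", length(records),
                                       " records -> ", nrow(segs),
                                       " segments"))
    cache_write(segs, path, fp)
    segs_by_unit[[i]] <- segs
  }
  invisible(segs_by_unit)
}

stage_cluster <- function(cfg) {
  tx <- cache_read(cache_path(cfg$wd, "taxise.rds"),
                   config_fingerprint(cfg, taxise_fields))
  if (is.null(tx)) {
    stop("stage error: 'cluster' needs the cached outputs of earlier ",
         "stages; run from 'taxise'", call. = FALSE)
  }
  tx <- tx$value
  dl_fp <- config_fingerprint(cfg, download_fields)
  fp <- config_fingerprint(cfg, cluster_fields)
  params <- cfg_params(cfg)
  backend <- cfg_backend(cfg)
  unit_clusters <- list()
  all_segs <- list()
  for (i in seq_along(tx$units)) {
    seg_hit <- cache_read(cache_path(cfg$wd, "download",
                                     sprintf("unit_%03d.rds", i)), dl_fp)
    if (is.null(seg_hit)) {
      stop("stage error: 'cluster' needs the cached output of 'download' ",
           "for unit ", i, "; run stage 'download' first", call. = FALSE)
    }
    segs <- seg_hit$value
    all_segs[[i]] <- segs
    path <- cache_path(cfg$wd, "cluster", sprintf("unit_%03d.rds", i))
    hit <- cache_read(path, fp)
    if (!is.null(hit)) {
      log_event(NULL, "cluster", paste0("unit ", i, " cached"))
      unit_clusters[[i]] <- hit$value$clusters
      next
    }
    hits <- if (nrow(segs) >= 2) {
      filter_hits(all_vs_all(segs, params, backend), params)
    } else empty_hits()
    clusters <- cluster_unit(tx$units[[i]], segs, hits,
                             cfg$min_cluster_seqs)
    log_event(NULL, "cluster", paste0("unit ", i, " computed: ", nrow(hits),
                                      " filtered hits, ", length(clusters),
                                      " clusters"))
    cache_write(list(hits = hits, clusters = clusters), path, fp)
    unit_clusters[[i]] <- clusters
  }
  segments <- do.call(rbind, c(list(empty_segments()), all_segs))
  segments <- segments[order_c(segments$segment_id), , drop = FALSE]
  rownames(segments) <- NULL
  cset <- cluster_set(unit_clusters, segments,
                      metadata = list(root = tx$root, tree = tx$tree,
                                      min_cluster_seqs = cfg$min_cluster_seqs,
                                      params = unclass(cfg_params(cfg))))
  cache_write(cset, cache_path(cfg$wd, "clusterset.rds"), fp)
  invisible(cset)
}

stage_cluster2 <- function(cfg) {
  fp <- config_fingerprint(cfg, cluster_fields)
  base <- cache_read(cache_path(cfg$wd, "clusterset.rds"), fp)
  if (is.null(base)) {
    stop("stage error: 'cluster2' needs the cached output of 'cluster'; ",
         "run stage 'cluster' first", call. = FALSE)
  }
  path <- cache_path(cfg$wd, "cluster2.rds")
  hit <- cache_read(path, fp)
  if (!is.null(hit)) {
    log_event(NULL, "cluster2", "cached")
    return(invisible(hit$value))
  }
  merged <- merge_clusters(base$value, cfg_params(cfg), cfg_backend(cfg))
  n_new <- length(merged$clusters) - length(base$value$clusters)
  log_event(NULL, "cluster2", paste0(n_new, " merged cluster(s) created"))
  cache_write(merged, path, fp)
  invisible(merged)
}

last_cluster_set <- function(wd) {
  for (f in c("cluster2.rds", "clusterset.rds")) {
    p <- cache_path(wd, f)
    if (file.exists(p)) {
      entry <- tryCatch(readRDS(p), error = function(e) NULL)
      if (!is.null(entry)) return(entry$value)
    }
  }
  NULL
}

print_summary <- function(cset) {
  kinds <- vapply(reported_clusters(cset), `[[`, "", "kind")
  cat("Pipeline summary\n")
  cat("  taxa with sequences: ", length(unique(cset$segments$taxid)), "\n",
      sep = "")
  cat("  segments: ", nrow(cset$segments), "\n", sep = "")
  cat("  reported clusters: ", length(kinds), "\n", sep = "")
  for (k in c("subtree", "paraphyletic", "direct", "merged")) {
    cat("    ", k, ": ", sum(kinds == k), "\n", sep = "")
  }
  invisible(cset)
}

#' Restart a halted run
#'
#' Re-reads the persisted configuration from a run directory and re-runs
#' the pipeline; stages and clade units with intact caches are skipped,
#' so only unfinished work is recomputed. Corrupted cache entries are
#' discarded with a warning and recomputed.
#'
#' @param wd A run working directory.
#' @param quiet Suppress the console summary.
#' @return The final `cluster_set` (invisibly).
#' @export
restart_pipeline <- function(wd, quiet = FALSE) {
  cfg_file <- file.path(wd, "config.yaml")
  if (!file.exists(cfg_file)) {
    stop("no run found in ", wd, call. = FALSE)
  }
  raw <- yaml::read_yaml(cfg_file)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character(0))])
  log_event(file.path(wd, "log.txt"), "run", "restart requested")
  run_pipeline(cfg, quiet = quiet)
}
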