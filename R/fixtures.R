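#' Configuration for the synthetic corpus generator
#'
#' The generator builds a ranked taxonomy, evolves orthologous gene
#' families along it under an i.i.d. (Jukes-Cantor-style) substitution
#' process, and emits the corpus in every dialect the pipeline reads,
#' together with a ground-truth table mapping each sequence unit to its
#' family. Optional decoys reproduce the known failure modes of public
#' sequence repositories: over-represented model organisms, long
#' feature-bearing records, mislabeled records and chimeric records.
#'
#' @param n_taxa Number of species (leaf taxa); default 20.
#' @param n_families Number of orthologous gene families; default 10.
#' @param tree_depth Ranked levels below the root, 2-4, using the tail of
#'   family - tribe - genus - species; default 4.
#' @param family_length_range Root sequence length range (nt); default
#'   500-900, inside the pipeline's default length window.
#' @param within_family_divergence Expected substitutions per site from
#'   family root to tip, in \[0, 0.75); default 0.05, giving expected
#'   within-family pairwise identity of at least 0.90.
#' @param n_model_taxa Species given duplicated near-identical records.
#' @param model_dup_factor Copies per record for model taxa; default 5.
#' @param n_long_records Long records concatenating three family genes as
#'   annotated features inside random spacer.
#' @param n_mislabeled Records assigned a wrong taxid.
#' @param n_chimeras Records concatenating halves of two families,
#'   without feature annotation.
#' @param rng_seed Integer seed; identical configs give byte-identical
#'   corpora.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_taxa = 20, n_families = 10, tree_depth = 4,
                       family_length_range = c(500, 900),
                       within_family_divergence = 0.05,
                       n_model_taxa = 0, model_dup_factor = 5,
                       n_long_records = 0, n_mislabeled = 0,
                       n_chimeras = 0, rng_seed = 1) {
  stopifnot(n_taxa >= 2, n_families >= 1,
            tree_depth >= 2, tree_depth <= 4,
            length(family_length_range) == 2,
            family_length_range[1] > 0,
            family_length_range[1] <= family_length_range[2],
            within_family_divergence >= 0, within_family_divergence < 0.75,
            n_model_taxa >= 0, n_model_taxa <= n_taxa, model_dup_factor >= 1,
            n_long_records >= 0, n_mislabeled >= 0, n_chimeras >= 0)
  if (n_chimeras > 0 && n_families < 2) {
    stop("config error: chimeras need at least 2 families", call. = FALSE)
  }
  if (n_long_records > 0 && n_families < 3) {
    stop("config error: long records need at least 3 families", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic corpus with known ground truth
#'
#' See [sim_config()] for the generative model. When `out_dir` is given,
#' the corpus is written out as `nodes.dmp`/`names.dmp` (taxdump
#' dialect), `records.fasta` (annotated FASTA dialect), `records.gb`
#' (GenBank flat-file dialect, same records) and `truth.tsv`
#' (segment id to family).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return A list: `tree` (`tax_tree`), `records` (list of `seq_record`),
#'   `truth` (data frame `segment_id`, `accession`, `family`), `files`
#'   (named paths when written).
#' @export
simulate_corpus <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, simulate_corpus_impl(config, out_dir))
}

simulate_corpus_impl <- function(config, out_dir) {
  tree <- simulate_taxonomy(config)
  species <- tree$nodes$taxid[tree$nodes$rank == "species"]
  fam <- simulate_families(config)
  depth <- config$tree_depth

  # evolve each family along the taxonomy: per-edge substitution
  # probability divergence/depth, so root-to-tip totals the target
  per_edge <- config$within_family_divergence / depth
  tip_seqs <- lapply(fam$roots, function(root_seq) {
    evolve_along_tree(tree, root_seq, per_edge)
  })

  records <- list()
  truth <- list()
  acc_counter <- 0L
  next_acc <- function() {
    acc_counter <<- acc_counter + 1L
    sprintf("SYN%05d.1", acc_counter)
  }
  add <- function(rec, family, span = NULL) {
    records[[length(records) + 1L]] <<- rec
    sid <- if (is.null(span)) segment_id(rec$accession, 0L, rec$length)
           else span
    truth[[length(truth) + 1L]] <<- data.frame(
      segment_id = sid, accession = rec$accession, family = family,
      stringsAsFactors = FALSE)
  }

  for (f in seq_len(config$n_families)) {
    for (s in species) {
      rec <- seq_record(next_acc(), s, tip_seqs[[f]][[as.character(s)]],
                        sprintf("%s gene%02d gene, partial sequence",
                                taxon_name(tree, s), f))
      add(rec, paste0("fam", f))
    }
  }

  # model organisms: near-identical duplicate records
  if (config$n_model_taxa > 0) {
    model_sp <- species[seq_len(config$n_model_taxa)]
    for (s in model_sp) {
      for (f in seq_len(config$n_families)) {
        base <- tip_seqs[[f]][[as.character(s)]]
        for (d in seq_len(config$model_dup_factor - 1L)) {
          rec <- seq_record(next_acc(), s, mutate_seq(base, 0.005),
                            sprintf("%s gene%02d gene, isolate %d",
                                    taxon_name(tree, s), f, d))
          add(rec, paste0("fam", f))
        }
      }
    }
  }

  # long feature-bearing records: three family genes in random spacer,
  # total length forced beyond the default 3000 nt window
  if (config$n_long_records > 0) {
    for (k in seq_len(config$n_long_records)) {
      s <- species[[((k - 1L) %% length(species)) + 1L]]
      fams <- sample(config$n_families, 3)
      genes <- lapply(fams, function(f) tip_seqs[[f]][[as.character(s)]])
      spacer <- function(n) random_seq(n)
      parts <- list(spacer(300))
      feats <- list()
      spans <- character(3)
      pos <- 300L
      for (gi in seq_along(genes)) {
        g <- genes[[gi]]
        feats[[gi]] <- data.frame(kind = "gene", start = pos,
                                  end = pos + nchar(g), strand = "+",
                                  label = paste0("gene", fams[[gi]]),
                                  stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- g
        pos <- pos + nchar(g)
        parts[[length(parts) + 1L]] <- spacer(300)
        pos <- pos + 300L
      }
      total <- pos
      if (total <= 3000L) {
        pad <- 3001L - total + 100L
        parts[[length(parts) + 1L]] <- spacer(pad)
      }
      res <- paste(unlist(parts), collapse = "")
      acc <- next_acc()
      rec <- seq_record(acc, s, res,
                        sprintf("%s genomic region with gene features",
                                taxon_name(tree, s)),
                        do.call(rbind, feats))
      records[[length(records) + 1L]] <- rec
      for (gi in seq_along(genes)) {
        truth[[length(truth) + 1L]] <- data.frame(
          segment_id = segment_id(acc, feats[[gi]]$start, feats[[gi]]$end),
          accession = acc, family = paste0("fam", fams[[gi]]),
          stringsAsFactors = FALSE)
      }
    }
  }

  # mislabeled records: right family, wrong taxid
  if (config$n_mislabeled > 0) {
    for (k in seq_len(config$n_mislabeled)) {
      f <- ((k - 1L) %% config$n_families) + 1L
      s_true <- species[[((k - 1L) %% length(species)) + 1L]]
      s_wrong <- species[[(k %% length(species)) + 1L]]
      rec <- seq_record(next_acc(), s_wrong,
                        mutate_seq(tip_seqs[[f]][[as.character(s_true)]],
                                   0.005),
                        sprintf("%s gene%02d gene (mislabeled decoy)",
                                taxon_name(tree, s_wrong), f))
      add(rec, paste0("fam", f))
    }
  }

  # chimeras: halves of two families glued together, no annotation
  if (config$n_chimeras > 0) {
    for (k in seq_len(config$n_chimeras)) {
      fs <- sample(config$n_families, 2)
      s <- species[[((k - 1L) %% length(species)) + 1L]]
      g1 <- tip_seqs[[fs[[1]]]][[as.character(s)]]
      g2 <- tip_seqs[[fs[[2]]]][[as.character(s)]]
      res <- paste0(substr(g1, 1, nchar(g1) %/% 2),
                    substr(g2, nchar(g2) %/% 2 + 1, nchar(g2)))
      rec <- seq_record(next_acc(), s, res,
                        sprintf("%s unannotated sequence (chimeric decoy)",
                                taxon_name(tree, s)))
      add(rec, "decoy_chimera")
    }
  }

  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  out <- list(tree = tree, records = records, truth = truth_df,
              files = NULL)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- c(nodes = file.path(out_dir, "nodes.dmp"),
               names = file.path(out_dir, "names.dmp"),
               fasta = file.path(out_dir, "records.fasta"),
               genbank = file.path(out_dir, "records.gb"),
               truth = file.path(out_dir, "truth.tsv"))
    write_taxdump(tree, files[["nodes"]], files[["names"]])
    write_annotated_fasta(records, files[["fasta"]])
    write_genbank(records, files[["genbank"]])
    write_tsv_atomic(truth_df, files[["truth"]])
    out$files <- files
  }
  out
}

# Ranked taxonomy: root -> families -> tribes -> genera -> species, the
# shallower depths dropping the upper ranks.
simulate_taxonomy <- function(config) {
  ranks <- utils::tail(c("family", "tribe", "genus", "species"),
                       config$tree_depth)
  n_species <- config$n_taxa
  # group sizes upward: ~3 species/genus, ~2 groups per higher level
  level_counts <- integer(length(ranks))
  level_counts[[length(ranks)]] <- n_species
  want <- max(2L, ceiling(n_species / 3))
  for (lv in rev(seq_len(length(ranks) - 1L))) {
    level_counts[[lv]] <- min(want, level_counts[[lv + 1L]])
    want <- max(2L, ceiling(want / 2))
  }
  taxid <- 1L
  nodes <- data.frame(taxid = 1L, parent_taxid = 1L, rank = "order",
                      name = "Simulandia", stringsAsFactors = FALSE)
  prev_ids <- 1L
  for (lv in seq_along(ranks)) {
    n_here <- level_counts[[lv]]
    ids <- taxid + seq_len(n_here)
    taxid <- taxid + n_here
    # random surjective assignment to parents (every parent gets >= 1)
    parents <- c(prev_ids[seq_len(min(length(prev_ids), n_here))],
                 if (n_here > length(prev_ids)) {
                   prev_ids[sample.int(length(prev_ids),
                                       n_here - length(prev_ids),
                                       replace = TRUE)]
                 })
    parents <- parents[sample.int(length(parents))] # shuffle pairing
    rank_name <- ranks[[lv]]
    names_here <- if (rank_name == "species") {
      paste0("Species sp", seq_len(n_here))
    } else {
      paste0(toupper(substr(rank_name, 1, 1)),
             substr(rank_name, 2, nchar(rank_name)), seq_len(n_here))
    }
    nodes <- rbind(nodes, data.frame(
      taxid = ids, parent_taxid = parents, rank = rank_name,
      name = names_here, stringsAsFactors = FALSE))
    prev_ids <- ids
  }
  # species binomials follow their genus
  if ("genus" %in% ranks) {
    sp <- nodes$rank == "species"
    gnames <- nodes$name[match(nodes$parent_taxid[sp], nodes$taxid)]
    nodes$name[sp] <- paste0(gnames, " sp", seq_len(sum(sp)))
  }
  name_tab <- data.frame(taxid = nodes$taxid, name = nodes$name,
                         class = "scientific name", stringsAsFactors = FALSE)
  tax_tree(nodes, name_tab)
}

# Family root sequences; resampled if too similar to an existing root
# (per-site identity over the shorter length above 0.40), which keeps
# between-family similarity at the random baseline.
simulate_families <- function(config) {
  roots <- list()
  for (f in seq_len(config$n_families)) {
    for (try in seq_len(200)) {
      lens <- seq(config$family_length_range[1],
                  config$family_length_range[2])
      len <- lens[sample.int(length(lens), 1)]
      cand <- random_seq(len)
      ok <- all(vapply(roots, function(r)
        site_identity(r, cand) <= 0.40, logical(1)))
      if (ok) break
      if (try == 200) {
        stop("config error: cannot draw ", config$n_families,
             " sufficiently distinct family roots", call. = FALSE)
      }
    }
    roots[[f]] <- cand
  }
  list(roots = roots)
}

site_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  mean(av == bv)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# i.i.d. substitution: each site mutates with probability p to one of the
# other three bases, drawn uniformly (Jukes-Cantor-style).
mutate_seq <- function(s, p) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[[i]] <- sample(setdiff(bases, chars[[i]]), 1)
    }
  }
  paste(chars, collapse = "")
}

# Evolve one family root down every edge of the taxonomy; returns tip
# sequences named by species taxid.
evolve_along_tree <- function(tree, root_seq, per_edge_p) {
  seqs <- list()
  seqs[[as.character(tree$root)]] <- root_seq
  for (v in descendants(tree, tree$root)) { # preorder: parents first
    p <- taxon_parent(tree, v)
    seqs[[as.character(v)]] <- mutate_seq(seqs[[as.character(p)]], per_edge_p)
  }
  species <- tree$nodes$taxid[tree$nodes$rank == "species"]
  seqs[as.character(species)]
}

write_taxdump <- function(tree, nodes_path, names_path) {
  n <- tree$nodes
  write_lines_atomic(
    paste0(n$taxid, "\t|\t", n$parent_taxid, "\t|\t", n$rank, "\t|"),
    nodes_path)
  tab <- tree$name_tab
  write_lines_atomic(
    paste0(tab$taxid, "\t|\t", tab$name, "\t|\t", "", "\t|\t", tab$class,
           "\t|"),
    names_path)
}
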