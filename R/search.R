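#' Similarity search parameters
#'
#' Thresholds applied to pairwise hits before clustering. Defaults:
#' e-value at most 1e-10, query coverage at least 0.5, no identity floor,
#' and an 11-nt word size for the built-in backend (matching common
#' nucleotide-BLAST practice).
#'
#' @param evalue_max Maximum e-value.
#' @param coverage_min Minimum query coverage (aligned query span / query
#'   length), in \[0, 1\].
#' @param identity_min Minimum percent identity, in \[0, 100\]; 0 disables.
#' @param word_size Seed word size for the built-in backend.
#' @return A `search_params` object.
#' @export
search_params <- function(evalue_max = 1e-10, coverage_min = 0.5,
                          identity_min = 0, word_size = 11) {
  stopifnot(evalue_max >= 0, coverage_min >= 0, coverage_min <= 1,
            identity_min >= 0, identity_min <= 100, word_size >= 4)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 identity_min = identity_min, word_size = as.integer(word_size)),
            class = "search_params")
}

#' Search backends
#'
#' `builtin_backend()` runs entirely in R: shared k-mer screening selects
#' candidate pairs, which are then aligned locally (match +1, mismatch -1,
#' gap -2 per gap position) via [Biostrings::pairwiseAlignment()].
#' E-values follow a Karlin-Altschul-style approximation
#' `E = K m n exp(-lambda S)` with `lambda = ln 3`, `K = 0.333` (the
#' analytic values for +1/-1 scoring on uniform base composition) and `n`
#' the total residue count of the run's database; this is an approximation
#' of, not a drop-in for, BLAST statistics, and is intended for tests and
#' modest corpora.
#'
#' `blast_backend()` shells out to `makeblastdb`/`blastn` (BLAST+) with
#' tabular output; the executables must be on the PATH.
#'
#' @param makeblastdb,blastn Paths to the BLAST+ executables.
#' @return A search backend object.
#' @name search_backends
NULL

#' @rdname search_backends
#' @export
builtin_backend <- function() {
  structure(list(type = "builtin"),
            class = c("builtin_backend", "search_backend"))
}

#' @rdname search_backends
#' @export
blast_backend <- function(makeblastdb = "makeblastdb", blastn = "blastn") {
  structure(list(type = "blast", makeblastdb = makeblastdb, blastn = blastn),
            class = c("blast_backend", "search_backend"))
}

# loose reporting ceiling (BLAST's default); binding filters are applied
# later by filter_hits()
REPORT_EVALUE <- 10

#' All-vs-all similarity search over segments
#'
#' Produces directed pairwise hits among the given segments, ordered by
#' (query id, subject id, descending bitscore). Hits are reported at the
#' backend's native reporting threshold; apply [filter_hits()] before
#' clustering.
#'
#' @param segments Segment data frame (at least 2 rows, unique ids).
#' @param params A [search_params()] object.
#' @param backend A search backend (default [builtin_backend()]).
#' @return Hit data frame with columns `query_id`, `subject_id`,
#'   `identity_pct`, `align_len`, `mismatches`, `gapopen`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `query_coverage`
#'   (BLAST tabular conventions: 1-based inclusive coordinates;
#'   `s_start > s_end` on the minus strand).
#' @export
all_vs_all <- function(segments, params = search_params(),
                       backend = builtin_backend()) {
  stopifnot(nrow(segments) >= 2)
  if (anyDuplicated(segments$segment_id)) {
    stop("duplicate segment ids in search input", call. = FALSE)
  }
  hits <- search_impl(backend, segments, params)
  hits <- hits[order_c(hits$query_id, hits$subject_id, -hits$bitscore), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

search_impl <- function(backend, segments, params) UseMethod("search_impl")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             identity_pct = numeric(0), align_len = integer(0),
             mismatches = integer(0), gapopen = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             query_coverage = numeric(0), stringsAsFactors = FALSE)
}

# ---- built-in backend ---------------------------------------------------

KA_LAMBDA <- log(3)   # solves 0.25 e^l + 0.75 e^-l = 1 for +1/-1 scoring
KA_K <- 0.333

builtin_evalue <- function(score, qlen, dblen) {
  KA_K * as.numeric(qlen) * as.numeric(dblen) * exp(-KA_LAMBDA * score)
}

builtin_bitscore <- function(score) {
  (KA_LAMBDA * score - log(KA_K)) / log(2)
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# Candidate unordered pairs sharing words on either strand. Two-hit
# seeding: a pair must share at least `min_share` distinct words to be
# aligned, which suppresses chance single-word matches between unrelated
# sequences (a pair of unrelated ~700 nt sequences shares one 11-mer by
# chance fairly often, two almost never).
kmer_candidates <- function(seqs, k, min_share = 2) {
  n <- length(seqs)
  fwd <- lapply(seqs, seq_kmers, k = k)
  rc <- lapply(reverse_complement(seqs), seq_kmers, k = k)
  kf <- unlist(fwd, use.names = FALSE)
  i_f <- rep(seq_len(n), lengths(fwd))
  kr <- unlist(rc, use.names = FALSE)
  i_r <- rep(seq_len(n), lengths(rc))
  lev <- unique(kf)
  grp_f <- split(i_f, match(kf, lev))
  # plus/plus: all i<j pairs within each word group
  pp <- lapply(grp_f[lengths(grp_f) >= 2], function(g) {
    g <- sort(g)
    m <- length(g)
    cbind(i = rep(g[-m], times = (m - 1):1),
          j = g[sequence((m - 1):1, from = 2:m)])
  })
  # plus/minus: cross product of forward and reverse-complement carriers
  code_r <- match(kr, lev)
  ok <- !is.na(code_r)
  grp_r <- split(i_r[ok], code_r[ok])
  pm <- lapply(names(grp_r), function(code) {
    a <- grp_f[[code]]
    if (is.null(a)) return(NULL)
    b <- grp_r[[code]]
    m <- expand.grid(i = a, j = b)
    m <- m[m$i != m$j, , drop = FALSE]
    cbind(i = pmin(m$i, m$j), j = pmax(m$i, m$j))
  })
  count_pairs <- function(mats) {
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) == 0) return(NULL)
    m <- do.call(rbind, mats)
    if (nrow(m) == 0) return(NULL)
    key <- (m[, 1] - 1) * n + m[, 2]
    cnt <- table(key)
    keys <- as.numeric(names(cnt[cnt >= min_share]))
    if (length(keys) == 0) return(NULL)
    data.frame(i = as.integer((keys - 1) %/% n + 1),
               j = as.integer((keys - 1) %% n + 1))
  }
  plus <- count_pairs(pp)
  minus <- count_pairs(pm)
  if (!is.null(plus)) plus$strand <- "+"
  if (!is.null(minus)) minus$strand <- "-"
  both <- rbind(plus, minus)
  if (is.null(both) || nrow(both) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  # a pair seen on both strands is aligned on the plus strand
  both <- both[order(both$i, both$j, both$strand != "+"), , drop = FALSE]
  both[!duplicated(both[, c("i", "j")]), , drop = FALSE]
}

#' @export
search_impl.builtin_backend <- function(backend, segments, params) {
  seqs <- toupper(segments$residues)
  ids <- segments$segment_id
  lens <- segments$length
  dblen <- sum(as.numeric(lens))
  cand <- kmer_candidates(seqs, params$word_size)
  if (nrow(cand) == 0) return(empty_hits())
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  rows <- list()
  # one vectorized alignment call per (subject, strand) batch
  cand$key <- paste0(cand$j, cand$strand)
  for (key in unique(cand$key)) {
    sel <- cand[cand$key == key, , drop = FALSE]
    j <- sel$j[[1]]
    minus <- sel$strand[[1]] == "-"
    subj <- if (minus) reverse_complement(seqs[[j]]) else seqs[[j]]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[sel$i]), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    sc <- Biostrings::score(al)
    ev_i <- builtin_evalue(sc, lens[sel$i], dblen)
    ev_j <- builtin_evalue(sc, lens[[j]], dblen)
    keep <- sc > 0 & pmin(ev_i, ev_j) <= REPORT_EVALUE
    if (!any(keep)) next
    alen <- Biostrings::nchar(al)[keep]
    nmis <- Biostrings::nmismatch(al)[keep]
    indel <- Biostrings::nindel(al)
    ins <- Biostrings::insertion(indel)[keep, , drop = FALSE]
    del <- Biostrings::deletion(indel)[keep, , drop = FALSE]
    ngapcol <- ins[, "WidthSum"] + del[, "WidthSum"]
    ngapopen <- ins[, "Length"] + del[, "Length"]
    ident <- 100 * (alen - nmis - ngapcol) / alen
    qs <- IRanges::start(Biostrings::pattern(al))[keep]
    qe <- IRanges::end(Biostrings::pattern(al))[keep]
    ss0 <- IRanges::start(Biostrings::subject(al))[keep]
    se0 <- IRanges::end(Biostrings::subject(al))[keep]
    if (minus) {
      # coordinates on the original subject, reported minus-strand style
      ss <- lens[[j]] - ss0 + 1L
      se <- lens[[j]] - se0 + 1L
    } else {
      ss <- ss0; se <- se0
    }
    bit <- builtin_bitscore(sc[keep])
    i_ids <- ids[sel$i[keep]]
    # each alignment yields both directed hits
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = c(i_ids, rep(ids[[j]], length(i_ids))),
      subject_id = c(rep(ids[[j]], length(i_ids)), i_ids),
      identity_pct = c(ident, ident), align_len = c(alen, alen),
      mismatches = c(nmis, nmis), gapopen = c(ngapopen, ngapopen),
      q_start = c(qs, pmin(ss, se)), q_end = c(qe, pmax(ss, se)),
      s_start = c(ss, if (minus) qe else qs),
      s_end = c(se, if (minus) qs else qe),
      evalue = c(ev_i[keep], ev_j[keep]),
      bitscore = c(bit, bit),
      query_coverage = c((qe - qs + 1) / lens[sel$i[keep]],
                         (abs(se - ss) + 1) / lens[[j]]),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  out[out$evalue <= REPORT_EVALUE, , drop = FALSE]
}

# ---- external BLAST+ backend -------------------------------------------

BLAST_OUTFMT <- "6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore"

#' @export
search_impl.blast_backend <- function(backend, segments, params) {
  for (exe in c(backend$makeblastdb, backend$blastn)) {
    if (Sys.which(exe) == "" && !file.exists(exe)) {
      stop("configuration error: BLAST+ executable '", exe,
           "' not found; install the NCBI BLAST+ suite or use ",
           "builtin_backend()", call. = FALSE)
    }
  }
  work <- tempfile("blastdb_")
  dir.create(work)
  on.exit(unlink(work, recursive = TRUE), add = TRUE)
  fa <- file.path(work, "db.fasta")
  write_fasta_atomic(segments$segment_id, segments$residues, fa)
  out <- file.path(work, "hits.tsv")
  run_logged(backend$makeblastdb,
             c("-in", fa, "-dbtype", "nucl", "-out", file.path(work, "db")))
  run_logged(backend$blastn,
             c("-query", fa, "-db", file.path(work, "db"),
               "-task", "blastn", "-word_size", params$word_size,
               "-outfmt", shQuote(BLAST_OUTFMT),
               "-evalue", format(REPORT_EVALUE),
               "-out", out))
  qlens <- stats::setNames(segments$length, segments$segment_id)
  parse_blast_tabular(out, qlens)
}

run_logged <- function(exe, args) {
  log_event(NULL, "exec", paste(c(exe, args), collapse = " "))
  status <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0L
  if (code != 0) {
    stop("stage error: '", exe, "' exited with status ", code, ":\n",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  invisible(status)
}

#' Parse BLAST tabular (outfmt 6) hits
#'
#' Reads the canonical 12-column tabular dialect. Query coverage is not
#' part of the format, so query lengths are supplied separately.
#'
#' @param path Path to a tabular hit file.
#' @param query_lengths Named numeric vector: query id to length.
#' @return Hit data frame (see [all_vs_all()]).
#' @export
parse_blast_tabular <- function(path, query_lengths) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("parse error in ", path, " line ", bad, ": expected 12 columns, ",
         "found ", nf[bad], call. = FALSE)
  }
  col <- function(k) vapply(fields, `[[`, "", k)
  qid <- col(1)
  qlen <- query_lengths[qid]
  if (anyNA(qlen)) {
    stop("query id without a supplied length: ", qid[is.na(qlen)][1],
         call. = FALSE)
  }
  qs <- as.integer(col(7)); qe <- as.integer(col(8))
  data.frame(
    query_id = qid, subject_id = col(2),
    identity_pct = as.numeric(col(3)), align_len = as.integer(col(4)),
    mismatches = as.integer(col(5)), gapopen = as.integer(col(6)),
    q_start = qs, q_end = qe,
    s_start = as.integer(col(9)), s_end = as.integer(col(10)),
    evalue = as.numeric(col(11)), bitscore = as.numeric(col(12)),
    query_coverage = (abs(qe - qs) + 1) / as.numeric(qlen),
    stringsAsFactors = FALSE
  )
}

#' Filter hits by the run thresholds
#'
#' Removes self-hits, hits failing the e-value/coverage/identity
#' thresholds, and collapses duplicate (query, subject) pairs to the hit
#' with the best bitscore. Output is ordered by (query id, subject id).
#'
#' @param hits Hit data frame.
#' @param params A [search_params()] object.
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, params = search_params()) {
  if (nrow(hits) == 0) return(hits)
  keep <- hits$query_id != hits$subject_id &
    hits$evalue <= params$evalue_max &
    hits$query_coverage >= params$coverage_min &
    hits$identity_pct >= params$identity_min
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    rownames(hits) <- NULL
    return(hits)
  }
  hits <- hits[order_c(hits$query_id, hits$subject_id, -hits$bitscore), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_id", "subject_id")]), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Undirected edges from filtered directed hits
#'
#' An undirected edge joins two segments if a hit passes the filters in
#' either direction (union symmetrization) — a fragment aligned
#' full-length to a longer sequence keeps its edge even though coverage
#' on the longer side is poor. Each edge carries the summed bitscore of
#' the directed hits that support it.
#'
#' @param hits Filtered hit data frame.
#' @return Data frame with columns `a`, `b` (`a < b` lexicographically)
#'   and `bitscore`.
#' @export
symmetrize_edges <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  agg <- stats::aggregate(list(bitscore = hits$bitscore),
                          by = list(a = a, b = b), FUN = sum)
  agg <- agg[order_c(agg$a, agg$b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
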