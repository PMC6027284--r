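#' Sequence record sources
#'
#' A record source is any object answering `get_records(source, taxids)`
#' and `count_by_taxon(source)`. Two local file dialects are supported:
#'
#' * **Annotated FASTA**: headers of the form
#'   `>ACC taxid=<int> [feature=kind:start-end[:rc] ...] def=<free text>`.
#'   Feature coordinates in this dialect are 0-based half-open (the
#'   internal convention).
#' * **GenBank flat file**: the LOCUS/DEFINITION/FEATURES/ORIGIN subset;
#'   1-based inclusive feature spans (converted on read), `complement(..)`
#'   locations, and the organism taxid taken from the source feature's
#'   `/db_xref="taxon:<int>"` qualifier.
#'
#' Files are parsed once and cached inside the source object.
#'
#' @param path Path to the record file.
#' @return A record source object.
#' @name record_sources
NULL

#' @rdname record_sources
#' @export
fasta_source <- function(path) {
  stopifnot(file.exists(path))
  new_source("fasta_source", path, read_annotated_fasta)
}

#' @rdname record_sources
#' @export
genbank_source <- function(path) {
  stopifnot(file.exists(path))
  new_source("genbank_source", path, read_genbank)
}

#' In-memory record source (mainly for tests)
#' @param records A list of `seq_record` objects.
#' @export
memory_source <- function(records) {
  env <- new.env(parent = emptyenv())
  env$records <- records
  structure(list(path = NA_character_, env = env, n_failures = 0L),
            class = c("memory_source", "record_source"))
}

new_source <- function(cls, path, reader) {
  env <- new.env(parent = emptyenv())
  env$records <- NULL
  env$reader <- reader
  structure(list(path = path, env = env), class = c(cls, "record_source"))
}

source_records <- function(source) {
  if (is.null(source$env$records)) {
    source$env$records <- source$env$reader(source$path)
  }
  source$env$records
}

#' Retrieve records for a set of taxa
#'
#' Returns every record whose taxid is in `taxids`, in deterministic
#' (accession) order. Transient source failures are retried up to
#' `retries` times before the call fails.
#'
#' @param source A record source.
#' @param taxids Integer vector of taxids (nonempty).
#' @param retries Number of retries on source failure.
#' @return List of `seq_record` objects.
#' @export
fetch_records <- function(source, taxids, retries = 3) {
  stopifnot(length(taxids) > 0)
  recs <- NULL
  for (attempt in seq_len(retries + 1)) {
    recs <- tryCatch(source_records(source), error = function(e) e)
    if (!inherits(recs, "error")) break
    if (attempt == retries + 1) {
      stop("record source failed after ", retries, " retries: ",
           conditionMessage(recs), call. = FALSE)
    }
  }
  keep <- vapply(recs, function(r) r$taxid %in% taxids, logical(1))
  recs <- recs[keep]
  recs[order_c(vapply(recs, `[[`, "", "accession"))]
}

#' Direct per-taxon sequence tallies of a source
#' @param source A record source.
#' @return Named integer vector (names are taxids).
#' @export
count_by_taxon <- function(source) {
  recs <- source_records(source)
  if (length(recs) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(vapply(recs, `[[`, 0L, "taxid"))
  stats::setNames(as.integer(tab), names(tab))
}

#' Construct a sequence record
#'
#' @param accession Versioned accession string.
#' @param taxid Integer taxid.
#' @param residues IUPAC nucleotide string.
#' @param definition Free-text definition line.
#' @param features Data frame with columns `kind`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`) and `label`; may be empty.
#' @return A `seq_record`.
#' @export
seq_record <- function(accession, taxid, residues, definition = "",
                       features = empty_features()) {
  if (!grepl("^[ACGTUMRWSYKVHDBN]*$", toupper(residues))) {
    stop("record ", accession, ": residues outside the IUPAC nucleotide ",
         "alphabet", call. = FALSE)
  }
  structure(list(accession = accession, taxid = as.integer(taxid),
                 definition = definition, residues = residues,
                 length = nchar(residues), features = features),
            class = "seq_record")
}

empty_features <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             strand = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$accession, " taxid=", x$taxid, " ", x$length,
      " nt, ", nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

# ---- annotated FASTA dialect -------------------------------------------

read_annotated_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  headers <- names(dna)
  seqs <- as.character(dna)
  lapply(seq_along(dna), function(i) {
    h <- headers[[i]]
    def <- sub("^.*?def=", "", h)
    if (identical(def, h)) def <- ""
    pre <- sub("[[:space:]]*def=.*$", "", h)
    toks <- strsplit(pre, "[[:space:]]+")[[1]]
    acc <- toks[[1]]
    taxid_tok <- grep("^taxid=", toks, value = TRUE)
    if (length(taxid_tok) != 1) {
      stop("annotated FASTA record '", acc, "': expected one taxid= token",
           call. = FALSE)
    }
    taxid <- as.integer(sub("^taxid=", "", taxid_tok))
    feat_toks <- sub("^feature=", "", grep("^feature=", toks, value = TRUE))
    features <- if (length(feat_toks) > 0) {
      m <- regmatches(feat_toks,
                      regexec("^([A-Za-z_]+):([0-9]+)-([0-9]+)(:rc)?$", feat_toks))
      bad <- vapply(m, length, 0L) == 0
      if (any(bad)) {
        stop("annotated FASTA record '", acc, "': malformed feature token '",
             feat_toks[bad][1], "'", call. = FALSE)
      }
      data.frame(
        kind = vapply(m, `[[`, "", 2),
        start = as.integer(vapply(m, `[[`, "", 3)),
        end = as.integer(vapply(m, `[[`, "", 4)),
        strand = ifelse(vapply(m, `[[`, "", 5) == ":rc", "-", "+"),
        label = vapply(m, `[[`, "", 2),
        stringsAsFactors = FALSE
      )
    } else {
      empty_features()
    }
    seq_record(acc, taxid, seqs[[i]], def, features)
  })
}

format_fasta_header <- function(record) {
  feats <- record$features
  feat_part <- if (nrow(feats) > 0) {
    paste0(" feature=", feats$kind, ":", feats$start, "-", feats$end,
           ifelse(feats$strand == "-", ":rc", ""), collapse = "")
  } else ""
  paste0(record$accession, " taxid=", record$taxid, feat_part,
         " def=", record$definition)
}

write_annotated_fasta <- function(records, path) {
  write_fasta_atomic(
    vapply(records, format_fasta_header, character(1)),
    vapply(records, `[[`, "", "residues"),
    path
  )
}

# ---- GenBank flat-file dialect -----------------------------------------

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(lines == "//")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  if (length(ends) == 0) {
    stop("no '//' record terminator found in ", path, call. = FALSE)
  }
  lapply(seq_along(ends), function(i) {
    parse_genbank_record(lines[starts[[i]]:(ends[[i]] - 1L)], path)
  })
}

parse_genbank_record <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines, "right")) | nzchar(lines)]
  grab <- function(key) {
    idx <- grep(paste0("^", key, " "), lines)
    if (length(idx) == 0) return(NA_character_)
    val <- sub(paste0("^", key, "\\s+"), "", lines[[idx[[1]]]])
    # continuation lines are indented by 12 spaces
    j <- idx[[1]] + 1L
    while (j <= length(lines) && grepl("^ {12}", lines[[j]]) &&
           !grepl("^FEATURES|^ORIGIN", lines[[j]])) {
      val <- paste(val, trimws(lines[[j]]))
      j <- j + 1L
    }
    val
  }
  version <- grab("VERSION")
  accession <- if (!is.na(version)) strsplit(version, "\\s+")[[1]][[1]] else {
    acc <- grab("ACCESSION")
    if (is.na(acc)) sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[[1]]) else
      strsplit(acc, "\\s+")[[1]][[1]]
  }
  definition <- grab("DEFINITION")
  if (is.na(definition)) definition <- ""
  definition <- sub("\\.$", "", definition)

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) != 1) {
    stop("GenBank record ", accession, ": missing ORIGIN section",
         call. = FALSE)
  }
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_at <- grep("^FEATURES", lines)
  taxid <- NA_integer_
  features <- empty_features()
  if (length(feat_at) == 1) {
    fl <- lines[(feat_at + 1L):(origin_at - 1L)]
    parsed <- parse_feature_table(fl, accession)
    taxid <- parsed$taxid
    features <- parsed$features
  }
  if (is.na(taxid)) {
    stop("GenBank record ", accession,
         ": no /db_xref=\"taxon:...\" qualifier found", call. = FALSE)
  }
  seq_record(accession, taxid, residues, definition, features)
}

parse_feature_table <- function(fl, accession) {
  key_at <- grep("^ {5}\\S", fl)
  taxid <- NA_integer_
  rows <- list()
  for (i in seq_along(key_at)) {
    from <- key_at[[i]]
    to <- if (i < length(key_at)) key_at[[i + 1L]] - 1L else length(fl)
    block <- fl[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[[1]])
    loc <- trimws(sub("^ {5}\\S+\\s*", "", block[[1]]))
    quals <- paste(trimws(block[-1]), collapse = " ")
    if (key == "source") {
      m <- regmatches(quals, regexec("/db_xref=\"taxon:([0-9]+)\"", quals))[[1]]
      if (length(m) == 2) taxid <- as.integer(m[[2]])
      next
    }
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
    if (length(m) != 3) next # joins and other operators are not supported
    lab <- regmatches(quals, regexec("/(?:gene|product)=\"([^\"]*)\"", quals))[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = if (key == "misc_feature") "misc" else key,
      start = as.integer(m[[2]]) - 1L, # to 0-based half-open
      end = as.integer(m[[3]]),
      strand = strand,
      label = if (length(lab) == 2) lab[[2]] else "",
      stringsAsFactors = FALSE
    )
  }
  list(taxid = taxid,
       features = if (length(rows) > 0) do.call(rbind, rows) else empty_features())
}

write_genbank <- function(records, path) {
  fmt_one <- function(r) {
    out <- c(
      sprintf("LOCUS       %-16s %5d bp    DNA     linear   SYN",
              sub("\\.\\d+$", "", r$accession), r$length),
      paste0("DEFINITION  ", r$definition, "."),
      paste0("ACCESSION   ", sub("\\.\\d+$", "", r$accession)),
      paste0("VERSION     ", r$accession),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", r$length),
      sprintf("                     /db_xref=\"taxon:%d\"", r$taxid)
    )
    if (nrow(r$features) > 0) {
      for (i in seq_len(nrow(r$features))) {
        f <- r$features[i, ]
        loc <- sprintf("%d..%d", f$start + 1L, f$end)
        if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
        out <- c(out,
                 sprintf("     %-15s %s", f$kind, loc),
                 sprintf("                     /gene=\"%s\"", f$label))
      }
    }
    out <- c(out, "ORIGIN")
    starts <- seq(1L, r$length, by = 60L)
    for (s in starts) {
      chunk <- substr(r$residues, s, min(s + 59L, r$length))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", s, paste(tolower(blocks), collapse = " ")))
    }
    c(out, "//")
  }
  write_lines_atomic(unlist(lapply(records, fmt_one)), path)
}

# ---- filtering, splitting, subsampling ---------------------------------

#' Partition records (or segments) by length
#'
#' @param records List of records or a segment data frame.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @return A list with elements `kept`, `too_long`, `too_short`.
#' @export
length_filter <- function(records, min_len, max_len) {
  stopifnot(min_len > 0, min_len <= max_len)
  lens <- if (is.data.frame(records)) records$length else
    vapply(records, `[[`, 0L, "length")
  pick <- function(idx) {
    if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
  }
  list(kept = pick(which(lens >= min_len & lens <= max_len)),
       too_long = pick(which(lens > max_len)),
       too_short = pick(which(lens < min_len)))
}

segment_id <- function(accession, start, end, strand = "+") {
  paste0(accession, "/", start, "-", end, ifelse(strand == "-", ":rc", ""))
}

make_segment <- function(record, start, end, strand = "+",
                         source_kind = "feature-slice") {
  res <- substr(record$residues, start + 1L, end)
  if (strand == "-") res <- reverse_complement(res)
  data.frame(
    segment_id = segment_id(record$accession, start, end, strand),
    parent_accession = record$accession,
    taxid = record$taxid,
    start = start, end = end, strand = strand,
    residues = res,
    source_kind = source_kind,
    definition = record$definition,
    length = end - start,
    stringsAsFactors = FALSE
  )
}

#' Whole-record segment
#'
#' Wraps a record as a single segment spanning its full length
#' (`source_kind = "whole"`).
#'
#' @param record A `seq_record`.
#' @return One-row segment data frame.
#' @export
whole_segment <- function(record) {
  make_segment(record, 0L, record$length, "+", source_kind = "whole")
}

#' Split an over-long record into feature-derived segments
#'
#' Records longer than `max_len` would otherwise be discarded; instead,
#' each annotated gene/CDS/rRNA feature whose span length lies within
#' `[min_len, max_len]` is sliced out as its own segment. Overlapping
#' features are deduplicated, keeping the earlier-starting (then longer)
#' span. Reverse-strand features are reverse-complemented into canonical
#' orientation and marked with an `:rc` suffix in the segment id. A record
#' with a feature span outside its bounds is considered malformed and
#' skipped entirely (with a warning); a record with no qualifying feature
#' yields an empty result.
#'
#' @param record A `seq_record` with `length > max_len`.
#' @param min_len,max_len Segment length bounds (nt).
#' @return Segment data frame (possibly 0 rows).
#' @export
split_by_features <- function(record, min_len, max_len) {
  feats <- record$features
  if (nrow(feats) == 0) return(empty_segments())
  if (any(feats$start < 0 | feats$end > record$length |
          feats$start >= feats$end)) {
    warning("record ", record$accession,
            " has a feature span outside record bounds; skipped",
            call. = FALSE)
    return(empty_segments())
  }
  feats <- feats[feats$kind %in% c("gene", "CDS", "rRNA"), , drop = FALSE]
  span <- feats$end - feats$start
  feats <- feats[span >= min_len & span <= max_len, , drop = FALSE]
  if (nrow(feats) == 0) return(empty_segments())
  # dedup overlaps: earlier-starting, then longer, wins
  feats <- feats[order(feats$start, -(feats$end - feats$start)), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(feats))) {
    overlaps <- any(feats$start[kept] < feats$end[[i]] &
                    feats$start[[i]] < feats$end[kept])
    if (!overlaps) kept <- c(kept, i)
  }
  feats <- feats[kept, , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    make_segment(record, feats$start[[i]], feats$end[[i]], feats$strand[[i]])
  }))
}

empty_segments <- function() {
  make_segment(seq_record("x.1", 0L, "A"), 0L, 1L)[0, , drop = FALSE]
}

#' Turn records into clustering-ready segments
#'
#' Records within the length bounds become whole-record segments; over-long
#' records are split by their features ([split_by_features()]); under-length
#' records are dropped. The result is ordered by segment id.
#'
#' @param records List of `seq_record`.
#' @param min_len,max_len Length bounds (nt).
#' @return Segment data frame.
#' @export
prepare_segments <- function(records, min_len = 250, max_len = 3000) {
  parts <- length_filter(records, min_len, max_len)
  whole <- lapply(parts$kept, whole_segment)
  sliced <- lapply(parts$too_long, split_by_features, min_len = min_len,
                   max_len = max_len)
  segs <- do.call(rbind, c(list(empty_segments()), whole, sliced))
  segs <- segs[order_c(segs$segment_id), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Cap the number of segments per taxon
#'
#' Taxa with more than `cap` segments (typically over-represented model
#' organisms) are reduced to a uniform random sample of size `cap`, drawn
#' from a generator seeded with `rng_seed` so the selection is
#' reproducible. Other taxa are untouched. Output order is by segment id.
#'
#' @param segments Segment data frame.
#' @param cap Maximum segments per taxid.
#' @param rng_seed Integer seed.
#' @return Segment data frame.
#' @export
subsample_per_taxon <- function(segments, cap = 100, rng_seed = 1) {
  stopifnot(cap > 0)
  if (nrow(segments) == 0) return(segments)
  keep <- with_seed(rng_seed, {
    idx <- logical(nrow(segments))
    for (t in sort_c(unique(segments$taxid))) {
      at <- which(segments$taxid == t)
      if (length(at) > cap) at <- sort(sample(at, cap))
      idx[at] <- TRUE
    }
    idx
  })
  out <- segments[keep, , drop = FALSE]
  out <- out[order_c(out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
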