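# Internal helpers shared across the pipeline.

# Locale-independent sorting (C collation) so exports and cluster ids are
# byte-identical across machines.
sort_c <- function(x, decreasing = FALSE) {
  sort(x, decreasing = decreasing, method = "radix")
}

order_c <- function(..., decreasing = FALSE) {
  order(..., decreasing = decreasing, method = "radix")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Atomic text write: temp file in the destination directory, then rename.
write_lines_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("directory does not exist: ", dir, call. = FALSE)
  }
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dir)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con, sep = "\n")
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  header <- paste(colnames(df), collapse = "\t")
  if (nrow(df) == 0) {
    return(write_lines_atomic(header, path))
  }
  cols <- lapply(df, function(x) {
    if (is.numeric(x) && !is.integer(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE) else as.character(x)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  write_lines_atomic(c(header, body), path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

# Wrap residues at `width` columns and write FASTA atomically.
write_fasta_atomic <- function(ids, seqs, path, width = 70) {
  stopifnot(length(ids) == length(seqs))
  lines <- character(0)
  if (length(ids) > 0) {
    chunks <- lapply(seq_along(ids), function(i) {
      s <- seqs[[i]]
      n <- nchar(s)
      starts <- seq(1L, n, by = width)
      c(paste0(">", ids[[i]]), substring(s, starts, pmin(starts + width - 1L, n)))
    })
    lines <- unlist(chunks, use.names = FALSE)
  }
  write_lines_atomic(lines, path)
}

reverse_complement <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
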