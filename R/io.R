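# FASTA and MAF input/output.

#' Read a FASTA file, preserving case
#'
#' Case is meaningful (lowercase marks repeat-masked regions), so
#' sequences are read as raw strings, multi-record, line-wrap and
#' CRLF agnostic.
#'
#' @param path FASTA file path.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no sequences in ", path)
  out <- as.character(set)
  # header word up to the first whitespace, the usual identifier convention
  names(out) <- sub("\\s.*$", "", names(out))
  gsub("\r", "", out, fixed = TRUE)
}

#' Write sequences to a FASTA file, preserving case
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# aligned (gapped) texts for one record from its ops path
record_texts <- function(record, qseq, rseq) {
  ops <- strsplit(record$ops, "", fixed = TRUE)[[1]]
  qchars <- strsplit(substr(qseq, record$query_start + 1L,
                            record$query_end), "", fixed = TRUE)[[1]]
  rchars <- strsplit(substr(rseq, record$ref_start + 1L,
                            record$ref_end), "", fixed = TRUE)[[1]]
  qt <- character(length(ops))
  rt <- character(length(ops))
  qi <- 0L
  ri <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] != "D") { qi <- qi + 1L; qt[i] <- qchars[qi] } else qt[i] <- "-"
    if (ops[i] != "I") { ri <- ri + 1L; rt[i] <- rchars[ri] } else rt[i] <- "-"
  }
  list(query = paste(qt, collapse = ""), ref = paste(rt, collapse = ""))
}

#' Write alignment records as MAF
#'
#' Standard MAF blocks: an `a score=` line followed by two `s` lines
#' (source, 0-based start, block size, strand, source size, gapped text),
#' reference first. Coordinates of `-` strand query rows refer to the
#' reverse-complemented query, the MAF convention.
#'
#' @param records alignment records from [align()] (`keep_ops = TRUE`).
#' @param query,ref the (masked) sequences that were aligned; named
#'   character vectors, looked up by the records' `query`/`ref` fields
#'   (a single unnamed sequence is accepted).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_maf <- function(records, query, ref, path) {
  lines <- c("##maf version=1 program=subseed")
  lookup <- function(seqs, nm) {
    if (is.null(names(seqs)) || !nm %in% names(seqs)) unname(seqs[[1]])
    else unname(seqs[[nm]])
  }
  if (nrow(records)) {
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      if (is.na(rec$ops) || !nzchar(rec$ops))
        stop("records need their ops path for MAF output (keep_ops = TRUE)")
      qseq <- lookup(query, rec$query)
      if (rec$strand == "-") qseq <- revcomp(qseq)
      rseq <- lookup(ref, rec$ref)
      tx <- record_texts(rec, qseq, rseq)
      src_w <- max(nchar(rec$ref), nchar(rec$query))
      lines <- c(lines,
        sprintf("a score=%d", rec$score),
        sprintf("s %-*s %d %d + %d %s", src_w, rec$ref, rec$ref_start,
                rec$ref_end - rec$ref_start, rec$ref_srcsize, tx$ref),
        sprintf("s %-*s %d %d %s %d %s", src_w, rec$query, rec$query_start,
                rec$query_end - rec$query_start, rec$strand,
                rec$query_srcsize, tx$query),
        "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a MAF file written by [write_maf()]
#'
#' @param path MAF path.
#' @return a data frame, one row per block: `score`, then
#'   `ref`/`ref_start`/`ref_size`/`ref_srcsize`/`ref_text` and the same
#'   for the query with its `strand`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  a_idx <- which(startsWith(lines, "a "))
  parse_s <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    list(src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
         strand = f[5], srcsize = as.integer(f[6]), text = f[7])
  }
  rows <- lapply(a_idx, function(i) {
    score <- as.integer(sub("^a score=", "", lines[i]))
    s1 <- parse_s(lines[i + 1L])
    s2 <- parse_s(lines[i + 2L])
    data.frame(score = score, ref = s1$src, ref_start = s1$start,
               ref_size = s1$size, ref_srcsize = s1$srcsize,
               ref_text = s1$text, query = s2$src, query_start = s2$start,
               query_size = s2$size, strand = s2$strand,
               query_srcsize = s2$srcsize, query_text = s2$text,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(score = integer(0), ref = character(0),
                      ref_start = integer(0), ref_size = integer(0),
                      ref_srcsize = integer(0), ref_text = character(0),
                      query = character(0), query_start = integer(0),
                      query_size = integer(0), strand = character(0),
                      query_srcsize = integer(0), query_text = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
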