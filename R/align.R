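# Gapless and gapped X-drop extension, and the seed-and-extend pipeline.

#' Default gapless score threshold
#'
#' The score a gapless extension must reach before gapped extension is
#' attempted. The default rule is `d = round(t_scale * log(m * r / (10 * n)))`
#' where `m` is the rareness threshold, `n` the number of seed patterns,
#' `r` the number of unmasked bases in the reference and `t_scale` the
#' scale factor of the score matrix; it crudely keeps the number of
#' gapped-phase candidates proportional to the gapless-phase work.
#'
#' @param m rareness threshold (positive).
#' @param n number of seed patterns (positive).
#' @param r number of unmasked reference bases (positive).
#' @param t_scale score-matrix scale factor (positive).
#' @return the rounded threshold `d`.
#' @examples
#' default_gapless_threshold(1000, 1, 1363595724, 96.1735)  # 2466
#' default_gapless_threshold(10, 8, 1363595724, 96.1735)    # 1823
#' @export
default_gapless_threshold <- function(m, n, r, t_scale) {
  if (any(c(m, n, r, t_scale) <= 0))
    stop("all of m, n, r, t_scale must be positive")
  round(t_scale * log(m * r / (10 * n)))
}

#' Gapless X-drop extension from a seed
#'
#' Extends along the diagonal through the seed's first column, left then
#' right; each direction stops once the running score drops more than `y`
#' below its maximum and is trimmed back to the maximum. The returned
#' segment's `anchor_*` fields give the column achieving the maximal
#' running score (leftmost on ties), which is where gapped extension
#' restarts.
#'
#' @param query,ref (masked) sequences.
#' @param seed a list or one-row data frame with `query_pos` and `ref_pos`
#'   (0-based), e.g. a row of [adaptive_seeds()] output.
#' @param scheme a [scoring_scheme()] or scheme name.
#' @param y gapless score-drop limit; default the scheme's.
#' @return a `gapless_alignment`: `query_start`, `ref_start`, `length`,
#'   `score`, `anchor_query`, `anchor_ref` (0-based).
#' @export
gapless_extend <- function(query, ref, seed, scheme = last_scheme(),
                           y = NULL) {
  scheme <- get_scheme(scheme)
  if (is.null(y)) y <- scheme$gapless_drop
  stopifnot(y >= 0)
  res <- gapless_extend_cpp(seq_to_codes(query), seq_to_codes(ref),
                            as.integer(seed$query_pos),
                            as.integer(seed$ref_pos),
                            scheme$submat5, as.integer(y))
  structure(res, class = "gapless_alignment")
}

#' Gapped X-drop extension from an anchor column
#'
#' Affine-gap X-drop dynamic programming in both directions from the
#' anchor (the gapless alignment's maximal-score column). Adjacent
#' insertions and deletions are permitted. Cells are pruned once their
#' score falls more than `ydrop` below the best seen.
#'
#' @inheritParams gapless_extend
#' @param anchor a `gapless_alignment`, or a list with `anchor_query` and
#'   `anchor_ref` (0-based column indices).
#' @param ydrop gapped score-drop limit; default `min_score - 1`.
#' @return a one-row alignment record data frame (see [align()]), with
#'   strand `"+"`.
#' @export
gapped_extend <- function(query, ref, anchor, scheme = last_scheme(),
                          ydrop = NULL) {
  scheme <- get_scheme(scheme)
  if (is.null(ydrop)) ydrop <- scheme$min_score - 1L
  stopifnot(ydrop >= 0)
  res <- gapped_extend_cpp(seq_to_codes(query), seq_to_codes(ref),
                           as.integer(anchor$anchor_query),
                           as.integer(anchor$anchor_ref),
                           scheme$submat5, scheme$gap_exist,
                           scheme$gap_extend, as.integer(ydrop))
  data.frame(query = "query", ref = "ref", strand = "+",
             score = res$score, query_start = res$query_start,
             query_end = res$query_end, ref_start = res$ref_start,
             ref_end = res$ref_end, query_srcsize = nchar(query),
             ref_srcsize = nchar(ref), ops = res$ops,
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local alignment of a query against indexed references
#'
#' The full pipeline, run for both query strands by default: adaptive
#' seeds from every index, gapless X-drop extension (threshold `d`),
#' gapped X-drop extension from each distinct anchor, and reporting of
#' records with score at least the scheme's `min_score`. Exact duplicate
#' records are merged; records are sorted by score, descending.
#'
#' For `"-"` strand records, query coordinates refer to the
#' reverse-complemented query (the usual MAF convention); `query_srcsize`
#' allows conversion.
#'
#' @param query a single (masked) query sequence; see [mask_lowercase()].
#' @param indexes a `subset_index` or list of them, all built from the
#'   same reference.
#' @param scheme a [scoring_scheme()] or scheme name.
#' @param m rareness threshold for adaptive seeds (default 10).
#' @param k query seeding step (default 1).
#' @param y gapless score-drop limit; default the scheme's.
#' @param d gapless score threshold; default
#'   [default_gapless_threshold()] when the scheme has a `t_scale`,
#'   otherwise the scheme's `min_score`.
#' @param ydrop gapped score-drop limit; default `min_score - 1`.
#' @param strand `"both"` (default), `"forward"` or `"reverse"`.
#' @param query_name name used in output records.
#' @param keep_ops record the column-level alignment path (needed for MAF
#'   output and rescoring; default `TRUE`).
#' @return a data frame of alignment records with columns `query`, `ref`,
#'   `strand`, `score`, `query_start`, `query_end`, `ref_start`,
#'   `ref_end` (0-based half-open), `query_srcsize`, `ref_srcsize`, `ops`
#'   (per-column path over `M`, `I` = query-only, `D` = reference-only).
#' @export
align <- function(query, indexes, scheme = last_scheme(), m = 10L, k = 1L,
                  y = NULL, d = NULL, ydrop = NULL, strand = "both",
                  query_name = NULL, keep_ops = TRUE) {
  scheme <- get_scheme(scheme)
  if (inherits(indexes, "subset_index")) indexes <- list(indexes)
  stopifnot(length(indexes) >= 1L,
            all(vapply(indexes, inherits, logical(1), "subset_index")))
  ref <- indexes[[1L]]$ref
  for (ix in indexes)
    if (!identical(ix$ref, ref))
      stop("all indexes must be built from the same reference")
  if (is.null(y)) y <- scheme$gapless_drop
  if (is.null(ydrop)) ydrop <- scheme$min_score - 1L
  if (is.null(d)) {
    d <- if (!is.null(scheme$t_scale)) {
      r_unmasked <- nchar(ref) - lengths(regmatches(ref, gregexpr("N", ref)))
      max(scheme$min_score,
          default_gapless_threshold(m, length(indexes), max(1, r_unmasked),
                                    scheme$t_scale))
    } else scheme$min_score
  }
  strand <- match.arg(strand, c("both", "forward", "reverse"))
  if (is.null(query_name)) query_name <- names(query) %||% "query"
  query <- unname(query)

  ref_codes <- indexes[[1L]]$ref_codes %||% seq_to_codes(ref)
  sas <- lapply(indexes, `[[`, "sa")
  pats <- lapply(indexes, function(ix) pattern_codes(ix$pattern))
  maxdepth <- min(vapply(indexes, `[[`, integer(1), "max_depth"))

  run_strand <- function(qseq, st) {
    recs <- align_core_cpp(seq_to_codes(qseq), ref_codes, sas, pats,
                           as.integer(m), as.integer(k), as.integer(y),
                           as.integer(d), as.integer(ydrop), scheme$submat5,
                           scheme$gap_exist, scheme$gap_extend,
                           scheme$min_score, as.integer(maxdepth),
                           isTRUE(keep_ops))
    if (!nrow(recs)) return(NULL)
    data.frame(query = query_name, ref = indexes[[1L]]$ref_name,
               strand = st, score = recs$score,
               query_start = recs$query_start, query_end = recs$query_end,
               ref_start = recs$ref_start, ref_end = recs$ref_end,
               query_srcsize = nchar(qseq), ref_srcsize = nchar(ref),
               ops = recs$ops, stringsAsFactors = FALSE)
  }
  out <- list()
  if (strand %in% c("both", "forward")) out$fwd <- run_strand(query, "+")
  if (strand %in% c("both", "reverse"))
    out$rev <- run_strand(revcomp(query), "-")
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty_records())
  # sort first so coordinate-duplicate merging keeps the best-scoring path
  out <- out[order(-out$score, out$ref_start, out$query_start), ,
             drop = FALSE]
  key <- paste(out$strand, out$query_start, out$query_end, out$ref_start,
               out$ref_end)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(query = character(0), ref = character(0), strand = character(0),
             score = integer(0), query_start = integer(0),
             query_end = integer(0), ref_start = integer(0),
             ref_end = integer(0), query_srcsize = integer(0),
             ref_srcsize = integer(0), ops = character(0),
             stringsAsFactors = FALSE)
}

#' Recompute a record's score from its column path
#'
#' Self-consistency check: walks the record's `ops` over the actual
#' sequences and re-adds substitution scores and affine gap costs.
#'
#' @param record a one-row alignment record (as returned by [align()]).
#' @param query,ref the (masked) sequences the record refers to. For a
#'   `"-"` strand record pass the original query; it is
#'   reverse-complemented internally.
#' @param scheme the scoring scheme used.
#' @return the recomputed integer score.
#' @export
rescore_record <- function(record, query, ref, scheme = last_scheme()) {
  scheme <- get_scheme(scheme)
  qseq <- if (record$strand == "-") revcomp(query) else unname(query)
  qc <- seq_to_codes(qseq)
  rc <- seq_to_codes(unname(ref))
  ops <- strsplit(record$ops, "", fixed = TRUE)[[1]]
  qi <- record$query_start
  ri <- record$ref_start
  S <- scheme$submat5
  score <- 0L
  prev <- "M"
  for (op in ops) {
    if (op == "M") {
      score <- score + S[qc[qi + 1L] + 1L, rc[ri + 1L] + 1L]
      qi <- qi + 1L
      ri <- ri + 1L
    } else {
      # each maximal run of same-direction gap columns is one affine gap;
      # an I run abutting a D run opens a second gap
      if (op != prev) score <- score - scheme$gap_exist
      score <- score - scheme$gap_extend
      if (op == "I") qi <- qi + 1L else ri <- ri + 1L
    }
    prev <- op
  }
  if (qi != record$query_end || ri != record$ref_end)
    stop("ops path does not reach the record end coordinates")
  score
}
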