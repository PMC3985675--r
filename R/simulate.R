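# Synthetic related-genome-pair generator and substitution counting.

#' Simulate a pair of related genomes with a known alignment
#'
#' Generates an ancestor sequence (i.i.d. uniform ACGT), optionally
#' implants self-similar lowercase-masked repeat tracts (segments copied
#' from elsewhere in the ancestor), then derives a second genome under an
#' i.i.d. column model: per aligned column the identity is `identity`, a
#' substitution is a transition with odds `ts_tv_ratio : 1` against a
#' transversion, and indels occur at rate `indel_rate` per ancestor
#' position with geometric lengths of mean `indel_length_mean`. The true
#' column-level alignment is recorded during simulation, so downstream
#' substitution counting does not depend on re-alignment.
#'
#' Defaults emulate the human-mouse regime: 70% identity with a 3:2
#' transition:transversion ratio (so aligned columns are 70% identities,
#' 18% transitions, 12% transversions).
#'
#' @param genome_length ancestor length in bases.
#' @param identity per-column probability of an identical base (default
#'   0.70).
#' @param ts_tv_ratio transition:transversion probability ratio among
#'   substituted columns (default 1.5, i.e. 3:2; 1 gives 1:1).
#' @param indel_rate per-ancestor-position probability of an indel event
#'   (default 0.02).
#' @param indel_length_mean mean indel length in bases (default 3).
#' @param repeat_fraction fraction of the ancestor covered by implanted
#'   lowercase repeat tracts (default 0).
#' @param rng_seed optional integer seed for reproducibility.
#' @return a `genome_pair`: `ancestor` and `derived` sequences (lowercase
#'   marks repeats), `alignment` (the two gapped rows of the true
#'   alignment), `intervals` (0-based half-open homologous blocks between
#'   indels: `anc_start`, `anc_end`, `der_start`, `der_end`) and `params`.
#' @export
synth_genome_pair <- function(genome_length, identity = 0.70,
                              ts_tv_ratio = 1.5, indel_rate = 0.02,
                              indel_length_mean = 3,
                              repeat_fraction = 0, rng_seed = NULL) {
  stopifnot(genome_length >= 1, identity >= 0, identity <= 1,
            ts_tv_ratio > 0, indel_rate >= 0, indel_rate < 1,
            indel_length_mean >= 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- as.integer(genome_length)
  anc <- sample(0:3, L, replace = TRUE)
  lower <- rep(FALSE, L)
  if (repeat_fraction > 0 && L >= 20L) {
    target <- repeat_fraction * L
    while (sum(lower) < target) {
      len <- min(L %/% 2L, 20L + stats::rgeom(1L, 1 / 280))
      src <- sample.int(L - len + 1L, 1L)
      dst <- sample.int(L - len + 1L, 1L)
      anc[dst:(dst + len - 1L)] <- anc[src:(src + len - 1L)]
      lower[dst:(dst + len - 1L)] <- TRUE
    }
  }
  ts_frac <- ts_tv_ratio / (1 + ts_tv_ratio)
  rows <- mutate_genome_cpp(anc, 1 - identity, ts_frac, indel_rate,
                            indel_length_mean)
  ga <- rows$ancestor_row
  gd <- rows$derived_row

  # carry lowercase repeat masking through the alignment: a derived char is
  # lowercase iff its aligned ancestor char is lowercase; insertions stay
  # uppercase
  ar <- charToRaw(ga)
  dr <- charToRaw(gd)
  gap <- charToRaw("-")[1]
  anc_cols <- ar != gap
  if (any(lower)) {
    low_cols <- logical(length(ar))
    low_cols[anc_cols] <- lower
    idx <- low_cols & dr != gap
    dr[idx] <- as.raw(as.integer(dr[idx]) + 32L)  # tolower
    idx_a <- low_cols
    ar[idx_a] <- as.raw(as.integer(ar[idx_a]) + 32L)
    ga <- rawToChar(ar)
    gd <- rawToChar(dr)
  }
  ancestor <- gsub("-", "", ga, fixed = TRUE)
  derived <- gsub("-", "", gd, fixed = TRUE)

  # homologous blocks: maximal runs of columns with no gap in either row
  both <- anc_cols & dr != gap
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  apos <- cumsum(anc_cols)      # ancestor coordinate after each column
  dpos <- cumsum(dr != gap)
  keep <- r$values
  intervals <- data.frame(
    anc_start = apos[starts[keep]] - 1L, anc_end = apos[ends[keep]],
    der_start = dpos[starts[keep]] - 1L, der_end = dpos[ends[keep]])
  structure(
    list(ancestor = ancestor, derived = derived,
         alignment = list(ancestor_row = ga, derived_row = gd),
         intervals = intervals,
         params = list(genome_length = L, identity = identity,
                       ts_tv_ratio = ts_tv_ratio, indel_rate = indel_rate,
                       indel_length_mean = indel_length_mean,
                       repeat_fraction = repeat_fraction,
                       rng_seed = rng_seed)),
    class = "genome_pair"
  )
}

#' @export
print.genome_pair <- function(x, ...) {
  p <- x$params
  cat("synthetic genome pair: ", p$genome_length, " bp ancestor, identity ",
      p$identity, ", ts:tv ", p$ts_tv_ratio, ":1, indel rate ",
      p$indel_rate, ", ", nrow(x$intervals), " homologous block(s)\n",
      sep = "")
  invisible(x)
}

#' Sample random chunks from a genome
#'
#' Uniformly random, non-duplicated start positions; a chunk is rejected
#' and redrawn if it contains any uppercase letter other than A, C, G, T
#' (lowercase repeat letters are allowed and masked later).
#'
#' @param genome a single sequence (case-sensitive).
#' @param count number of chunks.
#' @param length chunk length in bases (default 1000).
#' @param rng_seed optional integer seed.
#' @param max_tries rejection budget (default `100 * count`); exceeding it
#'   (e.g. an N-rich genome) is an error.
#' @return a named character vector of `count` chunks (`chunk<i>_<start>`,
#'   0-based start).
#' @export
sample_chunks <- function(genome, count, length = 1000L, rng_seed = NULL,
                          max_tries = 100L * count) {
  stopifnot(is.character(genome), base::length(genome) == 1L)
  L <- nchar(genome)
  if (L <= length) stop("genome shorter than the chunk length")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  chunks <- character(0)
  starts <- integer(0)
  used <- integer(0)
  tries <- 0L
  while (base::length(chunks) < count) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("rejection budget exhausted after ", max_tries,
           " tries (genome too N-rich?)")
    s <- sample.int(L - length + 1L, 1L)
    if (s %in% used) next
    used <- c(used, s)
    chunk <- substr(genome, s, s + length - 1L)
    if (grepl("[^ACGT]", gsub("[a-z]", "", chunk))) next
    chunks <- c(chunks, chunk)
    starts <- c(starts, s - 1L)
  }
  names(chunks) <- sprintf("chunk%d_%d", seq_along(chunks), starts)
  chunks
}

#' Count identities, transitions and transversions in aligned columns
#'
#' Takes the two rows of a (gapped) pairwise alignment and classifies
#' every column where both letters are in `{A, C, G, T}` (case folded;
#' gaps and N excluded from the denominator). Transitions are `A<->G` and
#' `C<->T`; every other mismatch is a transversion.
#'
#' @param row1,row2 equal-length alignment rows (strings, `-` for gaps).
#' @return named percentages `c(identity=, transition=, transversion=)`.
#' @examples
#' count_substitutions("ACGT", "GCGT")  # 75% identity, 25% transition
#' @export
count_substitutions <- function(row1, row2) {
  stopifnot(nchar(row1) == nchar(row2))
  a <- charToRaw(toupper(row1))
  b <- charToRaw(toupper(row2))
  acgt <- charToRaw("ACGT")
  ok <- (a %in% acgt) & (b %in% acgt)
  if (!any(ok)) stop("no aligned ACGT/ACGT columns to classify")
  a <- a[ok]
  b <- b[ok]
  ident <- a == b
  pur <- charToRaw("AG")
  pyr <- charToRaw("CT")
  transition <- !ident & (((a %in% pur) & (b %in% pur)) |
                          ((a %in% pyr) & (b %in% pyr)))
  n <- length(a)
  c(identity = 100 * sum(ident) / n,
    transition = 100 * sum(transition) / n,
    transversion = 100 * sum(!ident & !transition) / n)
}
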