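# Seed patterns over the alphabet {0, T, 1}.
#
# '1' positions accept only match letters, 'T' positions accept transitions
# and matches, '0' positions accept anything. The weight is the number of
# '1's plus half the number of 'T's; it is stored exactly as twice-weight
# (an integer) so equal-weight comparisons never hit floating point.

new_seed_pattern <- function(text) {
  syms <- strsplit(text, "", fixed = TRUE)[[1]]
  twice <- 2L * sum(syms == "1") + sum(syms == "T")
  structure(
    list(text = text, span = length(syms), weight = twice / 2,
         twice_weight = twice),
    class = "seed_pattern"
  )
}

#' Parse a seed pattern string
#'
#' A seed pattern is a string over `{0, T, 1}`: `1` accepts only match
#' letters, `T` accepts transitions and matches, `0` accepts any letter.
#' Its *span* is the number of symbols and its *weight* is the number of
#' `1`s plus half the number of `T`s. Only uppercase `T` is accepted.
#'
#' @param text a non-empty string over `{0, T, 1}`.
#' @return a `seed_pattern` object with fields `text`, `span`, `weight`
#'   and `twice_weight`.
#' @examples
#' p <- parse_pattern("11101011")
#' p$weight  # 6
#' parse_pattern("11T0TT010T")$weight  # 5
#' @export
parse_pattern <- function(text) {
  if (inherits(text, "seed_pattern")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text) || nchar(text) == 0L)
    stop("seed pattern must be a single non-empty string")
  syms <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(syms), c("0", "T", "1"))
  if (length(bad))
    stop("invalid seed pattern symbol(s): ", paste(bad, collapse = ", "),
         " (allowed: 0, T, 1)")
  if (syms[1L] == "0" || syms[length(syms)] == "0")
    warning("seed pattern '", text, "' begins or ends with '0'")
  new_seed_pattern(text)
}

#' @export
format.seed_pattern <- function(x, ...) x$text

#' @export
as.character.seed_pattern <- function(x, ...) x$text

#' @export
print.seed_pattern <- function(x, ...) {
  cat("seed pattern ", x$text, " (span ", x$span, ", weight ",
      format(x$weight), ")\n", sep = "")
  invisible(x)
}

# integer symbol codes used by the C++ kernels: '0'=0, 'T'=1, '1'=2
pattern_codes <- function(p) {
  p <- parse_pattern(p)
  match(strsplit(p$text, "", fixed = TRUE)[[1]], c("0", "T", "1")) - 1L
}

#' Cyclically extend a seed pattern
#'
#' Repeats the pattern to infinite length (`110T -> 110T110T...`) and
#' returns the first `length` symbols. This is how a finite pattern is
#' applied at arbitrary depth during adaptive seeding.
#'
#' @param p a seed pattern (object or string).
#' @param length target span, at least 1.
#' @return a `seed_pattern` of span `length`.
#' @examples
#' as.character(cyclic_extend("110T", 12))  # "110T110T110T"
#' @export
cyclic_extend <- function(p, length) {
  p <- parse_pattern(p)
  if (!is.numeric(length) || length < 1)
    stop("length must be >= 1")
  length <- as.integer(length)
  reps <- strrep(p$text, ceiling(length / p$span))
  new_seed_pattern(substr(reps, 1L, length))
}

#' Trim a pattern to its shortest cyclic prefix
#'
#' Returns the shortest prefix `q` of `p` such that cyclically extending
#' `q` to the span of `p` recovers `p`. Idempotent. Used because patterns
#' are applied by cyclic extension, so only this prefix matters.
#'
#' @param p a seed pattern (object or string).
#' @return a `seed_pattern`.
#' @examples
#' as.character(trim_to_cyclic_prefix("11011"))  # "110"
#' @export
trim_to_cyclic_prefix <- function(p) {
  p <- parse_pattern(p)
  for (len in seq_len(p$span)) {
    q <- new_seed_pattern(substr(p$text, 1L, len))
    if (as.character(cyclic_extend(q, p$span)) == p$text)
      return(q)
  }
  p  # unreachable: len == span always regenerates p
}

# ---- seed sets --------------------------------------------------------------

#' Construct a seed set
#'
#' @param patterns a character vector of pattern strings, or a list of
#'   `seed_pattern` objects. Must be non-empty.
#' @return a `seed_set`: a list with `patterns` (list of `seed_pattern`)
#'   and `n`.
#' @examples
#' seed_set(c("1T1", "11T"))
#' @export
seed_set <- function(patterns) {
  if (inherits(patterns, "seed_set")) return(patterns)
  if (inherits(patterns, "seed_pattern")) patterns <- list(patterns)
  if (length(patterns) < 1L) stop("a seed set needs at least one pattern")
  pats <- lapply(patterns, parse_pattern)
  structure(list(patterns = pats, n = length(pats)), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed set of ", x$n, " pattern(s):\n", sep = "")
  for (p in x$patterns)
    cat("  ", p$text, " (span ", p$span, ", weight ", format(p$weight),
        ")\n", sep = "")
  invisible(x)
}

seed_set_codes <- function(s) lapply(seed_set(s)$patterns, pattern_codes)

#' Read or write seed sets as plain text
#'
#' One pattern per line; blank lines and lines starting with `#` ignored.
#'
#' @param path file path.
#' @return `read_seed_file` returns a `seed_set`.
#' @export
read_seed_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no seed patterns in ", path)
  seed_set(lines)
}

#' @param seeds a `seed_set` (or coercible).
#' @param header optional comment line(s) written before the patterns.
#' @rdname read_seed_file
#' @export
write_seed_file <- function(seeds, path, header = NULL) {
  seeds <- seed_set(seeds)
  lines <- vapply(seeds$patterns, function(p) p$text, character(1))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

# ---- direct matching semantics ---------------------------------------------

#' Does a seed set hit a gapless alignment?
#'
#' Direct (non-automaton) implementation of the matching semantics: pattern
#' symbol `0` accepts any alignment letter, `T` accepts transition and
#' match letters, `1` accepts only match letters. A hit at offset `i`
#' (0-based) counts only if `i %% sparsity == 0`.
#'
#' @param seeds a `seed_set` (or character vector of patterns).
#' @param letters alignment letters: a character vector over `"v"`
#'   (transversion), `"t"` (transition), `"m"` (match).
#' @param sparsity hit offsets restricted to multiples of this (default 1).
#' @return `TRUE` iff some pattern matches at some allowed offset.
#' @examples
#' seed_hits_alignment("1T", c("m", "t"))        # TRUE
#' seed_hits_alignment("11", c("m", "v", "m"))   # FALSE
#' @export
seed_hits_alignment <- function(seeds, letters, sparsity = 1L) {
  stopifnot(sparsity >= 1L)
  lc <- aln_letter_codes(letters)
  l <- length(lc)
  for (pc in seed_set_codes(seeds)) {
    s <- length(pc)
    if (s > l) next
    for (i in seq(0L, l - s, by = sparsity)) {
      if (all(lc[(i + 1L):(i + s)] >= pc)) return(TRUE)
    }
  }
  FALSE
}
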