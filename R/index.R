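# Subset suffix arrays and adaptive seeds.

#' Mask a sequence for indexing and alignment
#'
#' Replaces every lowercase letter (repeat-masked regions) and every
#' uppercase letter other than A, C, G, T with `N`, so masked and ambiguous
#' positions can neither seed nor be distinguished during extension.
#'
#' @param seq a character vector of sequences (names preserved).
#' @return the masked sequences, over `{A, C, G, T, N}` only.
#' @examples
#' mask_lowercase("acgT")  # "NNNT"
#' @export
mask_lowercase <- function(seq) {
  out <- gsub("[^ACGT]", "N", seq)
  names(out) <- names(seq)
  out
}

#' Build a subset suffix array for one seed pattern
#'
#' Indexes every `step`-th position of the (masked) reference and sorts the
#' sampled suffixes under the position-dependent letter classes of the
#' cyclically extended pattern: at a `1` position the four bases are
#' distinct, at a `T` position purines and pyrimidines form two classes
#' (`A == G`, `C == T`), at a `0` position all bases are one class. `N`
#' acts as a terminator that ends comparison. Positions whose first
#' transformed letter is `N` are not indexed.
#'
#' @param ref a single (masked) reference sequence; see [mask_lowercase()].
#' @param pattern the seed pattern (cyclically extended on demand).
#' @param step index every `step`-th position (sparse reference seeding),
#'   default 1.
#' @param max_depth comparison depth cap (default 512; adaptive seeds
#'   terminate far earlier at any realistic rareness threshold).
#' @param ref_name optional reference name (used in alignment output).
#' @return a `subset_index` holding the suffix array (0-based positions),
#'   the pattern, `step`, and the reference it was built from.
#' @export
build_index <- function(ref, pattern, step = 1L, max_depth = 512L,
                        ref_name = NULL) {
  stopifnot(is.character(ref), length(ref) == 1L, step >= 1L)
  if (nchar(ref) == 0L) stop("empty reference")
  pattern <- parse_pattern(pattern)
  codes <- seq_to_codes(ref)
  sa <- build_subset_sa_cpp(codes, pattern_codes(pattern),
                            as.integer(step), as.integer(max_depth))
  if (is.null(ref_name)) ref_name <- names(ref) %||% "ref"
  structure(
    list(sa = sa, pattern = pattern, step = as.integer(step),
         max_depth = as.integer(max_depth), ref = unname(ref),
         ref_codes = codes, ref_name = ref_name, ref_length = nchar(ref)),
    class = "subset_index"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subset_index <- function(x, ...) {
  cat("subset suffix index: pattern ", x$pattern$text, ", step ", x$step,
      ", ", length(x$sa), " indexed positions over ", x$ref_length,
      " bases ('", x$ref_name, "')\n", sep = "")
  invisible(x)
}

#' Find adaptive seeds for a query
#'
#' From each query start position `q` with `q %% k == 0`, finds the
#' shortest prefix of the (cyclically extended) pattern-transformed query
#' that occurs at most `m` times among the indexed reference positions,
#' and emits every occurrence at that minimal length. If the classes
#' diverge, an `N` is reached, or the count never drops to `m` or below,
#' no seed is emitted from that start.
#'
#' @param query a single (masked) query sequence.
#' @param index a `subset_index` from [build_index()].
#' @param m rareness threshold: maximum occurrence count (default 10).
#' @param k query seeding step (sparse query seeding), default 1.
#' @return a data frame with 0-based columns `query_pos`, `ref_pos`,
#'   `length`.
#' @export
adaptive_seeds <- function(query, index, m = 10L, k = 1L) {
  stopifnot(inherits(index, "subset_index"), m >= 1L, k >= 1L)
  qm <- adaptive_seeds_cpp(seq_to_codes(query),
                           index$ref_codes %||% seq_to_codes(index$ref),
                           index$sa, pattern_codes(index$pattern),
                           as.integer(m), as.integer(k), index$max_depth)
  as.data.frame(qm)
}

#' Persist a subset index as a JSON sidecar
#'
#' Stores the suffix-array positions plus metadata (pattern, step, reference
#' name/length and a content checksum) so an index can be rebuilt-checked
#' and reloaded without re-sorting. The reference sequence itself is not
#' stored; supply it again when reading.
#'
#' @param index a `subset_index`.
#' @param path output path.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "subset_index"))
  obj <- list(pattern = index$pattern$text, step = index$step,
              max_depth = index$max_depth, ref_name = index$ref_name,
              ref_length = index$ref_length,
              ref_checksum = .seq_checksum(index$ref), sa = index$sa)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @param ref the reference sequence the index was built from (checked
#'   against the stored checksum).
#' @rdname write_index
#' @export
read_index <- function(path, ref) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(.seq_checksum(unname(ref)), obj$ref_checksum))
    stop("reference does not match the checksum stored in ", path)
  structure(
    list(sa = as.integer(obj$sa), pattern = parse_pattern(obj$pattern),
         step = as.integer(obj$step), max_depth = as.integer(obj$max_depth),
         ref = unname(ref), ref_codes = seq_to_codes(unname(ref)),
         ref_name = obj$ref_name, ref_length = as.integer(obj$ref_length)),
    class = "subset_index"
  )
}

# cheap order-sensitive content checksum (no digest dependency)
.seq_checksum <- function(s) {
  v <- as.numeric(utf8ToInt(s))
  w <- (seq_along(v) %% 9973) + 1
  sprintf("%d-%.0f-%.0f", length(v), sum(v), sum(v * w) %% 2^40)
}
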