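# Chunk-based sensitivity benchmark: for each chunk record the best
# alignment score under every configuration; a configuration's error count
# is the number of chunks where it missed the best score seen by any
# configuration.

#' Describe one alignment configuration for the benchmark
#'
#' @param label configuration name (used in result tables).
#' @param seeds a `seed_set` (or character vector of patterns).
#' @param m rareness threshold.
#' @param k query seeding step.
#' @param scheme a [scoring_scheme()] or scheme name.
#' @param y,d,ydrop extension parameters (defaults as in [align()]).
#' @param step reference index sampling step.
#' @return an `align_config` list.
#' @export
align_config <- function(label, seeds, m = 10L, k = 1L,
                         scheme = last_scheme(), y = NULL, d = NULL,
                         ydrop = NULL, step = 1L) {
  structure(list(label = label, seeds = seed_set(seeds), m = as.integer(m),
                 k = as.integer(k), scheme = get_scheme(scheme), y = y,
                 d = d, ydrop = ydrop, step = as.integer(step)),
            class = "align_config")
}

#' Run the chunk benchmark over a grid of configurations
#'
#' Masks the chunks and the target genome ([mask_lowercase()]), aligns
#' every chunk under every configuration, records each configuration's
#' best score per chunk, takes the per-chunk maximum over all
#' configurations, and counts, per configuration, the chunks where it
#' failed to reach that maximum. Wall time per configuration is recorded
#' but is hardware-dependent and never part of any correctness check.
#'
#' @param chunks named character vector of query chunks (case-sensitive,
#'   e.g. from [sample_chunks()]).
#' @param genome the target genome (case-sensitive).
#' @param configs a list of [align_config()]s.
#' @param strand passed to [align()] (default `"both"`).
#' @return a `benchmark_result`: `scores` (long data frame: `config`,
#'   `chunk`, `score`), `summary` (`config`, `errors`, `seconds`), and
#'   `best` (per-chunk maximum).
#' @export
run_benchmark <- function(chunks, genome, configs, strand = "both") {
  stopifnot(length(configs) >= 1L, length(chunks) >= 1L)
  labels <- vapply(configs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("config labels must be unique")
  genome_m <- mask_lowercase(unname(genome))
  chunks_m <- mask_lowercase(chunks)

  # share indexes across configs that use the same (pattern, step)
  index_cache <- new.env(parent = emptyenv())
  get_index <- function(pattern, step) {
    key <- paste0(pattern$text, "@", step)
    if (is.null(index_cache[[key]]))
      index_cache[[key]] <- build_index(genome_m, pattern, step = step,
                                        ref_name = "target")
    index_cache[[key]]
  }

  scores <- matrix(0L, nrow = length(chunks), ncol = length(configs),
                   dimnames = list(names(chunks), labels))
  seconds <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    idx <- lapply(cfg$seeds$patterns, get_index, step = cfg$step)
    t0 <- proc.time()[["elapsed"]]
    for (qi in seq_along(chunks_m)) {
      recs <- align(chunks_m[[qi]], idx, scheme = cfg$scheme, m = cfg$m,
                    k = cfg$k, y = cfg$y, d = cfg$d, ydrop = cfg$ydrop,
                    strand = strand, query_name = names(chunks)[qi],
                    keep_ops = FALSE)
      scores[qi, ci] <- if (nrow(recs)) max(recs$score) else 0L
    }
    seconds[ci] <- proc.time()[["elapsed"]] - t0
  }
  best <- apply(scores, 1L, max)
  errors <- colSums(scores < best)
  structure(
    list(scores = data.frame(config = rep(labels, each = length(chunks)),
                             chunk = rep(names(chunks), length(configs)),
                             score = as.vector(scores),
                             stringsAsFactors = FALSE),
         summary = data.frame(config = labels, errors = as.integer(errors),
                              seconds = round(seconds, 3),
                              stringsAsFactors = FALSE),
         best = best),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  nchunk <- length(x$best)
  cat("chunk benchmark: ", nchunk, " chunks, ", nrow(x$summary),
      " configuration(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Error counts from per-chunk score tables
#'
#' The benchmark's counting rule on its own: given a chunk x config score
#' matrix, the per-chunk best is the row maximum and a configuration's
#' error count is the number of chunks where it scored below that best.
#'
#' @param scores numeric matrix, chunks in rows, configurations in columns.
#' @return named integer vector of error counts per configuration.
#' @export
count_benchmark_errors <- function(scores) {
  stopifnot(is.matrix(scores))
  best <- apply(scores, 1L, max)
  colSums(scores < best)
}
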