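# Hill-climbing co-design of seed patterns of fixed weight.

#' Draw a random seed pattern of given weight and span
#'
#' Picks a feasible count of `T` symbols uniformly (any `kT` with
#' `k1 = weight - kT/2` a non-negative integer and `k1 + kT <= span`),
#' then places the symbols uniformly at random, forcing the first and last
#' symbol to be non-`0` whenever at least two non-`0` symbols exist.
#'
#' @param weight target weight (half-integers allowed).
#' @param span pattern span; `weight <= span`.
#' @return a `seed_pattern`. Deterministic under `set.seed()`.
#' @export
random_pattern <- function(weight, span) {
  twice <- as.integer(round(2 * weight))
  if (abs(2 * weight - twice) > 1e-9) stop("weight must be a half-integer")
  if (weight < 0 || weight > span) stop("need 0 <= weight <= span")
  # feasible T counts: same parity as twice-weight, k1 >= 0, k1 + kT <= span
  kT_max <- min(twice, 2L * span - twice)
  if (kT_max < twice %% 2L) stop("infeasible weight/span combination")
  kT_opts <- seq.int(twice %% 2L, kT_max, by = 2L)
  kT <- if (length(kT_opts) == 1L) kT_opts else sample(kT_opts, 1L)
  k1 <- (twice - kT) %/% 2L
  syms <- c(rep("1", k1), rep("T", kT), rep("0", span - k1 - kT))
  nz <- k1 + kT
  if (span == 1L || nz == 0L) {
    syms <- sample(syms)
  } else if (nz == 1L) {
    mid <- sample(syms[syms == "0"])
    syms <- c(syms[syms != "0"], mid)
  } else {
    nz_syms <- sample(syms[syms != "0"])
    mid <- c(nz_syms[-(1:2)], syms[syms == "0"])
    if (length(mid) > 1L) mid <- sample(mid)
    syms <- c(nz_syms[1L], mid, nz_syms[2L])
  }
  new_seed_pattern(paste(syms, collapse = ""))
}

#' Weight-preserving neighborhood of a seed pattern
#'
#' Local moves used by the hill climber, all preserving weight and span:
#' swapping two unequal symbols; turning one `1` plus one `0` into two
#' `T`s; turning two `T`s into one `1` plus one `0` (both orientations).
#'
#' @param p a seed pattern (object or string).
#' @return a character vector of distinct neighbor pattern strings, not
#'   including `p` itself.
#' @export
pattern_neighbors <- function(p) {
  p <- parse_pattern(p)
  syms <- strsplit(p$text, "", fixed = TRUE)[[1]]
  out <- character(0)
  n <- length(syms)
  # (i) swap two unequal symbols
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (syms[i] != syms[j]) {
      s2 <- syms; s2[c(i, j)] <- syms[c(j, i)]
      out <- c(out, paste(s2, collapse = ""))
    }
  }
  ones <- which(syms == "1"); zeros <- which(syms == "0")
  ts <- which(syms == "T")
  # (ii) one '1' + one '0' -> two 'T's
  for (i in ones) for (j in zeros) {
    s2 <- syms; s2[c(i, j)] <- "T"
    out <- c(out, paste(s2, collapse = ""))
  }
  # (iii) two 'T's -> one '1' + one '0' (both assignments)
  if (length(ts) >= 2L) {
    for (i in seq_along(ts)) for (j in seq_along(ts)) {
      if (i == j) next
      s2 <- syms; s2[ts[i]] <- "1"; s2[ts[j]] <- "0"
      out <- c(out, paste(s2, collapse = ""))
    }
  }
  setdiff(unique(out), p$text)
}

#' Co-design seed patterns by hill climbing with random restarts
#'
#' Maximizes the exact joint sensitivity ([sensitivity_dp()]) of `n`
#' patterns of fixed weight over a span range. Each restart draws random
#' initial patterns (spans sampled uniformly in `[span_min, span_max]`)
#' and climbs coordinate-wise: one pattern at a time is replaced by its
#' best improving neighbor until no neighbor of any pattern improves the
#' joint sensitivity. Ties prefer the lexicographically smaller pattern
#' text, so results are reproducible under a fixed seed.
#'
#' @param n number of patterns to co-design.
#' @param weight pattern weight (half-integers allowed).
#' @param span_min,span_max span bounds, `weight <= span_min <= span_max`.
#' @param model a [bernoulli_model()] or probability triple (the
#'   *foreground* alignment model the seeds should detect).
#' @param l length of the gapless alignments the sensitivity is computed
#'   for (default 64).
#' @param sparsity hit-offset sparsity (default 1).
#' @param restarts number of random restarts (default 200).
#' @param rng_seed optional integer; if given, `set.seed()` is called so
#'   the design is reproducible.
#' @param quiet suppress per-restart progress messages.
#' @return a `seed_design`: list with `seeds` (a `seed_set`),
#'   `sensitivity` (its [sensitivity_dp()] value) and the call parameters.
#' @export
design_seeds <- function(n, weight, span_min, span_max = span_min, model,
                         l = 64L, sparsity = 1L, restarts = 200L,
                         rng_seed = NULL, quiet = TRUE) {
  stopifnot(n >= 1L, span_min >= 1L, span_min <= span_max,
            weight <= span_min, restarts >= 1L)
  model <- as_model(model)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  # bypass parse-time warnings for climber-generated patterns ending in '0'
  codes_of <- function(tx)
    match(strsplit(tx, "", fixed = TRUE)[[1]], c("0", "T", "1")) - 1L
  score_set <- function(texts)
    sensitivity_dp_cpp(lapply(texts, codes_of), as.integer(sparsity),
                       model$p, as.integer(l))

  best_texts <- NULL
  best_sens <- -Inf
  for (rs in seq_len(restarts)) {
    spans <- if (span_min == span_max) rep(span_min, n) else
      sample(span_min:span_max, n, replace = TRUE)
    texts <- vapply(spans, function(sp) random_pattern(weight, sp)$text,
                    character(1))
    cur <- score_set(texts)
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        cands <- pattern_neighbors(new_seed_pattern(texts[i]))
        if (!length(cands)) next
        cands <- sort(cands)  # lexicographic tie-break among equal scores
        sens <- vapply(cands, function(tx) {
          t2 <- texts; t2[i] <- tx
          score_set(t2)
        }, numeric(1))
        jbest <- which.max(sens)
        if (sens[jbest] > cur) {
          texts[i] <- cands[jbest]
          cur <- unname(sens[jbest])
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (cur > best_sens ||
        (cur == best_sens && !is.null(best_texts) &&
         paste(sort(texts), collapse = ",") <
         paste(sort(best_texts), collapse = ","))) {
      best_sens <- cur
      best_texts <- texts
      if (!quiet)
        message(sprintf("restart %d: sensitivity %.6f  [%s]", rs, cur,
                        paste(texts, collapse = " ")))
    }
  }
  best_set <- structure(
    list(patterns = lapply(best_texts, new_seed_pattern),
         n = length(best_texts)), class = "seed_set")
  structure(
    list(seeds = best_set, sensitivity = best_sens, n = n,
         weight = weight, span_min = span_min, span_max = span_max,
         model = model, l = l, sparsity = sparsity, restarts = restarts),
    class = "seed_design"
  )
}

#' @export
print.seed_design <- function(x, ...) {
  cat("seed design: n = ", x$n, ", weight ", format(x$weight),
      ", span ", x$span_min, "..", x$span_max,
      ", l = ", x$l, ", sparsity ", x$sparsity, "\n", sep = "")
  cat("  sensitivity ", format(x$sensitivity, digits = 10), "\n", sep = "")
  print(x$seeds)
  invisible(x)
}
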