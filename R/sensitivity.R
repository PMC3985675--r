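# Exact seed-set sensitivity on i.i.d. gapless alignments over the
# 3-letter alphabet (transversion, transition, match).

#' Bernoulli alignment model
#'
#' Independent identically distributed alignment columns over the letters
#' (transversion, transition, match), in that order everywhere. This is the
#' model seed patterns are designed against, e.g. `(0.12, 0.18, 0.70)` for
#' a 3:2 transition:transversion substitution pattern at 70% identity.
#'
#' @param pv,pt,pm probabilities of transversion, transition and match;
#'   must be in `[0, 1]` and sum to 1 (tolerance 1e-12).
#' @return a `bernoulli_model` with field `p`, the probability triple.
#' @export
bernoulli_model <- function(pv, pt, pm) {
  p <- c(pv, pt, pm)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must be in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  structure(list(p = p), class = "bernoulli_model")
}

#' @export
print.bernoulli_model <- function(x, ...) {
  cat("Bernoulli alignment model (v, t, m) = (",
      paste(format(x$p), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

as_model <- function(model) {
  if (inherits(model, "bernoulli_model")) return(model)
  if (is.numeric(model) && length(model) == 3L)
    return(bernoulli_model(model[1], model[2], model[3]))
  stop("model must be a bernoulli_model or a probability triple")
}

#' Build the seed-hit automaton for a seed set
#'
#' Deterministic complete automaton over the 3-letter alignment alphabet
#' that accepts exactly those strings hit by the seed set (see
#' [seed_hits_alignment()]), with the accepting state absorbing. States are
#' sets of alive pattern-prefix lengths plus the position phase modulo the
#' sparsity, deduplicated by subset construction.
#'
#' @inheritParams seed_hits_alignment
#' @return a `seed_automaton`: `transitions` (`n_states x 3` matrix of
#'   0-based state ids, letter order v/t/m), `start`, `accept`, `n_states`,
#'   `sparsity`.
#' @export
build_automaton <- function(seeds, sparsity = 1L) {
  stopifnot(sparsity >= 1L)
  aut <- build_seed_automaton_cpp(seed_set_codes(seeds), as.integer(sparsity))
  aut$sparsity <- as.integer(sparsity)
  aut$seeds <- seed_set(seeds)
  class(aut) <- "seed_automaton"
  aut
}

#' @export
print.seed_automaton <- function(x, ...) {
  cat("seed-hit automaton: ", x$n_states, " states, sparsity ", x$sparsity,
      ", ", x$seeds$n, " pattern(s)\n", sep = "")
  invisible(x)
}

#' Exact sensitivity of a seed set by automaton dynamic programming
#'
#' Probability that the seed set hits a random gapless alignment of length
#' `l` drawn from the Bernoulli model, computed by forward dynamic
#' programming over the hit automaton. Exact up to double precision.
#'
#' @inheritParams seed_hits_alignment
#' @param model a [bernoulli_model()] (or probability triple `(pv, pt, pm)`).
#' @param l alignment length, `>= 0`.
#' @return the hit probability, in `[0, 1]`.
#' @examples
#' sensitivity_dp("11", c(0.15, 0.15, 0.7), l = 3)  # 2*0.7^2 - 0.7^3
#' @export
sensitivity_dp <- function(seeds, model, l, sparsity = 1L) {
  stopifnot(l >= 0, sparsity >= 1L)
  model <- as_model(model)
  sensitivity_dp_cpp(seed_set_codes(seeds), as.integer(sparsity), model$p,
                     as.integer(l))
}

#' Brute-force sensitivity by exhaustive enumeration
#'
#' Independent reference implementation: enumerates all `3^l` alignment
#' strings, tests each with the direct matcher semantics, and sums the
#' probabilities of the hit strings. Guarded to `l <= 14`.
#'
#' @inheritParams sensitivity_dp
#' @return the hit probability, in `[0, 1]`.
#' @export
sensitivity_bruteforce <- function(seeds, model, l, sparsity = 1L) {
  stopifnot(sparsity >= 1L)
  if (l > 14) stop("brute-force enumeration is guarded to l <= 14")
  if (l == 0) return(0)
  model <- as_model(model)
  n <- 3L^l
  idx <- 0:(n - 1L)
  X <- matrix(0L, n, l)
  for (j in seq_len(l)) X[, j] <- (idx %/% 3L^(j - 1L)) %% 3L
  hit <- rep(FALSE, n)
  for (pc in seed_set_codes(seeds)) {
    s <- length(pc)
    if (s > l) next
    for (i in seq(0L, l - s, by = sparsity)) {
      cols <- X[, (i + 1L):(i + s), drop = FALSE]
      ok <- rowSums(cols >= matrix(pc, n, s, byrow = TRUE)) == s
      hit <- hit | ok
    }
  }
  prob <- rep(1, n)
  for (j in seq_len(l)) prob <- prob * model$p[X[, j] + 1L]
  sum(prob[hit])
}
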