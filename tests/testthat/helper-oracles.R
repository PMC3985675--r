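# Independent reference implementations and fixture generators used across
# the suite. These deliberately avoid the package's optimized code paths.

# Full local affine-gap alignment (Gotoh) -- the oracle for extension and
# pipeline scores. Plain R matrices, no pruning.
sw_local <- function(qseq, rseq, scheme) {
  S <- scheme$submat5
  go <- scheme$gap_exist
  ge <- scheme$gap_extend
  qc <- subseed:::seq_to_codes(qseq) + 1L
  rc <- subseed:::seq_to_codes(rseq) + 1L
  n <- length(qc)
  m <- length(rc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(H[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(H[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
    h <- max(0, H[i - 1, j - 1] + S[qc[i - 1], rc[j - 1]], Ix[i, j], Iy[i, j])
    H[i, j] <- h
    if (h > best) best <- h
  }
  best
}

# Quadratic brute-force adaptive-seed matcher: scan all indexed reference
# positions, apply the per-position letter classes of the cyclically
# extended pattern directly.
brute_adaptive_seeds <- function(query, ref, pattern, m, k = 1L, step = 1L) {
  tclass <- function(base, sym) {
    if (base >= 4L) return(-1L)
    if (sym == 2L) return(base)
    if (sym == 1L) return(if (base == 0L || base == 2L) 0L else 1L)
    0L
  }
  qc <- subseed:::seq_to_codes(query)
  rc <- subseed:::seq_to_codes(ref)
  pat <- subseed:::pattern_codes(pattern)
  span <- length(pat)
  idxpos <- seq(0L, length(rc) - 1L, by = step)
  idxpos <- idxpos[vapply(idxpos, function(p) tclass(rc[p + 1L], pat[1L]) >= 0L,
                          logical(1))]
  out <- list()
  for (q0 in seq(0L, length(qc) - 1L, by = k)) {
    cand <- idxpos
    found <- FALSE
    for (depth in 0L:(length(qc) - q0 - 1L)) {
      sym <- pat[depth %% span + 1L]
      qcl <- tclass(qc[q0 + depth + 1L], sym)
      if (qcl < 0L) break
      keep <- vapply(cand, function(p) {
        if (p + depth >= length(rc)) return(FALSE)
        tclass(rc[p + depth + 1L], sym) == qcl
      }, logical(1))
      cand <- cand[keep]
      if (!length(cand)) break
      if (length(cand) <= m) {
        out[[length(out) + 1L]] <-
          data.frame(query_pos = q0, ref_pos = cand, length = depth + 1L)
        found <- TRUE
        break
      }
    }
    invisible(found)
  }
  if (!length(out))
    return(data.frame(query_pos = integer(0), ref_pos = integer(0),
                      length = integer(0)))
  do.call(rbind, out)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Related pair for alignment-oracle tests: identical ends (>= 60 bp) so the
# optimal alignment includes long clean gapless runs under both scoring
# schemes; substitutions and at most one short indel confined to the middle.
make_related_pair <- function(len) {
  bases <- c("A", "C", "G", "T")
  q <- sample(bases, len, replace = TRUE)
  r <- q
  mid <- 61:(len - 60)
  nsub <- stats::rbinom(1, length(mid), 0.06)
  if (nsub > 0) {
    at <- sample(mid, nsub)
    r[at] <- vapply(r[at], function(b) sample(setdiff(bases, b), 1), "")
  }
  if (stats::runif(1) < 0.7) {
    g <- sample(1:3, 1)
    at <- sample(mid, 1)
    if (stats::runif(1) < 0.5) r <- append(r, sample(bases, g, TRUE), after = at)
    else r <- r[-(at:min(at + g - 1, max(mid)))]
  }
  list(q = paste(q, collapse = ""), r = paste(r, collapse = ""))
}

# random seed pattern text for property tests (always starts/ends non-'0')
rand_pattern_text <- function(max_span = 10L) {
  span <- sample(1:max_span, 1L)
  syms <- sample(c("0", "T", "1"), span, replace = TRUE,
                 prob = c(0.3, 0.3, 0.4))
  if (syms[1L] == "0") syms[1L] <- "1"
  if (syms[span] == "0") syms[span] <- sample(c("T", "1"), 1L)
  paste(syms, collapse = "")
}

rand_model <- function() {
  p <- stats::runif(3)
  p <- p / sum(p)
  bernoulli_model(p[1], p[2], p[3])
}
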