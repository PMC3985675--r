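# Alignment scoring schemes.

#' Construct an alignment scoring scheme
#'
#' @param substitution symmetric 4x4 integer score matrix with rows/columns
#'   named `A, C, G, T`; diagonal must be positive.
#' @param gap_exist,gap_extend non-negative gap costs: a gap of length `g`
#'   costs `gap_exist + gap_extend * g`.
#' @param min_score minimum reported alignment score (> 0).
#' @param n_score score of `N` aligned to anything.
#' @param gapless_drop default gapless X-drop limit `y` for this scheme.
#' @param t_scale scale factor of the score matrix (used by
#'   [default_gapless_threshold()]); may be `NULL` when unknown.
#' @param name scheme label.
#' @return a `scoring_scheme`; `$submat5` is the 5x5 table over
#'   `A, C, G, T, N` used by the alignment kernels.
#' @export
scoring_scheme <- function(substitution, gap_exist, gap_extend, min_score,
                           n_score, gapless_drop, t_scale = NULL,
                           name = "custom") {
  stopifnot(is.matrix(substitution), all(dim(substitution) == c(4, 4)))
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (any(diag(substitution) <= 0))
    stop("substitution matrix diagonal must be positive")
  stopifnot(gap_exist >= 0, gap_extend >= 0, min_score > 0)
  if (!is.null(t_scale) && t_scale <= 0) stop("t_scale must be positive")
  sub5 <- matrix(as.integer(n_score), 5, 5,
                 dimnames = list(c("A", "C", "G", "T", "N"),
                                 c("A", "C", "G", "T", "N")))
  sub5[1:4, 1:4] <- as.integer(substitution)
  structure(
    list(substitution = substitution, submat5 = sub5,
         gap_exist = as.integer(gap_exist),
         gap_extend = as.integer(gap_extend),
         min_score = as.integer(min_score), n_score = as.integer(n_score),
         gapless_drop = as.integer(gapless_drop), t_scale = t_scale,
         name = name),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring scheme '", x$name, "': gap ", x$gap_exist, "+", x$gap_extend,
      "g, min score ", x$min_score, ", N ", x$n_score, ", gapless drop ",
      x$gapless_drop, "\n", sep = "")
  print(x$substitution)
  invisible(x)
}

#' Built-in scoring schemes
#'
#' `last_scheme()`: match/mismatch +1/-1, gap exist/extend 7/1, minimum
#' alignment score 35, N scores -1. `hoxd70_scheme()`: the HoxD70
#' substitution matrix (Chiaromonte, Yap & Miller 2002), gap exist/extend
#' 400/30, minimum alignment score 4000, N scores -100, score-matrix scale
#' factor 96.1735. Default gapless drops are 10 and 962 respectively.
#'
#' @return a [scoring_scheme()].
#' @export
last_scheme <- function() {
  sub <- matrix(-1L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(sub) <- 1L
  scoring_scheme(sub, gap_exist = 7, gap_extend = 1, min_score = 35,
                 n_score = -1, gapless_drop = 10, t_scale = NULL,
                 name = "last")
}

#' @rdname last_scheme
#' @export
hoxd70_scheme <- function() {
  sub <- matrix(c(
      91, -114,  -31, -123,
    -114,  100, -125,  -31,
     -31, -125,  100, -114,
    -123,  -31, -114,   91), 4, 4, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  scoring_scheme(sub, gap_exist = 400, gap_extend = 30, min_score = 4000,
                 n_score = -100, gapless_drop = 962, t_scale = 96.1735,
                 name = "hoxd70")
}

#' Look up a scheme by name
#'
#' @param scheme a `scoring_scheme` or one of `"last"`, `"hoxd70"`.
#' @export
get_scheme <- function(scheme) {
  if (inherits(scheme, "scoring_scheme")) return(scheme)
  switch(match.arg(scheme, c("last", "hoxd70")),
         last = last_scheme(), hoxd70 = hoxd70_scheme())
}
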