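test_that("bernoulli_model validates its probability triple", {
  m <- bernoulli_model(0.12, 0.18, 0.70)
  expect_equal(m$p, c(0.12, 0.18, 0.70))
  expect_error(bernoulli_model(0.5, 0.5, 0.5), "sum to 1")
  expect_error(bernoulli_model(-0.1, 0.4, 0.7), "\\[0, 1\\]")
})

test_that("the hit automaton recognizes exactly the hit language", {
  aut <- build_automaton("1")
  expect_equal(aut$n_states, 2L)  # start + absorbing accept

  # language check against the direct matcher on full enumerations
  enumerate <- function(l) {
    idx <- 0:(3^l - 1)
    X <- matrix(0L, 3^l, l)
    for (j in seq_len(l)) X[, j] <- (idx %/% 3L^(j - 1L)) %% 3L
    X
  }
  check_language <- function(seeds, l, sparsity = 1) {
    aut <- build_automaton(seeds, sparsity)
    X <- enumerate(l)
    got <- subseed:::automaton_accepts_cpp(aut$transitions, aut$start,
                                           aut$accept, X)
    want <- apply(X, 1, function(row)
      seed_hits_alignment(seeds, c("v", "t", "m")[row + 1], sparsity))
    expect_identical(got, unname(want))
  }
  check_language("11", 3)
  check_language(c("1T1", "11T"), 5)
  check_language("1T01", 5, sparsity = 2)
})

test_that("sensitivity_dp reproduces closed-form small cases", {
  # single-letter seed: P(match) over one column
  expect_equal(sensitivity_dp("1", c(0.5, 0.25, 0.25), 1), 0.25)
  # inclusion-exclusion over two offsets of "11" at p_m = 0.7
  expect_equal(sensitivity_dp("11", c(0.15, 0.15, 0.7), 3),
               2 * 0.7^2 - 0.7^3, tolerance = 1e-14)
  # sparsity 2 leaves only offset 0
  expect_equal(sensitivity_dp("11", c(0.15, 0.15, 0.7), 3, sparsity = 2),
               0.49, tolerance = 1e-14)
})

test_that("brute-force enumeration handles edge cases and guards l", {
  expect_equal(sensitivity_bruteforce("T", c(0.3, 0.2, 0.5), 1), 0.7)
  expect_equal(sensitivity_bruteforce("1", c(0.3, 0.2, 0.5), 0), 0)
  expect_equal(
    sensitivity_bruteforce(suppressWarnings(parse_pattern("0")),
                           c(0.3, 0.2, 0.5), 1), 1)
  expect_error(sensitivity_bruteforce("1", c(0.3, 0.2, 0.5), 15), "l <= 14")
})

test_that("DP matches exhaustive enumeration for a transition-rich seed", {
  # value frozen from sensitivity_bruteforce("11T0TT010T", (0.12, 0.18, 0.70),
  # l = 12): exhaustive sum over all 3^12 alignment strings
  frozen <- 0.433889168895508
  model <- c(0.12, 0.18, 0.70)
  expect_equal(sensitivity_bruteforce("11T0TT010T", model, 12), frozen,
               tolerance = 1e-12)
  expect_equal(sensitivity_dp("11T0TT010T", model, 12), frozen,
               tolerance = 1e-12)
  # self-consistency at design length: bounded and monotone vs l = 12
  s64 <- sensitivity_dp("11T0TT010T", model, 64)
  expect_gte(s64, frozen)
  expect_lte(s64, 1)
})

test_that("DP equals brute force on randomized seed sets and models", {
  set.seed(104)
  for (i in 1:40) {
    pats <- replicate(sample(1:3, 1), rand_pattern_text(8))
    model <- rand_model()
    l <- sample(0:9, 1)
    cc <- sample(1:3, 1)
    expect_equal(sensitivity_dp(pats, model, l, cc),
                 sensitivity_bruteforce(pats, model, l, cc),
                 tolerance = 1e-12)
  }
})

test_that("sensitivity is monotone in length, set size and density", {
  set.seed(105)
  for (i in 1:10) {
    p1 <- rand_pattern_text(8)
    p2 <- rand_pattern_text(8)
    model <- rand_model()
    s_l <- vapply(c(4, 8, 16, 32), function(l)
      sensitivity_dp(p1, model, l), numeric(1))
    expect_true(all(diff(s_l) >= -1e-15))          # non-decreasing in l
    expect_gte(sensitivity_dp(c(p1, p2), model, 16),
               sensitivity_dp(p1, model, 16) - 1e-15)  # adding a pattern
    expect_lte(sensitivity_dp(p1, model, 16, sparsity = 3),
               sensitivity_dp(p1, model, 16, sparsity = 1) + 1e-15)
    s <- sensitivity_dp(p1, model, 16)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})
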