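test_that("random_pattern hits exact weight and forced endpoints", {
  expect_identical(random_pattern(3, 3)$text, "111")
  set.seed(106)
  expect_true(random_pattern(1.5, 2)$text %in% c("1T", "T1"))
  # determinism under a fixed seed
  set.seed(42)
  a <- random_pattern(6, 8)$text
  set.seed(42)
  b <- random_pattern(6, 8)$text
  expect_identical(a, b)
  # weight always exact, endpoints non-'0' whenever two non-zeros exist
  for (i in 1:40) {
    w <- sample(c(1, 1.5, 2, 2.5, 3, 4), 1)
    sp <- sample(ceiling(w):8, 1)
    p <- random_pattern(w, sp)
    expect_equal(p$weight, w)
    expect_equal(p$span, sp)
    syms <- strsplit(p$text, "")[[1]]
    if (sum(syms != "0") >= 2 && sp >= 2)
      expect_true(syms[1] != "0" && syms[sp] != "0")
  }
  expect_error(random_pattern(4, 3), "<= span")
})

test_that("the neighborhood preserves weight and span", {
  expect_setequal(intersect(suppressWarnings(pattern_neighbors("110")),
                            c("101", "011")),
                  c("101", "011"))
  expect_length(pattern_neighbors("11"), 0)
  set.seed(107)
  for (i in 1:25) {
    p <- parse_pattern(rand_pattern_text(8))
    for (nb in pattern_neighbors(p)) {
      q <- suppressWarnings(parse_pattern(nb))
      expect_equal(q$twice_weight, p$twice_weight)
      expect_equal(q$span, p$span)
      expect_false(identical(nb, p$text))
    }
  }
})

test_that("hill climbing finds the forced and the exhaustive optimum", {
  model <- bernoulli_model(0.15, 0.15, 0.7)
  d <- design_seeds(1, weight = 3, span_min = 3, model = model, l = 10,
                    restarts = 2, rng_seed = 1)
  expect_identical(d$seeds$patterns[[1]]$text, "111")
  expect_equal(d$sensitivity, sensitivity_dp("111", model, 10),
               tolerance = 1e-14)

  # tiny search space: compare with exhaustive enumeration of all feasible
  # weight-2 span-3 patterns under a transition-free model
  m0 <- bernoulli_model(0.3, 0, 0.7)
  all_pats <- apply(expand.grid(rep(list(c("0", "T", "1")), 3)), 1, paste,
                    collapse = "")
  feasible <- Filter(function(tx) {
    p <- suppressWarnings(parse_pattern(tx))
    p$weight == 2
  }, all_pats)
  best_exh <- max(vapply(feasible, function(tx)
    sensitivity_dp(suppressWarnings(parse_pattern(tx)), m0, 24), numeric(1)))
  d2 <- design_seeds(1, weight = 2, span_min = 3, model = m0, l = 24,
                     restarts = 10, rng_seed = 2)
  expect_equal(d2$sensitivity, best_exh, tolerance = 1e-12)
  # a spaced pattern should do at least as well as the contiguous one
  expect_gte(d2$sensitivity,
             sensitivity_dp(suppressWarnings(parse_pattern("110")), m0, 24) -
               1e-15)
})

test_that("two codesigned seeds never do worse than one", {
  model <- bernoulli_model(0.12, 0.18, 0.7)
  d1 <- design_seeds(1, weight = 2.5, span_min = 4, span_max = 5,
                     model = model, l = 16, restarts = 6, rng_seed = 3)
  d2 <- design_seeds(2, weight = 2.5, span_min = 4, span_max = 5,
                     model = model, l = 16, restarts = 6, rng_seed = 3)
  expect_gte(d2$sensitivity, d1$sensitivity - 1e-12)
})

test_that("climbing never worsens its initialization and is reproducible", {
  model <- bernoulli_model(0.2, 0.2, 0.6)
  # reported sensitivity must match an independent recomputation
  d <- design_seeds(1, weight = 2, span_min = 4, model = model, l = 12,
                    restarts = 4, rng_seed = 9)
  expect_equal(d$sensitivity,
               sensitivity_dp(d$seeds, model, 12), tolerance = 1e-14)
  # and beat (or tie) every random initialization drawn the same way
  set.seed(9)
  for (i in 1:4) {
    init <- random_pattern(2, 4)
    expect_gte(d$sensitivity, sensitivity_dp(init, model, 12) - 1e-12)
  }
  d_again <- design_seeds(1, weight = 2, span_min = 4, model = model, l = 12,
                          restarts = 4, rng_seed = 9)
  expect_identical(vapply(d$seeds$patterns, `[[`, "", "text"),
                   vapply(d_again$seeds$patterns, `[[`, "", "text"))
})
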