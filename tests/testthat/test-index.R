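test_that("mask_lowercase keeps only uppercase ACGT", {
  expect_identical(mask_lowercase("acgT"), "NNNT")
  expect_identical(mask_lowercase("ACGT"), "ACGT")
  expect_identical(mask_lowercase("AcNg"), "ANNN")
  expect_identical(unname(mask_lowercase(c(x = "aA", y = "nN"))),
                   c("NA", "NN"))
})

test_that("the subset suffix array indexes sampled, non-N positions", {
  ix <- build_index("AAAA", "1")
  expect_length(ix$sa, 4L)
  expect_identical(sort(ix$sa), 0:3)  # equal suffix ranks tie by position

  # sparse sampling keeps exactly every step-th position
  ix2 <- build_index("ACGTACGT", "1", step = 2)
  expect_setequal(ix2$sa, c(0L, 2L, 4L, 6L))

  # N starts are not indexed
  ix3 <- build_index("ANGT", "1")
  expect_false(1L %in% ix3$sa)
  expect_error(build_index("", "1"), "empty")
})

test_that("transition positions merge purines and pyrimidines", {
  # under pattern "T", A == G, so every suffix of AGAG class-matches "A..."
  ix <- build_index("AGAG", "T")
  seeds <- adaptive_seeds("A", ix, m = 10)
  expect_equal(nrow(seeds), 4L)
  expect_true(all(seeds$length == 1L))
  # under pattern "1" only the true A's match
  seeds1 <- adaptive_seeds("A", build_index("AGAG", "1"), m = 10)
  expect_setequal(seeds1$ref_pos, c(0L, 2L))
})

test_that("adaptive seeds are minimal-length matches occurring <= m times", {
  ix <- build_index("ACACAC", "1")
  s <- adaptive_seeds("ACA", ix, m = 2)
  s0 <- s[s$query_pos == 0, ]
  expect_equal(nrow(s0), 2L)            # "ACA" at reference 0 and 2
  expect_setequal(s0$ref_pos, c(0L, 2L))
  expect_true(all(s0$length == 3L))

  # count <= m already at the first tested length
  s2 <- adaptive_seeds("A", build_index("AAAA", "1"), m = 10)
  expect_equal(nrow(s2), 4L)
  expect_true(all(s2$length == 1L))

  # an N in the query start yields no seed from that start
  s3 <- adaptive_seeds("NA", build_index("AAAA", "1"), m = 10)
  expect_true(all(s3$query_pos != 0L))
})

test_that("adaptive seeds match a quadratic brute-force matcher", {
  set.seed(108)
  for (i in 1:12) {
    ref <- rand_dna(sample(200:600, 1))
    query <- rand_dna(sample(20:60, 1))
    pat <- rand_pattern_text(5)
    m <- sample(c(1, 2, 5, 20), 1)
    k <- sample(1:3, 1)
    step <- sample(1:2, 1)
    ix <- build_index(ref, suppressWarnings(parse_pattern(pat)), step = step)
    got <- adaptive_seeds(query, ix, m = m, k = k)
    want <- brute_adaptive_seeds(query, ref, pat, m = m, k = k, step = step)
    ord <- function(d) d[order(d$query_pos, d$ref_pos), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))),
                 info = sprintf("case %d: pattern %s m=%d k=%d w=%d",
                                i, pat, m, k, step))
  }
})

test_that("minimality: one shorter and the count would exceed m", {
  set.seed(109)
  # direct count of reference positions whose length-`len` prefix
  # class-matches the query prefix starting at q0
  count_occ <- function(query, ref, pat, q0, len, step) {
    tclass <- function(base, sym) {
      if (base >= 4L) return(-1L)
      if (sym == 2L) return(base)
      if (sym == 1L) return(if (base %in% c(0L, 2L)) 0L else 1L)
      0L
    }
    qc <- subseed:::seq_to_codes(query)
    rc <- subseed:::seq_to_codes(ref)
    pc <- subseed:::pattern_codes(pat)
    span <- length(pc)
    hits <- 0L
    for (p in seq(0L, length(rc) - 1L, by = step)) {
      ok <- TRUE
      for (d in 0L:(len - 1L)) {
        sym <- pc[d %% span + 1L]
        if (p + d >= length(rc)) { ok <- FALSE; break }
        qcl <- tclass(qc[q0 + d + 1L], sym)
        rcl <- tclass(rc[p + d + 1L], sym)
        if (qcl < 0L || rcl < 0L || qcl != rcl) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  for (i in 1:6) {
    ref <- rand_dna(400)
    query <- rand_dna(30)
    pat <- rand_pattern_text(4)
    m <- sample(c(1, 3, 10), 1)
    ix <- build_index(ref, suppressWarnings(parse_pattern(pat)))
    got <- adaptive_seeds(query, ix, m = m)
    for (q0 in unique(got$query_pos)) {
      sub <- got[got$query_pos == q0, ]
      L <- unique(sub$length)
      expect_length(L, 1L)
      expect_lte(nrow(sub), m)
      expect_equal(nrow(sub), count_occ(query, ref, pat, q0, L, 1L))
      if (L > 1L)
        expect_gt(count_occ(query, ref, pat, q0, L - 1L, 1L), m)
    }
  }
})

test_that("sparse indexing yields a subset of dense matches at even positions", {
  set.seed(110)
  ref <- rand_dna(500)
  query <- rand_dna(40)
  ix1 <- build_index(ref, "11T1")
  ix2 <- build_index(ref, "11T1", step = 2)
  m <- 4
  dense <- adaptive_seeds(query, ix1, m = m)
  sparse <- adaptive_seeds(query, ix2, m = m)
  expect_true(all(sparse$ref_pos %% 2 == 0))
  # sparse indexing makes seeds *rarer*: the occurrence count drops to m at
  # an equal or shorter length, so every even-position dense match start is
  # also a sparse match start (sparse starts are a superset of dense-even)
  sparse_keys <- paste(sparse$query_pos, sparse$ref_pos)
  dense_even <- dense[dense$ref_pos %% 2 == 0, ]
  expect_true(all(paste(dense_even$query_pos, dense_even$ref_pos)
                  %in% sparse_keys))
})

test_that("indexes round-trip through the JSON sidecar", {
  ref <- c(chr = "ACGTACGTNNacgt")
  refm <- mask_lowercase(ref)
  ix <- build_index(refm, "1T", step = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_index(ix, path)
  ix2 <- read_index(path, refm)
  expect_identical(ix2$sa, ix$sa)
  expect_identical(ix2$pattern$text, "1T")
  expect_error(read_index(path, "TTTT"), "checksum")
})
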