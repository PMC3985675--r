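test_that("the default gapless threshold reproduces its endpoints", {
  expect_equal(default_gapless_threshold(1000, 1, 1363595724, 96.1735), 2466)
  expect_equal(default_gapless_threshold(10, 8, 1363595724, 96.1735), 1823)
  # m*r = 10*n*e gives ln(e) = 1
  expect_equal(default_gapless_threshold(10 * exp(1), 1, 1, 1), 1)
  expect_error(default_gapless_threshold(0, 1, 1, 1), "positive")
})

test_that("gapless extension trims to the running maximum", {
  sch <- last_scheme()
  # identical sequences: full length regardless of seed placement
  g <- gapless_extend("GATTACA", "GATTACA",
                      list(query_pos = 3, ref_pos = 3), sch, y = 10)
  expect_equal(g$score, 7L)
  expect_equal(g$query_start, 0L)
  expect_equal(g$length, 7L)

  # right extension dies after three mismatches (drop 3 > 2), trimmed to AA
  g2 <- gapless_extend("AATTTT", "AACCCC",
                       list(query_pos = 0, ref_pos = 0), sch, y = 2)
  expect_equal(g2$score, 2L)
  expect_equal(g2$length, 2L)
  expect_equal(g2$query_start, 0L)

  # y = 0 with negative flanks: the maximal-score core around the seed col
  g3 <- gapless_extend("CAC", "GAG", list(query_pos = 1, ref_pos = 1),
                       sch, y = 0)
  expect_equal(g3$score, 1L)
  expect_equal(g3$length, 1L)
  expect_equal(g3$anchor_query, 1L)
})

test_that("gapped extension recovers gaps and never loses the anchor", {
  sch <- last_scheme()
  # identical sequences: no gap helps, score equals the gapless full length
  rec <- gapped_extend("GATTACA", "GATTACA",
                       list(anchor_query = 3, anchor_ref = 3), sch,
                       ydrop = 100)
  expect_equal(rec$score, 7L)
  expect_equal(rec$ops, "MMMMMMM")

  # one deletion: equals the full local-alignment optimum
  q <- "ACGTACGT"
  r <- "ACGACGT"
  best <- sw_local(q, r, sch)
  rec2 <- gapped_extend(q, r, list(anchor_query = 5, anchor_ref = 4), sch,
                        ydrop = 1000)
  expect_equal(rec2$score, best)

  # ydrop = 0 still keeps at least the anchor column
  rec3 <- gapped_extend("AT", "AG", list(anchor_query = 0, anchor_ref = 0),
                        sch, ydrop = 0)
  expect_gte(rec3$score, 1L)
})

test_that("a unique substring aligns back at full score and position", {
  set.seed(111)
  ref <- rand_dna(5000)
  start <- 1500L
  query <- substr(ref, start + 1L, start + 1000L)
  ix <- build_index(ref, "1")
  recs <- align(query, ix, scheme = "last", m = 10, k = 1)
  expect_gte(nrow(recs), 1L)
  expect_equal(recs$score[1], 1000L)
  expect_equal(recs$ref_start[1], start)
  expect_equal(recs$query_start[1], 0L)
  expect_equal(recs$strand[1], "+")

  # an all-N query yields nothing
  expect_equal(nrow(align(strrep("N", 100), ix, scheme = "last")), 0L)
})

test_that("degenerate configuration equals the full local DP oracle", {
  set.seed(112)
  for (i in 1:8) {
    pr <- make_related_pair(sample(150:200, 1))
    for (sch in list(last_scheme(), hoxd70_scheme())) {
      ix <- build_index(pr$r, "1")
      recs <- align(pr$q, ix, scheme = sch, m = nchar(pr$r), k = 1,
                    d = sch$min_score, ydrop = 100 * sch$min_score,
                    strand = "forward")
      top <- if (nrow(recs)) max(recs$score) else 0
      oracle <- sw_local(pr$q, pr$r, sch)
      if (oracle < sch$min_score) oracle <- 0
      expect_equal(top, oracle,
                   info = sprintf("case %d scheme %s", i, sch$name))
    }
  }
})

test_that("record scores are self-consistent with their column paths", {
  set.seed(113)
  pr <- make_related_pair(180)
  for (sch in list(last_scheme(), hoxd70_scheme())) {
    ix <- build_index(pr$r, "11T1")
    recs <- align(pr$q, ix, scheme = sch, m = 50, k = 1)
    expect_gte(nrow(recs), 1L)
    for (i in seq_len(nrow(recs)))
      expect_equal(rescore_record(recs[i, ], pr$q, pr$r, sch),
                   recs$score[i])
  }
})

test_that("reverse-complementing the query mirrors coordinates and scores", {
  set.seed(114)
  pr <- make_related_pair(160)
  ix <- build_index(pr$r, "1T1")
  sch <- last_scheme()
  fwd <- align(pr$q, ix, scheme = sch, m = 30)
  rev <- align(subseed:::revcomp(pr$q), ix, scheme = sch, m = 30)
  expect_equal(sort(fwd$score), sort(rev$score))
  # a + record for the original query appears as a - record for the
  # reverse-complemented query at mirrored query coordinates
  f1 <- fwd[fwd$strand == "+", ]
  r1 <- rev[rev$strand == "-", ]
  expect_equal(nrow(f1), nrow(r1))
  if (nrow(f1)) {
    key_f <- paste(f1$query_start, f1$query_end, f1$ref_start, f1$ref_end,
                   f1$score)
    key_r <- paste(r1$query_start, r1$query_end, r1$ref_start, r1$ref_end,
                   r1$score)
    expect_setequal(key_f, key_r)
  }
})

test_that("relaxing thresholds never removes fixture alignments", {
  set.seed(115)
  pr <- make_related_pair(200)
  ix <- build_index(pr$r, "11T1")
  sch <- last_scheme()
  base <- align(pr$q, ix, scheme = sch, m = 10, k = 2, y = 10, d = 40,
                ydrop = 34)
  keys <- function(r) paste(r$strand, r$query_start, r$query_end,
                            r$ref_start, r$ref_end)
  # lower d / higher m keep the seed->anchor superset structure: every base
  # record survives, at the same or better score
  for (alt in list(
    align(pr$q, ix, scheme = sch, m = 10, k = 2, y = 10, d = 35, ydrop = 34),
    align(pr$q, ix, scheme = sch, m = 50, k = 2, y = 10, d = 40, ydrop = 34)
  )) {
    expect_true(all(keys(base) %in% keys(alt)))
    ka <- keys(alt)
    for (i in seq_len(nrow(base)))
      expect_gte(alt$score[match(keys(base)[i], ka)], base$score[i])
  }
  # higher y / ydrop can move anchors, but never lower the best score found
  for (alt in list(
    align(pr$q, ix, scheme = sch, m = 10, k = 2, y = 30, d = 40, ydrop = 34),
    align(pr$q, ix, scheme = sch, m = 10, k = 2, y = 10, d = 40, ydrop = 80)
  )) {
    expect_gte(max(alt$score), max(base$score))
  }
})
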