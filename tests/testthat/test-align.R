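test_that("swg_align handles hand-checked cases", {
  m <- scoring_model()
  a <- swg_align("AATTCCC", "AATTCCC", m)
  expect_equal(a$score, 14)
  expect_equal(a$aligned_db, "AATTCCC")
  expect_equal(a$identity_fraction, 1)

  # best local alignment of TAAT vs TAAAT without flow data is the ungapped
  # 3-mer (score 6); the full-length gapped alignment only reaches 8 - 5 = 3
  b <- swg_align("TAAAT", "TAAT", m)
  expect_equal(b$score, 6)
  expect_equal(nrow(b$corrections), 0L)

  expect_error(swg_align("", "ACGT"), "non-empty")
})

test_that("swg_align equals the exhaustive path enumerator on random pairs", {
  set.seed(12)
  for (i in 1:30) {
    d <- random_seq(8)
    q <- random_seq(8)
    expect_equal(swg_align(d, q)$score,
                 flowalign:::cpp_enum_local_score(d, q, 2L, -3L, 5L, 2L))
  }
})

test_that("flow_align applies the worked homopolymer correction", {
  m <- scoring_model()
  r <- call_flowgram(flowgram("r", "TAT", c(1.0, 2.40, 1.0)))  # "TAAT"
  a <- flow_align("TAAAT", r, model = m)
  expect_equal(a$score, 7)  # 4 matches x 2 - up-call penalty 1
  expect_equal(a$aligned_db, "TAAAT")
  expect_equal(a$aligned_query, "TAAaT")  # inserted lower-case base
  expect_equal(a$db_interval, c(0L, 5L))
  expect_equal(a$corrections$kind, "up")
  expect_equal(a$corrections$n, 1L)
  expect_equal(a$corrections$penalty, 1L)
  expect_true(a$score > swg_align("TAAAT", r$sequence, m)$score)

  # no correction against TAACT: the consumed database base C != A
  b <- flow_align("TAACT", r, model = m)
  s <- swg_align("TAACT", r$sequence, m)
  expect_equal(b$score, s$score)
  expect_equal(nrow(b$corrections), 0L)
  expect_equal(b$aligned_query, s$aligned_query)
})

test_that("down-calls render query bases lower-case against database gaps", {
  m <- scoring_model()
  # read TAAAG with an over-called A peak 2.60: down-calling one A costs
  # round(20 * 0.10 / 3) = 1, far cheaper than an ordinary gap (5), and
  # lets the trailing G keep matching: score 4 x 2 - 1 = 7
  r <- call_flowgram(flowgram("r", "TAG", c(1.0, 2.60, 1.0)))  # "TAAAG"
  a <- flow_align("TAAG", r, model = m)
  expect_equal(a$corrections$kind, "down")
  expect_equal(a$corrections$penalty, 1L)
  expect_equal(a$score, 4 * m$match - 1)
  expect_match(a$aligned_query, "a")
  expect_match(a$aligned_db, "-")
  expect_gt(a$score, swg_align("TAAG", r$sequence, m)$score)
})

test_that("k = 0 reverts the flow-assisted aligner to Smith-Waterman-Gotoh", {
  set.seed(5)
  m0 <- scoring_model(k = 0)
  for (i in 1:50) {
    db <- random_seq(sample(10:50, 1))
    s <- random_seq(sample(5:30, 1))
    r <- call_flowgram(add_flow_noise(sequence_to_flowgram(s), noise_model()))
    if (!nzchar(r$sequence)) next
    a <- flow_align(db, r, model = m0)
    b <- swg_align(db, r$sequence, m0)
    expect_identical(a$score, b$score)
    expect_identical(a$aligned_db, b$aligned_db)
    expect_identical(a$aligned_query, b$aligned_query)
    expect_identical(a$db_interval, b$db_interval)
  }
})

test_that("scores are non-negative and reconstructable from the columns", {
  set.seed(6)
  m <- scoring_model()
  for (i in 1:60) {
    db <- random_seq(sample(10:60, 1))
    s <- random_seq(sample(5:40, 1))
    r <- call_flowgram(add_flow_noise(sequence_to_flowgram(s), noise_model()))
    if (!nzchar(r$sequence)) next
    a <- flow_align(db, r, model = m)
    expect_gte(a$score, 0)
    expect_equal(flowalign:::rescore_alignment(a, m), a$score)
    b <- swg_align(db, s, m)
    expect_equal(flowalign:::rescore_alignment(b, m), b$score)
  }
})

test_that("flow-assisted score dominates the plain score when k > 0", {
  set.seed(14)
  for (i in 1:50) {
    db <- random_seq(50)
    s <- random_seq(30)
    r <- call_flowgram(add_flow_noise(sequence_to_flowgram(s), noise_model()))
    if (!nzchar(r$sequence)) next
    expect_gte(flow_align(db, r)$score, swg_align(db, r$sequence)$score)
  }
})

test_that("score_only agrees with the full alignment", {
  set.seed(9)
  m <- scoring_model()
  for (i in 1:50) {
    db <- random_seq(sample(10:60, 1))
    s <- random_seq(sample(6:30, 1))
    r <- call_flowgram(add_flow_noise(sequence_to_flowgram(s), noise_model()))
    if (!nzchar(r$sequence)) next
    expect_identical(score_only(db, r, model = m), flow_align(db, r)$score)
    expect_identical(score_only(db, s, model = m), swg_align(db, s)$score)
  }
  # vectorized over databases
  dbs <- c("ACGTACGT", "TTTTTTTT", "GGGGCCCC")
  expect_identical(score_only(dbs, "ACGT"),
                   vapply(dbs, function(d) swg_align(d, "ACGT")$score,
                          integer(1), USE.NAMES = FALSE))
  expect_equal(score_only("ACGTACGT", "ACGTACGT", model = scoring_model(k = 0)),
               8 * 2)
})

test_that("empty alignments are returned when nothing scores positively", {
  a <- swg_align("AAAA", "CCCC")
  expect_equal(a$score, 0)
  expect_equal(a$aligned_db, "")
  expect_equal(a$db_interval, c(0L, 0L))
})

test_that("alignment rendering marks corrections and 1-based coordinates", {
  r <- call_flowgram(flowgram("r", "TAT", c(1.0, 2.40, 1.0)))
  txt <- alignment_text(flow_align("TAAAT", r))
  expect_true(any(grepl("TAAaT", txt)))
  expect_true(any(grepl("db\\s+1 ", txt)))
  tab <- write_hits(flow_align("TAAAT", r), tempfile())
  expect_equal(tab$score, 7)
  expect_equal(tab$db_start, 0)
  expect_equal(tab$db_end, 5)
})
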