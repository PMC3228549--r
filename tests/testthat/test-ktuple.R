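test_that("index occurrences match a brute-force window scan", {
  idx <- build_index(c(a = "TTTT"), tuple_size = 2)
  expect_equal(length(idx$L$seq_id), 3L)        # three TT windows
  expect_equal(diff(idx$P)[1], 3)               # tuple TT encodes to 0
  expect_equal(sum(diff(idx$P) > 0), 1L)        # no other tuple occupied

  # windows overlapping a non-ACGT character are excluded
  idx2 <- build_index(c(a = "ACGTNACGT"), tuple_size = 3)
  expect_equal(length(idx2$L$seq_id), 4L)       # 2 windows per clean segment

  set.seed(18)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    db <- setNames(c(random_seq(sample(100:300, 1)),
                     random_seq(sample(50:200, 1), c(ACGT, "N"))),
                   c("s1", "s2"))
    idx <- build_index(db, tuple_size = k)
    got <- data.frame(seq_id = idx$L$seq_id, offset = idx$L$offset)
    want <- brute_occurrences(db, k)[, c("seq_id", "offset")]
    expect_equal(got[order(got$seq_id, got$offset), ],
                 want[order(want$seq_id, want$offset), ],
                 ignore_attr = TRUE)
    # P ranges recover every occurrence, sorted within tuple
    expect_equal(utils::tail(idx$P, 1) - 1, nrow(want))
    expect_true(all(diff(idx$P) >= 0))
  }
})

test_that("find_hits equals the brute-force all-pairs window comparison", {
  set.seed(25)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    db <- setNames(c(random_seq(200), random_seq(150)), c("s1", "s2"))
    query <- random_seq(60)
    got <- find_hits(build_index(db, tuple_size = k), query)
    want <- brute_hits(db, query, k)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  idx <- build_index(c(a = random_seq(100)), tuple_size = 11)
  expect_equal(nrow(find_hits(idx, "ACGT")), 0L)  # query shorter than k
})

test_that("a repeated substring yields co-diagonal hits", {
  set.seed(2)
  g <- random_seq(500)
  idx <- build_index(c(g = g), tuple_size = 11)
  q <- substr(g, 101, 160)
  h <- find_hits(idx, q)
  ondiag <- h[h$diagonal == 100, ]
  expect_gte(nrow(ondiag), 2L)
  expect_equal(ondiag$db_offset - ondiag$q_offset, rep(100L, nrow(ondiag)))
})

test_that("candidate selection uses strict spacing and exact diagonals", {
  h <- data.frame(db_id = 1L, db_offset = c(10L, 59L), q_offset = c(0L, 49L))
  h$diagonal <- h$db_offset - h$q_offset
  expect_equal(nrow(select_candidates(h, heuristic_params(2, 50))), 1L)

  h2 <- data.frame(db_id = 1L, db_offset = c(10L, 60L), q_offset = c(0L, 50L))
  h2$diagonal <- h2$db_offset - h2$q_offset
  expect_equal(nrow(select_candidates(h2, heuristic_params(2, 50))), 0L)

  # same spacing but different diagonals never chain
  h3 <- data.frame(db_id = 1L, db_offset = c(10L, 12L), q_offset = c(0L, 1L))
  h3$diagonal <- h3$db_offset - h3$q_offset
  expect_equal(nrow(select_candidates(h3, heuristic_params(2, 50))), 0L)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    h <- data.frame(db_id = sample(1:2, n, TRUE),
                    db_offset = sample(0:200, n, TRUE),
                    q_offset = sample(0:60, n, TRUE))
    h$diagonal <- h$db_offset - h$q_offset
    h <- h[order(h$db_id, h$diagonal, h$q_offset), ]
    h <- h[!duplicated(h), ]
    p <- heuristic_params(min_hits = sample(2:3, 1),
                          max_spacing = sample(c(5L, 20L, 50L), 1))
    got <- select_candidates(h, p)
    want <- brute_candidates(h, p$min_hits, p$max_spacing)
    got <- got[order(got$db_id, got$diagonal, got$q_start), ]
    rownames(got) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("search recovers a verbatim sample at rank 1 with identity 1", {
  set.seed(44)
  db <- setNames(vapply(1:5, function(i) random_seq(800), character(1)),
                 paste0("s", 1:5))
  idx <- build_index(db, tuple_size = 11)
  q <- substr(db[["s3"]], 201, 400)
  res <- flow_search(idx, as_called_read(q, name = "q"))
  expect_equal(res$hits$db[1], "s3")
  expect_equal(res$hits$strand[1], "+")
  aln <- res$alignments[[1]]
  expect_equal(aln$identity_fraction, 1)
  expect_equal(aln$db_interval, c(200L, 400L))
  expect_equal(aln$score, 200 * 2)

  # strand symmetry: the reverse complement finds the same locus, same score
  res2 <- flow_search(idx, as_called_read(reverse_complement(q), name = "q"))
  expect_equal(res2$hits$db[1], "s3")
  expect_equal(res2$hits$strand[1], "-")
  expect_equal(res2$hits$score[1], res$hits$score[1])
  expect_equal(res2$alignments[[1]]$db_interval, c(200L, 400L))
})

test_that("the heuristic filters pairs but never alters scores", {
  set.seed(52)
  g <- random_seq(2000)
  idx <- build_index(c(g = g), tuple_size = 11)
  for (i in 1:10) {
    start <- sample(1700, 1)
    s <- mutate_to_identity(substr(g, start, start + 149), 0.95)
    r <- call_flowgram(add_flow_noise(sequence_to_flowgram(s),
                                      noise_model(scale = 0.5)))
    res <- flow_search(idx, r)
    if (!nrow(res$hits)) next
    direct <- max(score_only(g, r), score_only(g, reverse_complement(r)))
    expect_equal(res$hits$score[1], direct)
    # clipped-window DP must agree with the unclipped full-sequence DP
    expect_equal(res$alignments[[1]]$score, direct)
  }
})

test_that("search results are deterministic", {
  set.seed(61)
  db <- setNames(vapply(1:3, function(i) random_seq(500), character(1)),
                 paste0("s", 1:3))
  idx <- build_index(db, tuple_size = 11)
  r <- as_called_read(substr(db[["s2"]], 100, 220), name = "q")
  a <- flow_search(idx, r)
  b <- flow_search(idx, r)
  expect_identical(a$hits, b$hits)
  expect_identical(a$alignments[[1]]$aligned_db, b$alignments[[1]]$aligned_db)
})

test_that("index statistics summarize tuple occupancy", {
  st <- index_stats(build_index(c(a = "TTTTT"), tuple_size = 2))
  expect_equal(st$occurrences, 4L)  # one tuple (TT) seen 4 times
  expect_equal(st$tuples, 1L)
})
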