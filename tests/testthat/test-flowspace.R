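test_that("base calling follows the >= 0.5 positive-flow convention", {
  fg <- flowgram("r1", "ACGT", c(0.11, 1.83, 0.97, 0.97))
  cr <- call_flowgram(fg)
  expect_equal(cr$sequence, "CCGT")
  expect_equal(cr$base_flow, c(2L, 2L, 3L, 4L))
  expect_equal(cr$base_peak, c(1.83, 1.83, 0.97, 0.97))
  expect_equal(cr$homopolymer_last, c(FALSE, TRUE, TRUE, TRUE))

  expect_equal(call_flowgram(flowgram("r", "T", 0.49))$sequence, "")
  expect_equal(call_flowgram(flowgram("r", "T", 0.50))$sequence, "T")
  expect_equal(call_flowgram(flowgram("r", "T", 2.50))$sequence, "TTT")
})

test_that("flowgram construction rejects invalid input", {
  expect_error(flowgram("r", "AC", c(1)), "equal length")
  expect_error(flowgram("r", "AC", c(1, -0.2)), "non-negative")
  expect_error(flowgram("r", "AN", c(1, 1)), "T, A, C, G")
})

test_that("noiseless flowgrams round-trip through calling", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_seq(sample(5:200, 1))
    expect_identical(call_flowgram(sequence_to_flowgram(s))$sequence, s)
  }
})

test_that("flowpeak deviation matches the rounding-interval definition", {
  expect_equal(flowpeak_deviation(2.60, 2), 0.10)
  expect_equal(flowpeak_deviation(3.47, 4), 0.03)
  expect_equal(flowpeak_deviation(2.60, 3), 0)
  expect_error(flowpeak_deviation(1.0, -1), ">= 0")

  # against an independent grid-minimization oracle
  set.seed(7)
  for (i in 1:50) {
    f <- round(runif(1, 0, 8), 2)
    m <- sample(0:9, 1)
    # the grid attains the half-open interval edge only to its step size
    expect_lt(abs(flowpeak_deviation(f, m) - grid_deviation(f, m)), 2e-4)
  }
})

test_that("correction penalties follow P = alpha * Dev / n with half-up rounding", {
  m <- scoring_model(gap_open = 5, k = 0.25)  # alpha = 20
  expect_equal(correction_penalty(2.60, 3, 2, m), 1)   # round(20*0.10/3)
  expect_equal(correction_penalty(3.47, 3, 4, m), 0)   # round(20*0.03/3)
  expect_identical(correction_penalty(2.60, 3, 2, scoring_model(k = 0)), Inf)
  expect_error(correction_penalty(0.2, 0, 1, m), "negative flow")
  expect_error(correction_penalty(2.60, 2, 1, m), "called length")
  expect_error(correction_penalty(2.60, 3, 3, m), "between 1 and 4")
})

test_that("penalty is non-decreasing in correction size and scales with 1/k", {
  set.seed(21)
  for (i in 1:30) {
    f <- round(runif(1, 0.5, 6.4), 2)
    nc <- floor(f + 0.5)
    pens <- vapply(1:4, function(d) {
      m <- nc + d
      correction_penalty(f, nc, m, scoring_model(k = 0.25))
    }, numeric(1))
    expect_true(all(diff(pens) >= 0))
    # halving k at least doubles every pre-rounding penalty: on the rounded
    # values, penalty(k/2) >= penalty(k) always holds and the unrounded ratio
    # is exactly 2
    m <- nc + sample(1:4, 1)
    p1 <- scoring_model(k = 0.25)$alpha * flowpeak_deviation(f, m) / nc
    p2 <- scoring_model(k = 0.125)$alpha * flowpeak_deviation(f, m) / nc
    expect_equal(p2, 2 * p1)
  }
})

test_that("alpha is the gap penalty divided by k", {
  expect_equal(scoring_model(gap_open = 7, k = 0.25)$alpha, 28)
  expect_equal(scoring_model(gap_open = 5, k = 0.25)$alpha, 20)
  expect_identical(scoring_model(k = 0)$alpha, Inf)
  m <- scoring_model(gap_open = 6, k = 0.4)
  expect_equal(m$alpha * m$k, m$gap_open)
})

test_that("penalty tables are finite only at run ends and gate below gap cost", {
  m <- scoring_model()  # G0/Ge 5/2, k 0.25, alpha 20
  r <- call_flowgram(flowgram("r", "TAT", c(1.0, 2.40, 1.0)))  # "TAAT"
  expect_equal(r$sequence, "TAAT")
  pt <- build_penalty_tables(r, m)
  # up-call by one base at the A-run end (position 3): round(20*0.10/2) = 1
  expect_equal(pt$Pu[1, 3], 1)
  # non-last positions carry only infinite entries
  expect_true(all(!is.finite(pt$Pd[, !r$homopolymer_last])))
  expect_true(all(!is.finite(pt$Pu[, !r$homopolymer_last])))
  # k = 0 disables everything
  pt0 <- build_penalty_tables(r, scoring_model(k = 0))
  expect_true(all(!is.finite(pt0$Pd)) && all(!is.finite(pt0$Pu)))
})

test_that("an entry equal to the ordinary gap cost is disallowed", {
  # engineer a penalty of exactly G0 for n = 1: alpha * dev / L = 5 with
  # L = 1 requires dev = 5 * k / . : use k such that alpha * 0.25 = 5
  m <- scoring_model(gap_open = 5, gap_extend = 2, k = 1)  # alpha = 5
  # f = 1.0, up-call to 2: dev = 0.5, penalty round(5 * 0.5 / 1) = 3 < 5 ok
  # f = 1.0, up-call to 3: dev = 1.5, penalty round(7.5) = 8 >= G0+Ge = 7
  r <- call_flowgram(flowgram("r", "A", 1.0))
  pt <- build_penalty_tables(r, m)
  expect_equal(pt$Pu[1, 1], 3)
  expect_false(is.finite(pt$Pu[2, 1]))

  # exact equality with the gap cost is gated out (strictly-smaller rule):
  # alpha = 10, f = 1.0, up-call by 1: round(10 * 0.5 / 1) = 5 = G0
  m2 <- scoring_model(gap_open = 5, k = 0.5)
  pt2 <- build_penalty_tables(r, m2)
  expect_false(is.finite(pt2$Pu[1, 1]))
})

test_that("penalty table invariants hold under a random sweep", {
  set.seed(33)
  m <- scoring_model()
  gapcost <- m$gap_open + (1:4 - 1) * m$gap_extend
  for (i in 1:40) {
    s <- random_seq(sample(10:80, 1))
    fg <- add_flow_noise(sequence_to_flowgram(s), noise_model())
    r <- call_flowgram(fg)
    if (!nzchar(r$sequence)) next
    pt <- build_penalty_tables(r, m)
    nb <- nchar(r$sequence)
    ends <- which(r$homopolymer_last)
    lens <- diff(c(0L, ends))
    for (tab in list(pt$Pd, pt$Pu)) {
      fin <- which(is.finite(tab), arr.ind = TRUE)
      # finiteness only at homopolymer-last positions
      expect_true(all(fin[, "col"] %in% ends))
      # strictly below the corresponding ordinary gap cost
      expect_true(all(tab[fin] < gapcost[fin[, "row"]]))
      # monotone-infinity and monotone penalties down the correction size
      for (j in seq_len(nb)) {
        v <- tab[, j]
        inf <- !is.finite(v)
        if (any(inf)) expect_true(all(inf[min(which(inf)):4]))
        if (sum(!inf) > 1) expect_true(all(diff(v[!inf]) >= 0))
      }
    }
    # down-calls never exceed the called length
    for (e in seq_along(ends)) {
      L <- lens[e]
      if (L < 4) expect_true(all(!is.finite(pt$Pd[(L + 1):4, ends[e]])))
    }
  }
})

test_that("reverse complement carries flow values to their mapped bases", {
  r <- call_flowgram(flowgram("r", "TAT", c(1.0, 2.40, 1.0)))  # TAAT
  rc <- reverse_complement(r)
  expect_equal(rc$sequence, "ATTA")
  expect_equal(rc$base_peak, rev(r$base_peak))
  expect_equal(rc$base_flow, rev(r$base_flow))
  expect_equal(rc$homopolymer_last, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(reverse_complement("ACGTN"), "NACGT")
})
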