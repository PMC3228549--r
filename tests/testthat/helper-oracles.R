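# Shared fixtures and independent oracles used across the suite.

ACGT <- c("A", "C", "G", "T")

random_seq <- function(n, alphabet = ACGT) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent oracle for the flowpeak deviation: minimize |f' - f| over a
# fine grid of candidate peak values f' whose called length is m.
grid_deviation <- function(f, m, step = 1e-4, span = 12) {
  fp <- seq(0, span, by = step)
  fp <- fp[floor(fp + 0.5) == m]
  min(abs(fp - f))
}

# Brute-force k-tuple occurrence scan: every window of length k made only of
# ACGT, as (seq_id, 0-based offset) pairs.
brute_occurrences <- function(db, k) {
  out <- data.frame(seq_id = integer(0), offset = integer(0),
                    tuple = character(0))
  for (s in seq_along(db)) {
    n <- nchar(db[[s]])
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    wins <- substring(db[[s]], starts, starts + k - 1L)
    keep <- !grepl("[^ACGT]", wins)
    if (any(keep))
      out <- rbind(out, data.frame(seq_id = s, offset = starts[keep] - 1L,
                                   tuple = wins[keep]))
  }
  out
}

# Brute-force hit finder: all (query window, database window) pairs with
# identical k-tuples.
brute_hits <- function(db, query, k) {
  occ <- brute_occurrences(db, k)
  qocc <- brute_occurrences(list(query), k)
  if (!nrow(occ) || !nrow(qocc))
    return(data.frame(db_id = integer(0), db_offset = integer(0),
                      q_offset = integer(0), diagonal = integer(0)))
  m <- merge(qocc[, c("offset", "tuple")], occ, by = "tuple")
  h <- data.frame(db_id = m$seq_id, db_offset = m$offset.y,
                  q_offset = m$offset.x)
  h$diagonal <- h$db_offset - h$q_offset
  h <- h[order(h$db_id, h$diagonal, h$q_offset), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Direct evaluation of the diagonal-run rule: maximal runs of >= n hits on
# one exact diagonal with consecutive query offsets spaced < J apart.
brute_candidates <- function(hits, min_hits, max_spacing) {
  out <- list()
  if (!nrow(hits)) {
    return(data.frame(db_id = integer(0), diagonal = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      n_hits = integer(0)))
  }
  for (key in unique(paste(hits$db_id, hits$diagonal))) {
    sub <- hits[paste(hits$db_id, hits$diagonal) == key, , drop = FALSE]
    qs <- sort(sub$q_offset)
    run <- qs[1]
    for (i in seq_along(qs)[-1]) {
      if (qs[i] - qs[i - 1] < max_spacing) run <- c(run, qs[i])
      else {
        if (length(run) >= min_hits)
          out[[length(out) + 1L]] <- data.frame(
            db_id = sub$db_id[1], diagonal = sub$diagonal[1],
            q_start = run[1], q_end = run[length(run)],
            n_hits = length(run))
        run <- qs[i]
      }
    }
    if (length(run) >= min_hits)
      out[[length(out) + 1L]] <- data.frame(
        db_id = sub$db_id[1], diagonal = sub$diagonal[1],
        q_start = run[1], q_end = run[length(run)], n_hits = length(run))
  }
  if (!length(out)) {
    return(data.frame(db_id = integer(0), diagonal = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      n_hits = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$db_id, res$diagonal, res$q_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# A random fixed-flow-count flowgram over the TACG cycle.
random_flowgram <- function(name, n_cycles = 25L) {
  chars <- rep(c("T", "A", "C", "G"), n_cycles)
  peaks <- round(pmax(0, rnorm(length(chars),
                               mean = sample(0:3, length(chars), TRUE),
                               sd = 0.2)), 2)
  flowgram(name, chars, peaks)
}

# Upper bound of the one-sided 95% normal-approximation interval for
# p_b - p_a; "a >= b within binomial confidence" <=> this is >= 0.
ci_margin_ge <- function(succ_a, succ_b, n) {
  pa <- succ_a / n; pb <- succ_b / n
  se <- sqrt(pa * (1 - pa) / n + pb * (1 - pb) / n)
  (pa - pb) + 1.96 * se
}
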