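#' Flowgram: the raw pyrosequencing signal
#'
#' A flowgram is the ordered series of flowpeak intensities recorded while
#' nucleotide reagents are cycled (for 454 chemistry, in the fixed order
#' T, A, C, G) over a template. Each flowpeak is approximately proportional to
#' the length of the homopolymer incorporated at that flow; peaks below 0.5
#' are *negative flows* (no incorporation), peaks at or above 0.5 are
#' *positive flows*.
#'
#' @param name read identifier.
#' @param flow_chars the flowed nucleotide per flow: either a single string
#'   (e.g. `"TACGTACG"`) or a character vector of single bases.
#' @param flowpeaks numeric vector of non-negative peak intensities, one per
#'   flow (instrument resolution 0.01).
#' @return An object of class `flowgram`.
#' @examples
#' fg <- flowgram("r1", "ACGT", c(0.11, 1.83, 0.97, 0.97))
#' call_flowgram(fg)$sequence  # "CCGT"
#' @export
flowgram <- function(name, flow_chars, flowpeaks) {
  if (length(flow_chars) == 1L && nchar(flow_chars) != 1L)
    flow_chars <- strsplit(flow_chars, "")[[1]]
  flow_chars <- as.character(flow_chars)
  flowpeaks <- as.numeric(flowpeaks)
  if (length(flow_chars) != length(flowpeaks))
    stop("flow_chars and flowpeaks must have equal length")
  if (length(flowpeaks) && any(flowpeaks < 0))
    stop("flowpeaks must be non-negative")
  if (!all(flow_chars %in% c("T", "A", "C", "G")))
    stop("flow characters must be one of T, A, C, G")
  structure(list(name = as.character(name), flow_chars = flow_chars,
                 flowpeaks = flowpeaks),
            class = "flowgram")
}

#' @export
print.flowgram <- function(x, ...) {
  cat("<flowgram> ", x$name, ": ", length(x$flowpeaks), " flows\n", sep = "")
  nshow <- min(12L, length(x$flowpeaks))
  if (nshow)
    cat(paste0(x$flow_chars[seq_len(nshow)],
               sprintf("(%.2f)", x$flowpeaks[seq_len(nshow)])),
        if (length(x$flowpeaks) > nshow) "...", "\n")
  invisible(x)
}

#' Called read: base calls with their flow provenance
#'
#' The base-called nucleotide sequence of a flowgram together with, per base,
#' the flow it was called from, that flow's peak value, and a flag marking the
#' last base of each homopolymer run (each positive flow is one run).
#'
#' @param sequence nucleotide string.
#' @param base_flow integer vector, per-base index of the originating flow.
#' @param base_peak numeric vector, per-base flowpeak of the originating flow.
#' @param homopolymer_last logical vector, `TRUE` on the last base of each run.
#' @param name read identifier.
#' @return An object of class `called_read`.
#' @seealso [call_flowgram()], [as_called_read()]
#' @export
called_read <- function(sequence, base_flow, base_peak, homopolymer_last,
                        name = "read") {
  n <- nchar(sequence)
  if (length(base_flow) != n || length(base_peak) != n ||
      length(homopolymer_last) != n)
    stop("per-base vectors must match the sequence length")
  structure(list(name = as.character(name), sequence = sequence,
                 base_flow = as.integer(base_flow),
                 base_peak = as.numeric(base_peak),
                 homopolymer_last = as.logical(homopolymer_last)),
            class = "called_read")
}

#' @export
print.called_read <- function(x, ...) {
  cat("<called_read> ", x$name, ": ", nchar(x$sequence), " bases\n", sep = "")
  cat(" ", substr(x$sequence, 1, 60),
      if (nchar(x$sequence) > 60) "...", "\n", sep = "")
  invisible(x)
}

#' Base-call a flowgram
#'
#' Each flow with peak `f` emits `floor(f + 0.5)` copies of its flowed base:
#' peaks below 0.5 are negative flows and call nothing, a peak of exactly
#' `m + 0.5` calls `m + 1` bases. Each positive flow is treated as one
#' homopolymer run.
#'
#' @param flowgram a [flowgram].
#' @return A [called_read].
#' @export
call_flowgram <- function(flowgram) {
  stopifnot(inherits(flowgram, "flowgram"))
  if (length(flowgram$flowpeaks) && any(flowgram$flowpeaks < 0))
    stop("flowpeaks must be non-negative")
  counts <- as.integer(floor(flowgram$flowpeaks + 0.5))
  pos <- which(counts > 0L)
  if (!length(pos))
    return(called_read("", integer(0), numeric(0), logical(0),
                       name = flowgram$name))
  cnt <- counts[pos]
  seq <- paste(rep(flowgram$flow_chars[pos], cnt), collapse = "")
  base_flow <- rep(pos, cnt)
  base_peak <- rep(flowgram$flowpeaks[pos], cnt)
  # last base of each flow emission
  hl <- rep(FALSE, sum(cnt))
  hl[cumsum(cnt)] <- TRUE
  called_read(seq, base_flow, base_peak, hl, name = flowgram$name)
}

#' Coerce to a called read
#'
#' Plain sequences are given ideal (integer-valued) flowpeaks by building the
#' noiseless flowgram over the given flow order and calling it back.
#'
#' @param x a `called_read`, `flowgram`, or nucleotide string.
#' @param flow_order flow cycle used for plain sequences.
#' @param name read identifier for plain sequences.
#' @return A [called_read].
#' @export
as_called_read <- function(x, flow_order = "TACG", name = "read") {
  if (inherits(x, "called_read")) return(x)
  if (inherits(x, "flowgram")) return(call_flowgram(x))
  if (is.character(x) && length(x) == 1L)
    return(call_flowgram(sequence_to_flowgram(x, flow_order = flow_order,
                                              name = name)))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a called_read")
}

#' Scoring model for (flow-space assisted) local alignment
#'
#' Match/mismatch scores and affine gap penalties of the Smith-Waterman-Gotoh
#' model, plus the flow-deviation parameter `k` controlling homopolymer
#' correction penalties. A correction requiring relative flowpeak deviation
#' `Dev/n` is penalized `P = alpha * Dev / n` with `alpha = G0 / k`, so `k` is
#' the relative deviation at which a correction costs as much as a minimum
#' gap, i.e. the maximum flowpeak correction effectively allowed. `k = 0`
#' makes every correction penalty infinite and reduces the aligner to plain
#' Smith-Waterman-Gotoh.
#'
#' @param match score for an identical base pair (> 0); default 2.
#' @param mismatch score for a differing base pair (<= 0); default -3.
#' @param gap_open penalty `G0` of a length-1 gap (>= `gap_extend`); default 5.
#' @param gap_extend penalty `Ge` per additional gap base; default 2.
#' @param k maximum relative flowpeak deviation (>= 0); default 0.25.
#' @param max_correction maximum bases corrected per event (fixed at 4).
#' @return An object of class `scoring_model` with the derived constant
#'   `alpha = gap_open / k` (`Inf` when `k = 0`).
#' @examples
#' scoring_model(gap_open = 7, k = 0.25)$alpha  # 28
#' @export
scoring_model <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, k = 0.25, max_correction = 4L) {
  if (!(match > 0)) stop("match score must be positive")
  if (!(mismatch <= 0)) stop("mismatch score must be <= 0")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("gap penalties must satisfy gap_open >= gap_extend >= 0")
  if (!(k >= 0)) stop("k must be >= 0")
  if (max_correction != 4L) stop("max_correction is fixed at 4")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), k = k,
                 max_correction = 4L,
                 alpha = if (k > 0) gap_open / k else Inf),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model> match/mismatch ", x$match, "/", x$mismatch,
      ", gap open/extend ", x$gap_open, "/", x$gap_extend,
      ", k = ", x$k, " (alpha = ", format(x$alpha), ")\n", sep = "")
  invisible(x)
}

#' Flowpeak deviation needed to call a peak as an m-homopolymer
#'
#' A peak `f` is called as `floor(f + 0.5)` bases. The deviation to length `m`
#' is the smallest `|f' - f|` over peak values `f'` that call as `m`: zero if
#' `f` already calls as `m`, else the distance from `f` to the nearer edge of
#' the rounding interval `[m - 0.5, m + 0.5)`.
#'
#' @param f flowpeak value(s), >= 0.
#' @param m target homopolymer length(s), integer >= 0.
#' @return Numeric deviation(s) `Dev_m`.
#' @examples
#' flowpeak_deviation(2.60, 2)  # 0.10
#' flowpeak_deviation(3.47, 4)  # 0.03
#' @export
flowpeak_deviation <- function(f, m) {
  if (any(m < 0)) stop("target homopolymer length m must be >= 0")
  if (any(f < 0)) stop("flowpeak value must be >= 0")
  if (any(m != floor(m))) stop("m must be integer")
  called <- floor(f + 0.5)
  ifelse(called == m, 0,
         ifelse(m < called, f - (m + 0.5), (m - 0.5) - f))
}

#' Penalty for a single homopolymer correction
#'
#' The integer score penalty for re-calling a flowpeak `f` (called length
#' `n_called`) as an `m`-homopolymer: `round(alpha * Dev_m / n_called)` with
#' `alpha = G0 / k`, half-up rounding. With `k = 0` all corrections are
#' infinitely penalized.
#'
#' @param f flowpeak value.
#' @param n_called called homopolymer length, `floor(f + 0.5)`, >= 1.
#' @param m corrected homopolymer length, `1 <= |m - n_called| <= 4`.
#' @param model a [scoring_model].
#' @return Integer penalty, or `Inf` when `k = 0`.
#' @examples
#' m <- scoring_model(gap_open = 5, k = 0.25)
#' correction_penalty(2.60, 3, 2, m)  # 1
#' correction_penalty(3.47, 3, 4, m)  # 0
#' @export
correction_penalty <- function(f, n_called, m, model) {
  stopifnot(inherits(model, "scoring_model"))
  if (n_called == 0)
    stop("a negative flow (called length 0) admits no correction")
  if (n_called != floor(f + 0.5))
    stop("n_called must equal the called length floor(f + 0.5)")
  dm <- abs(m - n_called)
  if (dm < 1 || dm > model$max_correction)
    stop("|m - n_called| must be between 1 and ", model$max_correction)
  if (model$k == 0) return(Inf)
  round_half_up(model$alpha * flowpeak_deviation(f, m) / n_called)
}

#' Pre-computed homopolymer correction penalty tables
#'
#' For every query position `j` that ends a homopolymer run of called length
#' `L` with flowpeak `f`, the down-call penalties `Pd[n, j]` (shorten by
#' `n = 1..min(4, L)` bases, down to length 0) and up-call penalties
#' `Pu[n, j]` (lengthen by `n = 1..4` bases) are computed with
#' [correction_penalty()]. An entry is kept only if it is strictly smaller
#' than the cost of an ordinary gap of the same length,
#' `G0 + (n - 1) * Ge`; all other entries are infinite, and once an entry is
#' infinite all larger `n` at that position are too. Positions that do not
#' end a run carry only infinite entries.
#'
#' @param read a [called_read] (or object coercible via [as_called_read()]).
#' @param model a [scoring_model].
#' @return An object of class `penalty_table`: list with `Pd` and `Pu`,
#'   4 x nchar numeric matrices (`Inf` = disallowed).
#' @examples
#' r <- call_flowgram(flowgram("r", "TAT", c(1, 2.4, 1)))
#' pt <- build_penalty_tables(r, scoring_model())
#' pt$Pu[1, 3]  # 1: up-call of the AA run (peak 2.40) by one base
#' @export
build_penalty_tables <- function(read, model) {
  read <- as_called_read(read)
  stopifnot(inherits(model, "scoring_model"))
  m <- nchar(read$sequence)
  Pd <- matrix(Inf, nrow = 4, ncol = m)
  Pu <- matrix(Inf, nrow = 4, ncol = m)
  tab <- structure(list(Pd = Pd, Pu = Pu, query_length = m),
                   class = "penalty_table")
  if (m == 0L || model$k == 0) return(tab)
  ends <- which(read$homopolymer_last)
  if (!length(ends)) return(tab)
  lens <- diff(c(0L, ends))      # run lengths, runs partition the read
  f <- read$base_peak[ends]
  alpha <- model$alpha
  gapcost <- model$gap_open + (seq_len(4) - 1) * model$gap_extend
  for (i in seq_along(ends)) {
    j <- ends[i]; L <- lens[i]; fi <- f[i]
    for (n in seq_len(min(4L, L))) {
      p <- round_half_up(alpha * flowpeak_deviation(fi, L - n) / L)
      Pd[n, j] <- if (p < gapcost[n]) p else Inf
    }
    for (n in 1:4) {
      p <- round_half_up(alpha * flowpeak_deviation(fi, L + n) / L)
      Pu[n, j] <- if (p < gapcost[n]) p else Inf
    }
    # monotone-infinity: once infinite, larger corrections stay infinite
    for (n in 2:4) {
      if (!is.finite(Pd[n - 1, j])) Pd[n, j] <- Inf
      if (!is.finite(Pu[n - 1, j])) Pu[n, j] <- Inf
    }
  }
  tab$Pd <- Pd; tab$Pu <- Pu
  tab
}

#' @export
print.penalty_table <- function(x, ...) {
  fin <- sum(is.finite(x$Pd)) + sum(is.finite(x$Pu))
  cat("<penalty_table> query length ", x$query_length, ", ", fin,
      " finite entries\n", sep = "")
  invisible(x)
}
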