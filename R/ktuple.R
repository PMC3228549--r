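#' SSAHA-style k-tuple database index
#'
#' Every window of `tuple_size` consecutive plain nucleotides (T, A, C or G;
#' windows containing any other character are skipped) in every database
#' sequence is encoded as a base-4 integer (alphabet order T, A, C, G) and its
#' occurrences recorded in a flat list `L` of (sequence id, 0-based offset)
#' pairs, sorted by tuple, then sequence, then offset. A pointer list `P` of
#' length `4^tuple_size + 1` gives, for tuple `t`, the occurrence range
#' `L[P[t] .. P[t + 1])`.
#'
#' @param db named character vector of database sequences.
#' @param tuple_size k-mer length, 1..14 (default 11).
#' @return An object of class `ktuple_index`.
#' @export
build_index <- function(db, tuple_size = 11L) {
  tuple_size <- as.integer(tuple_size)
  if (tuple_size < 1L || tuple_size > 14L)
    stop("tuple_size must be between 1 and 14")
  if (!length(db)) stop("database is empty")
  if (is.null(names(db))) names(db) <- paste0("seq", seq_along(db))
  occ_seq <- integer(0); occ_off <- integer(0); occ_tup <- numeric(0)
  for (s in seq_along(db)) {
    enc <- encode_tuples(db[[s]], tuple_size)
    keep <- which(!is.na(enc))
    if (length(keep)) {
      occ_seq <- c(occ_seq, rep.int(s, length(keep)))
      occ_off <- c(occ_off, keep - 1L)   # 0-based offsets
      occ_tup <- c(occ_tup, enc[keep])
    }
  }
  if (!length(occ_tup) && all(nchar(db) < tuple_size))
    warning("tuple_size is larger than every database sequence; empty index")
  o <- order(occ_tup, occ_seq, occ_off)
  occ_seq <- occ_seq[o]; occ_off <- occ_off[o]; occ_tup <- occ_tup[o]
  ntup <- 4^tuple_size
  counts <- tabulate(as.integer(occ_tup) + 1L, nbins = ntup)
  P <- c(1, cumsum(as.numeric(counts)) + 1)  # 1-based starts into L, 4^k + 1
  structure(list(tuple_size = tuple_size,
                 L = list(seq_id = occ_seq, offset = occ_off),
                 P = P, db = db),
            class = "ktuple_index")
}

#' @export
print.ktuple_index <- function(x, ...) {
  cat("<ktuple_index> k = ", x$tuple_size, ", ", length(x$db),
      " sequences, ", length(x$L$seq_id), " tuple occurrences\n", sep = "")
  invisible(x)
}

# Base-4 encoding (T=0, A=1, C=2, G=3) of all windows of length k;
# NA where the window contains a non-ACGT character.
encode_tuples <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  codes <- match(strsplit(toupper(seq), "")[[1]], c("T", "A", "C", "G")) - 1
  nw <- n - k + 1L
  val <- numeric(nw)
  for (l in seq_len(k)) val <- val * 4 + codes[l:(nw + l - 1L)]
  val
}

#' Index occupancy statistics
#'
#' Histogram of tuple occupancy: how many distinct tuples occur 1, 2, ...
#' times in the database.
#'
#' @param index a [build_index()] result.
#' @return A data frame with columns `occurrences` and `tuples`.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "ktuple_index"))
  occ <- diff(index$P)
  occ <- occ[occ > 0]
  tb <- table(occ)
  data.frame(occurrences = as.integer(names(tb)), tuples = as.integer(tb))
}

#' Find k-tuple hits of a query against an index
#'
#' Every (query window, database occurrence) pair sharing a k-tuple is a hit,
#' with `diagonal = db_offset - q_offset`. Hits are sorted by database
#' sequence, diagonal, then query offset.
#'
#' @param index a [build_index()] result.
#' @param query nucleotide string.
#' @return A data frame with columns `db_id`, `db_offset`, `q_offset`,
#'   `diagonal` (all offsets 0-based). Empty when the query is shorter than
#'   the tuple size.
#' @export
find_hits <- function(index, query) {
  stopifnot(inherits(index, "ktuple_index"))
  empty <- data.frame(db_id = integer(0), db_offset = integer(0),
                      q_offset = integer(0), diagonal = integer(0))
  if (nchar(query) < index$tuple_size) return(empty)
  enc <- encode_tuples(query, index$tuple_size)
  qoff <- which(!is.na(enc)) - 1L
  if (!length(qoff)) return(empty)
  tup <- enc[qoff + 1L]
  from <- index$P[tup + 1]
  cnt <- index$P[tup + 2] - from
  keep <- cnt > 0
  if (!any(keep)) return(empty)
  qoff <- qoff[keep]; from <- from[keep]; cnt <- as.integer(cnt[keep])
  li <- sequence(cnt) + rep(from, cnt) - 1
  hits <- data.frame(db_id = index$L$seq_id[li],
                     db_offset = index$L$offset[li],
                     q_offset = rep(qoff, cnt))
  hits$diagonal <- hits$db_offset - hits$q_offset
  hits[order(hits$db_id, hits$diagonal, hits$q_offset), , drop = FALSE]
}

#' Seeding heuristic parameters
#'
#' An alignment is attempted for a database region only if at least
#' `min_hits` k-tuple hits fall on the same exact diagonal with consecutive
#' query offsets spaced strictly less than `max_spacing` apart. The `top_v`
#' best-scoring candidates are re-aligned with full traceback.
#'
#' @param min_hits required hits per diagonal run (default 2).
#' @param max_spacing maximum spacing between consecutive hits, exclusive
#'   (default 50).
#' @param top_v number of top-scoring alignments re-aligned with trace
#'   (default 1).
#' @return An object of class `heuristic_params`.
#' @export
heuristic_params <- function(min_hits = 2L, max_spacing = 50L, top_v = 1L) {
  if (min_hits < 1L || max_spacing < 1L || top_v < 1L)
    stop("min_hits, max_spacing and top_v must all be >= 1")
  structure(list(min_hits = as.integer(min_hits),
                 max_spacing = as.integer(max_spacing),
                 top_v = as.integer(top_v)),
            class = "heuristic_params")
}

#' Select candidate regions from diagonal hit runs
#'
#' Scans each (database sequence, diagonal) group for maximal runs of at
#' least `min_hits` hits whose consecutive query offsets differ by strictly
#' less than `max_spacing`.
#'
#' @param hits a [find_hits()] data frame (sorted per its contract).
#' @param params a [heuristic_params()].
#' @return A data frame with one candidate per qualifying run: `db_id`,
#'   `diagonal`, `q_start`, `q_end` (offsets of the run's first and last
#'   hit), `n_hits`.
#' @export
select_candidates <- function(hits, params = heuristic_params()) {
  stopifnot(inherits(params, "heuristic_params"))
  empty <- data.frame(db_id = integer(0), diagonal = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      n_hits = integer(0))
  if (!nrow(hits)) return(empty)
  # run breaks: new (db, diagonal) group or spacing >= max_spacing
  newgrp <- c(TRUE, hits$db_id[-1] != hits$db_id[-nrow(hits)] |
                    hits$diagonal[-1] != hits$diagonal[-nrow(hits)])
  gap <- c(Inf, diff(hits$q_offset))
  brk <- newgrp | gap >= params$max_spacing
  run <- cumsum(brk)
  size <- tabulate(run)
  keep <- which(size >= params$min_hits)
  if (!length(keep)) return(empty)
  first <- match(keep, run)
  last <- length(run) - match(keep, rev(run)) + 1L
  data.frame(db_id = hits$db_id[first], diagonal = hits$diagonal[first],
             q_start = hits$q_offset[first], q_end = hits$q_offset[last],
             n_hits = size[keep])
}

# Merge candidate diagonals on one database sequence into clipped DP windows:
# each candidate contributes the db range [diag - (qlen + J), diag + qlen +
# (qlen + J)); overlapping ranges are merged.
candidate_windows <- function(cands, qlen, db_len, max_spacing) {
  pad <- qlen + max_spacing
  lo <- pmax(0L, cands$diagonal - pad)
  hi <- pmin(db_len, cands$diagonal + qlen + pad)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1) for (i in 2:length(lo)) {
    if (lo[i] <= out_hi[length(out_hi)]) {
      out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[i])
    } else {
      out_lo <- c(out_lo, lo[i]); out_hi <- c(out_hi, hi[i])
    }
  }
  data.frame(lo = out_lo, hi = out_hi)
}

#' Search a database index with a read
#'
#' The full search pipeline: k-tuple hits on both strands, diagonal-run
#' candidate selection, score-only flow-assisted (or plain) alignment of the
#' query against each candidate database window, ranking by score, and full
#' traceback re-alignment of the `top_v` best candidates. The minus strand is
#' searched by reverse-complementing the called read (flowpeak values carried
#' to their mapped bases) and rebuilding its penalty tables. Results are
#' deterministic: ties rank by database order, then strand (`+` first).
#'
#' Plain character queries carry no flow information, so they are aligned
#' with ordinary Smith-Waterman-Gotoh scoring regardless of `model$k`.
#'
#' @param index a [build_index()] result.
#' @param read a [called_read], [flowgram], or plain nucleotide string.
#' @param model a [scoring_model].
#' @param params a [heuristic_params()].
#' @return An object of class `search_result`: list with `hits` (data frame
#'   of all scored candidates: query, db, strand, score) and `alignments`
#'   (list of `alignment_result` for the `top_v` best).
#' @export
flow_search <- function(index, read, model = scoring_model(),
                        params = heuristic_params()) {
  stopifnot(inherits(index, "ktuple_index"))
  plain <- is.character(read) && !inherits(read, "called_read")
  if (plain) {
    qname <- if (!is.null(names(read))) names(read)[1] else "query"
    reads <- list("+" = setNames(unname(read[1]), NULL),
                  "-" = reverse_complement(unname(read[1])))
  } else {
    read <- as_called_read(read)
    qname <- read$name
    reads <- list("+" = read, "-" = reverse_complement(read))
  }
  rows <- list(); wins <- list()
  for (strand in c("+", "-")) {
    q <- reads[[strand]]
    qseq <- if (plain) q else q$sequence
    if (!nzchar(qseq)) next
    pens <- if (plain) NULL else build_penalty_tables(q, model)
    cands <- select_candidates(find_hits(index, qseq), params)
    for (s in unique(cands$db_id)) {
      cw <- candidate_windows(cands[cands$db_id == s, , drop = FALSE],
                              nchar(qseq), nchar(index$db[[s]]),
                              params$max_spacing)
      segs <- substring(index$db[[s]], cw$lo + 1L, cw$hi)
      scores <- if (plain) score_only(segs, qseq, model = model)
                else score_only(segs, q, penalties = pens, model = model)
      b <- which.max(scores)
      rows[[length(rows) + 1L]] <- data.frame(
        query = qname, db = names(index$db)[s], strand = strand,
        score = scores[b], stringsAsFactors = FALSE)
      wins[[length(wins) + 1L]] <- list(db_id = s, strand = strand,
                                        lo = cw$lo[b], hi = cw$hi[b],
                                        pens = pens, q = q)
    }
  }
  if (!length(rows)) {
    return(structure(list(hits = data.frame(query = character(0),
                                            db = character(0),
                                            strand = character(0),
                                            score = integer(0)),
                          alignments = list()),
                     class = "search_result"))
  }
  hits <- do.call(rbind, rows)
  ord <- order(-hits$score, match(hits$db, names(index$db)),
               hits$strand != "+")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  wins <- wins[ord]
  ntrace <- min(params$top_v, nrow(hits))
  alns <- vector("list", ntrace)
  for (i in seq_len(ntrace)) {
    w <- wins[[i]]
    seg <- substring(index$db[[w$db_id]], w$lo + 1L, w$hi)
    raw <- if (is.null(w$pens)) {
      cpp_swg_align(seg, if (plain) w$q else w$q$sequence, model$match,
                    model$mismatch, model$gap_open, model$gap_extend, TRUE)
    } else {
      cpp_flow_align(seg, w$q$sequence, w$pens$Pd, w$pens$Pu, model$match,
                     model$mismatch, model$gap_open, model$gap_extend, TRUE)
    }
    alns[[i]] <- new_alignment_result(
      raw, method = if (is.null(w$pens)) "swg" else "flow",
      db_name = names(index$db)[w$db_id], q_name = qname,
      strand = w$strand, db_offset = w$lo)
  }
  structure(list(hits = hits, alignments = alns), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$hits), " scored candidate(s), ",
      length(x$alignments), " traced\n", sep = "")
  if (nrow(x$hits)) print(head(x$hits, 10))
  invisible(x)
}
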