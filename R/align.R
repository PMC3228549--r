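#' @rdname swg_align
#' @name alignment_result
#' @details
#' Both aligners return an `alignment_result`: a list with the optimal local
#' `score`, 0-based half-open `db_interval` and `q_interval`, the gapped
#' strings `aligned_db` and `aligned_query` (corrected query bases in lower
#' case), a `corrections` data frame (query position of the corrected
#' homopolymer's last base, kind `"up"`/`"down"`, size, penalty charged) and
#' the `identity_fraction` (matching columns / alignment columns).
NULL

new_alignment_result <- function(raw, method, db_name = "db",
                                 q_name = "query", strand = "+",
                                 db_offset = 0L) {
  corr <- data.frame(
    j = raw$corr_j, kind = c("up", "down")[raw$corr_kind],
    n = raw$corr_n, penalty = raw$corr_pen,
    stringsAsFactors = FALSE)
  cols <- nchar(raw$aligned_db)
  nmatch <- 0L
  if (cols > 0) {
    a <- strsplit(raw$aligned_db, "")[[1]]
    b <- strsplit(raw$aligned_query, "")[[1]]
    nmatch <- sum(a == b & a %in% c("A", "C", "G", "T"))
  }
  structure(list(
    score = raw$score,
    db_interval = c(raw$db_start + db_offset, raw$db_end + db_offset),
    q_interval = c(raw$q_start, raw$q_end),
    aligned_db = raw$aligned_db,
    aligned_query = raw$aligned_query,
    corrections = corr,
    identity_fraction = if (cols > 0) nmatch / cols else NA_real_,
    method = method, db_name = db_name, q_name = q_name, strand = strand),
    class = "alignment_result")
}

#' Smith-Waterman-Gotoh local alignment
#'
#' Optimal local alignment with match/mismatch scoring and affine gap
#' penalties (a length-`n` gap costs `G0 + (n - 1) * Ge`), with full
#' traceback. Non-ACGT characters always score as mismatches. Traceback ties
#' prefer, in order: diagonal, up-call, down-call, database gap, query gap;
#' among equally scoring end cells the one with the smallest (db, query)
#' coordinates is used.
#'
#' @param db database nucleotide sequence (string).
#' @param query query nucleotide sequence (string) or [called_read].
#' @param model a [scoring_model] (its `k` is ignored here).
#' @param db_name,q_name identifiers used in rendered output.
#' @return An `alignment_result`; see Details.
#' @examples
#' swg_align("TAAAT", "TAAT", scoring_model())$score  # 6
#' @export
swg_align <- function(db, query, model = scoring_model(), db_name = "db",
                      q_name = NULL) {
  stopifnot(inherits(model, "scoring_model"))
  if (inherits(query, "called_read")) {
    if (is.null(q_name)) q_name <- query$name
    query <- query$sequence
  }
  if (is.null(q_name)) q_name <- "query"
  if (!nzchar(db) || !nzchar(query)) stop("sequences must be non-empty")
  raw <- cpp_swg_align(db, query, model$match, model$mismatch,
                       model$gap_open, model$gap_extend, TRUE)
  new_alignment_result(raw, "swg", db_name, q_name)
}

#' Flow-space assisted local alignment
#'
#' Smith-Waterman-Gotoh extended with homopolymer corrections: each DP cell
#' takes `C = max(D, S)` where `D` is the ordinary Gotoh score (its gap and
#' diagonal recursions referencing `C`, so corrections and gaps compose) and
#' `S` considers, for the query homopolymer ending at `j`, down-calls
#' (`C[i, j - n] - Pd[n, j]`: the run's last `n` bases placed against
#' database gaps) and up-calls (`C[i - n, j] - Pu[n, j]`, valid only when all
#' `n` consumed database bases equal the query base: the run lengthened by
#' `n` inserted copies). Corrected bases are rendered in lower case and
#' contribute no substitution score; the correction penalty is the entire
#' cost of the event. With `k = 0` every penalty is infinite and the result
#' is identical to [swg_align()].
#'
#' @param db database nucleotide sequence (string).
#' @param read a [called_read] (or [flowgram], or plain sequence, coerced via
#'   [as_called_read()]).
#' @param penalties a [build_penalty_tables()] result for `read` under
#'   `model`; built on the fly when `NULL`.
#' @param model a [scoring_model].
#' @param db_name database identifier used in rendered output.
#' @return An `alignment_result`; see [swg_align()].
#' @examples
#' r <- call_flowgram(flowgram("r", "TAT", c(1, 2.4, 1)))  # "TAAT"
#' a <- flow_align("TAAAT", r)
#' a$score          # 7 (vs 6 for swg_align)
#' a$aligned_query  # "TAaAT": one up-called, lower-case base
#' @export
flow_align <- function(db, read, penalties = NULL, model = scoring_model(),
                       db_name = "db") {
  stopifnot(inherits(model, "scoring_model"))
  read <- as_called_read(read)
  if (!nzchar(db) || !nzchar(read$sequence))
    stop("sequences must be non-empty")
  if (is.null(penalties)) penalties <- build_penalty_tables(read, model)
  stopifnot(inherits(penalties, "penalty_table"))
  if (penalties$query_length != nchar(read$sequence))
    stop("penalty table width does not match the read length")
  raw <- cpp_flow_align(db, read$sequence, penalties$Pd, penalties$Pu,
                        model$match, model$mismatch, model$gap_open,
                        model$gap_extend, TRUE)
  new_alignment_result(raw, "flow", db_name, read$name)
}

#' Alignment score without traceback
#'
#' Returns the same optimal local score as [flow_align()] (or [swg_align()]
#' for a plain sequence) without materializing traceback state; used by the
#' two-pass database search (score every candidate, trace only the top hits).
#'
#' @inheritParams flow_align
#' @param read_or_seq a [called_read] (flow-assisted scoring) or a plain
#'   nucleotide string (plain Smith-Waterman-Gotoh scoring).
#' @return Integer score. `db` may be a character vector; one score per
#'   database sequence is returned.
#' @export
score_only <- function(db, read_or_seq, penalties = NULL,
                       model = scoring_model()) {
  stopifnot(inherits(model, "scoring_model"))
  if (is.character(read_or_seq) && !inherits(read_or_seq, "called_read")) {
    q <- read_or_seq
    empty <- matrix(numeric(0), nrow = 4, ncol = 0)
    return(cpp_score_batch(db, q, empty, empty, model$match, model$mismatch,
                           model$gap_open, model$gap_extend, FALSE))
  }
  read <- as_called_read(read_or_seq)
  if (is.null(penalties)) penalties <- build_penalty_tables(read, model)
  if (penalties$query_length != nchar(read$sequence))
    stop("penalty table width does not match the read length")
  cpp_score_batch(db, read$sequence, penalties$Pd, penalties$Pu, model$match,
                  model$mismatch, model$gap_open, model$gap_extend, TRUE)
}

#' Render an alignment as pairwise text
#'
#' Two-row text rendering with `-` for gaps and lower-case query characters
#' marking homopolymer corrections; coordinates in the flanking labels are
#' 1-based.
#'
#' @param x an `alignment_result`.
#' @param width characters per block.
#' @return A character vector of lines, invisibly printed by
#'   `print.alignment_result`.
#' @export
alignment_text <- function(x, width = 60L) {
  stopifnot(inherits(x, "alignment_result"))
  n <- nchar(x$aligned_db)
  if (n == 0L) return(sprintf("%s vs %s: empty alignment (score 0)",
                              x$q_name, x$db_name))
  a <- strsplit(x$aligned_db, "")[[1]]
  b <- strsplit(x$aligned_query, "")[[1]]
  mid <- ifelse(a == b & a %in% c("A", "C", "G", "T"), "|",
                ifelse(tolower(a) == tolower(b) | a == "-" | b == "-",
                       " ", "."))
  lines <- character(0)
  dpos <- x$db_interval[1]; qpos <- x$q_interval[1]
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    dseg <- a[s:e]; qseg <- b[s:e]
    nd <- sum(dseg != "-"); nq <- sum(qseg != "-")
    lines <- c(lines,
      sprintf("db    %6d %s %d", dpos + 1L, paste(dseg, collapse = ""),
              dpos + nd),
      sprintf("             %s", paste(mid[s:e], collapse = "")),
      sprintf("query %6d %s %d", qpos + 1L, paste(qseg, collapse = ""),
              qpos + nq),
      "")
    dpos <- dpos + nd; qpos <- qpos + nq
  }
  lines
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$q_name, " vs ", x$db_name,
      " (", x$method, ", strand ", x$strand, ")\n", sep = "")
  cat(" score ", x$score,
      ", identity ", if (is.na(x$identity_fraction)) "NA" else
        sprintf("%.3f", x$identity_fraction),
      ", db [", x$db_interval[1], ",", x$db_interval[2],
      "), query [", x$q_interval[1], ",", x$q_interval[2], ")\n", sep = "")
  if (nrow(x$corrections))
    cat(" corrections: ",
        paste(sprintf("%s%+d@%d(-%d)", x$corrections$kind,
                      ifelse(x$corrections$kind == "up", 1L, -1L) *
                        x$corrections$n,
                      x$corrections$j, x$corrections$penalty),
              collapse = " "), "\n", sep = "")
  cat("\n")
  cat(alignment_text(x), sep = "\n")
  invisible(x)
}

#' Tab-separated hit records
#'
#' Writes one row per alignment: query id, database id, strand, score,
#' identity fraction, and the 0-based half-open database and query intervals.
#'
#' @param alignments a list of `alignment_result` objects (or a single one).
#' @param path output file path, or `""` for stdout.
#' @return The hit table, invisibly.
#' @export
write_hits <- function(alignments, path = "") {
  if (inherits(alignments, "alignment_result")) alignments <- list(alignments)
  tab <- do.call(rbind, lapply(alignments, function(a) {
    data.frame(query = a$q_name, db = a$db_name, strand = a$strand,
               score = a$score, identity = a$identity_fraction,
               db_start = a$db_interval[1], db_end = a$db_interval[2],
               q_start = a$q_interval[1], q_end = a$q_interval[2],
               stringsAsFactors = FALSE)
  }))
  write.table(tab, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# Recompute an alignment's score from its rendered columns and corrections
# list (used by tests and internal consistency checks): upper-case pairs score
# match/mismatch, ordinary gap runs cost G0 + (len-1)*Ge, corrected
# (lower-case query) columns score 0, and each correction's penalty is
# subtracted.
rescore_alignment <- function(x, model) {
  n <- nchar(x$aligned_db)
  if (n == 0L) return(0L)
  a <- strsplit(x$aligned_db, "")[[1]]
  b <- strsplit(x$aligned_query, "")[[1]]
  corrected <- b %in% letters  # lower-case query characters
  score <- 0L
  gap_type <- ""  # "d": '-' in db; "q": '-' in query
  for (i in seq_len(n)) {
    if (corrected[i]) { gap_type <- ""; next }
    if (a[i] == "-" || b[i] == "-") {
      this <- if (a[i] == "-") "d" else "q"
      score <- score -
        if (identical(gap_type, this)) model$gap_extend else model$gap_open
      gap_type <- this
    } else {
      gap_type <- ""
      score <- score +
        if (a[i] == b[i] && a[i] %in% c("A", "C", "G", "T"))
          model$match else model$mismatch
    }
  }
  score - sum(x$corrections$penalty)
}
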