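#' Configuration of the decoy-recovery experiment
#'
#' The experiment measures, per cell of a (target length x query identity x
#' data mode x k) grid, how often the true target is recovered as the unique
#' highest-scoring database sequence among 100 decoys at 92% identity.
#'
#' @param target_lengths target sequence lengths (default 25, 50, 100).
#' @param decoy_identity identity of decoys to the target (default 0.92).
#' @param query_identities query identity grid (default 1.00 down to 0.72).
#' @param modes data modes: `"plain"` (ideal flowpeaks, no noise) and/or
#'   `"noisy"` (flow noise per `noise`).
#' @param k_values flow-deviation parameters compared (0 = plain
#'   Smith-Waterman-Gotoh, 0.25 = flow-assisted default).
#' @param replicates replicates per cell. The default 500 keeps the full grid
#'   to minutes of CPU; 10,000 reproduces survey-scale precision.
#' @param n_decoys decoys per database.
#' @param noise a [noise_model] for the noisy mode.
#' @param model base [scoring_model]; its `k` is replaced by each `k_values`
#'   entry in turn.
#' @param seed RNG seed for the whole experiment.
#' @return An object of class `recovery_config`.
#' @export
recovery_config <- function(target_lengths = c(25L, 50L, 100L),
                            decoy_identity = 0.92,
                            query_identities = seq(1.00, 0.72, by = -0.04),
                            modes = c("plain", "noisy"),
                            k_values = c(0, 0.25),
                            replicates = 500L,
                            n_decoys = 100L,
                            noise = noise_model(),
                            model = scoring_model(),
                            seed = 1L) {
  if (any(query_identities <= 0 | query_identities > 1))
    stop("query identities must be in (0, 1]")
  if (replicates < 1) stop("replicates must be >= 1")
  modes <- match.arg(modes, c("plain", "noisy"), several.ok = TRUE)
  structure(list(target_lengths = as.integer(target_lengths),
                 decoy_identity = decoy_identity,
                 query_identities = query_identities, modes = modes,
                 k_values = k_values, replicates = as.integer(replicates),
                 n_decoys = as.integer(n_decoys), noise = noise,
                 model = model, seed = as.integer(seed)),
            class = "recovery_config")
}

#' Decoy-recovery experiment
#'
#' For every grid cell the query is a SNP-mutated copy of the target (plain
#' mode: ideal flowpeaks; noisy mode: flow noise added before base calling),
#' scored against the full target-plus-decoys database with [score_only()]
#' under each `k`. A replicate succeeds when the target's score strictly
#' exceeds every decoy's (ties count as failures). The same queries are
#' scored under every `k`, so `k` comparisons are paired.
#'
#' @param config a [recovery_config()].
#' @return A data frame with one row per cell: `target_length`, `identity`,
#'   `mode`, `k`, `replicates`, `successes`, `rate`.
#' @export
recovery_experiment <- function(config = recovery_config()) {
  stopifnot(inherits(config, "recovery_config"))
  models <- lapply(config$k_values, function(k) {
    m <- config$model
    scoring_model(m$match, m$mismatch, m$gap_open, m$gap_extend, k = k)
  })
  out <- list()
  with_local_seed(config$seed, {
    for (tl in config$target_lengths) {
      target <- generate_reference(tl)
      db <- make_decoy_set(target, n_decoys = config$n_decoys,
                           decoy_identity = config$decoy_identity)
      succ <- array(0L, dim = c(length(config$query_identities),
                                length(config$modes),
                                length(config$k_values)))
      for (rep in seq_len(config$replicates)) {
        for (qi in seq_along(config$query_identities)) {
          qseq <- mutate_to_identity(target, config$query_identities[qi])
          fg <- sequence_to_flowgram(qseq)
          for (mi in seq_along(config$modes)) {
            fgm <- if (config$modes[mi] == "noisy")
              add_flow_noise(fg, config$noise) else fg
            read <- call_flowgram(fgm)
            if (!nzchar(read$sequence)) next
            for (ki in seq_along(models)) {
              scores <- score_only(db, read, model = models[[ki]])
              if (scores[1] > max(scores[-1]))
                succ[qi, mi, ki] <- succ[qi, mi, ki] + 1L
            }
          }
        }
      }
      for (qi in seq_along(config$query_identities))
        for (mi in seq_along(config$modes))
          for (ki in seq_along(config$k_values))
            out[[length(out) + 1L]] <- data.frame(
              target_length = tl,
              identity = config$query_identities[qi],
              mode = config$modes[mi], k = config$k_values[ki],
              replicates = config$replicates,
              successes = succ[qi, mi, ki],
              rate = succ[qi, mi, ki] / config$replicates,
              stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Read-mapping experiment: correctly aligned nucleotides
#'
#' Aligns simulated reads (with known origins) back against their genome
#' under each `k` and counts correctly aligned nucleotides. A read base is
#' correct iff it is aligned (upper case, not a correction) to the database
#' coordinate it truly originated from; gap columns, corrections, overcalled
#' bases without a true coordinate, and unaligned bases all count in the
#' denominator only. Strict coordinate equality is used: a base placed at a
#' shifted but homologous coordinate is incorrect.
#'
#' @param genome the genome the reads were sampled from.
#' @param sim a [sample_reads()] result for that genome.
#' @param k_values flow-deviation parameters compared.
#' @param model base [scoring_model].
#' @param params [heuristic_params()] for the index search.
#' @param tuple_size index tuple size.
#' @return A data frame with one row per `k`: `k`, `total_bases`,
#'   `correct`, `incorrect`, `fraction_correct`.
#' @export
mapping_experiment <- function(genome, sim, k_values = c(0, 0.25),
                               model = scoring_model(),
                               params = heuristic_params(),
                               tuple_size = 11L) {
  stopifnot(inherits(sim, "simulated_reads"))
  index <- build_index(c(genome = genome), tuple_size = tuple_size)
  n_reads <- nrow(sim$truth)
  truth_coords <- lapply(seq_len(n_reads), function(i)
    true_base_coords(sim$true_seqs[i], sim$reads[[i]],
                     sim$truth$start[i], sim$truth$end[i],
                     sim$truth$strand[i]))
  out <- list()
  for (k in k_values) {
    mk <- scoring_model(model$match, model$mismatch, model$gap_open,
                        model$gap_extend, k = k)
    total <- 0L; correct <- 0L
    for (i in seq_len(n_reads)) {
      read <- sim$reads[[i]]
      nb <- nchar(read$sequence)
      total <- total + nb
      if (nb == 0L) next
      res <- flow_search(index, read, model = mk, params = params)
      if (!length(res$alignments)) next
      aln <- res$alignments[[1]]
      coords <- aligned_base_coords(aln)
      tc <- truth_coords[[i]]
      ok <- which(!is.na(coords))
      # minus-strand alignments index positions of the reverse-complemented
      # read; tc$minus is the truth vector in that same orientation
      tv <- if (aln$strand == "-") tc$minus else tc$plus
      correct <- correct + sum(tv[ok] == coords[ok], na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      k = k, total_bases = total, correct = correct,
      incorrect = total - correct,
      fraction_correct = if (total > 0) correct / total else NA_real_)
  }
  do.call(rbind, out)
}

# Per-called-base true genome coordinate of a simulated read.
#
# The called read's bases are matched flow-by-flow against the ideal flowgram
# of the read's true (mutated) sequence: within one flow the first
# min(called, true) bases map, in order, to that homopolymer's genome
# positions; overcalled extras have no true coordinate (NA). Returns plus- and
# minus-orientation coordinate vectors (the latter indexed by position in the
# reverse-complemented called read).
true_base_coords <- function(true_seq, read, start, end, strand) {
  ideal <- sequence_to_flowgram(true_seq)
  true_counts <- as.integer(floor(ideal$flowpeaks + 0.5))
  rl <- nchar(true_seq)
  # genome coordinate of each base of the true sequence, in read orientation
  base_coord <- if (strand == "+") start + seq_len(rl) - 1L
                else end - seq_len(rl)
  # genome coordinates grouped by originating flow of the TRUE sequence
  flow_of_true_base <- rep(seq_along(true_counts), true_counts)
  nb <- nchar(read$sequence)
  plus <- rep(NA_integer_, nb)
  if (nb > 0L) {
    # rank of each called base within its flow
    r <- sequence(rle(read$base_flow)$lengths)
    flow_first_true <- c(0L, cumsum(true_counts))  # bases before each flow
    fl <- read$base_flow
    valid <- fl <= length(true_counts) & r <= true_counts[pmin(fl,
               length(true_counts))]
    ti <- flow_first_true[fl[valid]] + r[valid]
    plus[valid] <- base_coord[ti]
  }
  list(plus = plus, minus = rev(plus))
}

# 0-based database coordinate of each query base in an alignment
# (NA for query bases outside the local alignment, in gaps-to-db columns, or
# lower-case corrected columns).
aligned_base_coords <- function(aln) {
  a <- strsplit(aln$aligned_db, "")[[1]]
  b <- strsplit(aln$aligned_query, "")[[1]]
  di <- aln$db_interval[1]; qi <- aln$q_interval[1]
  res <- rep(NA_integer_, aln$q_interval[2])
  for (i in seq_along(a)) {
    if (b[i] == "-") { di <- di + 1L; next }       # gap in query
    lower <- b[i] %in% letters
    if (a[i] == "-") { qi <- qi + 1L; next }       # db gap / down-call column
    if (lower) { di <- di + 1L; next }             # up-call insertion: no
                                                   # query position consumed
    qi <- qi + 1L
    res[qi] <- di
    di <- di + 1L
  }
  res
}
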