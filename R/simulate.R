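#' Flowgram noise model
#'
#' Parameters of the simulator's per-flow noise. Negative (zero) flows draw a
#' peak from `LogNormal(negative_mu, negative_sigma * scale)` (natural-log
#' parameterization); a positive flow of true homopolymer length `n` draws
#' from `Normal(n, positive_cv * n * scale)`, truncated at 0. The defaults
#' (`mu = -2.5`, `sigma = 0.2`, `cv = 0.15`, `scale = 1`) are the high-noise
#' regime of a 454 run; smaller `scale` emulates cleaner chemistry (the
#' instrument-specific Titanium/GS20 parameter sets are approximated by this
#' single knob, not reproduced).
#'
#' @param negative_mu,negative_sigma log-scale mean and sd for negative flows.
#' @param positive_cv coefficient of variation per called base for positive
#'   flows.
#' @param scale global multiplier on both spreads (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(negative_mu = -2.5, negative_sigma = 0.2,
                        positive_cv = 0.15, scale = 1) {
  if (negative_sigma < 0 || positive_cv < 0 || scale < 0)
    stop("spreads and scale must be >= 0")
  structure(list(negative_mu = negative_mu, negative_sigma = negative_sigma,
                 positive_cv = positive_cv, scale = scale),
            class = "noise_model")
}

#' Random reference sequence
#'
#' Uniform i.i.d. ACGT sequence; reproducible under `seed`.
#'
#' @param length sequence length (>= 1).
#' @param seed RNG seed (NULL = use the current stream).
#' @return A nucleotide string.
#' @export
generate_reference <- function(length, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  with_local_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

#' Mutate a sequence to a target identity
#'
#' Introduces exactly `round((1 - identity) * nchar(seq))` substitutions
#' (SNPs) at positions chosen without replacement, each to a base drawn
#' uniformly from the three alternatives.
#'
#' @param seq nucleotide string.
#' @param identity target identity in (0, 1].
#' @param seed RNG seed.
#' @return The mutated string (same length).
#' @export
mutate_to_identity <- function(seq, identity, seed = NULL) {
  if (!(identity > 0 && identity <= 1))
    stop("identity must be in (0, 1]")
  n <- nchar(seq)
  nmut <- round((1 - identity) * n)
  if (nmut == 0) return(seq)
  with_local_seed(seed, {
    pos <- sample.int(n, nmut)
    chars <- strsplit(seq, "")[[1]]
    alts <- c("A", "C", "G", "T")
    for (p in pos) {
      choices <- setdiff(alts, chars[p])
      chars[p] <- choices[sample.int(length(choices), 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Ideal flowgram of a sequence
#'
#' Cycles the flow order over the sequence: a flow's peak equals the length
#' of the homopolymer it incorporates (0 for negative flows). Calling the
#' result with [call_flowgram()] returns the sequence exactly.
#'
#' @param seq nucleotide string over ACGT.
#' @param flow_order flow cycle (default `"TACG"`).
#' @param name read identifier.
#' @return A [flowgram].
#' @export
sequence_to_flowgram <- function(seq, flow_order = "TACG", name = "read") {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) && !all(chars %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T")
  cycle <- strsplit(flow_order, "")[[1]]
  if (!length(chars))
    return(flowgram(name, character(0), numeric(0)))
  r <- rle(chars)
  flow_chars <- character(0)
  peaks <- numeric(0)
  ci <- 1L
  for (i in seq_along(r$values)) {
    while (cycle[ci] != r$values[i]) {
      flow_chars <- c(flow_chars, cycle[ci])
      peaks <- c(peaks, 0)
      ci <- ci %% length(cycle) + 1L
    }
    flow_chars <- c(flow_chars, r$values[i])
    peaks <- c(peaks, r$lengths[i])
    ci <- ci %% length(cycle) + 1L
  }
  flowgram(name, flow_chars, peaks)
}

#' Add flow noise to an ideal flowgram
#'
#' Replaces each zero peak by a log-normal draw and each positive peak of
#' (true) length `n` by a truncated normal draw, per the [noise_model].
#'
#' @param flowgram an ideal [flowgram] (integer-valued peaks).
#' @param noise a [noise_model].
#' @param seed RNG seed.
#' @return A noisy [flowgram].
#' @export
add_flow_noise <- function(flowgram, noise = noise_model(), seed = NULL) {
  stopifnot(inherits(flowgram, "flowgram"), inherits(noise, "noise_model"))
  with_local_seed(seed, {
    p <- flowgram$flowpeaks
    neg <- p == 0
    out <- numeric(length(p))
    if (any(neg))
      out[neg] <- rlnorm(sum(neg), meanlog = noise$negative_mu,
                         sdlog = noise$negative_sigma * noise$scale)
    if (any(!neg)) {
      n <- p[!neg]
      out[!neg] <- pmax(0, rnorm(length(n), mean = n,
                                 sd = noise$positive_cv * n * noise$scale))
    }
    flowgram(flowgram$name, flowgram$flow_chars, out)
  })
}

#' Target plus SNP decoys
#'
#' Builds the decoy-recovery database: the target followed by `n_decoys`
#' independent mutations of it at `decoy_identity` (default: 100 decoys at
#' 92% identity, a 101-sequence database).
#'
#' @param target target nucleotide string.
#' @param n_decoys number of decoys.
#' @param decoy_identity identity of each decoy to the target.
#' @param seed RNG seed.
#' @return Named character vector: `target`, `decoy1`, `decoy2`, ...
#' @export
make_decoy_set <- function(target, n_decoys = 100L, decoy_identity = 0.92,
                           seed = NULL) {
  with_local_seed(seed, {
    decoys <- vapply(seq_len(n_decoys),
                     function(i) mutate_to_identity(target, decoy_identity),
                     character(1))
    setNames(c(target, decoys),
             c("target", if (n_decoys) paste0("decoy", seq_len(n_decoys))))
  })
}

#' Simulate reads from a genome with truth coordinates
#'
#' Samples reads of fixed length at uniform start positions and strands,
#' mutates each to the requested identity, builds the ideal flowgram and adds
#' flow noise. The true origin of every read is recorded for mapping
#' evaluation.
#'
#' @param genome nucleotide string.
#' @param n_reads number of reads.
#' @param read_length read length (all reads; must not exceed the genome).
#' @param identity per-read SNP identity in (0, 1].
#' @param noise a [noise_model]; `scale = 0` gives noiseless flows.
#' @param seed RNG seed.
#' @param flow_order flow cycle.
#' @return An object of class `simulated_reads`: list with `truth` (data
#'   frame: `read`, `start`, `end` 0-based half-open, `strand`, `identity`),
#'   `true_seqs` (mutated sequences as sampled, read orientation),
#'   `flowgrams` (noisy [flowgram]s) and `reads` (their [called_read]s).
#' @export
sample_reads <- function(genome, n_reads, read_length, identity = 1,
                         noise = noise_model(), seed = NULL,
                         flow_order = "TACG") {
  glen <- nchar(genome)
  if (read_length > glen) stop("read length exceeds the genome length")
  with_local_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n_reads, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    ids <- sprintf("read%05d", seq_len(n_reads))
    true_seqs <- character(n_reads)
    fgs <- vector("list", n_reads)
    crs <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      s <- substr(genome, starts[i] + 1L, starts[i] + read_length)
      if (strands[i] == "-") s <- reverse_complement(s)
      s <- mutate_to_identity(s, identity)
      true_seqs[i] <- s
      fg <- sequence_to_flowgram(s, flow_order = flow_order, name = ids[i])
      fg <- add_flow_noise(fg, noise)
      fgs[[i]] <- fg
      crs[[i]] <- call_flowgram(fg)
    }
    structure(list(
      truth = data.frame(read = ids, start = starts,
                         end = starts + read_length, strand = strands,
                         identity = identity, stringsAsFactors = FALSE),
      true_seqs = true_seqs, flowgrams = fgs, reads = crs),
      class = "simulated_reads")
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat("<simulated_reads> ", nrow(x$truth), " reads\n", sep = "")
  print(head(x$truth))
  invisible(x)
}

#' Write simulated reads plus their truth table
#'
#' Writes the reads as SFF and/or FFASTA and the truth coordinates as TSV
#' (`<prefix>.sff`, `<prefix>.ffasta`, `<prefix>.truth.tsv`).
#'
#' @param sim a [sample_reads()] result.
#' @param prefix output path prefix.
#' @param formats subset of `c("sff", "ffasta")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_simulated_reads <- function(sim, prefix, formats = c("sff", "ffasta")) {
  stopifnot(inherits(sim, "simulated_reads"))
  written <- character(0)
  if ("sff" %in% formats) {
    f <- paste0(prefix, ".sff")
    # SFF carries one flow count for the whole file: pad every read's
    # flowgram to the longest with zero-intensity flows along the cycle
    nmax <- max(vapply(sim$flowgrams, function(g) length(g$flowpeaks),
                       integer(1)))
    padded <- lapply(sim$flowgrams, function(g) {
      n <- length(g$flowpeaks)
      if (n == nmax) return(g)
      cyc <- g$flow_chars[seq_len(min(4L, n))]
      extra <- cyc[(seq_len(nmax - n) + n - 1L) %% length(cyc) + 1L]
      flowgram(g$name, c(g$flow_chars, extra), c(g$flowpeaks,
                                                 numeric(nmax - n)))
    })
    write_sff(padded, f)
    written <- c(written, f)
  }
  if ("ffasta" %in% formats) {
    f <- paste0(prefix, ".ffasta")
    fo <- paste(sim$flowgrams[[1]]$flow_chars[
      seq_len(min(4, length(sim$flowgrams[[1]]$flow_chars)))], collapse = "")
    write_ffasta(sim$flowgrams, f, flow_order = if (nzchar(fo)) fo else "TACG")
    written <- c(written, f)
  }
  f <- paste0(prefix, ".truth.tsv")
  write.table(sim$truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(written, f))
}
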