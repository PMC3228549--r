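#' @rdname read_sff
#' @name sff_record
#' @details
#' An SFF record is a list with `name`, `flow_chars`, `flowpeaks` (per-flow
#' intensities, resolution 0.01), `bases` (raw called sequence), `flow_index`
#' (1-based flow of origin per base), `quality` (per-base scores, parsed but
#' unused by alignment), and 1-based clip points `clip_qual` and
#' `clip_adapter` (`c(left, right)`, 0 = unset). `sff_effective()` applies the
#' intersection of the quality and adapter clips; [as_flowgram()] converts a
#' record to a [flowgram].
NULL

SFF_MAGIC <- 0x2E736666

pad8 <- function(n) (8L - (n %% 8L)) %% 8L

read_u <- function(con, size, n = 1L, what = "field") {
  v <- readBin(con, "integer", n = n, size = size, signed = size == 4L,
               endian = "big")
  if (length(v) < n) stop("truncated SFF file while reading ", what)
  if (size == 4L && any(v < 0)) v <- ifelse(v < 0, v + 2^32, v)
  v
}

#' Read a Standard Flowgram Format (SFF) file
#'
#' Parses big-endian SFF version 1: the common header (magic `.sff`, flow
#' order, key sequence), then one header and data section per read (flowgram
#' values as unsigned 16-bit integers scaled by 100, per-base flow index as
#' delta-encoded bytes, called bases, per-base qualities), each section padded
#' to an 8-byte boundary. Index blocks are skipped safely.
#'
#' @param path path to an SFF file.
#' @return A list of `sff_record` objects (see Details).
#' @seealso [write_sff()], [as_flowgram()], [sff_effective()]
#' @export
read_sff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_u(con, 4L, what = "magic number")
  if (magic != SFF_MAGIC)
    stop(sprintf("bad SFF magic number at offset 0: %.0f (expected %.0f)",
                 magic, SFF_MAGIC))
  version <- readBin(con, "raw", n = 4L)
  if (!identical(as.integer(version), c(0L, 0L, 0L, 1L)))
    stop("unsupported SFF version: ",
         paste(as.integer(version), collapse = "."))
  idx_off <- read_u(con, 4L, n = 2L, what = "index offset")  # uint64 as 2x32
  index_offset <- idx_off[1] * 2^32 + idx_off[2]
  index_length <- read_u(con, 4L, what = "index length")
  n_reads <- read_u(con, 4L, what = "read count")
  header_length <- read_u(con, 2L, what = "header length")
  key_length <- read_u(con, 2L, what = "key length")
  n_flows <- read_u(con, 2L, what = "flow count")
  fmt <- read_u(con, 1L, what = "flowgram format code")
  if (fmt != 1L) stop("unsupported flowgram format code: ", fmt)
  flow_chars <- rawToChar(readBin(con, "raw", n = n_flows))
  key <- if (key_length > 0) rawToChar(readBin(con, "raw", n = key_length))
         else ""
  consumed <- 31L + n_flows + key_length
  if (header_length < consumed) stop("corrupt SFF common header length")
  readBin(con, "raw", n = header_length - consumed)  # header padding
  records <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    # an index block may sit between reads; detect and skip it
    pos <- seek(con, where = NA)
    if (index_length > 0 && pos == index_offset) {
      skip <- index_length + pad8(index_length)
      readBin(con, "raw", n = skip)
    }
    rhl <- read_u(con, 2L, what = "read header length")
    name_len <- read_u(con, 2L, what = "name length")
    n_bases <- read_u(con, 4L, what = "base count")
    clips <- read_u(con, 2L, n = 4L, what = "clip points")
    name <- rawToChar(readBin(con, "raw", n = name_len))
    rconsumed <- 16L + name_len
    if (rhl < rconsumed) stop("corrupt read header for record ", r)
    readBin(con, "raw", n = rhl - rconsumed)
    flowvals <- read_u(con, 2L, n = n_flows, what = "flowgram values")
    fidx_raw <- read_u(con, 1L, n = n_bases, what = "flow index")
    bases <- rawToChar(readBin(con, "raw", n = n_bases))
    qual <- read_u(con, 1L, n = n_bases, what = "quality scores")
    dlen <- 2L * n_flows + 3L * n_bases
    readBin(con, "raw", n = pad8(dlen))
    records[[r]] <- structure(list(
      name = name, flow_chars = strsplit(flow_chars, "")[[1]],
      flowpeaks = flowvals / 100, bases = bases,
      flow_index = cumsum(fidx_raw),  # delta-decoded, 1-based
      quality = qual,
      clip_qual = c(clips[1], clips[2]),
      clip_adapter = c(clips[3], clips[4])),
      class = "sff_record")
  }
  attr(records, "flow_chars") <- flow_chars
  attr(records, "key_sequence") <- key
  records
}

#' Effective (clipped) read sequence of an SFF record
#'
#' Applies the standard SFF clipping semantics: the effective read runs from
#' `max(1, clip_qual_left, clip_adapter_left)` to
#' `min(clip_qual_right or n, clip_adapter_right or n)` (1-based, inclusive;
#' a right clip of 0 means unset).
#'
#' @param record an `sff_record`.
#' @param clipped set `FALSE` to return the raw, unclipped sequence.
#' @return The (clipped) nucleotide string.
#' @export
sff_effective <- function(record, clipped = TRUE) {
  stopifnot(inherits(record, "sff_record"))
  n <- nchar(record$bases)
  if (!clipped) return(record$bases)
  left <- max(1L, record$clip_qual[1], record$clip_adapter[1])
  right <- min(if (record$clip_qual[2] == 0) n else record$clip_qual[2],
               if (record$clip_adapter[2] == 0) n else record$clip_adapter[2])
  if (left > right) return("")
  substr(record$bases, left, right)
}

#' Convert an SFF record to a flowgram
#'
#' @param record an `sff_record`.
#' @return A [flowgram] with the record's flow order and flowpeaks.
#' @export
as_flowgram <- function(record) {
  stopifnot(inherits(record, "sff_record"))
  flowgram(record$name, record$flow_chars, record$flowpeaks)
}

#' @export
print.sff_record <- function(x, ...) {
  cat("<sff_record> ", x$name, ": ", length(x$flowpeaks), " flows, ",
      nchar(x$bases), " bases\n", sep = "")
  invisible(x)
}

#' Write a Standard Flowgram Format (SFF) file
#'
#' Emits big-endian SFF v1 readable by [read_sff()]. Records may be
#' `sff_record` objects or [flowgram]s (which are base-called to fill in the
#' bases and flow-index sections; qualities written as zero).
#'
#' @param records list of `sff_record` or [flowgram] objects sharing one flow
#'   order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sff <- function(records, path) {
  records <- lapply(records, function(x) {
    if (inherits(x, "flowgram")) {
      cr <- call_flowgram(x)
      structure(list(name = x$name, flow_chars = x$flow_chars,
                     flowpeaks = x$flowpeaks, bases = cr$sequence,
                     flow_index = cr$base_flow,
                     quality = rep(0L, nchar(cr$sequence)),
                     clip_qual = c(0L, 0L), clip_adapter = c(0L, 0L)),
                class = "sff_record")
    } else if (inherits(x, "sff_record")) x
    else stop("records must be sff_record or flowgram objects")
  })
  if (length(records)) {
    fc <- vapply(records, function(r) paste(r$flow_chars, collapse = ""),
                 character(1))
    if (length(unique(fc)) != 1L)
      stop("all records must share one flow order")
    flow_chars <- fc[1]
  } else flow_chars <- ""
  for (r in records) {
    if (any(r$flowpeaks < 0 | r$flowpeaks > 655.35))
      stop("flowpeak outside the encodable range [0, 655.35] in record ",
           r$name)
  }
  n_flows <- nchar(flow_chars)
  con <- file(path, "wb")
  on.exit(close(con))
  wu <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "big")
  wu(SFF_MAGIC, 4L)
  writeBin(as.raw(c(0, 0, 0, 1)), con)
  wu(c(0L, 0L), 4L)            # index offset (none)
  wu(0L, 4L)                   # index length
  wu(length(records), 4L)
  header_len <- 31L + n_flows  # key_length = 0
  pad <- pad8(header_len)
  wu(header_len + pad, 2L)
  wu(0L, 2L)                   # key length
  wu(n_flows, 2L)
  writeBin(as.raw(1L), con)    # flowgram format code
  if (n_flows) writeBin(charToRaw(flow_chars), con)
  if (pad) writeBin(raw(pad), con)
  for (r in records) {
    n_bases <- nchar(r$bases)
    name_len <- nchar(r$name)
    rhl <- 16L + name_len
    rpad <- pad8(rhl)
    wu(rhl + rpad, 2L)
    wu(name_len, 2L)
    wu(n_bases, 4L)
    wu(c(r$clip_qual, r$clip_adapter), 2L)
    writeBin(charToRaw(r$name), con)
    if (rpad) writeBin(raw(rpad), con)
    wu(as.integer(round(r$flowpeaks * 100)), 2L)
    fidx <- as.integer(r$flow_index)
    deltas <- if (length(fidx)) diff(c(0L, fidx)) else integer(0)
    if (any(deltas < 0L | deltas > 255L))
      stop("flow index delta outside [0, 255] in record ", r$name)
    wu(deltas, 1L)
    if (n_bases) writeBin(charToRaw(r$bases), con)
    wu(r$quality, 1L)
    dpad <- pad8(2L * length(r$flowpeaks) + 3L * n_bases)
    if (dpad) writeBin(raw(dpad), con)
  }
  invisible(path)
}

#' Read / write flowgram-FASTA (FFASTA)
#'
#' FFASTA is a FASTA-like text format in which each entry carries a flowgram
#' instead of a sequence: the body is white-space separated non-negative
#' decimal flowpeak values (like the QUAL format). The flow order is taken
#' from an optional `# flow_order=XXXX` comment line (default `TACG`); the
#' writer emits that comment and at most 60 values per line, at 0.01
#' resolution.
#'
#' @param path file path.
#' @return `read_ffasta()` returns a list of [flowgram]s.
#' @examples
#' tf <- tempfile(fileext = ".ffasta")
#' writeLines(c(">r1", "0.11 1.83 0.97 0.97"), tf)
#' call_flowgram(read_ffasta(tf)[[1]])$sequence  # "CCGT"
#' @export
read_ffasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  flow_order <- "TACG"
  fo <- grep("^#\\s*flow_order=", lines)
  if (length(fo))
    flow_order <- toupper(sub("^#\\s*flow_order=\\s*", "", lines[fo[1]]))
  keep <- !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  hdr <- grep("^>", lines)
  if (!length(hdr)) return(list())
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    name <- sub("\\s.*$", "", name)
    body_idx <- if (hdr[i] + 1L <= bounds[i + 1L] - 1L)
      seq(hdr[i] + 1L, bounds[i + 1L] - 1L) else integer(0)
    peaks <- numeric(0)
    for (b in body_idx) {
      toks <- strsplit(trimws(lines[b]), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) next
      v <- suppressWarnings(as.numeric(toks))
      if (anyNA(v))
        stop("non-numeric flowpeak token '", toks[which(is.na(v))[1]],
             "' on line ", lineno[b], " of ", path)
      peaks <- c(peaks, v)
    }
    nfl <- length(peaks)
    chars <- if (nfl) strsplit(flow_order, "")[[1]][
      (seq_len(nfl) - 1L) %% nchar(flow_order) + 1L] else character(0)
    out[[i]] <- flowgram(name, chars, peaks)
  }
  out
}

#' @param flowgrams list of [flowgram]s (for `write_ffasta()`).
#' @param flow_order flow cycle recorded in the file header comment.
#' @rdname read_ffasta
#' @export
write_ffasta <- function(flowgrams, path, flow_order = "TACG") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# flow_order=", flow_order), con)
  for (fg in flowgrams) {
    stopifnot(inherits(fg, "flowgram"))
    writeLines(paste0(">", fg$name), con)
    vals <- sprintf("%.2f", fg$flowpeaks)
    if (length(vals)) {
      grp <- split(vals, (seq_along(vals) - 1L) %/% 60L)
      writeLines(vapply(grp, paste, character(1), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read / write multi-FASTA
#'
#' Thin wrappers over Biostrings. Sequences are upper-cased on read;
#' IUPAC ambiguity codes are preserved as-is. Duplicate record ids and empty
#' files are errors.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  setNames(toupper(as.character(ss)), ids)
}

#' @param seqs named character vector of sequences (for `write_fasta()`).
#' @param width line wrap width.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}
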