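# Sequence IO, IUPAC-aware primer matching, perfect-match demultiplexing.
#
# Sequence sets are plain data.frames with columns:
#   id      character, record identifier
#   bases   character over {A,C,G,T,N}
#   quality list-column of integer vectors (Phred, 0-40) or NA when absent
# This keeps records trivially subsettable with base R while file parsing is
# delegated to Biostrings.

IUPAC_EXPANSION <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) strsplit(s, "", fixed = TRUE)[[1]])
})

#' Construct a sequence record set
#'
#' @param id character vector of record ids.
#' @param bases character vector of sequences over A,C,G,T,N.
#' @param quality optional list of integer Phred vectors (0-40), one per
#'   record, each the same length as its sequence.
#' @return data.frame with columns `id`, `bases` and list-column `quality`.
#' @export
seq_records <- function(id, bases, quality = NULL) {
  stopifnot(length(id) == length(bases))
  if (any(nchar(bases) == 0)) stop("empty sequence in record set")
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop("sequence alphabet restricted to A,C,G,T,N; offending record: ",
         id[which(bad)[1]])
  }
  if (is.null(quality)) {
    quality <- rep(list(NULL), length(id))
  } else {
    stopifnot(length(quality) == length(id))
    ok <- vapply(seq_along(quality), function(i) {
      is.null(quality[[i]]) || length(quality[[i]]) == nchar(bases[i])
    }, logical(1))
    if (!all(ok)) {
      stop("quality length differs from sequence length for record: ",
           id[which(!ok)[1]])
    }
  }
  data.frame(id = as.character(id), bases = as.character(bases),
             quality = I(unname(quality)), stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTQ qualities are decoded from the Sanger/Phred+33 dialect only. Records
#' are returned in file order.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return A sequence record set (see [seq_records()]).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "fastq") {
    .validate_fastq_lines(path)
    x <- withCallingHandlers(
      tryCatch(
        Biostrings::readQualityScaledDNAStringSet(path,
          quality.scoring = "phred"),
        error = function(e) stop("FASTQ parse error in ", path, ": ",
                                 conditionMessage(e), call. = FALSE)),
      # harmless notice about empty mcols on the parsed set
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    qual <- as(Biostrings::quality(x), "IntegerList")
    seq_records(names(x), as.character(x), as.list(qual))
  } else {
    first <- readLines(path, n = 1L)
    if (length(first) == 1L && startsWith(first, "@")) {
      stop("file ", path, " looks like FASTQ, not FASTA (line 1 starts with '@')")
    }
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("FASTA parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    # keep only the first whitespace token of the description line as id
    ids <- sub("\\s.*$", "", names(x))
    seq_records(ids, as.character(x))
  }
}

# line-level FASTQ structure check so parse errors can name the line
.validate_fastq_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error in ", path, ": truncated record near line ",
         length(lines), call. = FALSE)
  }
  for (i in seq(1L, length(lines), by = 4L)) {
    if (!startsWith(lines[i], "@")) {
      stop("FASTQ parse error in ", path, ": expected '@' header at line ", i,
           call. = FALSE)
    }
    if (!startsWith(lines[i + 2L], "+")) {
      stop("FASTQ parse error in ", path, ": expected '+' separator at line ",
           i + 2L, call. = FALSE)
    }
    if (nchar(lines[i + 3L]) != nchar(lines[i + 1L])) {
      stop("FASTQ parse error in ", path,
           ": quality length differs from sequence length at line ", i + 3L,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records sequence record set from [seq_records()].
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires qualities on every
#'   record and encodes them as Phred+33.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fastq") {
    if (any(vapply(records$quality, is.null, logical(1)))) {
      stop("FASTQ output requires qualities on every record")
    }
    qs <- vapply(records$quality,
                 function(q) rawToChar(as.raw(q + 33L)), character(1))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(records$bases, records$id)),
      Biostrings::PhredQuality(qs))
    # the constructor attaches empty mcols that the writer warns about
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  } else {
    x <- Biostrings::DNAStringSet(setNames(records$bases, records$id))
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Define a PCR primer
#'
#' @param name primer name (e.g. `"338F"`).
#' @param sequence IUPAC nucleotide string; degenerate codes (N, Y, ...) allowed.
#' @param orientation `"forward"` or `"reverse"`.
#' @return A `primer_def` list.
#' @export
primer_def <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(nchar(sequence) > 0)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(ch %in% names(IUPAC_EXPANSION))) {
    stop("invalid IUPAC code in primer ", name, ": ",
         paste(setdiff(ch, names(IUPAC_EXPANSION)), collapse = ","))
  }
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "primer_def")
}

#' Standard primer pairs targeting the V3-V4 and V6 hypervariable regions
#'
#' Canonical 16S rRNA gene primer sequences widely used for these regions;
#' the V6 reverse primer carries a degenerate N position.
#'
#' @param region `"v3v4"` or `"v6"`.
#' @return list with elements `forward` and `reverse` (each a [primer_def()]).
#' @export
default_primer_pair <- function(region = c("v3v4", "v6")) {
  region <- match.arg(region)
  if (region == "v3v4") {
    list(forward = primer_def("338F", "ACTCCTACGGGAGGCAGCAG", "forward"),
         reverse = primer_def("806R", "GGACTACCAGGGTATCTAAT", "reverse"))
  } else {
    list(forward = primer_def("967F", "AACGCGAAGAACCTTACC", "forward"),
         reverse = primer_def("1046R", "CGACAGCCATGCANCACCT", "reverse"))
  }
}

#' Count IUPAC-aware mismatches between a primer pattern and a sequence window
#'
#' Position i is a mismatch iff `window[i]` is not in the IUPAC expansion of
#' `pattern[i]`; `N` in the pattern matches every base. Positions are 1-based
#' from the 5' end.
#'
#' @param pattern IUPAC nucleotide string.
#' @param window plain A/C/G/T string of the same length.
#' @return list with `count` (integer) and `positions` (1-based integer vector).
#' @export
iupac_mismatches <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length (",
         nchar(pattern), " vs ", nchar(window), ")")
  }
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  if (!all(p %in% names(IUPAC_EXPANSION))) stop("invalid IUPAC code in pattern")
  if (!all(w %in% DNA_BASES)) stop("window must contain only A,C,G,T")
  mis <- !vapply(seq_along(p),
                 function(i) w[i] %in% IUPAC_EXPANSION[[p[i]]], logical(1))
  list(count = sum(mis), positions = which(mis))
}

# TRUE iff window IUPAC-matches pattern exactly; tolerant of N in the window
# (an N base can never satisfy a concrete pattern position, but matches N)
.iupac_exact <- function(pattern, window) {
  if (nchar(pattern) != nchar(window)) return(FALSE)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  all(vapply(seq_along(p), function(i) {
    w[i] %in% DNA_BASES && w[i] %in% IUPAC_EXPANSION[[p[i]]]
  }, logical(1)))
}

#' Read a MID (barcode) assignment table
#'
#' @param path TSV with columns `mid` and `sample_id`.
#' @return data.frame with those columns.
#' @export
read_mid_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mid", "sample_id") %in% names(df))) {
    stop("MID table must have columns 'mid' and 'sample_id'")
  }
  df
}

#' Demultiplex reads by exact MID + primer prefix and trim
#'
#' A read is assigned to a sample iff its prefix equals that sample's MID
#' exactly, immediately followed by an exact IUPAC match to the forward
#' primer (zero mismatches). Assigned reads are returned with the MID and
#' primer removed; everything else lands in the discard pile. Reads shorter
#' than MID+primer can never match and are discarded.
#'
#' @param reads sequence record set.
#' @param mid_assignments data.frame with columns `mid`, `sample_id`; MIDs
#'   must be unique and of one common length.
#' @param forward_primer a [primer_def()] (IUPAC codes allowed).
#' @return list with `samples` (named list of trimmed record sets, one per
#'   sample_id, possibly empty) and `discarded` (record set).
#' @export
demultiplex_and_trim <- function(reads, mid_assignments, forward_primer) {
  mids <- mid_assignments$mid
  if (anyDuplicated(mids)) stop("duplicate MIDs in assignment table")
  if (length(unique(nchar(mids))) > 1L) stop("MIDs must share one length")
  if (any(grepl("[^ACGT]", mids))) stop("MIDs must be plain A/C/G/T")
  mid_len <- nchar(mids[1])
  prim <- forward_primer$sequence
  plen <- nchar(prim)
  need <- mid_len + plen

  n <- nrow(reads)
  assigned_sample <- rep(NA_character_, n)
  long_enough <- nchar(reads$bases) >= need
  prefix <- substr(reads$bases, 1L, mid_len)
  hit <- match(prefix, mids)
  for (i in which(long_enough & !is.na(hit))) {
    window <- substr(reads$bases[i], mid_len + 1L, need)
    if (.iupac_exact(prim, window)) {
      assigned_sample[i] <- mid_assignments$sample_id[hit[i]]
    }
  }

  trim_one <- function(idx) {
    out <- reads[idx, , drop = FALSE]
    out$bases <- substr(out$bases, need + 1L, nchar(out$bases))
    out$quality <- I(lapply(out$quality, function(q) {
      if (is.null(q)) NULL else q[-seq_len(need)]
    }))
    rownames(out) <- NULL
    out
  }
  samples <- lapply(unique(mid_assignments$sample_id), function(s) {
    trim_one(which(!is.na(assigned_sample) & assigned_sample == s))
  })
  names(samples) <- unique(mid_assignments$sample_id)
  discarded <- reads[is.na(assigned_sample), , drop = FALSE]
  rownames(discarded) <- NULL
  list(samples = samples, discarded = discarded)
}
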