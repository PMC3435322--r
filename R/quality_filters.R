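# Error-free read identification (exact match over the amplified region,
# optionally allowing sanctioned premature terminations) and the two
# pre-denoising quality-filter styles.

#' Minimum unambiguous prefix length of a reference set
#'
#' The smallest k such that all references' amplified-region prefixes of
#' length `min(k, len)` are pairwise distinct — the shortest prefix at which
#' every reference is unequivocally identifiable.
#'
#' @param references reference set from [build_reference_set()], or a
#'   character vector of amplified regions.
#' @return integer L.
#' @export
min_unambiguous_length <- function(references) {
  amp <- if (is.character(references)) references else
    vapply(references, `[[`, character(1), "amplicon")
  if (length(amp) < 2) stop("need at least 2 references")
  if (anyDuplicated(amp)) stop("duplicate amplified regions: no prefix length distinguishes them")
  for (k in seq_len(max(nchar(amp)))) {
    pref <- substr(amp, 1, k)
    if (!anyDuplicated(pref)) return(k)
  }
  stop("unreachable")  # distinct full sequences guarantee a k exists
}

#' Identify error-free reads by exact match against references
#'
#' A read matches `full` iff its bases equal a reference amplified region
#' end-to-end; it matches as `premature_prefix` iff `allow_premature` is set
#' and its bases (length >= `min_prefix`) equal a strict prefix of a
#' reference. A full match takes precedence. Reads containing N never match.
#'
#' @param reads primer/MID-trimmed record set.
#' @param references reference set.
#' @param allow_premature allow sanctioned premature terminations.
#' @param min_prefix minimum prefix length for premature matches; must be at
#'   least [min_unambiguous_length()] of the references.
#' @return list: `matches` (data.frame read_id, matched_template,
#'   match_kind in full/premature_prefix/none) and `frequencies` (data.frame
#'   template_id, count, frequency over matched reads).
#' @export
identify_error_free <- function(reads, references, allow_premature = FALSE,
                                min_prefix = NULL) {
  amp <- vapply(references, `[[`, character(1), "amplicon")
  if (allow_premature) {
    bound <- min_unambiguous_length(references)
    if (is.null(min_prefix)) min_prefix <- bound
    if (min_prefix < bound) {
      stop("min_prefix (", min_prefix, ") is below the unambiguity bound (",
           bound, ")")
    }
  }
  full_map <- setNames(names(amp), unname(amp))

  tpl <- rep(NA_character_, nrow(reads))
  kind <- rep("none", nrow(reads))
  has_n <- grepl("N", reads$bases, fixed = TRUE)
  hit <- full_map[reads$bases]
  ok <- !is.na(hit) & !has_n
  tpl[ok] <- hit[ok]
  kind[ok] <- "full"
  if (allow_premature) {
    cand <- which(!ok & !has_n & nchar(reads$bases) >= min_prefix)
    for (i in cand) {
      l <- nchar(reads$bases[i])
      pm <- which(substr(amp, 1, l) == reads$bases[i] & nchar(amp) > l)
      if (length(pm) == 1L) {
        tpl[i] <- names(amp)[pm]
        kind[i] <- "premature_prefix"
      }
    }
  }
  matches <- data.frame(read_id = reads$id, matched_template = tpl,
                        match_kind = kind, stringsAsFactors = FALSE)
  matched <- matches[matches$match_kind != "none", , drop = FALSE]
  counts <- table(factor(matched$matched_template, levels = names(amp)))
  freqs <- data.frame(template_id = names(amp),
                      count = as.integer(counts),
                      frequency = if (sum(counts) > 0)
                        as.numeric(counts) / sum(counts) else 0,
                      stringsAsFactors = FALSE)
  list(matches = matches, frequencies = freqs)
}

#' SLP-style quality filter
#'
#' Removes reads with one or more ambiguous bases (N / quality 0), reads
#' whose arithmetic mean quality is strictly below `min_mean_quality`, and
#' reads shorter than `min_length`. Order is preserved; a read with mean
#' quality exactly 30 is kept.
#'
#' @param reads record set with qualities on every read.
#' @param min_mean_quality mean-quality cutoff (default 30).
#' @param min_length length cutoff (default 50).
#' @return list: `kept` (record set) and `discarded` (data.frame read_id,
#'   reason in ambiguous_base/low_mean_quality/too_short).
#' @export
filter_slp_style <- function(reads, min_mean_quality = 30, min_length = 50) {
  if (any(vapply(reads$quality, is.null, logical(1)))) {
    stop("SLP-style filtering requires qualities on every read")
  }
  reason <- rep(NA_character_, nrow(reads))
  has_amb <- grepl("N", reads$bases, fixed = TRUE) |
    vapply(reads$quality, function(q) any(q == 0L), logical(1))
  meanq <- vapply(reads$quality, mean, numeric(1))
  reason[nchar(reads$bases) < min_length] <- "too_short"
  reason[is.na(reason) & meanq < min_mean_quality] <- "low_mean_quality"
  reason[has_amb] <- "ambiguous_base"   # checked first in the published order
  kept <- reads[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       discarded = data.frame(read_id = reads$id[!is.na(reason)],
                              reason = reason[!is.na(reason)],
                              stringsAsFactors = FALSE))
}

#' Fixed-length trim filter
#'
#' Reads shorter than `trim_length` are removed; the rest are truncated to
#' `trim_length` and then removed if the fraction of bases with quality
#' <= `q_threshold` is at least `max_lowq_fraction` (a read with exactly the
#' threshold fraction is removed).
#'
#' @param reads record set with qualities.
#' @param trim_length target length (e.g. 60 for short amplicons, 216 for
#'   long ones).
#' @param max_lowq_fraction removal threshold on the low-quality fraction
#'   (default 0.03).
#' @param q_threshold quality score counted as low (default 27).
#' @return list: `kept` (trimmed record set) and `discarded` (data.frame
#'   read_id, reason in too_short/low_quality).
#' @export
filter_fixed_length <- function(reads, trim_length, max_lowq_fraction = 0.03,
                                q_threshold = 27) {
  if (trim_length <= 0) stop("trim_length must be positive")
  if (any(vapply(reads$quality, is.null, logical(1)))) {
    stop("fixed-length filtering requires qualities on every read")
  }
  too_short <- nchar(reads$bases) < trim_length
  kept <- reads[!too_short, , drop = FALSE]
  kept$bases <- substr(kept$bases, 1, trim_length)
  kept$quality <- I(lapply(kept$quality, function(q) q[seq_len(trim_length)]))
  lowq <- vapply(kept$quality, function(q) sum(q <= q_threshold), numeric(1)) /
    trim_length
  bad <- lowq >= max_lowq_fraction
  discarded <- data.frame(
    read_id = c(reads$id[too_short], kept$id[bad]),
    reason = c(rep("too_short", sum(too_short)),
               rep("low_quality", sum(bad))),
    stringsAsFactors = FALSE)
  kept <- kept[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, discarded = discarded)
}
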