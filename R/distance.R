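# Alignment-based pairwise distances. Scoring is fixed (match +1,
# mismatch -1, gap open 2, gap extend 1) so distances are reproducible
# bit-for-bit; the distance ignores terminal-gap columns, counts each
# internal gapped column once, and divides by the remaining column count.

.SUBST_MATRIX <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
    }
    m
  }
})

#' Pairwise alignment distance between two sequences
#'
#' Global alignment (match +1, mismatch -1, gap opening 2, gap extension 1),
#' then distance = (mismatches + internal gap columns) / alignment columns,
#' excluding terminal-gap columns. Symmetric; `d(a, a) = 0`. Equal-length
#' pairs whose optimal alignment is gap-free reduce to Hamming / length;
#' for equal-length pairs with at most 3 differences the gap-free alignment
#' is provably optimal under this scoring (a gapped global alignment of
#' equal-length strings needs two gap runs costing >= 6, capping its score
#' at L - 7 < L - 2h for h <= 3), so that case short-circuits.
#'
#' @param a,b non-empty nucleotide strings.
#' @return distance in [0, 1].
#' @export
pairwise_distance <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  unname(batch_distances(a, b))
}

# distances from one query to many targets, with the equal-length
# low-divergence Hamming short-circuit and vectorized alignment fallback.
# Alignments are always computed with the lexicographically smaller sequence
# as the pattern so ties between equal-score alignments resolve identically
# in both argument orders (the distance is then symmetric by construction).
batch_distances <- function(query, targets) {
  n <- length(targets)
  d <- numeric(n)
  if (n == 0L) return(d)
  qr <- charToRaw(query)
  lq <- length(qr)
  need_aln <- logical(n)
  for (k in seq_len(n)) {
    if (targets[k] == query) next
    tr <- charToRaw(targets[k])
    if (length(tr) == lq) {
      h <- sum(tr != qr)
      if (h <= 3L) d[k] <- h / lq else need_aln[k] <- TRUE
    } else {
      need_aln[k] <- TRUE
    }
  }
  todo <- which(need_aln)
  if (length(todo)) {
    swap <- targets[todo] > query
    pat <- ifelse(swap, query, targets[todo])
    sub <- ifelse(swap, targets[todo], query)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(pat), Biostrings::DNAStringSet(sub),
      type = "global", substitutionMatrix = .SUBST_MATRIX(),
      gapOpening = 2, gapExtension = 1)
    # nchar() of a global PairwiseAlignments counts alignment columns
    # excluding terminal-gap runs, and the indel accessors report internal
    # gap runs only — exactly the columns this distance is defined over
    ni <- Biostrings::nindel(aln)
    gapcols <- Biostrings::insertion(ni)[, "WidthSum"] +
      Biostrings::deletion(ni)[, "WidthSum"]
    cols <- Biostrings::nchar(aln)
    mism <- Biostrings::nmismatch(aln)
    d[todo] <- ifelse(cols > 0, (mism + gapcols) / cols, 1)
  }
  names(d) <- names(targets)
  d
}

#' Full pairwise distance matrix
#'
#' @param seqs character vector of sequences.
#' @return symmetric numeric matrix of [pairwise_distance()] values.
#' @export
dist_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1L)) {
    js <- seq.int(i + 1L, n)
    d[i, js] <- d[js, i] <- unname(batch_distances(seqs[i], seqs[js]))
  }
  d
}
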