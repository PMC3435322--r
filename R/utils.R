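# Shared internal helpers: seed substreams, random DNA, small checks.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' (references, pcr, chimeras, reads, bootstrap, ...) draws from a named
#' substream so stages can be re-run in isolation and still reproduce.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return An integer seed below 2^31, deterministic in (root_seed, stage).
#' @export
stage_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stage))
  # small multiplicative hash over the stage name, folded with the root seed
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003
  as.integer((abs(root_seed) %% 1000003) * 1009 + h) %% 2147483587L + 1L
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute `k` random positions of `seq` with a different base; returns string
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Largest-remainder apportionment of counts
#'
#' Deterministically rounds `n * p` to integer counts summing exactly to `n`,
#' assigning leftover units to the largest fractional remainders; ties are
#' broken by element order.
#'
#' @param p numeric vector of proportions (normalized internally).
#' @param n total count to apportion.
#' @return Integer vector, same length as `p`, summing to `n`.
#' @export
largest_remainder <- function(p, n) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(p))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
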