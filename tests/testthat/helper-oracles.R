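# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain-R arithmetic, exhaustive enumeration, and (for
# alignment distances) direct column counting on the aligned strings.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

oracle_iupac_positions <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  out <- integer(0)
  for (i in seq_along(p)) {
    if (!(w[i] %in% IUPAC_SETS[[p[i]]])) out <- c(out, i)
  }
  out
}

# expansion set of an IUPAC pattern with few degenerate positions
oracle_iupac_expansion <- function(pattern) {
  p <- strsplit(pattern, "")[[1]]
  combos <- expand.grid(lapply(p, function(c) IUPAC_SETS[[c]]),
                        stringsAsFactors = FALSE)
  apply(combos, 1, paste, collapse = "")
}

oracle_dereplicate <- function(seqs) {
  tab <- table(seqs)
  df <- data.frame(sequence = names(tab), abundance = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$abundance, df$sequence), ]
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_chao1 <- function(ab) {
  s <- length(ab)
  f1 <- length(ab[ab == 1])
  f2 <- length(ab[ab == 2])
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# exact one-sided Mann-Whitney p (greater: first group tends larger) by
# enumerating all assignments of the pooled values to the two groups
oracle_mw_exact_p_greater <- function(g0, g1) {
  pool <- c(g0, g1)
  n0 <- length(g0)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(g0, g1)
  idx <- utils::combn(length(pool), n0)
  us <- apply(idx, 2, function(k) u_stat(pool[k], pool[-k]))
  mean(us >= u_obs)
}

# exact one-sided Spearman p (greater) by full permutation enumeration
oracle_spearman_exact_p_greater <- function(x, y) {
  rho_obs <- oracle_spearman(x, y)
  perms <- .all_perms(length(y))
  rhos <- apply(perms, 1, function(p) oracle_spearman(x, y[p]))
  mean(rhos >= rho_obs - 1e-12)
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# aligned-string distance: align with Biostrings, then count columns
# directly on the gapped strings (independent of the metadata arithmetic
# used inside the package)
oracle_align_distance <- function(a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }   # canonical orientation
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAStringSet(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  n <- length(p)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  if (!length(keep)) return(1)
  (sum(p[keep] != s[keep])) / length(keep)
}

# from-scratch average-linkage agglomeration: recompute every cluster-pair
# average from the original distance matrix at each step (no Lance-Williams
# updates), merging the smallest average <= cutoff, lowest pair index first
oracle_average_neighbor <- function(d, cutoff) {
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    # order clusters by smallest member, as the implementation defines
    clusters <- clusters[order(vapply(clusters, min, 1L))]
    best_d <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d - 1e-15) { best_d <- avg; bi <- i; bj <- j }
      }
    }
    if (best_d > cutoff) break
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
  }
  # canonical form: list of sorted member vectors, sorted by first member
  clusters[order(vapply(clusters, min, 1L))]
}

# direct replay of the greedy centroid rule using pairwise_distance
oracle_greedy_partition <- function(seqs, cutoff) {
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0
    for (k in centroids) {
      if (mockamp::pairwise_distance(seqs[i], seqs[k]) <= cutoff) {
        hit <- k; break
      }
    }
    if (hit == 0) { centroids <- c(centroids, i); hit <- i }
    assign[i] <- hit
  }
  assign
}

# replay of the six-category precedence rules straight off the truth table,
# written as flat data.frame filtering over all member reads per OTU
oracle_classify_replay <- function(otus, amp, contam_seqs, truth,
                                   cutoff = 0.03) {
  n <- length(otus)
  cats <- rep(NA_character_, n)
  claimed <- character(0)
  member_tab <- lapply(otus, function(o) {
    ids <- unlist(o$members$member_read_ids)
    truth[truth$read_id %in% ids, , drop = FALSE]
  })
  for (i in seq_len(n)) {
    o <- otus[[i]]
    if (any(o$members$sequence %in% amp)) {
      cats[i] <- "true"
      claimed <- union(claimed,
                       names(amp)[match(o$members$sequence, amp)])
      next
    }
    tt <- member_tab[[i]]
    clean <- tt[tt$n_errors == 0 & !tt$is_chimera & !tt$is_contaminant, ]
    if (nrow(clean) > 0) {
      cats[i] <- "miscalled"
      claimed <- union(claimed, unique(clean$source))
    }
  }
  claimed <- claimed[!is.na(claimed)]
  for (i in which(is.na(cats))) {
    o <- otus[[i]]
    rep_ids <- o$members$member_read_ids[[
      which(o$members$sequence == o$representative)[1]]]
    tt <- truth[truth$read_id %in% rep_ids, , drop = FALSE]
    votes <- c(chimera = sum(tt$is_chimera),
               contaminant = sum(tt$is_contaminant),
               normal = sum(!tt$is_chimera & !tt$is_contaminant))
    top <- names(votes)[which.max(votes)]
    if (top == "chimera") { cats[i] <- "chimeric"; next }
    if (top == "contaminant") { cats[i] <- "contamination"; next }
    d_con <- vapply(contam_seqs, function(cs)
      mockamp::pairwise_distance(o$representative, cs), 1)
    if (length(d_con) && min(d_con) <= cutoff) {
      cats[i] <- "contamination"; next
    }
    d_ref <- vapply(amp, function(a)
      mockamp::pairwise_distance(o$representative, a), 1)
    near <- names(amp)[d_ref <= cutoff]
    if (length(setdiff(near, claimed)) > 0) {
      cats[i] <- "near_match"
    } else {
      cats[i] <- "false_derived"
    }
  }
  cats
}

random_seq <- function(l) paste(sample(c("A", "C", "G", "T"), l, TRUE),
                                collapse = "")

mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
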