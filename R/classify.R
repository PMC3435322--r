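# Six-category OTU truth classification: true, miscalled, chimeric,
# contamination, near_match, false_derived. Two passes so that "a reference
# not found in any true or miscalled OTU" is well defined before near-match
# status is decided.

#' Map a unique sequence to the reference set
#'
#' Exact matching uses the same rule as [identify_error_free()] (full match,
#' or a sanctioned unambiguous prefix when `allow_premature`); otherwise the
#' best identity `1 - min(pairwise_distance)` over references is reported.
#'
#' @param sequence a nucleotide string.
#' @param references reference set.
#' @param allow_premature accept unambiguous-prefix matches as exact.
#' @param min_prefix minimum prefix length for premature matches.
#' @return list: `exact` (reference id or NA), `best_reference`,
#'   `best_identity`.
#' @export
map_unique_to_reference <- function(sequence, references,
                                    allow_premature = FALSE,
                                    min_prefix = NULL) {
  amp <- vapply(references, `[[`, character(1), "amplicon")
  hit <- names(amp)[amp == sequence]
  if (length(hit) == 0 && allow_premature && !grepl("N", sequence, fixed = TRUE)) {
    bound <- min_unambiguous_length(references)
    if (is.null(min_prefix)) min_prefix <- bound
    l <- nchar(sequence)
    if (l >= max(min_prefix, bound)) {
      hit <- names(amp)[substr(amp, 1, l) == sequence & nchar(amp) > l]
    }
  }
  if (length(hit) >= 1) {
    return(list(exact = hit[1], best_reference = hit[1], best_identity = 1))
  }
  dists <- batch_distances(sequence, amp)
  k <- which.min(dists)
  list(exact = NA_character_, best_reference = names(amp)[k],
       best_identity = unname(1 - dists[k]))
}

# majority provenance of one unique's member reads from the truth table;
# ties prefer chimera, then contaminant, then a normal template source
.representative_provenance <- function(member_read_ids, truth) {
  rows <- truth[match(member_read_ids, truth$read_id), , drop = FALSE]
  n_ch <- sum(rows$is_chimera, na.rm = TRUE)
  n_co <- sum(rows$is_contaminant, na.rm = TRUE)
  n_no <- nrow(rows) - n_ch - n_co
  lab <- c("chimera", "contaminant", "normal")
  lab[which.max(c(n_ch, n_co, n_no))]
}

#' Classify OTUs against the references and truth table
#'
#' Pass 1 assigns `true` (some member unique exactly matches a reference)
#' and `miscalled` (no exact unique, but at least one raw member read is an
#' error-free, non-chimeric, non-contaminant copy of a reference). Pass 2
#' applies, in precedence order, `chimeric` (representative's member reads
#' are chimeric by majority in the truth table; without a truth table, a
#' two-parent prefix+suffix reconstruction from the references attains near
#' identity while no single reference does), `contamination`
#' (representative within `near_match_cutoff` of the contaminant set),
#' `near_match` (representative within `near_match_cutoff` of a reference
#' claimed by no true/miscalled OTU), and `false_derived` otherwise.
#' For each false-derived OTU the abundance ratio to its most similar true
#' OTU is reported.
#'
#' @param otus list of OTUs (from the clustering functions).
#' @param references reference set.
#' @param contaminant_set contaminant record set (or NULL).
#' @param truth truth table from [simulate_reads()]; NULL in scoring mode.
#' @param near_match_cutoff distance defining "close to" a reference
#'   (default 0.03, the clustering cutoff).
#' @param allow_premature accept unambiguous-prefix matches as exact.
#' @return data.frame: otu_id, category, abundance, rel_abundance,
#'   matched_reference, best_identity, chimera_parents, nearest_true_otu,
#'   derived_abundance_ratio.
#' @export
classify_otus <- function(otus, references, contaminant_set = NULL,
                          truth = NULL, near_match_cutoff = 0.03,
                          allow_premature = FALSE) {
  n <- length(otus)
  amp <- vapply(references, `[[`, character(1), "amplicon")
  category <- rep(NA_character_, n)
  matched_ref <- rep(NA_character_, n)
  best_ident <- rep(NA_real_, n)
  chim_parents <- rep(NA_character_, n)
  claimed <- character(0)

  # lightweight exact matcher for pass 1 (full match or sanctioned prefix)
  bound <- if (allow_premature) min_unambiguous_length(references) else NA
  exact_ref <- function(s) {
    hit <- names(amp)[amp == s]
    if (length(hit) == 0 && allow_premature &&
        !grepl("N", s, fixed = TRUE) && nchar(s) >= bound) {
      hit <- names(amp)[substr(amp, 1, nchar(s)) == s & nchar(amp) > nchar(s)]
    }
    if (length(hit)) hit[1] else NA_character_
  }

  # pass 1: true / miscalled
  for (i in seq_len(n)) {
    o <- otus[[i]]
    exact <- vapply(o$members$sequence, exact_ref, character(1))
    if (any(!is.na(exact))) {
      category[i] <- "true"
      matched_ref[i] <- exact[!is.na(exact)][1]
      best_ident[i] <- 1
      claimed <- union(claimed, exact[!is.na(exact)])
      next
    }
    if (!is.null(truth)) {
      ids <- unlist(o$members$member_read_ids)
      rows <- truth[match(ids, truth$read_id), , drop = FALSE]
      ok <- !is.na(rows$n_errors) & rows$n_errors == 0 &
        !rows$is_chimera & !rows$is_contaminant
      if (any(ok)) {
        category[i] <- "miscalled"
        matched_ref[i] <- rows$source[ok][1]
        claimed <- union(claimed, unique(rows$source[ok]))
      }
    }
    # scoring mode (no truth table): miscalled needs raw-read provenance,
    # which dereplication collapses; such OTUs fall through to pass 2
  }

  # pass 2: chimeric / contamination / near_match / false_derived
  for (i in which(is.na(category))) {
    o <- otus[[i]]
    rep_seq <- o$representative
    rep_member <- which(o$members$sequence == rep_seq)[1]
    if (!is.null(truth) && !is.na(rep_member)) {
      prov <- .representative_provenance(
        o$members$member_read_ids[[rep_member]], truth)
      if (prov == "chimera") {
        category[i] <- "chimeric"
        ids <- o$members$member_read_ids[[rep_member]]
        rows <- truth[match(ids, truth$read_id), , drop = FALSE]
        ch <- rows[rows$is_chimera, , drop = FALSE]
        if (nrow(ch) > 0) {
          chim_parents[i] <- paste(ch$source[1], ch$source_b[1], sep = "|")
        }
        next
      }
      if (prov == "contaminant") {
        category[i] <- "contamination"
        next
      }
    } else if (is.null(truth)) {
      chim <- .chimera_reconstruction(rep_seq, amp, near_match_cutoff)
      if (!is.null(chim)) {
        category[i] <- "chimeric"
        chim_parents[i] <- paste(chim, collapse = "|")
        next
      }
    }
    if (!is.null(contaminant_set) && nrow(contaminant_set) > 0) {
      dc <- batch_distances(rep_seq, contaminant_set$bases)
      if (min(dc) <= near_match_cutoff) {
        category[i] <- "contamination"
        next
      }
    }
    dr <- batch_distances(rep_seq, amp)
    k <- which.min(dr)
    best_ident[i] <- unname(1 - dr[k])
    unclaimed <- setdiff(names(amp)[dr <= near_match_cutoff], claimed)
    if (length(unclaimed) > 0) {
      category[i] <- "near_match"
      matched_ref[i] <- unclaimed[which.min(dr[unclaimed])]
      next
    }
    category[i] <- "false_derived"
    matched_ref[i] <- names(amp)[k]
  }

  abundance <- vapply(otus, `[[`, numeric(1), "total_abundance")
  out <- data.frame(
    otu_id = sprintf("otu%03d", seq_len(n)),
    category = category,
    abundance = abundance,
    rel_abundance = abundance / sum(abundance),
    matched_reference = matched_ref,
    best_identity = best_ident,
    chimera_parents = chim_parents,
    nearest_true_otu = NA_character_,
    derived_abundance_ratio = NA_real_,
    stringsAsFactors = FALSE)

  # false-derived OTUs: abundance relative to the most similar true OTU
  true_idx <- which(out$category == "true")
  for (i in which(out$category == "false_derived")) {
    if (length(true_idx) == 0) break
    dt <- vapply(true_idx, function(j)
      pairwise_distance(otus[[i]]$representative,
                        otus[[j]]$representative), numeric(1))
    j <- true_idx[which.min(dt)]
    out$nearest_true_otu[i] <- out$otu_id[j]
    out$derived_abundance_ratio[i] <- out$abundance[i] / out$abundance[j]
  }
  out
}

# best two-parent prefix+suffix reconstruction of `seq` from equal-length
# references; returns c(parentA, parentB) when the reconstruction reaches
# near-identity while no single reference does, else NULL
.chimera_reconstruction <- function(seq, amp, cutoff) {
  L <- nchar(seq)
  if (!all(nchar(amp) == L)) return(NULL)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  mat <- vapply(amp, function(a)
    strsplit(a, "", fixed = TRUE)[[1]] == s, logical(L))
  single_best <- max(colSums(mat)) / L
  if (single_best >= 1 - cutoff) return(NULL)   # a single parent explains it
  pre <- apply(mat, 2, cumsum)                  # prefix match counts
  suf <- apply(mat[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  best <- 0
  best_pair <- NULL
  for (bp in seq_len(L - 1)) {
    a <- which.max(pre[bp, ])
    b <- which.max(suf[bp + 1, ])
    sc <- (pre[bp, a] + suf[bp + 1, b]) / L
    if (sc > best && a != b) {
      best <- sc
      best_pair <- c(colnames(mat)[a], colnames(mat)[b])
    }
  }
  if (best >= 1 - cutoff) best_pair else NULL
}

#' Rank-frequency report by OTU category
#'
#' Observed OTUs sorted by abundance (rank, relative abundance, category)
#' with the expected ("theoretical") template frequencies interleaved as
#' their own category, ready for rank-abundance plotting.
#'
#' @param classified data.frame from [classify_otus()].
#' @param expected_profile named expected frequencies per template.
#' @return data.frame: rank, label, category, rel_abundance, observed flag.
#' @export
rank_frequency_report <- function(classified, expected_profile) {
  obs <- data.frame(label = classified$otu_id,
                    category = classified$category,
                    rel_abundance = classified$rel_abundance,
                    observed = TRUE, stringsAsFactors = FALSE)
  theo <- data.frame(label = names(expected_profile),
                     category = "theoretical",
                     rel_abundance = as.numeric(expected_profile),
                     observed = FALSE, stringsAsFactors = FALSE)
  out <- rbind(obs, theo)
  out <- out[order(-out$rel_abundance, out$label), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "label", "category", "rel_abundance", "observed")]
}
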