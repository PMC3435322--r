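# Dereplication, abundance-greedy preclustering, greedy identity clustering,
# average-neighbor (UPGMA-cut) clustering, and the clustering control.
#
# Unique-read sets are data.frames with columns:
#   sequence, abundance (integer), member_read_ids (list-column)
# sorted by abundance descending, then sequence ascending. OTUs are lists
# with fields members (unique-read data.frame), representative (sequence of
# the most abundant member) and total_abundance.

.sort_uniques <- function(u) {
  u <- u[order(-u$abundance, u$sequence), , drop = FALSE]
  rownames(u) <- NULL
  u
}

.make_otu <- function(members) {
  members <- .sort_uniques(members)
  list(members = members,
       representative = members$sequence[1],
       total_abundance = sum(members$abundance))
}

#' Dereplicate reads into unique sequences with abundances
#'
#' @param reads a sequence record set, or a character vector of sequences.
#' @return unique-read data.frame sorted by abundance descending then
#'   sequence ascending; abundances sum to the input count and member ids
#'   partition the input ids.
#' @export
dereplicate <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("r", seq_along(reads)), bases = reads,
                        stringsAsFactors = FALSE)
  }
  sp <- split(reads$id, reads$bases)
  u <- data.frame(sequence = names(sp),
                  abundance = lengths(sp),
                  member_read_ids = I(unname(sp)),
                  stringsAsFactors = FALSE)
  .sort_uniques(u)
}

#' Single-linkage preclustering of unique reads
#'
#' Descending-abundance passes: each unique is absorbed into the most
#' abundant earlier unique within `width` of it (abundances and member lists
#' merge; the absorbed sequence disappears). Passes repeat until a pass
#' makes no merge, or every surviving unique has abundance at least
#' `min_cluster_size`. Total abundance is conserved.
#'
#' @param uniques unique-read data.frame (sorted as from [dereplicate()]).
#' @param width pairwise-distance threshold for absorption (default 0.02).
#' @param min_cluster_size stop once all survivors reach this abundance
#'   (default 10).
#' @return merged unique-read data.frame, same sort convention.
#' @export
precluster_single_linkage <- function(uniques, width = 0.02,
                                      min_cluster_size = 10) {
  if (nrow(uniques) < 2) return(uniques)
  ab <- uniques$abundance
  members <- uniques$member_read_ids
  alive <- rep(TRUE, nrow(uniques))
  # Visiting absorbers v in descending-abundance order and letting v absorb
  # every still-unmerged less-abundant unique within `width` assigns each
  # unique to its most abundant eligible absorber; distances are computed
  # lazily in batches instead of as a full matrix.
  repeat {
    ord <- which(alive)[order(-ab[alive], uniques$sequence[alive])]
    merged <- FALSE
    for (pos in seq_len(length(ord) - 1L)) {
      v <- ord[pos]
      if (!alive[v]) next
      cand <- ord[seq.int(pos + 1L, length(ord))]
      cand <- cand[alive[cand]]
      if (length(cand) == 0) next
      d <- batch_distances(uniques$sequence[v], uniques$sequence[cand])
      hit <- cand[d <= width]
      if (length(hit)) {
        ab[v] <- ab[v] + sum(ab[hit])
        members[[v]] <- c(members[[v]], unlist(members[hit]))
        alive[hit] <- FALSE
        merged <- TRUE
      }
    }
    if (!merged || all(ab[alive] >= min_cluster_size)) break
  }
  out <- data.frame(sequence = uniques$sequence[alive],
                    abundance = ab[alive],
                    member_read_ids = I(members[alive]),
                    stringsAsFactors = FALSE)
  .sort_uniques(out)
}

#' Greedy centroid clustering at a fixed identity
#'
#' Uniques are visited in descending abundance; each joins the first
#' existing centroid within `1 - identity`, else seeds a new OTU. The
#' centroid (and OTU representative) is the seeding unique, which is the
#' most abundant member by visit order.
#'
#' @param uniques unique-read data.frame.
#' @param identity identity threshold (default 0.97, i.e. distance 0.03).
#' @return list of OTUs (see file header).
#' @export
cluster_greedy <- function(uniques, identity = 0.97) {
  uniques <- .sort_uniques(uniques)
  cutoff <- 1 - identity
  centroids <- character(0)
  assign <- integer(nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    hit <- 0L
    if (length(centroids)) {
      d <- batch_distances(uniques$sequence[i], centroids)
      w <- which(d <= cutoff)
      if (length(w)) hit <- w[1]
    }
    if (hit == 0L) {
      centroids <- c(centroids, uniques$sequence[i])
      hit <- length(centroids)
    }
    assign[i] <- hit
  }
  lapply(seq_along(centroids), function(k) {
    otu <- .make_otu(uniques[assign == k, , drop = FALSE])
    otu$representative <- centroids[k]
    otu
  })
}

#' Average-neighbor (UPGMA-cut) clustering
#'
#' Agglomerative average-linkage clustering on the full pairwise distance
#' matrix: the pair of clusters with the smallest average inter-cluster
#' distance merges while that distance does not exceed `cutoff`; ties break
#' on the lowest pair index (clusters ordered by their smallest original
#' member index). Average distances are maintained with the UPGMA
#' Lance-Williams update.
#'
#' @param uniques unique-read data.frame.
#' @param cutoff maximum average inter-cluster distance merged (default 0.03).
#' @return list of OTUs.
#' @export
cluster_average_neighbor <- function(uniques, cutoff = 0.03) {
  uniques <- .sort_uniques(uniques)
  n <- nrow(uniques)
  if (n == 1) return(list(.make_otu(uniques)))
  d <- dist_matrix(uniques$sequence)
  groups <- as.list(seq_len(n))   # each ordered; list ordered by min member
  sizes <- rep(1L, n)
  repeat {
    m <- length(groups)
    if (m == 1) break
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (d[i, j] < best_d - 1e-15) {  # strict improvement; ties keep lowest (i,j)
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    if (!is.finite(best_d) || best_d > cutoff) break
    i <- best[1]; j <- best[2]
    # Lance-Williams UPGMA update of row/col i, then drop j
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    groups[[j]] <- NULL
    sizes <- sizes[-j]
    d <- d[-j, -j, drop = FALSE]
    # keep list ordered by smallest original member index
    ord <- order(vapply(groups, min, integer(1)))
    groups <- groups[ord]
    sizes <- sizes[ord]
    d <- d[ord, ord, drop = FALSE]
  }
  lapply(groups, function(g) .make_otu(uniques[g, , drop = FALSE]))
}

#' Clustering control: OTU count on the references alone
#'
#' Runs the named clustering on the reference amplified regions (each with
#' abundance 1) and returns the OTU count — how many OTUs an error-free
#' dataset would produce.
#'
#' @param references reference set.
#' @param method `"greedy"` or `"average_neighbor"`.
#' @param identity identity for greedy clustering (default 0.97).
#' @param cutoff distance cutoff for average-neighbor clustering
#'   (default 0.03).
#' @return integer OTU count.
#' @export
clustering_control <- function(references,
                               method = c("average_neighbor", "greedy"),
                               identity = 0.97, cutoff = 0.03) {
  if (!is.character(method) || !all(method %in% c("average_neighbor", "greedy"))) {
    stop("unknown clustering method: ", paste(method, collapse = ","))
  }
  method <- match.arg(method)
  amp <- vapply(references, `[[`, character(1), "amplicon")
  u <- dereplicate(unname(amp))
  otus <- if (method == "greedy") cluster_greedy(u, identity)
          else cluster_average_neighbor(u, cutoff)
  length(otus)
}

#' Write an OTU table to TSV
#'
#' @param otus list of OTUs.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(otus, path) {
  df <- data.frame(
    otu_id = sprintf("otu%03d", seq_along(otus)),
    representative_sequence = vapply(otus, `[[`, character(1),
                                     "representative"),
    total_abundance = vapply(otus, `[[`, numeric(1), "total_abundance"),
    member_sequences = vapply(otus, function(o)
      paste(o$members$sequence, collapse = ";"), character(1)),
    member_abundances = vapply(otus, function(o)
      paste(o$members$abundance, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
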