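# Generative model of the amplicon library: template-level PCR with
# mismatch-penalized per-cycle efficiencies, post-PCR chimera formation,
# cloning-host contamination, and per-base read errors with qualities.
# Every emitted read carries a truth record (source, error count, chimera
# parents/breakpoint, contaminant flag) so downstream OTUs can be scored
# against ground truth.

#' Simulation configuration
#'
#' Rates are per the unit stated; all randomness flows from `seed` via named
#' substreams (see [stage_seed()]).
#'
#' @param pcr_cycles number of PCR cycles (endpoint model; default 30, a
#'   low-cycle protocol).
#' @param base_efficiency per-cycle amplification efficiency of a perfectly
#'   primer-matched template, in (0, 1].
#' @param per_mismatch_penalty multiplicative efficiency factor per primer
#'   mismatch, in (0, 1].
#' @param three_prime_extra_penalty additional factor per mismatch in the 3'
#'   half of a priming region (polymerase extends from the 3' end), in (0, 1].
#' @param chimera_rate total relative frequency of chimeric molecules in the
#'   post-PCR pool, in [0, 1).
#' @param n_chimera_species number of distinct chimeric species sharing that
#'   frequency equally.
#' @param contamination_rate fraction of reads drawn from the contaminant
#'   set, in [0, 1).
#' @param substitution_rate per-base substitution probability.
#' @param homopolymer_indel_base_rate per-run indel probability scale; a run
#'   of length L >= 2 gains or loses one base with probability
#'   `rate * (L - 1)`.
#' @param ambiguous_call_rate per-base probability of an N call (quality 0).
#' @param truncation_rate probability a read terminates prematurely at a
#'   uniform position in the second half of the amplicon.
#' @param n_reads number of reads to emit.
#' @param seed root RNG seed.
#' @param deterministic_counts if TRUE, per-species read counts are exact
#'   largest-remainder apportionments instead of multinomial draws.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(pcr_cycles = 30, base_efficiency = 0.9,
                       per_mismatch_penalty = 0.85,
                       three_prime_extra_penalty = 0.7,
                       chimera_rate = 0.005, n_chimera_species = 5,
                       contamination_rate = 0.005,
                       substitution_rate = 0.003,
                       homopolymer_indel_base_rate = 0.001,
                       ambiguous_call_rate = 0.0005,
                       truncation_rate = 0,
                       n_reads = 10000, seed = 1,
                       deterministic_counts = FALSE) {
  cfg <- list(pcr_cycles = pcr_cycles, base_efficiency = base_efficiency,
              per_mismatch_penalty = per_mismatch_penalty,
              three_prime_extra_penalty = three_prime_extra_penalty,
              chimera_rate = chimera_rate,
              n_chimera_species = n_chimera_species,
              contamination_rate = contamination_rate,
              substitution_rate = substitution_rate,
              homopolymer_indel_base_rate = homopolymer_indel_base_rate,
              ambiguous_call_rate = ambiguous_call_rate,
              truncation_rate = truncation_rate,
              n_reads = n_reads, seed = seed,
              deterministic_counts = isTRUE(deterministic_counts))
  with(cfg, {
    stopifnot(pcr_cycles >= 1,
              base_efficiency > 0, base_efficiency <= 1,
              per_mismatch_penalty > 0, per_mismatch_penalty <= 1,
              three_prime_extra_penalty > 0, three_prime_extra_penalty <= 1,
              chimera_rate >= 0, chimera_rate < 1,
              contamination_rate >= 0, contamination_rate < 1,
              substitution_rate >= 0, substitution_rate < 1,
              homopolymer_indel_base_rate >= 0,
              ambiguous_call_rate >= 0, truncation_rate >= 0,
              n_reads > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Endpoint PCR with mismatch-penalized efficiencies
#'
#' Per-template per-cycle efficiency is
#' `e_i = base_efficiency * per_mismatch_penalty^m5 *
#'   (per_mismatch_penalty * three_prime_extra_penalty)^m3`
#' where `m5`/`m3` count the template's primer mismatches in the 5'/3' halves
#' of both priming regions. After `C` cycles the post-PCR frequency is
#' `f_i` proportional to `p_i * (1 + e_i)^C`, renormalized. With zero
#' mismatches everywhere the input profile is returned unchanged.
#'
#' @param templates reference set from [build_reference_set()].
#' @param profile abundance profile (named, sums to 1).
#' @param primer_pair primer pair used for mismatch counting.
#' @param config a [sim_config()].
#' @return named numeric vector: post-PCR relative frequency per template.
#' @export
simulate_pcr <- function(templates, profile, primer_pair, config) {
  stopifnot(abs(sum(profile) - 1) < 1e-9,
            all(names(profile) %in% names(templates)))
  eff <- vapply(names(profile), function(id) {
    mm <- template_primer_mismatches(templates[[id]], primer_pair)
    config$base_efficiency *
      config$per_mismatch_penalty^mm$m5 *
      (config$per_mismatch_penalty * config$three_prime_extra_penalty)^mm$m3
  }, numeric(1))
  w <- profile * (1 + eff)^config$pcr_cycles
  w / sum(w)
}

#' Inject chimeric species into a post-PCR pool
#'
#' Total chimera frequency equals `chimera_rate`; each of
#' `n_chimera_species` chimeric species receives an equal share. Parents are
#' drawn (distinct) with probability proportional to pool frequencies and a
#' single breakpoint is uniform over interior positions of the amplified
#' region; the chimera is parent A's prefix up to the breakpoint followed by
#' parent B's suffix. Chimeras identical to an existing template are redrawn.
#'
#' @param pool named post-PCR frequencies over template ids.
#' @param templates reference set (provides amplicon sequences).
#' @param chimera_rate total chimera frequency in [0, 1).
#' @param n_species number of chimeric species.
#' @param seed RNG seed.
#' @return list: `pool` (extended frequencies, chimera ids `chimN`),
#'   `chimeras` (data.frame id, parent_a, parent_b, breakpoint, sequence).
#' @export
simulate_chimeras <- function(pool, templates, chimera_rate,
                              n_species = 5, seed = 1) {
  stopifnot(chimera_rate >= 0, chimera_rate < 1)
  if (chimera_rate == 0) {
    return(list(pool = pool,
                chimeras = data.frame(id = character(), parent_a = character(),
                                      parent_b = character(),
                                      breakpoint = integer(),
                                      sequence = character())))
  }
  if (length(pool) < 2) stop("chimera formation needs at least 2 templates")
  set.seed(seed)
  amp <- vapply(templates[names(pool)], `[[`, character(1), "amplicon")
  existing <- unname(amp)
  rows <- vector("list", n_species)
  for (k in seq_len(n_species)) {
    for (try in 1:100) {
      parents <- sample(names(pool), 2, prob = pool)
      la <- nchar(amp[parents[1]])
      bp <- sample(seq(2L, la - 1L), 1)
      seqk <- paste0(substr(amp[parents[1]], 1, bp),
                     substr(amp[parents[2]], bp + 1, nchar(amp[parents[2]])))
      if (!(seqk %in% existing)) break
    }
    existing <- c(existing, seqk)
    rows[[k]] <- data.frame(id = sprintf("chim%d", k),
                            parent_a = parents[1], parent_b = parents[2],
                            breakpoint = bp, sequence = seqk,
                            stringsAsFactors = FALSE)
  }
  chim <- do.call(rbind, rows)
  new_pool <- c(pool * (1 - chimera_rate),
                setNames(rep(chimera_rate / n_species, n_species), chim$id))
  list(pool = new_pool, chimeras = chim)
}

#' Emit error-bearing reads with qualities and a truth table
#'
#' Each read is MID + forward primer + amplified region with simulated
#' errors. Species counts are multinomial over the pool (or exact
#' largest-remainder counts when `deterministic_counts` is set); a
#' `contamination_rate` fraction is instead drawn from `contaminants`.
#' Per base: substitution with `substitution_rate`, ambiguous call (N,
#' quality 0) with `ambiguous_call_rate`; per homopolymer run of length
#' L >= 2, one insertion or deletion of the run base with probability
#' `homopolymer_indel_base_rate * (L - 1)`. Errors touch only the amplified
#' region, so the truth table's `n_errors` counts exactly the events that
#' corrupt the amplicon. Qualities: correct bases 35-40, errored bases 5-15,
#' N bases 0.
#'
#' @param pool named frequencies (templates and, optionally, chimera ids).
#' @param templates reference set.
#' @param config a [sim_config()].
#' @param mid the sample's MID barcode string.
#' @param primer_pair primer pair (forward primer is emitted on each read).
#' @param chimeras chimera table from [simulate_chimeras()] (may be empty).
#' @param contaminants contaminant record set; required when
#'   `contamination_rate > 0`.
#' @return list: `reads` (record set with qualities), `truth` (data.frame
#'   read_id, source, source_b, n_errors, is_chimera, breakpoint,
#'   is_contaminant).
#' @export
simulate_reads <- function(pool, templates, config, mid = "ACGTACGTAC",
                           primer_pair = default_primer_pair("v3v4"),
                           chimeras = NULL, contaminants = NULL) {
  stopifnot(abs(sum(pool) - 1) < 1e-9, config$n_reads > 0)
  if (config$contamination_rate > 0 && is.null(contaminants)) {
    stop("contamination_rate > 0 requires a contaminant set")
  }
  set.seed(stage_seed(config$seed, "reads"))
  n <- config$n_reads

  # species sequences (amplified regions) and provenance
  amp <- vapply(templates, `[[`, character(1), "amplicon")
  species_seq <- amp[intersect(names(pool), names(amp))]
  is_chim <- setNames(rep(FALSE, length(pool)), names(pool))
  if (!is.null(chimeras) && nrow(chimeras) > 0) {
    species_seq <- c(species_seq,
                     setNames(chimeras$sequence, chimeras$id))
    is_chim[chimeras$id] <- TRUE
  }
  species_seq <- species_seq[names(pool)]

  # apportion reads: contaminants first, then pool species
  n_contam <- if (config$contamination_rate == 0) 0L else {
    if (config$deterministic_counts) {
      as.integer(round(config$contamination_rate * n))
    } else {
      stats::rbinom(1, n, config$contamination_rate)
    }
  }
  n_pool <- n - n_contam
  counts <- if (config$deterministic_counts) {
    largest_remainder(pool, n_pool)
  } else {
    as.integer(stats::rmultinom(1, n_pool, pool))
  }
  names(counts) <- names(pool)

  src <- rep(names(counts), counts)
  if (n_contam > 0) {
    ci <- sample.int(nrow(contaminants), n_contam, replace = TRUE)
    src <- c(src, contaminants$id[ci])
  }
  src <- sample(src)  # shuffle emission order
  n <- length(src)

  contam_seq <- if (!is.null(contaminants)) {
    setNames(contaminants$bases, contaminants$id)
  } else c()
  all_seq <- c(species_seq, contam_seq)
  contam_ids <- names(contam_seq)

  prefix <- paste0(mid, .concretize_iupac(primer_pair$forward$sequence))
  npref <- nchar(prefix)
  pref_q <- rep(40L, npref)

  no_errors <- config$substitution_rate == 0 &&
    config$ambiguous_call_rate == 0 &&
    config$homopolymer_indel_base_rate == 0 && config$truncation_rate == 0

  if (no_errors) {
    # vectorized clean path: identical per-read structure, no per-base RNG loop
    body <- unname(all_seq[src])
    bases <- paste0(prefix, body)
    lens <- nchar(body)
    qbody <- split(sample(35:40, sum(lens), replace = TRUE),
                   rep(seq_len(n), lens))
    quals <- lapply(qbody, function(qb) c(pref_q, as.integer(qb)))
    nerr <- integer(n)
    ids <- sprintf("read%06d", seq_len(n))
    reads <- seq_records(ids, bases, quals)
    return(.finish_simulated_reads(ids, reads, src, nerr, is_chim, chimeras,
                                   contam_ids))
  }

  bases <- character(n)
  quals <- vector("list", n)
  nerr <- integer(n)
  for (i in seq_len(n)) {
    tpl <- all_seq[[src[i]]]
    if (config$truncation_rate > 0 &&
        stats::runif(1) < config$truncation_rate) {
      L <- nchar(tpl)
      cut <- sample(seq(floor(L / 2), L - 1L), 1)
      tpl <- substr(tpl, 1, cut)
    }
    mut <- .apply_read_errors(tpl, config)
    bases[i] <- paste0(prefix, mut$bases)
    quals[[i]] <- c(pref_q, mut$quality)
    nerr[i] <- mut$n_errors
  }
  ids <- sprintf("read%06d", seq_len(n))
  reads <- seq_records(ids, bases, quals)
  .finish_simulated_reads(ids, reads, src, nerr, is_chim, chimeras, contam_ids)
}

.finish_simulated_reads <- function(ids, reads, src, nerr, is_chim, chimeras,
                                    contam_ids) {
  chim_ids <- names(is_chim)[is_chim]
  chim_hit <- src %in% chim_ids
  truth <- data.frame(
    read_id = ids,
    source = ifelse(chim_hit, chimeras$parent_a[match(src, chimeras$id)], src),
    source_b = ifelse(chim_hit, chimeras$parent_b[match(src, chimeras$id)],
                      NA_character_),
    species = src,
    n_errors = nerr,
    is_chimera = chim_hit,
    breakpoint = ifelse(chim_hit, chimeras$breakpoint[match(src, chimeras$id)],
                        NA_integer_),
    is_contaminant = src %in% contam_ids,
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

# apply substitutions, N calls and homopolymer indels to one sequence;
# returns bases, integer qualities, and the number of error events
.apply_read_errors <- function(seq, config) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  q <- if (L > 0) sample(35:40, L, replace = TRUE) else integer(0)
  n_err <- 0L

  if (config$substitution_rate > 0 && L > 0) {
    hit <- which(stats::runif(L) < config$substitution_rate)
    for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    if (length(hit)) q[hit] <- sample(5:15, length(hit), replace = TRUE)
    n_err <- n_err + length(hit)
  }
  if (config$ambiguous_call_rate > 0 && L > 0) {
    hit <- which(stats::runif(L) < config$ambiguous_call_rate & ch != "N")
    ch[hit] <- "N"
    q[hit] <- 0L
    n_err <- n_err + length(hit)
  }
  if (config$homopolymer_indel_base_rate > 0 && L > 1) {
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    runs <- which(r$lengths >= 2)
    # process right-to-left so earlier positions stay valid after edits
    for (k in rev(runs)) {
      pr <- config$homopolymer_indel_base_rate * (r$lengths[k] - 1)
      if (stats::runif(1) < pr) {
        pos <- ends[k]
        if (stats::runif(1) < 0.5) {          # insertion of the run base
          ch <- append(ch, r$values[k], after = pos)
          q <- append(q, sample(5:15, 1), after = pos)
        } else {                               # deletion of one run base
          ch <- ch[-pos]
          q <- q[-pos]
        }
        n_err <- n_err + 1L
      }
    }
  }
  list(bases = paste(ch, collapse = ""), quality = as.integer(q),
       n_errors = n_err)
}
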