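# Reference template construction and abundance profiles for simulated
# mock communities: a group of mutually similar templates descended from one
# random ancestor plus one or more divergent outliers, with primer binding
# sites (optionally carrying injected mismatches) flanking the amplified
# region. Mirrors the 19-similar + 1-divergent design of real clone panels.

#' Build a synthetic reference template set
#'
#' Templates share a random ancestor amplified region. Members of the similar
#' group each receive `within_group_substitutions` private substitutions, so
#' two group members differ at roughly twice that many sites. Divergent
#' templates receive `divergent_substitutions + within_group_substitutions`
#' substitutions, guaranteeing at least `divergent_substitutions` differences
#' from every similar template. Priming regions are concrete realizations of
#' the primer pair (degenerate positions resolved to one base) into which
#' per-template mismatches can be injected via `mismatch_spec`.
#'
#' @param n_templates total number of templates (20 in the canonical design).
#' @param n_divergent how many divergent outliers (default 1).
#' @param amplicon_length length of the amplified region between the primers.
#' @param within_group_substitutions private substitutions per similar-group
#'   member.
#' @param divergent_substitutions guaranteed minimum distance of each
#'   divergent template from all similar templates.
#' @param primer_pair list with `forward` and `reverse` [primer_def()]s.
#' @param mismatch_spec optional list keyed by template id; each entry a list
#'   of lists with fields `primer` ("forward"/"reverse"), `position` (1-based
#'   from the primer's 5' end) and optionally `base` (the substituted base).
#' @param seed integer RNG seed.
#' @return list of `reference_template`s: each has `id`, `full_sequence`,
#'   `amplicon`, `fwd_site`, `rev_site` (binding-site windows as read by each
#'   primer, 5'->3' of the primer), `taxon_label`,
#'   `injected_primer_mismatches`.
#' @export
build_reference_set <- function(n_templates = 20, n_divergent = 1,
                                amplicon_length = 250,
                                within_group_substitutions = 5,
                                divergent_substitutions = 40,
                                primer_pair = default_primer_pair("v3v4"),
                                mismatch_spec = list(), seed = 1) {
  stopifnot(n_divergent < n_templates, n_divergent >= 0,
            within_group_substitutions < amplicon_length,
            divergent_substitutions + within_group_substitutions <=
              amplicon_length)
  set.seed(seed)
  ancestor <- random_dna(amplicon_length)
  n_similar <- n_templates - n_divergent
  ids <- sprintf("t%02d", seq_len(n_templates))
  labels <- c(rep("similar-group", n_similar), rep("divergent", n_divergent))

  amplicons <- character(n_templates)
  repeat {
    for (i in seq_len(n_templates)) {
      k <- if (i <= n_similar) within_group_substitutions
           else divergent_substitutions + within_group_substitutions
      amplicons[i] <- mutate_positions(
        ancestor, sample.int(amplicon_length, k))
    }
    if (!anyDuplicated(amplicons)) break
  }

  fwd_oligo <- .concretize_iupac(primer_pair$forward$sequence)
  rev_oligo <- .concretize_iupac(primer_pair$reverse$sequence)

  out <- vector("list", n_templates)
  for (i in seq_len(n_templates)) {
    spec <- mismatch_spec[[ids[i]]] %||% list()
    fwd_site <- fwd_oligo
    rev_site <- rev_oligo
    injected <- list(forward = list(), reverse = list())
    for (m in spec) {
      primer <- match.arg(m$primer, c("forward", "reverse"))
      site <- if (primer == "forward") fwd_site else rev_site
      if (m$position < 1 || m$position > nchar(site)) {
        stop("mismatch position ", m$position, " outside primer length for ",
             ids[i])
      }
      old <- substr(site, m$position, m$position)
      newb <- m$base %||% sample(setdiff(DNA_BASES, old), 1L)
      substr(site, m$position, m$position) <- newb
      if (primer == "forward") fwd_site <- site else rev_site <- site
      injected[[primer]] <- c(injected[[primer]],
                              list(list(position = m$position, base = newb)))
    }
    # rev_site is stored 5'->3' of the reverse primer; on the template's top
    # strand the reverse binding site appears as its reverse complement
    full <- paste0(fwd_site, amplicons[i], reverse_complement(rev_site))
    out[[i]] <- structure(list(
      id = ids[i], full_sequence = full, amplicon = amplicons[i],
      fwd_site = fwd_site, rev_site = rev_site,
      taxon_label = labels[i],
      injected_primer_mismatches = injected), class = "reference_template")
  }
  names(out) <- ids
  out
}

# resolve degenerate IUPAC positions to the first base of their expansion
.concretize_iupac <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) IUPAC_EXPANSION[[c]][1], character(1)),
        collapse = "")
}

#' Count primer mismatches of a template against a primer pair
#'
#' Applies [iupac_mismatches()] to the template's forward and reverse binding
#' sites (each read 5'->3' of its primer) and splits positions into the 5'
#' and 3' halves of each primer (split at ceiling(len/2)).
#'
#' @param template a `reference_template`.
#' @param primer_pair list with `forward`/`reverse` [primer_def()]s.
#' @return list with per-primer positions and totals `m5` / `m3`.
#' @export
template_primer_mismatches <- function(template, primer_pair) {
  res <- list()
  m5 <- 0L; m3 <- 0L
  for (side in c("forward", "reverse")) {
    prim <- primer_pair[[side]]$sequence
    site <- if (side == "forward") template$fwd_site else template$rev_site
    mm <- iupac_mismatches(prim, site)
    half <- ceiling(nchar(prim) / 2)
    m5 <- m5 + sum(mm$positions <= half)
    m3 <- m3 + sum(mm$positions > half)
    res[[side]] <- mm$positions
  }
  res$m5 <- m5
  res$m3 <- m3
  res$total <- m5 + m3
  res
}

#' Build an abundance profile over a template set
#'
#' The tiered design spans 0.18 down to 0.00001 across 20 templates
#' (2x0.18, 2x0.15, 2x0.10, 2x0.05, 3x0.01, 3x0.001, 3x0.0001, 3x0.00001;
#' the raw tier values sum to 0.99333 and are renormalized to 1).
#'
#' @param kind `"equal"` or `"tiered"`.
#' @param template_ids character vector of template ids.
#' @param tiers optional numeric tier vector overriding the built-in tiered
#'   design (must match `length(template_ids)`).
#' @return named numeric vector summing to 1 (an abundance profile).
#' @export
make_profile <- function(kind = c("equal", "tiered"), template_ids,
                         tiers = NULL) {
  kind <- match.arg(kind)
  n <- length(template_ids)
  if (kind == "equal") {
    p <- rep(1 / n, n)
  } else {
    if (is.null(tiers)) {
      tiers <- c(0.18, 0.18, 0.15, 0.15, 0.10, 0.10, 0.05, 0.05,
                 0.01, 0.01, 0.01, 0.001, 0.001, 0.001,
                 0.0001, 0.0001, 0.0001, 0.00001, 0.00001, 0.00001)
      if (n != 20) {
        stop("tiered profile requires exactly 20 templates, or supply `tiers`")
      }
    }
    if (length(tiers) != n) stop("tier vector length must match template count")
    if (any(tiers <= 0)) stop("tier values must be positive")
    p <- tiers / sum(tiers)
  }
  names(p) <- template_ids
  p
}

#' Synthetic cloning-vector contaminant sequences
#'
#' Random sequences standing in for cloning-host (vector) contamination,
#' generated far (>10% diverged) from any template built off a different
#' seed stream; labelled synthetic.
#'
#' @param n number of contaminant species.
#' @param length sequence length.
#' @param seed RNG seed.
#' @return sequence record set with ids `contam1..n`.
#' @export
make_contaminant_set <- function(n = 1, length = 250, seed = 99) {
  set.seed(seed)
  seq_records(paste0("contam", seq_len(n)),
              vapply(seq_len(n), function(i) random_dna(length), character(1)))
}
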