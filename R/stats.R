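# Observed-vs-expected recovery statistics: rank and log-log correlations,
# bootstrap resampling with percentile CIs and one-sided Monte-Carlo p
# values, Chao1 richness, O:E ratios, and primer-mismatch effect tests.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties); `NA` when
#' either vector is constant.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in [-1, 1], or NA.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Log-log Pearson correlation
#'
#' Pearson correlation of `log10(observed)` vs `log10(expected)`; pairs in
#' which either value is non-positive are excluded (count attached as the
#' `"n_excluded"` attribute). NA with fewer than 3 positive pairs.
#'
#' @param observed,expected numeric vectors of equal length.
#' @return r in [-1, 1] (or NA), with attributes `n` and `n_excluded`.
#' @export
loglog_pearson <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  keep <- observed > 0 & expected > 0
  lo <- log10(observed[keep])
  le <- log10(expected[keep])
  r <- if (sum(keep) < 3 || stats::sd(lo) == 0 || stats::sd(le) == 0)
    NA_real_ else stats::cor(lo, le)
  attr(r, "n") <- sum(keep)
  attr(r, "n_excluded") <- sum(!keep)
  r
}

#' Bootstrap resampling of recovery correlations
#'
#' Each replicate resamples `target_size` reads with replacement from the
#' pool of per-read template labels (equivalently, a multinomial draw over
#' the pool frequencies), recomputes observed frequencies, and evaluates the
#' Spearman and log-log Pearson coefficients against `expected` over
#' templates with positive observed and expected frequency. Replicates with
#' fewer than 3 positive taxa are dropped and counted. The one-sided
#' Monte-Carlo p value uses the add-one rule
#' `p = (1 + #\{replicates <= comparison\}) / (B + 1)`.
#'
#' @param pool character vector: matched template id per error-free read.
#' @param expected named expected frequencies.
#' @param target_size reads drawn per replicate (<= `length(pool)` typical).
#' @param B number of replicates (default 10000).
#' @param seed RNG seed.
#' @param comparison_coefficient named list/vector with elements `spearman`
#'   and `pearson` to compare against (optional).
#' @param keep_replicates also return the replicate coefficient vectors.
#' @return list with one summary per coefficient (`spearman`, `pearson`),
#'   each holding B, point (mean), ci_low, ci_high (2.5/97.5 percentiles),
#'   p_one_sided (NA without a comparison), n_dropped; plus `replicates`
#'   when requested.
#' @export
bootstrap_correlations <- function(pool, expected, target_size, B = 10000,
                                   seed = 1, comparison_coefficient = NULL,
                                   keep_replicates = FALSE) {
  stopifnot(length(pool) >= 1, B >= 1, target_size >= 1)
  set.seed(seed)
  ids <- names(expected)
  base_counts <- table(factor(pool, levels = ids))
  pool_freq <- as.numeric(base_counts) / sum(base_counts)
  draws <- stats::rmultinom(B, target_size, pool_freq)  # ids x B
  exp_v <- as.numeric(expected)

  rho <- rep(NA_real_, B)
  r <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    obs <- draws[, b]
    keep <- obs > 0 & exp_v > 0
    if (sum(keep) < 3) next
    f <- obs[keep] / sum(obs)
    rho[b] <- spearman_rho(f, exp_v[keep])
    r[b] <- stats::cor(log10(f), log10(exp_v[keep]))
  }
  summarize <- function(v, comp) {
    ok <- !is.na(v)
    s <- list(B = B,
              point = mean(v[ok]),
              ci_low = unname(stats::quantile(v[ok], 0.025)),
              ci_high = unname(stats::quantile(v[ok], 0.975)),
              p_one_sided = if (is.null(comp)) NA_real_ else
                (1 + sum(v[ok] <= comp)) / (sum(ok) + 1),
              n_dropped = sum(!ok))
    s
  }
  comp_s <- comparison_coefficient$spearman %||% NULL
  comp_p <- comparison_coefficient$pearson %||% NULL
  out <- list(spearman = summarize(rho, comp_s),
              pearson = summarize(r, comp_p))
  if (keep_replicates) out$replicates <- list(spearman = rho, pearson = r)
  out
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1 the number of singleton and
#' F2 the number of doubleton OTUs. Returns 0 on empty input; with no
#' singletons the estimate equals the observed richness.
#'
#' @param otu_abundances positive integer abundances, one per OTU.
#' @return numeric Chao1 estimate.
#' @export
chao1 <- function(otu_abundances) {
  if (length(otu_abundances) == 0) return(0)
  stopifnot(all(otu_abundances >= 1))
  f1 <- sum(otu_abundances == 1)
  f2 <- sum(otu_abundances == 2)
  length(otu_abundances) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Observed:expected ratio table
#'
#' @param observed_freqs named observed relative frequencies.
#' @param expected_profile named expected frequencies (> 0 for every
#'   observed template).
#' @return data.frame: template_id, observed, expected, oe_ratio,
#'   unobserved flag (ratio 0 for templates never observed).
#' @export
oe_table <- function(observed_freqs, expected_profile) {
  ids <- names(expected_profile)
  obs <- observed_freqs[ids]
  obs[is.na(obs)] <- 0
  if (any(expected_profile <= 0 & obs > 0)) {
    stop("template observed with expected frequency 0")
  }
  data.frame(template_id = ids,
             observed = as.numeric(obs),
             expected = as.numeric(expected_profile),
             oe_ratio = as.numeric(obs) / as.numeric(expected_profile),
             unobserved = as.numeric(obs) == 0,
             stringsAsFactors = FALSE)
}

#' Primer-mismatch effect tests
#'
#' Tests whether per-template primer mismatch counts depress O:E ratios:
#' a Spearman rank correlation test (exact permutation p for n <= 10 without
#' ties, t-approximation otherwise) and a Mann-Whitney rank-sum test of the
#' 0-mismatch group against the >= 1-mismatch group (exact for small
#' tie-free groups, normal approximation with tie correction otherwise).
#' Exclusions are explicit and caller-supplied, never automatic.
#'
#' @param mismatch_counts named integer vector: mismatches per template.
#' @param oe_ratios named numeric vector: O:E ratio per template.
#' @param exclude_ids template ids to drop before testing.
#' @param alternative alternative hypothesis for both tests (default
#'   `"two.sided"`; use `"greater"` to test 0-mismatch O:E > mismatched O:E
#'   one-sided).
#' @return list: `spearman` (rho, p), `ranksum` (U, p; NA when a group is
#'   empty), `n`.
#' @export
mismatch_effect_tests <- function(mismatch_counts, oe_ratios,
                                  exclude_ids = character(0),
                                  alternative = "two.sided") {
  ids <- setdiff(intersect(names(mismatch_counts), names(oe_ratios)),
                 exclude_ids)
  if (length(ids) < 3) stop("need at least 3 templates after exclusions")
  m <- mismatch_counts[ids]
  oe <- oe_ratios[ids]

  ties <- anyDuplicated(m) > 0 || anyDuplicated(oe) > 0
  sp <- suppressWarnings(stats::cor.test(
    as.numeric(m), as.numeric(oe), method = "spearman",
    alternative = alternative,
    exact = length(ids) <= 10 && !ties))
  g0 <- oe[m == 0]
  g1 <- oe[m >= 1]
  if (length(g0) == 0 || length(g1) == 0) {
    rs <- list(U = NA_real_, p = NA_real_)
  } else {
    small <- length(g0) < 50 && length(g1) < 50
    wt <- suppressWarnings(stats::wilcox.test(
      as.numeric(g0), as.numeric(g1), alternative = alternative,
      exact = small && !anyDuplicated(oe)))
    rs <- list(U = unname(wt$statistic), p = wt$p.value)
  }
  list(spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       ranksum = rs, n = length(ids))
}
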