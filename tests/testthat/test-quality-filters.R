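# Error-free identification and the two quality-filter styles.

test_that("minimum unambiguous length matches a brute-force prefix scan", {
  expect_equal(min_unambiguous_length(c("ACGT", "TCGT")), 1)
  # identical through position 100 (1-based), differing at 101
  base <- strrep("A", 100)
  expect_equal(min_unambiguous_length(c(paste0(base, "CGG"),
                                        paste0(base, "TGG"))), 101)
  expect_error(min_unambiguous_length(c("ACGT", "ACGT")), "duplicate")

  set.seed(21)
  for (rep in 1:20) {
    refs <- tiny_refs(n = 8, amplicon_length = 40, seed = rep + 100)
    amp <- unname(ref_amplicons(refs))
    got <- min_unambiguous_length(amp)
    brute <- NA
    for (k in seq_len(40)) {
      if (!any(duplicated(substr(amp, 1, k)))) { brute <- k; break }
    }
    expect_equal(got, brute)
  }
})

test_that("error-free identification is exact, prefix-aware and N-averse", {
  refs <- tiny_refs(n = 5, amplicon_length = 250, seed = 22)
  amp <- ref_amplicons(refs)
  L <- min_unambiguous_length(refs)
  reads <- seq_records(
    c("full", "prem", "sub", "short_prem", "with_n"),
    c(amp[["t05"]],
      substr(amp[["t05"]], 1, 216),
      mutate_seq(amp[["t02"]], 1),
      substr(amp[["t03"]], 1, max(L - 1, 1)),
      sub("^.", "N", amp[["t01"]])))
  res <- identify_error_free(reads, refs, allow_premature = TRUE,
                             min_prefix = 216)
  m <- res$matches
  expect_equal(m$match_kind[m$read_id == "full"], "full")
  expect_equal(m$matched_template[m$read_id == "full"], "t05")
  expect_equal(m$match_kind[m$read_id == "prem"], "premature_prefix")
  expect_equal(m$matched_template[m$read_id == "prem"], "t05")
  expect_equal(m$match_kind[m$read_id == "sub"], "none")
  expect_equal(m$match_kind[m$read_id == "short_prem"], "none")
  expect_equal(m$match_kind[m$read_id == "with_n"], "none")
  expect_equal(sum(res$frequencies$count), 2)
  expect_error(identify_error_free(reads, refs, allow_premature = TRUE,
                                   min_prefix = L - 1), "unambiguity bound")
  # premature matching off: prefix read no longer matches
  res2 <- identify_error_free(reads, refs, allow_premature = FALSE)
  expect_equal(res2$matches$match_kind[res2$matches$read_id == "prem"],
               "none")
})

test_that("on simulated data the matched reads are exactly the clean ones", {
  refs <- tiny_refs(n = 6, amplicon_length = 100, seed = 23)
  pool <- make_profile("equal", names(refs))
  contam <- make_contaminant_set(1, 100, seed = 24)
  ch <- simulate_chimeras(pool, refs, 0.02, 3, seed = 25)
  cfg <- sim_config(substitution_rate = 0.008, ambiguous_call_rate = 0.001,
                    homopolymer_indel_base_rate = 0.002,
                    chimera_rate = 0.02, contamination_rate = 0.02,
                    n_reads = 2000, seed = 26)
  sim <- simulate_reads(ch$pool, refs, cfg, chimeras = ch$chimeras,
                        contaminants = contam)
  npref <- 10 + nchar(default_primer_pair("v3v4")$forward$sequence)
  trimmed <- sim$reads
  trimmed$bases <- substr(trimmed$bases, npref + 1, nchar(trimmed$bases))
  res <- identify_error_free(trimmed, refs)
  matched <- res$matches$read_id[res$matches$match_kind != "none"]
  want <- sim$truth$read_id[sim$truth$n_errors == 0 &
                              !sim$truth$is_chimera &
                              !sim$truth$is_contaminant]
  expect_setequal(matched, want)
})

test_that("SLP-style filter enforces ambiguity, mean-quality and length rules", {
  q40 <- function(n) rep(40L, n)
  reads <- seq_records(
    c("ok", "has_n", "meanq_2999", "meanq_30", "short"),
    c(random_seq(60), sub("^.", "N", random_seq(60)), random_seq(60),
      random_seq(60), random_seq(49)),
    list(q40(60),
         c(0L, q40(59)),
         c(rep(29L, 54), rep(30L, 5), 39L),         # mean 29.25 < 30
         rep(30L, 60),                              # mean exactly 30: kept
         q40(49)))
  out <- filter_slp_style(reads)
  expect_setequal(out$kept$id, c("ok", "meanq_30"))
  expect_equal(out$discarded$reason[out$discarded$read_id == "has_n"],
               "ambiguous_base")
  expect_equal(out$discarded$reason[out$discarded$read_id == "meanq_2999"],
               "low_mean_quality")
  expect_equal(out$discarded$reason[out$discarded$read_id == "short"],
               "too_short")
  # idempotent
  again <- filter_slp_style(out$kept)
  expect_identical(again$kept$bases, out$kept$bases)
  expect_error(filter_slp_style(seq_records("x", "ACGT")), "qualit")
})

test_that("fixed-length filter trims then applies the low-quality fraction rule", {
  mkq <- function(nlow, q = 27L, len = 100) c(rep(q, nlow), rep(40L, len - nlow))
  reads <- seq_records(
    c("three_low", "two_low", "short"),
    c(random_seq(120), random_seq(100), random_seq(99)),
    list(c(mkq(3), rep(40L, 20)), mkq(2), mkq(0, len = 99)))
  out <- filter_fixed_length(reads, trim_length = 100)
  # 3/100 low-quality bases hits the >= 3% rule; 2/100 passes
  expect_equal(out$kept$id, "two_low")
  expect_equal(nchar(out$kept$bases), 100)
  expect_setequal(out$discarded$read_id, c("three_low", "short"))
  expect_error(filter_fixed_length(reads, 0), "positive")

  # constructed cohort: 12 of 50 reads violate the fraction rule
  set.seed(27)
  n_bad <- 12
  quals <- c(lapply(seq_len(n_bad), function(i) mkq(sample(3:10, 1))),
             lapply(seq_len(50 - n_bad), function(i) mkq(sample(0:2, 1))))
  cohort <- seq_records(sprintf("c%02d", 1:50),
                        vapply(1:50, function(i) random_seq(100), ""),
                        quals)
  out2 <- filter_fixed_length(cohort, 100)
  expect_equal(nrow(out2$kept), 38)
  # idempotent
  expect_equal(nrow(filter_fixed_length(out2$kept, 100)$kept), 38)
})
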