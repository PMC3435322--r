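# Reference construction, abundance profiles, PCR bias, chimeras, reads.

test_that("reference sets embed clean priming regions and distinct amplicons", {
  pp <- default_primer_pair("v3v4")
  refs <- build_reference_set(n_templates = 20, n_divergent = 1,
                              primer_pair = pp, seed = 2)
  expect_length(refs, 20)
  for (r in refs) {
    expect_equal(iupac_mismatches(pp$forward$sequence, r$fwd_site)$count, 0)
    expect_equal(iupac_mismatches(pp$reverse$sequence, r$rev_site)$count, 0)
  }
  amp <- ref_amplicons(refs)
  # exhaustive pairwise distinctness
  for (i in 1:19) for (j in (i + 1):20) expect_true(amp[i] != amp[j])
  # divergent template is far from every similar one
  dv <- amp[20]
  for (i in 1:19) {
    expect_gte(sum(strsplit(dv, "")[[1]] != strsplit(amp[i], "")[[1]]), 40)
  }
})

test_that("injected primer mismatches appear where requested", {
  pp <- default_primer_pair("v3v4")
  spec <- list(t03 = list(list(primer = "forward", position = 5)))
  refs <- build_reference_set(primer_pair = pp, mismatch_spec = spec,
                              seed = 3)
  mm <- iupac_mismatches(pp$forward$sequence, refs$t03$fwd_site)
  expect_equal(mm$count, 1)
  expect_equal(mm$positions, 5L)
  expect_equal(template_primer_mismatches(refs$t03, pp)$total, 1)
  expect_error(
    build_reference_set(primer_pair = pp, seed = 3,
                        mismatch_spec = list(t01 = list(
                          list(primer = "forward", position = 99)))),
    "outside primer length")
})

test_that("abundance profiles reproduce the equal and tiered designs", {
  ids <- sprintf("t%02d", 1:20)
  eq <- make_profile("equal", ids)
  expect_true(all(eq == 0.05))
  ti <- make_profile("tiered", ids)
  expect_equal(sum(ti), 1)
  expect_equal(max(ti) / min(ti), 0.18 / 0.00001, tolerance = 1e-9)
  # raw tier values before renormalization sum to 0.99333
  raw <- c(0.18, 0.18, 0.15, 0.15, 0.10, 0.10, 0.05, 0.05,
           0.01, 0.01, 0.01, 0.001, 0.001, 0.001,
           0.0001, 0.0001, 0.0001, 0.00001, 0.00001, 0.00001)
  expect_equal(sum(raw), 0.99333)
  expect_equal(unname(ti), raw / sum(raw))
  expect_error(make_profile("tiered", ids[1:5]), "20 templates")
})

test_that("uniform primer matching leaves the profile unchanged by PCR", {
  refs <- build_reference_set(seed = 4)
  prof <- make_profile("tiered", names(refs))
  pool <- simulate_pcr(refs, prof, default_primer_pair("v3v4"),
                       sim_config(seed = 1))
  expect_equal(pool, prof)
})

test_that("two-template PCR skew follows the closed-form endpoint ratio", {
  # e1 = 1.0, e2 = 0.9, C = 30, equal input:
  # f1 = 2^30 / (2^30 + 1.9^30) = (2/1.9)^30 / (1 + (2/1.9)^30)
  pp <- default_primer_pair("v6")
  spec <- list(t02 = list(list(primer = "forward", position = 2)))
  refs <- build_reference_set(n_templates = 2, n_divergent = 0,
                              amplicon_length = 80,
                              within_group_substitutions = 10,
                              primer_pair = pp, mismatch_spec = spec,
                              seed = 5)
  prof <- make_profile("equal", names(refs))
  cfg <- sim_config(base_efficiency = 1, per_mismatch_penalty = 0.9,
                    three_prime_extra_penalty = 1, pcr_cycles = 30, seed = 1)
  pool <- simulate_pcr(refs, prof, pp, cfg)
  want <- (2 / 1.9)^30 / (1 + (2 / 1.9)^30)
  expect_equal(unname(pool["t01"]), want, tolerance = 1e-12)
  expect_equal(unname(pool["t01"]), 0.823, tolerance = 2e-3)
})

test_that("a rare perfectly matched template can dominate after PCR", {
  pp <- default_primer_pair("v3v4")
  spec <- setNames(lapply(1:19, function(i) list(
    list(primer = "forward", position = 12),
    list(primer = "forward", position = 18))),
    sprintf("t%02d", 1:19))
  refs <- build_reference_set(primer_pair = pp, mismatch_spec = spec,
                              seed = 6)
  prof <- make_profile("tiered", names(refs),
                       tiers = c(rep(0.99 / 19, 19), 0.01))
  pool <- simulate_pcr(refs, prof, pp, sim_config(seed = 1))
  expect_gt(pool["t20"], 0.5)
})

test_that("chimeras carry reconstructible parents and exact pool mass", {
  refs <- build_reference_set(seed = 7)
  prof <- make_profile("equal", names(refs))
  ch0 <- simulate_chimeras(prof, refs, chimera_rate = 0, seed = 1)
  expect_equal(ch0$pool, prof)

  ch <- simulate_chimeras(prof, refs, chimera_rate = 0.01, n_species = 5,
                          seed = 1)
  expect_equal(sum(ch$pool), 1)
  expect_equal(sum(ch$pool[ch$chimeras$id]), 0.01)
  amp <- ref_amplicons(refs)
  for (k in seq_len(nrow(ch$chimeras))) {
    row <- ch$chimeras[k, ]
    want <- paste0(substr(amp[row$parent_a], 1, row$breakpoint),
                   substr(amp[row$parent_b], row$breakpoint + 1,
                          nchar(amp[row$parent_b])))
    expect_equal(row$sequence, want)
    expect_true(row$parent_a != row$parent_b)
    expect_false(want %in% amp)
  }
  expect_error(simulate_chimeras(prof[1], refs, 0.5, seed = 1),
               "at least 2")
})

test_that("zero-error deterministic reads reproduce the pool exactly", {
  refs <- tiny_refs(n = 4, amplicon_length = 60, seed = 8)
  pool <- make_profile("equal", names(refs))
  cfg <- sim_config(chimera_rate = 0, contamination_rate = 0,
                    substitution_rate = 0, homopolymer_indel_base_rate = 0,
                    ambiguous_call_rate = 0, n_reads = 400, seed = 9,
                    deterministic_counts = TRUE)
  sim <- simulate_reads(pool, refs, cfg)
  expect_equal(nrow(sim$reads), 400)
  expect_true(all(sim$truth$n_errors == 0))
  expect_equal(as.integer(table(sim$truth$source)), rep(100L, 4))
  # each template's reads are identical and equal MID+primer+amplicon
  pp <- default_primer_pair("v3v4")
  prefix <- paste0("ACGTACGTAC",
                   gsub("N", "A", pp$forward$sequence))
  for (id in names(refs)) {
    b <- sim$reads$bases[sim$truth$source == id]
    expect_equal(unique(b), paste0(prefix, refs[[id]]$amplicon))
  }
})

test_that("deterministic chimera counts follow the configured rate exactly", {
  refs <- tiny_refs(n = 4, amplicon_length = 60, seed = 8)
  pool <- make_profile("equal", names(refs))
  ch <- simulate_chimeras(pool, refs, chimera_rate = 0.01, n_species = 5,
                          seed = 2)
  cfg <- sim_config(chimera_rate = 0.01, contamination_rate = 0,
                    substitution_rate = 0, homopolymer_indel_base_rate = 0,
                    ambiguous_call_rate = 0, n_reads = 10000, seed = 3,
                    deterministic_counts = TRUE)
  sim <- simulate_reads(ch$pool, refs, cfg, chimeras = ch$chimeras)
  expect_equal(sum(sim$truth$is_chimera), 100)
})

test_that("truth table is consistent: zero errors iff bases match the source amplicon", {
  refs <- tiny_refs(n = 4, amplicon_length = 120, seed = 10)
  pool <- make_profile("equal", names(refs))
  cfg <- sim_config(chimera_rate = 0, contamination_rate = 0,
                    substitution_rate = 0.01,
                    homopolymer_indel_base_rate = 0.002,
                    ambiguous_call_rate = 0.002, truncation_rate = 0.05,
                    n_reads = 500, seed = 12)
  sim <- simulate_reads(pool, refs, cfg)
  pp <- default_primer_pair("v3v4")
  npref <- 10 + nchar(pp$forward$sequence)
  amp <- ref_amplicons(refs)
  for (i in seq_len(nrow(sim$reads))) {
    body <- substr(sim$reads$bases[i], npref + 1,
                   nchar(sim$reads$bases[i]))
    expected <- amp[[sim$truth$source[i]]]
    is_clean <- body == expected ||
      (nchar(body) < nchar(expected) &&
         body == substr(expected, 1, nchar(body)))
    expect_equal(sim$truth$n_errors[i] == 0, is_clean)
  }
})

test_that("simulation is reproducible: same seed gives identical output", {
  refs <- tiny_refs(n = 4, amplicon_length = 80, seed = 13)
  pool <- make_profile("equal", names(refs))
  cfg <- sim_config(substitution_rate = 0.01, chimera_rate = 0,
                    contamination_rate = 0, n_reads = 200, seed = 77)
  s1 <- simulate_reads(pool, refs, cfg)
  s2 <- simulate_reads(pool, refs, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("contamination requires a contaminant set and is flagged in truth", {
  refs <- tiny_refs(n = 4, amplicon_length = 60, seed = 14)
  pool <- make_profile("equal", names(refs))
  cfg <- sim_config(contamination_rate = 0.1, chimera_rate = 0,
                    substitution_rate = 0, homopolymer_indel_base_rate = 0,
                    ambiguous_call_rate = 0, n_reads = 1000, seed = 15,
                    deterministic_counts = TRUE)
  expect_error(simulate_reads(pool, refs, cfg), "contaminant")
  contam <- make_contaminant_set(1, 60, seed = 16)
  sim <- simulate_reads(pool, refs, cfg, contaminants = contam)
  expect_equal(sum(sim$truth$is_contaminant), 100)
  expect_true(all(sim$truth$source[sim$truth$is_contaminant] == "contam1"))
})
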