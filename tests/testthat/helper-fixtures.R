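# Shared fixture builders; everything is generated in code at test time.

# a small reference panel with well-separated amplicons
tiny_refs <- function(n = 4, amplicon_length = 60, seed = 11,
                      region = "v3v4") {
  build_reference_set(n_templates = n, n_divergent = 0,
                      amplicon_length = amplicon_length,
                      within_group_substitutions = 6,
                      divergent_substitutions = 0,
                      primer_pair = default_primer_pair(region),
                      seed = seed)
}

ref_amplicons <- function(refs) vapply(refs, `[[`, character(1), "amplicon")

# uniques data.frame from sequences + abundances
make_uniques <- function(seqs, abundances) {
  ids <- lapply(seq_along(seqs), function(i)
    sprintf("r%d_%d", i, seq_len(abundances[i])))
  u <- data.frame(sequence = seqs, abundance = as.integer(abundances),
                  member_read_ids = I(ids), stringsAsFactors = FALSE)
  u[order(-u$abundance, u$sequence), ]
}

# substitute exactly the given positions (cycling through other bases)
mutate_at <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# canonical partition of an OTU list: sorted member-sequence sets
otu_partition <- function(otus) {
  parts <- lapply(otus, function(o) sort(o$members$sequence))
  parts[order(vapply(parts, `[`, "", 1))]
}

# default config scaled down for tests
small_run_config <- function(seed = 1, n_reads = 600, ...) {
  cfg <- default_run_config(seed = seed, n_reads = n_reads)
  extra <- list(...)
  for (nm in names(extra)) {
    sect <- strsplit(nm, "\\.")[[1]]
    cfg[[sect[1]]][[sect[2]]] <- extra[[nm]]
  }
  cfg
}
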