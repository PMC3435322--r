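Package: mockamp
Title: Mock-Community Amplicon Simulation and Recovery Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ground-truthing toolkit for amplicon-sequencing mock communities.
    Simulates in vitro-style communities of known 16S rRNA gene templates mixed
    at known (equal or tiered) proportions, with primer-mismatch-driven PCR
    amplification bias, chimera formation, cloning-host contamination, and
    pyrosequencing-style per-base errors, emitting reads with a full per-read
    truth table. Provides the downstream evaluation workflow: perfect-match
    MID/primer demultiplexing, error-free read identification (including
    sanctioned premature terminations), quality filtering, dereplication,
    single-linkage preclustering, greedy identity and average-neighbor OTU
    clustering, six-category truth classification of OTUs (true, miscalled,
    false-derived, near-match, contamination, chimeric), and
    community-structure recovery statistics (rank and log-log correlations
    with bootstrap confidence intervals, Chao1 richness, observed:expected
    ratios, and primer-mismatch effect tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
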