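# Distances, dereplication, preclustering, greedy and average-neighbor
# clustering, and the clustering control.

test_that("pairwise distance matches direct examples and the Hamming case", {
  expect_equal(pairwise_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_distance("ACGTACGT", "ACGAACGT"), 0.125)
  set.seed(31)
  for (i in 1:50) {
    a <- random_seq(40)
    k <- sample(1:6, 1)
    b <- mutate_seq(a, k)
    h <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(pairwise_distance(a, b), h / 40)
    expect_equal(pairwise_distance(b, a), pairwise_distance(a, b))
  }
})

test_that("pairwise distance agrees with aligned-string column counting", {
  set.seed(32)
  for (i in 1:40) {
    a <- random_seq(sample(30:60, 1))
    b <- if (i %% 3 == 0) random_seq(sample(30:60, 1)) else {
      # related pair with substitutions and possibly an indel
      x <- mutate_seq(a, sample(0:4, 1) + 1)
      if (i %% 2 == 0) {
        p <- sample(nchar(x) - 1, 1)
        paste0(substr(x, 1, p), substr(x, p + 2, nchar(x)))
      } else x
    }
    expect_equal(pairwise_distance(a, b), oracle_align_distance(a, b),
                 tolerance = 1e-12)
  }
  # a clean prefix is at distance 0 (terminal gaps ignored)
  a <- random_seq(80)
  expect_equal(pairwise_distance(substr(a, 1, 50), a), 0)
})

test_that("dereplication counts, sorts and partitions read ids", {
  x <- random_seq(30); y <- random_seq(30)
  reads <- seq_records(sprintf("r%d", 1:7), c(rep(x, 5), rep(y, 2)))
  u <- dereplicate(reads)
  expect_equal(u$sequence, if (x < y) c(x, y) else c(x, y))
  expect_equal(u$abundance, c(5L, 2L))
  expect_setequal(u$member_read_ids[[1]], sprintf("r%d", 1:5))

  all_distinct <- dereplicate(vapply(1:6, function(i) random_seq(25), ""))
  expect_true(all(all_distinct$abundance == 1))

  set.seed(33)
  base <- vapply(1:5, function(i) random_seq(20), "")
  seqs <- sample(base, 200, TRUE, prob = c(5, 4, 3, 2, 1))
  u2 <- dereplicate(seqs)
  o <- oracle_dereplicate(seqs)
  expect_equal(u2$sequence, o$sequence)
  expect_equal(u2$abundance, o$abundance)
  expect_equal(sum(u2$abundance), 200)
})

test_that("preclustering absorbs near variants into abundant uniques", {
  a <- random_seq(60)
  far <- mutate_seq(a, 10)                      # d = 10/60 > 0.02
  u <- make_uniques(c(a, far), c(20, 5))
  expect_equal(nrow(precluster_single_linkage(u)), 2)

  near <- mutate_seq(a, 1)                      # d = 1/60 <= 0.02
  u2 <- make_uniques(c(a, near), c(100, 3))
  merged <- precluster_single_linkage(u2)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$sequence, a)
  expect_equal(merged$abundance, 103L)
  expect_length(merged$member_read_ids[[1]], 103)

  # conservation on a random mixture
  set.seed(34)
  pool <- c(a, near, far, mutate_seq(far, 1))
  seqs <- sample(pool, 300, TRUE, prob = c(10, 1, 5, 1))
  u3 <- dereplicate(seqs)
  out <- precluster_single_linkage(u3)
  expect_equal(sum(out$abundance), 300)
})

test_that("greedy clustering matches a direct replay of the rule", {
  a <- random_seq(100)
  u <- make_uniques(rep(a, 1), 5)
  expect_length(cluster_greedy(u), 1)

  b <- mutate_seq(a, 10)                        # d = 0.10 > 0.03
  u2 <- make_uniques(c(a, b), c(5, 3))
  expect_length(cluster_greedy(u2), 2)

  set.seed(35)
  for (rep in 1:10) {
    base <- random_seq(80)
    seqs <- unique(c(base, vapply(1:7, function(i)
      mutate_seq(base, sample(c(1, 2, 5, 9), 1)), "")))
    ab <- sample(1:50, length(seqs))
    u3 <- make_uniques(seqs, ab)
    otus <- cluster_greedy(u3, identity = 0.97)
    oracle_assign <- oracle_greedy_partition(u3$sequence, 0.03)
    want_sets <- lapply(split(seq_along(oracle_assign), oracle_assign),
                        function(ix) sort(u3$sequence[ix]))
    got_sets <- otu_partition(otus)
    expect_setequal(got_sets, unname(want_sets))
    expect_equal(sum(vapply(otus, `[[`, 1, "total_abundance")), sum(ab))
  }
})

test_that("average-neighbor clustering follows hand-computed linkage", {
  # mutual distances all small: one OTU
  a <- random_seq(100)
  b <- mutate_seq(a, 1)
  c2 <- mutate_seq(a, 1)
  u <- make_uniques(unique(c(a, b, c2)), rep(4, length(unique(c(a, b, c2)))))
  expect_length(cluster_average_neighbor(u, 0.03), 1)

  # AB = 0.02, AC = 0.05, BC = 0.07 by construction: A,B merge, then the
  # average distance from {A,B} to C (0.06) exceeds the cutoff
  A <- random_seq(100)
  B <- mutate_at(A, 1:2)
  C <- mutate_at(A, 11:15)
  expect_equal(pairwise_distance(A, B), 0.02)
  expect_equal(pairwise_distance(A, C), 0.05)
  expect_equal(pairwise_distance(B, C), 0.07)
  otus <- cluster_average_neighbor(make_uniques(c(A, B, C), c(3, 2, 1)), 0.03)
  expect_length(otus, 2)
  sizes <- sort(vapply(otus, function(o) nrow(o$members), 1L))
  expect_equal(sizes, c(1L, 2L))
})

test_that("average-neighbor partitions equal the from-scratch oracle on small sets", {
  set.seed(36)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    base <- random_seq(60)
    seqs <- unique(vapply(seq_len(n), function(i)
      mutate_seq(base, sample(0:4, 1)), ""))
    u <- make_uniques(seqs, sample(1:20, length(seqs)))
    got <- cluster_average_neighbor(u, 0.03)
    d <- dist_matrix(u$sequence)
    want <- oracle_average_neighbor(d, 0.03)
    got_sets <- lapply(got, function(o)
      sort(match(o$members$sequence, u$sequence)))
    got_sets <- got_sets[order(vapply(got_sets, min, 1L))]
    expect_equal(got_sets, want)
  }
})

test_that("well-separated groups: greedy and average-neighbor agree", {
  set.seed(37)
  for (rep in 1:5) {
    centers <- vapply(1:3, function(i) random_seq(90), "")
    # within-group pairwise distances <= 2/90 < 0.03; between groups far
    seqs <- unlist(lapply(centers, function(cs)
      c(cs, mutate_at(cs, 1), mutate_at(cs, 2))))
    seqs <- unique(seqs)
    u <- make_uniques(seqs, sample(5:30, length(seqs)))
    g <- otu_partition(cluster_greedy(u, 0.97))
    av <- otu_partition(cluster_average_neighbor(u, 0.03))
    expect_setequal(g, av)
    expect_length(av, 3)
  }
})

test_that("clustering control counts OTUs on the references alone", {
  refs <- build_reference_set(n_templates = 20, n_divergent = 1,
                              within_group_substitutions = 8, seed = 38)
  expect_equal(clustering_control(refs, "average_neighbor"), 20)
  expect_equal(clustering_control(refs, "greedy"), 20)
  expect_error(clustering_control(refs, "pyroclust"), "unknown")

  # two templates within the cutoff are forced to merge
  close_refs <- tiny_refs(n = 6, amplicon_length = 200, seed = 39)
  amp <- ref_amplicons(close_refs)
  close_refs$t06$amplicon <- mutate_seq(amp[["t01"]], 2)  # d = 0.01
  expect_lte(clustering_control(close_refs, "average_neighbor"), 5)
  expect_lte(clustering_control(close_refs, "greedy"), 5)
})

test_that("clustering at cutoff 0 keeps every distinct sequence apart", {
  seqs <- unique(vapply(1:6, function(i) random_seq(50), ""))
  u <- make_uniques(seqs, rep(2, length(seqs)))
  expect_length(cluster_average_neighbor(u, 0), length(seqs))
  expect_length(cluster_greedy(u, 1), length(seqs))
})
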