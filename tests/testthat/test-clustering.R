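test_that("CpG scan records every CG by the index of its C", {
  expect_identical(scan_cpg_positions("ACGCGT"), c(1L, 3L))
  expect_identical(scan_cpg_positions("CGCG"), c(0L, 2L))
  expect_identical(scan_cpg_positions("AANGA"), integer(0))
  expect_identical(scan_cpg_positions("ACNGT"), integer(0))  # N never matches
})

test_that("adjacent distances follow d = next - current - 1", {
  expect_identical(adjacent_distances(c(0L, 2L)), 1L)
  expect_identical(adjacent_distances(c(1L, 3L, 10L)), c(1L, 6L))
  expect_identical(adjacent_distances(5L), integer(0))
})

test_that("distance threshold is the nearest-rank percentile of the gaps", {
  expect_equal(distance_threshold(1:20, 65), 13)
  expect_equal(distance_threshold(c(4, 4, 4), 10), 4)
  expect_equal(distance_threshold(c(4, 4, 4), 99), 4)
  expect_equal(distance_threshold(c(1, 6), 65), 6)
  expect_error(distance_threshold(integer(0), 65), "too few CpGs")
  # permutation invariance and the 100th percentile
  set.seed(42)
  for (i in 1:20) {
    d <- sample(1:200, sample(2:40, 1), replace = TRUE)
    expect_equal(distance_threshold(d, 100), max(d))
    pct <- runif(1, 1, 100)
    expect_equal(distance_threshold(d, pct),
                 distance_threshold(sort(d), pct))
  }
})

test_that("cluster sweep joins below threshold and closes at the last G", {
  cl <- build_clusters(c(1L, 3L, 10L), 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 1L)
  expect_equal(cl$end, 5L)
  expect_equal(cl$N, 2L)

  cl <- build_clusters(c(0L, 2L), 2)
  expect_equal(cl[1, c("start", "end", "N", "L", "nf")],
               data.frame(start = 0L, end = 4L, N = 2L, L = 4L, nf = 0L))

  expect_equal(nrow(build_clusters(c(0L, 10L), 5)), 0L)  # two singletons
  expect_equal(nrow(build_clusters(7L, 5)), 0L)
})

test_that("cluster sweep matches the naive repeated-merge oracle", {
  set.seed(7)
  for (i in 1:300) {
    pos <- random_positions(sample(2:40, 1))
    dt <- sample(1:15, 1)
    got <- build_clusters(pos, dt)
    want <- cluster_oracle(pos, dt)
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
    expect_identical(got$N, as.integer(want$N))
    # structural invariants: disjoint, sorted, spans hold their CpGs only
    if (nrow(got) > 1L) expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    for (k in seq_len(nrow(got))) {
      inside <- pos >= got$start[k] & pos < got$end[k]
      expect_gte(sum(inside), 2L)
      expect_equal(sum(inside), got$N[k])
    }
    expect_true(all(got$nf >= 0))
  }
})

test_that("genome stats count CpGs over independent dinucleotide frames", {
  gs <- genome_stats("CGCG")
  expect_equal(gs[c("Ns", "Nis", "p")], list(Ns = 2L, Nis = 2L, p = 1))
  expect_equal(genome_stats("ATATATAT")$p, 0)
  gs <- genome_stats("ACGTACGTAC")
  expect_equal(gs$Ns, 2L)
  expect_equal(gs$Nis, 5L)
  expect_equal(gs$p, 0.4)
  expect_equal(genome_stats("ACGTACGTAC", "overlapping")$Nis, 9L)
  expect_error(genome_stats("A"), "shorter")
})

test_that("cluster p-value equals the closed-form small cases", {
  expect_equal(cluster_pvalue(2, 0, 0.01), 1e-4, tolerance = 1e-12)
  expect_equal(cluster_pvalue(2, 1, 0.1), 0.028, tolerance = 1e-12)
  expect_equal(cluster_pvalue(3, 4, 0.05), nb_tail_oracle(3, 4, 0.05),
               tolerance = 1e-14)
  expect_equal(cluster_pvalue(5, 1000000, 0.3), 1, tolerance = 1e-9)
  expect_warning(p0 <- cluster_pvalue(2, 3, 0), "0")
  expect_equal(p0, 0)
  expect_equal(cluster_pvalue(2, 3, 1), 1)
})

test_that("cluster p-value is non-decreasing in nf and matches the oracle", {
  for (p in c(0.05, 0.3)) {
    for (N in c(2, 7, 15)) {
      nf <- 0:60
      pv <- cluster_pvalue(rep(N, length(nf)), nf, p)
      expect_true(all(diff(pv) >= 0))
      want <- vapply(nf, nb_tail_oracle, numeric(1), N = N, p = p)
      expect_equal(pv, want, tolerance = 1e-12)
    }
  }
})

test_that("candidate selection keeps p <= alpha and preserves order", {
  clusters <- data.frame(start = c(0L, 50L), end = c(10L, 60L),
                         N = c(3L, 2L), L = c(10L, 10L), nf = c(4L, 6L),
                         p_value = c(0.001, 0.5))
  kept <- select_candidates(clusters, 0.01)
  expect_equal(kept$start, 0L)
  expect_equal(nrow(select_candidates(clusters, 1.0)), 2L)
  expect_equal(nrow(select_candidates(clusters[0, ], 0.01)), 0L)
  # unscored clusters are scored in place from the background stats
  clusters$p_value <- NULL
  kept <- select_candidates(clusters, 1.0, stats = list(p = 0.1))
  expect_equal(kept$p_value, cluster_pvalue(clusters$N, clusters$nf, 0.1))
})
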