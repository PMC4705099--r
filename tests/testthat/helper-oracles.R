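# Independent oracles used by the test suite. Each is deliberately written
# along a different computational path than the package code it checks.

# Brute-force negative-binomial lower tail: direct log-space pmf summation.
nb_tail_oracle <- function(N, nf, p) {
  x <- 0:nf
  sum(exp(lchoose(x + N - 1, N - 1) + N * log(p) + x * log1p(-p)))
}

# Naive clustering oracle: start from singleton clusters and repeatedly
# merge any adjacent pair whose gap is below the threshold, until no merge
# applies; then drop singletons.
cluster_oracle <- function(positions, dt) {
  groups <- as.list(positions)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(groups)) {
      a <- groups[[i]]; b <- groups[[i + 1L]]
      gap <- b[1] - a[length(a)] - 1L
      if (gap < dt) {
        groups[[i]] <- c(a, b)
        groups[[i + 1L]] <- NULL
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) == 0L)
    return(data.frame(start = integer(), end = integer(), N = integer()))
  data.frame(
    start = vapply(groups, function(g) g[1], integer(1)),
    end = vapply(groups, function(g) g[length(g)] + 2L, integer(1)),
    N = vapply(groups, length, integer(1))
  )
}

# Random strictly increasing CpG position set (adjacent positions >= 2
# apart, as real CG occurrences are).
random_positions <- function(n, max_gap = 20L) {
  cumsum(sample(2:max_gap, n, replace = TRUE))
}

# Exhaustive search over every (start, length) window in a region; the
# ground-truth optimum for swarm validation.
exhaustive_best_fitness <- function(idx, region, min_length = 200,
                                    min_gc = 0.5, min_oe = 0.6) {
  W <- region$end - region$start
  best <- -Inf
  for (fl in seq_len(W)) {
    fs <- region$start + 0:(W - fl)
    f <- island_fitness(idx, fs, rep(fl, length(fs)), region,
                        min_length, min_gc, min_oe)
    m <- max(f)
    if (m > best) best <- m
  }
  best
}

# A deterministic GGF-compliant block: alternating CpG-rich repeat.
cg_repeat <- function(n_pairs) paste(rep("CG", n_pairs), collapse = "")

# Random residue string with given per-base alphabet weights.
random_dna <- function(n, weights = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}
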