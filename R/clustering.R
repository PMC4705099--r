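# Stage 1: distance-based CpG clustering with negative-binomial significance.
#
# A CpG cluster is a maximal run of CpGs whose adjacent gaps are all below a
# distance threshold taken at a percentile of the genome-wide gap
# distribution. Under a background model where a CpG occurs independently in
# each dinucleotide frame with probability p, the number of independent
# non-CpG units inside a cluster of N CpGs is negative-binomially
# distributed; the lower tail at the observed count is the cluster p-value,
# and small p-values mark unexpectedly compact clusters.

#' Scan CpG dinucleotide positions
#'
#' Finds every CG occurrence 5' to 3' and records the 0-based index of its C.
#' CG occurrences cannot overlap one another, so the scan is exact; `N`
#' residues never match.
#'
#' @param seq A sequence record (from [read_fasta()]) or a residue string.
#' @return Integer vector of 0-based positions, strictly increasing
#'   (possibly empty).
#' @examples
#' scan_cpg_positions("ACGCGT")  # 1, 3
#' scan_cpg_positions("CGCG")    # 0, 2 (shortest adjacent distance, gap 1)
#' @export
scan_cpg_positions <- function(seq) {
  s <- as_residues(seq)
  hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Gaps between adjacent CpGs
#'
#' The physical distance between adjacent CpGs is
#' `d_i = position[i+1] - position[i] - 1`, i.e. the number of bases strictly
#' between the C of one CpG and the C of the next minus the G it owns; the
#' shortest possible distance is 1 (`CGCG`).
#'
#' @param positions Strictly increasing integer vector of CpG positions.
#' @return Integer vector of length `n - 1` (empty when `n <= 1`).
#' @export
adjacent_distances <- function(positions) {
  if (length(positions) < 2L) return(integer(0))
  if (any(diff(positions) < 2L))
    stop("CpG positions must be strictly increasing and >= 2 apart",
         call. = FALSE)
  diff(positions) - 1L
}

#' Percentile distance threshold
#'
#' Nearest-rank percentile of the adjacent-CpG gap distribution: the k-th
#' smallest gap with `k = ceiling(percentile/100 * n_gaps)`. The threshold
#' is therefore always an observed gap, and is invariant to permutation of
#' the input.
#'
#' @param distances Non-empty integer vector of adjacent-CpG gaps.
#' @param percentile Percentile in (0, 100]; the detector default is 65.
#' @return The threshold gap `dt`.
#' @export
distance_threshold <- function(distances, percentile = 65) {
  if (length(distances) == 0L)
    stop("no adjacent-CpG distances: too few CpGs to cluster", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]", call. = FALSE)
  k <- ceiling(percentile / 100 * length(distances))
  sort(distances)[k]
}

empty_cluster_df <- function() {
  data.frame(start = integer(), end = integer(), N = integer(),
              L = integer(), nf = integer())
}

#' Build CpG clusters from positions and a distance threshold
#'
#' Left-to-right sweep: a gap strictly smaller than `dt` joins the two
#' adjacent CpGs into the same cluster; a gap `>= dt` closes the cluster at
#' the G of the upstream CpG. Only clusters with at least two CpGs are kept
#' (a cluster is defined over an adjacent-CpG distance, so singletons are
#' never clusters). A cluster spans from the C of its first CpG through the
#' G of its last CpG (half-open end).
#'
#' @param positions Strictly increasing 0-based CpG positions.
#' @param dt Distance threshold (`>= 1`).
#' @return Data frame with columns `start`, `end` (0-based half-open), `N`
#'   (CpG count), `L` (`end - start`), `nf` (independent non-CpGs,
#'   `L - 2N`).
#' @export
build_clusters <- function(positions, dt) {
  stopifnot(dt >= 1)
  n <- length(positions)
  if (n < 2L) return(empty_cluster_df())
  gaps <- diff(positions) - 1L
  grp <- cumsum(c(1L, as.integer(gaps >= dt)))
  size <- tabulate(grp)
  first <- positions[!duplicated(grp)]
  last <- positions[!duplicated(grp, fromLast = TRUE)]
  keep <- size >= 2L
  out <- data.frame(start = first[keep], end = last[keep] + 2L,
                    N = size[keep], L = integer(sum(keep)),
                    nf = integer(sum(keep)))
  out$L <- out$end - out$start
  out$nf <- out$L - 2L * out$N
  out
}

#' Genome-wide CpG background statistics
#'
#' The background success probability for the cluster p-value is
#' `p = Ns / Nis`, where `Ns` is the number of CpG occurrences in the
#' sequence and `Nis` the number of independent dinucleotides. By default
#' dinucleotides are counted as non-overlapping frames
#' (`Nis = floor(length/2)`); `counting = "overlapping"` uses
#' `Nis = length - 1` instead.
#'
#' @param seq Sequence record or residue string of length >= 2.
#' @param counting Dinucleotide counting convention, `"independent"`
#'   (default) or `"overlapping"`.
#' @return List with elements `Ns`, `Nis`, `p`.
#' @export
genome_stats <- function(seq, counting = c("independent", "overlapping")) {
  counting <- match.arg(counting)
  s <- as_residues(seq)
  len <- nchar(s)
  if (len < 2L) stop("sequence shorter than 2 bases", call. = FALSE)
  Ns <- length(scan_cpg_positions(s))
  Nis <- if (counting == "independent") len %/% 2L else len - 1L
  list(Ns = Ns, Nis = Nis, p = Ns / Nis)
}

#' Negative-binomial cluster p-value
#'
#' Probability of observing at most `nf` independent non-CpG units in a
#' cluster of `N` CpGs when CpGs occur with background probability `p`:
#' `sum_{x=0}^{nf} choose(x+N-1, N-1) p^N (1-p)^x`, the cumulative mass of
#' the negative-binomial distribution with `N` successes. Evaluated with
#' [stats::pnbinom()] for numerical stability. Vectorized over `N` and `nf`.
#'
#' @param N CpG count(s) in the cluster(s), `>= 2`.
#' @param nf Independent non-CpG count(s), `>= 0`.
#' @param p Background CpG probability from [genome_stats()].
#' @return p-value(s) in \[0, 1\]. `p = 0` returns 0 with a warning (no CpG
#'   background means no cluster can be scored); `p = 1` returns 1.
#' @examples
#' cluster_pvalue(2, 0, 0.01)  # collapses to p^N = 1e-4
#' @export
cluster_pvalue <- function(N, nf, p) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1, all(nf >= 0), all(N >= 1))
  if (p == 0) {
    warning("background CpG probability is 0; p-values reported as 0",
            call. = FALSE)
    return(rep(0, length.out = max(length(N), length(nf))))
  }
  if (p == 1) return(rep(1, length.out = max(length(N), length(nf))))
  pnbinom(nf, size = N, prob = p)
}

#' Score clusters and keep the statistically significant ones
#'
#' Adds a `p_value` column (via [cluster_pvalue()]) when absent, then keeps
#' clusters with `p_value <= alpha`, preserving order. Low p-values mark
#' clusters more compact than the genome-wide background predicts.
#'
#' @param clusters Cluster data frame from [build_clusters()].
#' @param alpha Significance level (detector default 0.01).
#' @param stats Background statistics from [genome_stats()]; required when
#'   `clusters` has no `p_value` column.
#' @return The retained clusters (with `p_value`).
#' @export
select_candidates <- function(clusters, alpha = 0.01, stats = NULL) {
  if (nrow(clusters) == 0L) {
    clusters$p_value <- numeric(0)
    return(clusters)
  }
  if (is.null(clusters$p_value)) {
    if (is.null(stats))
      stop("clusters are unscored; supply `stats`", call. = FALSE)
    clusters$p_value <- cluster_pvalue(clusters$N, clusters$nf, stats$p)
  }
  clusters[clusters$p_value <= alpha, , drop = FALSE]
}
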