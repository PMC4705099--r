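# Orchestration: Stage 1 clustering -> flank extension -> per-candidate
# swarm search -> merge of nearby calls.

#' Detector configuration
#'
#' Bundles every tunable of the two-stage detector. Defaults are the
#' standard operating point: 65th-percentile distance threshold, cluster
#' significance level 0.01, 200 bp flank extension (the minimum GGF island
#' length), merge gap 100 bp, and a 300-particle, 100-generation swarm.
#'
#' @param percentile Distance-threshold percentile in (0, 100].
#' @param alpha Cluster p-value significance level in (0, 1].
#' @param flank Candidate extension in bases on each side of a cluster.
#' @param merge_gap Calls closer than this many bases are merge candidates
#'   (0 disables merging).
#' @param min_length,min_gc,min_oe GGF island feasibility thresholds.
#' @param pso Swarm parameters, see [pso_params()].
#' @param seed Global RNG seed; per-region substreams are derived from it
#'   deterministically, so results do not depend on scheduling order.
#' @param dinucleotide_counting Convention for the background dinucleotide
#'   count, see [genome_stats()].
#' @return List of class `detector_config`.
#' @export
detector_config <- function(percentile = 65, alpha = 0.01, flank = 200,
                            merge_gap = 100, min_length = 200, min_gc = 0.5,
                            min_oe = 0.6, pso = pso_params(), seed = 1,
                            dinucleotide_counting = "independent") {
  stopifnot(percentile > 0, percentile <= 100, alpha > 0, alpha <= 1,
            flank >= 0, merge_gap >= 0)
  structure(list(percentile = percentile, alpha = alpha, flank = flank,
                 merge_gap = merge_gap, min_length = min_length,
                 min_gc = min_gc, min_oe = min_oe, pso = pso,
                 seed = as.integer(seed),
                 dinucleotide_counting = dinucleotide_counting),
            class = "detector_config")
}

#' Extend a cluster into a candidate search region
#'
#' `[max(0, start - flank), min(seq_length, end + flank))`. The extension
#' lets the swarm recover islands longer than the CpG cluster that seeded
#' them (clusters can be much shorter than the GGF minimum length).
#'
#' @param cluster_start,cluster_end Cluster bounds, 0-based half-open.
#' @param flank Extension in bases (vectorized over clusters).
#' @param seq_length Sequence length for clipping.
#' @return Data frame with columns `start`, `end`.
#' @export
extend_region <- function(cluster_start, cluster_end, flank, seq_length) {
  data.frame(start = pmax(0L, as.integer(cluster_start - flank)),
             end = pmin(as.integer(seq_length),
                        as.integer(cluster_end + flank)))
}

# Deterministic per-region seed from (global seed, sequence id, ordinal).
# Arithmetic stays exact in doubles and the result stays below 2^31 - 1.
derive_seed <- function(seed, id, ordinal) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(id)))
    h <- (h * 31 + code) %% 2147483647
  as.integer((h * 69069 + ordinal) %% 2147483647)
}

#' Merge nearby island calls with a feasibility recheck
#'
#' Calls separated by fewer than `gap` bases (overlap included) are
#' candidates for merging into one span. The merged span's GC content and
#' O/E ratio are recomputed from the sequence; if the span fails the GGF
#' criteria the merge is rolled back and the constituent calls are kept.
#' The sweep is left-to-right and a successful merge immediately becomes the
#' left operand of the next comparison, so chains collapse to a fixpoint in
#' one pass. A merged call's fitness is recomputed with its normalized
#' length taken over the union of the constituent candidate regions, and it
#' carries the smaller source p-value.
#'
#' @param calls Island-call data frame sorted by `start`.
#' @param seq Sequence record, residue string, or [sequence_index()].
#' @param gap Merge distance in bases (default 100; 0 disables).
#' @param min_length,min_gc,min_oe GGF thresholds for the recheck.
#' @return The merged call data frame.
#' @export
merge_islands <- function(calls, seq, gap = 100, min_length = 200,
                          min_gc = 0.5, min_oe = 0.6) {
  if (is.null(calls) || nrow(calls) < 2L || gap <= 0) return(calls)
  if (is.unsorted(calls$start)) stop("calls must be sorted by start",
                                     call. = FALSE)
  idx <- as_index(seq)
  if (is.null(calls$region_start)) calls$region_start <- calls$start
  if (is.null(calls$region_end)) calls$region_end <- calls$end
  out <- list()
  cur <- calls[1L, ]
  for (i in 2L:nrow(calls)) {
    nxt <- calls[i, ]
    if (nxt$start - cur$end < gap) {
      m_start <- cur$start
      m_end <- max(cur$end, nxt$end)
      comp <- window_composition(idx, m_start, m_end)
      gc <- gc_content(comp)
      oe <- oe_ratio(comp)
      ok <- (m_end - m_start) >= min_length && gc >= min_gc && oe >= min_oe
      if (ok) {
        cur$end <- m_end
        cur$length <- m_end - m_start
        cur$gc <- gc
        cur$oe <- oe
        cur$region_start <- min(cur$region_start, nxt$region_start)
        cur$region_end <- max(cur$region_end, nxt$region_end)
        cur$fitness <- gc + oe +
          cur$length / (cur$region_end - cur$region_start)
        cur$source_pvalue <- min(cur$source_pvalue, nxt$source_pvalue,
                                 na.rm = TRUE)
        next
      }
    }
    out[[length(out) + 1L]] <- cur
    cur <- nxt
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_call_df <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             length = integer(), gc = numeric(), oe = numeric(),
             fitness = numeric(), source_pvalue = numeric(),
             region_start = integer(), region_end = integer(),
             stringsAsFactors = FALSE)
}

#' Detect CpG islands in one sequence
#'
#' Full two-stage composition: scan CpG positions, derive the
#' percentile distance threshold from the sequence's own gap distribution,
#' build clusters, score their negative-binomial p-values against the
#' genome-wide background, keep significant clusters, extend each by the
#' flank, run an independent swarm search per candidate (each on a private
#' random substream derived from the global seed, the sequence id and the
#' candidate ordinal), and merge nearby calls. Deterministic for a fixed
#' seed and independent of the order of records in a multi-FASTA.
#'
#' @param seq Sequence record (from [read_fasta()]) or residue string of
#'   length >= 2.
#' @param config [detector_config()].
#' @return Island-call data frame (possibly empty) with columns
#'   `sequence_id`, `start`, `end`, `length`, `gc`, `oe`, `fitness`,
#'   `source_pvalue`, `region_start`, `region_end`, sorted by `start`.
#'   Sequences with fewer than two CpGs yield an empty call set with a
#'   message.
#' @export
detect_islands <- function(seq, config = detector_config()) {
  s <- as_residues(seq)
  id <- seq_id_of(seq)
  len <- nchar(s)
  if (len < 2L) stop("sequence shorter than 2 bases", call. = FALSE)

  pos <- scan_cpg_positions(s)
  if (length(pos) < 2L) {
    message("sequence '", id, "': fewer than 2 CpGs, no islands callable")
    return(empty_call_df())
  }
  d <- adjacent_distances(pos)
  dt <- distance_threshold(d, config$percentile)
  clusters <- build_clusters(pos, dt)
  if (nrow(clusters) == 0L) return(empty_call_df())
  stats <- genome_stats(s, config$dinucleotide_counting)
  clusters$p_value <- cluster_pvalue(clusters$N, clusters$nf, stats$p)
  cand <- select_candidates(clusters, config$alpha)
  if (nrow(cand) == 0L) return(empty_call_df())

  regions <- extend_region(cand$start, cand$end, config$flank, len)
  idx <- sequence_index(s)
  calls <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    region <- list(sequence_id = id, start = regions$start[k],
                   end = regions$end[k])
    calls[[k]] <- run_pso(idx, region, config$pso,
                          seed = derive_seed(config$seed, id, k),
                          min_length = config$min_length,
                          min_gc = config$min_gc, min_oe = config$min_oe,
                          source_pvalue = cand$p_value[k])
  }
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0L) return(empty_call_df())
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  merge_islands(calls, idx, config$merge_gap, config$min_length,
                config$min_gc, config$min_oe)
}
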