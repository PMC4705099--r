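# Synthetic benchmark sequences with known island truth.
#
# Both background and islands are first-order Markov chains over A/C/G/T.
# A first-order model is the minimum needed here: the detector's statistics
# are dinucleotide-level (the background CpG probability p and the O/E
# ratio), and an i.i.d. generator cannot decouple GC content from CpG
# frequency. The chain is parameterized by a stationary GC fraction and a
# CpG O/E target: the C->G transition is set to `oe * pi_G`, the remaining
# transition mass is redistributed so that the stationary distribution is
# exactly (pi_A, pi_C, pi_G, pi_T) with pi_C = pi_G = gc/2, and hence the
# expected whole-sequence O/E ratio equals `oe`.

markov_chain_model <- function(gc, oe) {
  stopifnot(gc > 0, gc < 1, oe > 0)
  pi <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  piC <- pi[["C"]]; piG <- pi[["G"]]
  p_cg <- oe * piG           # P(G | C)
  q <- piG * (1 - oe * piC) / (1 - piC)  # P(G | X != C), keeps pi stationary
  if (p_cg >= 1 || q <= 0 || q >= 1)
    stop("infeasible (gc, oe) combination: ", gc, ", ", oe, call. = FALSE)
  P <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (x in names(pi)) {
    pg <- if (x == "C") p_cg else q
    P[x, "G"] <- pg
    for (y in c("A", "C", "T")) P[x, y] <- pi[[y]] * (1 - pg) / (1 - piG)
  }
  list(pi = pi, P = P)
}

markov_sample <- function(n, model) {
  if (n <= 0L) return("")
  cum <- t(apply(model$P, 1, cumsum))
  states <- integer(n)
  u <- runif(n)
  states[1] <- findInterval(u[1], cumsum(model$pi)) + 1L
  for (i in seq_len(n)[-1])
    states[i] <- findInterval(u[i], cum[states[i - 1L], ]) + 1L
  paste(c("A", "C", "G", "T")[states], collapse = "")
}

#' Background sequence model
#'
#' Genome-background composition: stationary GC fraction `gc` and CpG
#' suppression factor `cpg_suppression` (the C->G transition is this
#' multiple of its GC-implied baseline, so the whole-sequence O/E ratio of
#' the output is approximately `cpg_suppression`). Defaults emulate
#' bulk-genome CpG depletion: GC 0.40, O/E 0.2.
#'
#' @param gc Background GC fraction in (0, 1).
#' @param cpg_suppression Multiplicative CpG suppression in (0, 1\];
#'   1 means no suppression (i.i.d.-like CpG frequency).
#' @return List of class `background_model`.
#' @export
background_model <- function(gc = 0.40, cpg_suppression = 0.2) {
  structure(list(gc = gc, cpg_suppression = cpg_suppression),
            class = "background_model")
}

#' Generate a background sequence
#'
#' Samples a first-order Markov chain whose stationary GC fraction is
#' `model$gc` and whose empirical CpG O/E ratio is approximately
#' `model$cpg_suppression`. Uses the current RNG stream unless `seed` is
#' given.
#'
#' @param length Sequence length in bases (`>= 0`).
#' @param model [background_model()].
#' @param seed Optional integer seed.
#' @return A residue string of the requested length.
#' @export
generate_background <- function(length, model = background_model(),
                                seed = NULL) {
  stopifnot(length >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  markov_sample(as.integer(length),
                markov_chain_model(model$gc, model$cpg_suppression))
}

#' Plant island segments into a background sequence
#'
#' Replaces each specified span with a segment drawn from an island-model
#' Markov chain (GC `spec$gc`, O/E target `spec$oe`). Each realized segment
#' is checked against the GGF criteria (length, GC, O/E as recounted from
#' the emitted bases) and resampled on failure up to `max_retries` times;
#' an unsatisfiable spec raises an error naming it. Island/background
#' junctions are hard switches, keeping the truth semantics of base-level
#' evaluation exact.
#'
#' @param background Residue string to plant into.
#' @param specs Data frame with columns `start` (0-based), `length`, `gc`,
#'   `oe`; sorted, non-overlapping, inside the background.
#' @param max_retries Resampling attempts per island.
#' @param min_length,min_gc,min_oe GGF acceptance thresholds for realized
#'   segments.
#' @return List with `residues` (the composite sequence) and `truth`
#'   (data frame of planted `start`, `end` spans, 0-based half-open).
#' @export
plant_islands <- function(background, specs, max_retries = 20,
                          min_length = 200, min_gc = 0.5, min_oe = 0.6) {
  len <- nchar(background)
  if (is.null(specs) || nrow(specs) == 0L)
    return(list(residues = background,
                truth = data.frame(start = integer(), end = integer())))
  ends <- specs$start + specs$length
  if (is.unsorted(specs$start, strictly = TRUE) ||
      any(specs$start < 0) || any(ends > len) ||
      any(specs$start[-1] < ends[-length(ends)]))
    stop("island specs must be sorted, non-overlapping, and in bounds",
         call. = FALSE)
  out <- background
  for (i in seq_len(nrow(specs))) {
    model <- markov_chain_model(specs$gc[i], specs$oe[i])
    seg <- NULL
    for (try in seq_len(max_retries)) {
      cand <- markov_sample(specs$length[i], model)
      comp <- window_composition(cand, 0, nchar(cand))
      if (comp$window_length >= min_length &&
          gc_content(comp) >= min_gc && oe_ratio(comp) >= min_oe) {
        seg <- cand
        break
      }
    }
    if (is.null(seg))
      stop("island spec ", i, " (start ", specs$start[i], ", length ",
           specs$length[i], ", gc ", specs$gc[i], ", oe ", specs$oe[i],
           ") unsatisfiable after ", max_retries, " attempts",
           call. = FALSE)
    substr(out, specs$start[i] + 1L, ends[i]) <- seg
  }
  list(residues = out,
       truth = data.frame(start = as.integer(specs$start),
                          end = as.integer(ends)))
}

#' Generate a benchmark sequence with planted islands
#'
#' Builds a background sequence and plants `n_islands` islands of uniform
#' random length at positions separated by at least `min_separation` bases
#' (also kept from both sequence ends), so that flank-extended candidates
#' of distinct truth islands cannot merge. The returned manifest records
#' every generation parameter plus the seed and regenerates the benchmark
#' bit-identically via [benchmark_from_manifest()].
#'
#' @param length Total sequence length (default 100 kb).
#' @param n_islands Number of planted islands (default 10).
#' @param island_gc,island_oe Island composition targets (defaults 0.60 and
#'   0.8).
#' @param island_length_range Inclusive island length range, sampled
#'   uniformly (default 500 to 1500 bases).
#' @param bg_gc,bg_suppression Background composition (defaults 0.40 and
#'   0.2).
#' @param min_separation Minimum distance between islands and from the
#'   sequence ends (default 500 = twice the 200 bp flank plus the 100 bp
#'   merge gap).
#' @param seed Integer seed controlling the entire generation.
#' @param id Sequence identifier for the record.
#' @return List with `record` (sequence record), `truth` (interval data
#'   frame) and `manifest` (named list of parameters).
#' @export
synthetic_benchmark <- function(length = 100000, n_islands = 10,
                                island_gc = 0.60, island_oe = 0.8,
                                island_length_range = c(500, 1500),
                                bg_gc = 0.40, bg_suppression = 0.2,
                                min_separation = 500, seed = 1,
                                id = "synthetic") {
  manifest <- list(length = length, n_islands = n_islands,
                   island_gc = island_gc, island_oe = island_oe,
                   island_length_range = island_length_range,
                   bg_gc = bg_gc, bg_suppression = bg_suppression,
                   min_separation = min_separation, seed = seed, id = id)
  set.seed(as.integer(seed))
  if (n_islands > 0) {
    span <- island_length_range[2] - island_length_range[1] + 1
    lens <- island_length_range[1] +
      sample.int(span, n_islands, replace = TRUE) - 1L
    free <- length - sum(lens) - (n_islands + 1) * min_separation
    if (free < 0)
      stop("sequence too short for the requested islands and separation",
           call. = FALSE)
    w <- runif(n_islands + 1)
    slack <- floor(free * w / sum(w))
    starts <- integer(n_islands)
    pos <- 0
    for (i in seq_len(n_islands)) {
      pos <- pos + min_separation + slack[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    specs <- data.frame(start = starts, length = lens,
                        gc = island_gc, oe = island_oe)
  } else {
    specs <- NULL
  }
  bg <- generate_background(length, background_model(bg_gc, bg_suppression))
  planted <- plant_islands(bg, specs)
  list(record = list(id = id, residues = planted$residues,
                     length = nchar(planted$residues)),
       truth = planted$truth,
       manifest = manifest)
}

#' Regenerate a benchmark from its manifest
#'
#' @param manifest Manifest list from [synthetic_benchmark()] (or read back
#'   from JSON with [read_manifest()]).
#' @return The regenerated benchmark, bit-identical to the original.
#' @export
benchmark_from_manifest <- function(manifest) {
  do.call(synthetic_benchmark, manifest)
}

#' Write or read a benchmark manifest as JSON
#'
#' @param manifest Manifest list.
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$island_length_range <- as.numeric(m$island_length_range)
  m
}
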