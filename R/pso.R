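# Stage 2: per-candidate particle swarm search for the best island under the
# Gardiner-Garden-Frommer (GGF) criteria. A particle encodes an island as
# (start Fs, length Fl); its fitness is GC content + O/E ratio + normalized
# length when the window is GGF-feasible (length >= 200, GC >= 50%,
# O/E >= 0.6), and -Inf otherwise. Window statistics are computed in O(1)
# from cumulative count arrays so swarms evaluate vectorized.

#' Cumulative composition index of a sequence
#'
#' Precomputes cumulative counts of A/C/G/T and of CG dinucleotide starts so
#' that any window's composition is an O(1) lookup. Used internally by the
#' swarm; exported because the exhaustive-search oracle in validation code
#' benefits from the same index.
#'
#' @param seq Sequence record or residue string.
#' @return An object of class `cpg_index` (list of cumulative count vectors
#'   plus the sequence length).
#' @export
sequence_index <- function(seq) {
  s <- as_residues(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(ch)
  cg <- if (len >= 2L) (ch[-len] == "C") & (ch[-1L] == "G") else logical(0)
  # CG[k + 1] = number of CG starts at positions < k (0-based)
  cgc <- c(0L, cumsum(as.integer(cg)))
  idx <- list(
    A = c(0L, cumsum(ch == "A")),
    C = c(0L, cumsum(ch == "C")),
    G = c(0L, cumsum(ch == "G")),
    T = c(0L, cumsum(ch == "T")),
    CG = c(cgc, cgc[length(cgc)]),
    length = len
  )
  class(idx) <- "cpg_index"
  idx
}

as_index <- function(seq) {
  if (inherits(seq, "cpg_index")) seq else sequence_index(seq)
}

# Vectorized window counts over 0-based half-open [fs, fs + fl).
window_counts <- function(idx, fs, fl) {
  e <- fs + fl
  list(
    a = idx$A[e + 1L] - idx$A[fs + 1L],
    c = idx$C[e + 1L] - idx$C[fs + 1L],
    g = idx$G[e + 1L] - idx$G[fs + 1L],
    t = idx$T[e + 1L] - idx$T[fs + 1L],
    cpg = idx$CG[e] - idx$CG[fs + 1L]  # CG starts within [fs, e-2]
  )
}

#' Residue composition of a window
#'
#' Counts A/T/C/G residues and CG dinucleotide occurrences over the 0-based
#' half-open window `[start, end)`. A CG pair straddling the window end
#' (C at `end - 1`) is not counted; `N` residues count toward
#' `window_length` but not toward any nucleotide count.
#'
#' @param seq Sequence record, residue string, or a [sequence_index()].
#' @param start,end Window bounds, 0-based half-open, `0 <= start < end <=`
#'   sequence length.
#' @return List with `a_count`, `t_count`, `c_count`, `g_count`,
#'   `cpg_count`, `window_length`.
#' @export
window_composition <- function(seq, start, end) {
  idx <- as_index(seq)
  if (start < 0 || end > idx$length || start >= end)
    stop("window bounds must satisfy 0 <= start < end <= length",
         call. = FALSE)
  w <- window_counts(idx, as.integer(start), as.integer(end - start))
  list(a_count = w$a, t_count = w$t, c_count = w$c, g_count = w$g,
       cpg_count = w$cpg, window_length = as.integer(end - start))
}

#' GC content of a window
#'
#' `(#C + #G) / (#A + #T + #C + #G)`; an all-N window is defined as 0 (it
#' can never be a feasible island).
#'
#' @param comp Composition from [window_composition()].
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(comp) {
  tot <- comp$a_count + comp$t_count + comp$c_count + comp$g_count
  if (tot == 0) return(0)
  (comp$c_count + comp$g_count) / tot
}

#' Observed/expected CpG ratio of a window
#'
#' `(#CpG / L) / ((#C / L) * (#G / L)) = #CpG * L / (#C * #G)` with `L` the
#' window length; defined as 0 when `#C` or `#G` is 0.
#'
#' @param comp Composition from [window_composition()].
#' @return Non-negative ratio (1 means CpGs occur exactly as often as the
#'   C and G frequencies predict; genomic background is typically < 1).
#' @export
oe_ratio <- function(comp) {
  if (comp$c_count == 0 || comp$g_count == 0) return(0)
  comp$cpg_count * comp$window_length / (comp$c_count * comp$g_count)
}

#' Normalized window length within a candidate region
#'
#' `window_length / region_width`, in (0, 1]. The denominator is the width
#' of the extended candidate region the swarm searches, so the length reward
#' of the fitness is bounded by 1 (attained by a window filling its region).
#'
#' @param window_length Window length in bases.
#' @param region Candidate region (list or one-row data frame with `start`,
#'   `end`).
#' @return Fraction in (0, 1].
#' @export
normalized_length <- function(window_length, region) {
  window_length / (region$end - region$start)
}

#' Swarm parameters
#'
#' Defaults follow the detector's standard configuration: 300 particles,
#' 100 generations, cognitive and social constants `c1 = c2 = 2`, inertia
#' weight annealed linearly from 0.9 to 0.4.
#'
#' @param population Number of particles.
#' @param max_generations Number of velocity/position updates (no early
#'   stopping, keeping runs deterministic per seed).
#' @param c1,c2 Acceleration constants toward the personal and global best.
#' @param w_max,w_min Initial and final inertia weights.
#' @return List of class `pso_params`.
#' @export
pso_params <- function(population = 300, max_generations = 100,
                       c1 = 2, c2 = 2, w_max = 0.9, w_min = 0.4) {
  stopifnot(population >= 1, max_generations >= 1, w_max >= w_min)
  structure(list(population = as.integer(population),
                 max_generations = as.integer(max_generations),
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min),
            class = "pso_params")
}

#' Linearly annealed inertia weight
#'
#' `w = (w_max - w_min) * (move_max - move_i) / move_max + w_min`: 0.9 at
#' the first move, 0.4 at the last, affine in between. Early generations
#' favor global exploration, late generations local refinement.
#'
#' @param move_i Current generation, `0 <= move_i <= move_max`.
#' @param move_max Maximum generation count.
#' @param w_max,w_min Inertia bounds.
#' @return The inertia weight.
#' @export
inertia_weight <- function(move_i, move_max, w_max = 0.9, w_min = 0.4) {
  (w_max - w_min) * (move_max - move_i) / move_max + w_min
}

# Vectorized fitness: GC + O/E + normalized length for GGF-feasible windows,
# -Inf otherwise.
region_fitness <- function(idx, fs, fl, region_start, region_end,
                           min_length = 200, min_gc = 0.5, min_oe = 0.6) {
  w <- window_counts(idx, fs, fl)
  tot <- w$a + w$c + w$g + w$t
  gc <- ifelse(tot > 0, (w$c + w$g) / tot, 0)
  oe <- ifelse(w$c > 0 & w$g > 0, w$cpg * fl / (w$c * w$g), 0)
  feasible <- fl >= min_length & gc >= min_gc & oe >= min_oe
  width <- region_end - region_start
  ifelse(feasible, gc + oe + fl / width, -Inf)
}

#' Fitness of a candidate island window
#'
#' The swarm's objective: `GC + O/E + normalized length` when the window
#' satisfies all three GGF constraints (length >= `min_length`,
#' GC >= `min_gc`, O/E >= `min_oe`), and `-Inf` (infeasible sentinel)
#' otherwise. Vectorized over `fs`/`fl`.
#'
#' @param seq Sequence record, residue string, or [sequence_index()].
#' @param fs Island start(s), 0-based, absolute coordinates.
#' @param fl Island length(s), `>= 1`.
#' @param region Candidate region with `start`, `end` bounds containing the
#'   window(s).
#' @param min_length,min_gc,min_oe GGF feasibility thresholds.
#' @return Numeric fitness vector; `-Inf` marks infeasible windows.
#' @export
island_fitness <- function(seq, fs, fl, region,
                           min_length = 200, min_gc = 0.5, min_oe = 0.6) {
  idx <- as_index(seq)
  stopifnot(all(fs >= region$start), all(fs + fl <= region$end), all(fl >= 1))
  region_fitness(idx, as.integer(fs), as.integer(fl),
                 region$start, region$end, min_length, min_gc, min_oe)
}

# Initialize a swarm: (Fs, Fl) uniform over all valid pairs inside the
# region (Fl sampled with weight equal to the number of admissible starts,
# then Fs uniform), zero velocities.
init_swarm <- function(idx, region, params, min_length, min_gc, min_oe) {
  W <- region$end - region$start
  np <- params$population
  fl <- sample.int(W, np, replace = TRUE, prob = W:1)
  fs <- as.integer(region$start + floor(runif(np) * (W - fl + 1)))
  fit <- region_fitness(idx, fs, fl, region$start, region$end,
                        min_length, min_gc, min_oe)
  feas <- is.finite(fit)
  swarm <- list(
    Fs = fs, Fl = fl,
    vFs = numeric(np), vFl = numeric(np),
    fit = fit,
    pb_Fs = fs, pb_Fl = fl, pb_fit = ifelse(feas, fit, -Inf),
    gb_Fs = NA_integer_, gb_Fl = NA_integer_, gb_fit = -Inf,
    generation = 0L
  )
  best <- max(swarm$pb_fit)
  if (best > -Inf) {
    j <- which.max(swarm$pb_fit)
    swarm$gb_Fs <- swarm$pb_Fs[j]
    swarm$gb_Fl <- swarm$pb_Fl[j]
    swarm$gb_fit <- best
  }
  swarm
}

#' Advance a swarm by one generation
#'
#' Per particle and dimension: velocity
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with fresh
#' `r1, r2 ~ U(0,1)` per particle per dimension, clamped to +/- the region
#' width; position `x <- round(x + v)`, then `Fl` is clamped into
#' `[1, width]` and `Fs` into `[region$start, region$end - Fl]` (length
#' first, then start). Fitness is re-evaluated and personal/global bests are
#' updated on strict improvement only; infeasible states never become bests,
#' and a particle without a feasible best yet feels no attraction on that
#' term.
#'
#' @param swarm Swarm state from a previous step (or internal
#'   initialization via [run_pso()]).
#' @param seq Sequence record, residue string, or [sequence_index()].
#' @param region Candidate region (`start`, `end`).
#' @param params [pso_params()].
#' @param move_i Current generation number (drives the inertia weight).
#' @param rand Optional list of pre-drawn uniforms `r1s`, `r2s`, `r1l`,
#'   `r2l` (each of length `population`); supplied by validation code to
#'   pin the stochastic terms, drawn from the current RNG stream otherwise.
#' @param min_length,min_gc,min_oe GGF feasibility thresholds.
#' @return The updated swarm state.
#' @export
step_swarm <- function(swarm, seq, region, params, move_i, rand = NULL,
                       min_length = 200, min_gc = 0.5, min_oe = 0.6) {
  idx <- as_index(seq)
  np <- length(swarm$Fs)
  W <- region$end - region$start
  v_max <- W
  w <- inertia_weight(move_i, params$max_generations, params$w_max,
                      params$w_min)
  if (is.null(rand))
    rand <- list(r1s = runif(np), r2s = runif(np),
                 r1l = runif(np), r2l = runif(np))

  has_pb <- is.finite(swarm$pb_fit)
  pb_fs <- ifelse(has_pb, swarm$pb_Fs, swarm$Fs)
  pb_fl <- ifelse(has_pb, swarm$pb_Fl, swarm$Fl)
  has_gb <- is.finite(swarm$gb_fit)
  gb_fs <- if (has_gb) swarm$gb_Fs else swarm$Fs
  gb_fl <- if (has_gb) swarm$gb_Fl else swarm$Fl

  vFs <- w * swarm$vFs + params$c1 * rand$r1s * (pb_fs - swarm$Fs) +
    params$c2 * rand$r2s * (gb_fs - swarm$Fs)
  vFl <- w * swarm$vFl + params$c1 * rand$r1l * (pb_fl - swarm$Fl) +
    params$c2 * rand$r2l * (gb_fl - swarm$Fl)
  vFs <- pmin(pmax(vFs, -v_max), v_max)
  vFl <- pmin(pmax(vFl, -v_max), v_max)

  fl <- as.integer(round(swarm$Fl + vFl))
  fl <- pmin(pmax(fl, 1L), W)
  fs <- as.integer(round(swarm$Fs + vFs))
  fs <- pmin(pmax(fs, region$start), region$end - fl)

  fit <- region_fitness(idx, fs, fl, region$start, region$end,
                        min_length, min_gc, min_oe)

  imp <- fit > swarm$pb_fit
  swarm$pb_Fs[imp] <- fs[imp]
  swarm$pb_Fl[imp] <- fl[imp]
  swarm$pb_fit[imp] <- fit[imp]

  best <- max(swarm$pb_fit)
  if (best > swarm$gb_fit) {
    j <- which.max(swarm$pb_fit)
    swarm$gb_Fs <- swarm$pb_Fs[j]
    swarm$gb_Fl <- swarm$pb_Fl[j]
    swarm$gb_fit <- best
  }

  swarm$Fs <- fs; swarm$Fl <- fl
  swarm$vFs <- vFs; swarm$vFl <- vFl
  swarm$fit <- fit
  swarm$generation <- move_i
  swarm
}

#' Run a particle swarm search over one candidate region
#'
#' Initializes `population` particles uniformly over all valid
#' (start, length) pairs with zero velocity, runs exactly `max_generations`
#' generations (the inertia weight anneals from `w_max` at the start to
#' `w_min` at the final generation), and returns the swarm's global best as
#' an island call if any GGF-feasible window was ever visited.
#'
#' @param seq Sequence record, residue string, or [sequence_index()].
#' @param region Candidate region (`start`, `end`, optionally
#'   `sequence_id`).
#' @param params [pso_params()].
#' @param seed Optional integer seed for this region's private random
#'   stream; when `NULL` the current RNG state is used.
#' @param min_length,min_gc,min_oe GGF feasibility thresholds.
#' @param source_pvalue p-value of the source cluster, carried into the
#'   call.
#' @param trace If `TRUE`, attach a numeric vector of per-generation global
#'   best fitnesses as attribute `"trace"`.
#' @return One-row data frame (`sequence_id`, `start`, `end`, `length`,
#'   `gc`, `oe`, `fitness`, `source_pvalue`, `region_start`, `region_end`)
#'   in absolute 0-based half-open coordinates, or `NULL` when no feasible
#'   window exists.
#' @export
run_pso <- function(seq, region, params = pso_params(), seed = NULL,
                    min_length = 200, min_gc = 0.5, min_oe = 0.6,
                    source_pvalue = NA_real_, trace = FALSE) {
  idx <- as_index(seq)
  W <- region$end - region$start
  stopifnot(W >= 1)
  if (W < min_length) return(NULL)  # no window can satisfy the length bound
  if (!is.null(seed)) set.seed(as.integer(seed))
  swarm <- init_swarm(idx, region, params, min_length, min_gc, min_oe)
  tr <- if (trace) numeric(params$max_generations) else NULL
  for (g in seq_len(params$max_generations)) {
    swarm <- step_swarm(swarm, idx, region, params, move_i = g,
                        min_length = min_length, min_gc = min_gc,
                        min_oe = min_oe)
    if (trace) tr[g] <- swarm$gb_fit
  }
  if (!is.finite(swarm$gb_fit)) return(NULL)
  comp <- window_composition(idx, swarm$gb_Fs, swarm$gb_Fs + swarm$gb_Fl)
  call <- data.frame(
    sequence_id = if (!is.null(region$sequence_id)) region$sequence_id
                  else seq_id_of(seq),
    start = swarm$gb_Fs,
    end = swarm$gb_Fs + swarm$gb_Fl,
    length = swarm$gb_Fl,
    gc = gc_content(comp),
    oe = oe_ratio(comp),
    fitness = swarm$gb_fit,
    source_pvalue = source_pvalue,
    region_start = region$start,
    region_end = region$end,
    stringsAsFactors = FALSE
  )
  if (trace) attr(call, "trace") <- tr
  call
}
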