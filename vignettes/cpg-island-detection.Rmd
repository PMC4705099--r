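---
title: "Detecting CpG islands with distance clustering and a particle swarm"
author: "cpgswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CpG islands with distance clustering and a particle swarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgswarm)
```

## The problem

CpG islands are short genomic regions unusually rich in the CpG
dinucleotide. Because most CpGs in vertebrate genomes are methylated and
eroded to TpG over evolutionary time, the bulk genome is CpG-depleted
(observed/expected ratios near 0.2), while unmethylated promoter-associated
regions retain CpGs. The classical operational definition
(Gardiner-Garden–Frommer, "GGF") calls a region an island when it is at
least 200 bp long, has GC content of at least 50%, and has an
observed/expected (O/E) CpG ratio of at least 0.6, where

$$\mathrm{O/E} = \frac{\#\mathrm{CpG} \cdot L}{\#C \cdot \#G}$$

over a window of length $L$. Sliding-window scanners apply these thresholds
directly but are slow on chromosome-scale input and sensitive to window
bookkeeping; purely statistical CpG-cluster detectors are fast but return
many fragments far shorter than the GGF minimum. `cpgswarm` is a hybrid: a
statistical clustering stage proposes a small set of candidate loci, and a
stochastic optimizer then searches only those loci for the best
GGF-compliant island.

## Stage 1: distance clustering with a negative-binomial filter

All CpG positions of a sequence are collected 5'→3'; the gap between
adjacent CpGs at positions $X_i < X_{i+1}$ is $d_i = X_{i+1} - X_i - 1$
(minimum 1, as in `CGCG`). A distance threshold $d_t$ is taken as the
nearest-rank 65th percentile of the sequence's own gap distribution: gaps
strictly below $d_t$ join adjacent CpGs into one cluster, gaps at or above
it close the cluster at the G of the upstream CpG. Only clusters of
$N \ge 2$ CpGs are kept — a cluster is defined over an adjacent-CpG
distance, so singletons cannot form one.

The nearest-rank convention (the $k$-th smallest gap with
$k = \lceil \mathrm{pct}/100 \cdot n \rceil$) was chosen over interpolating
percentile estimators because it is exactly reproducible across platforms
and always yields an observed gap. The threshold is derived per input
sequence, not pooled across a multi-FASTA, since the gap distribution is a
property of each sequence's composition.

Each cluster is then scored against a background in which a CpG occurs
independently in each dinucleotide frame with probability
$p = N_s / N_{is}$, where $N_s$ counts CpG occurrences in the sequence and
$N_{is} = \lfloor L_{seq}/2 \rfloor$ counts non-overlapping dinucleotide
frames (an overlapping count, $L_{seq} - 1$, is available as a
configuration switch). Under this model the number of independent non-CpG
units inside a cluster with $N$ CpGs and length $L$, namely
$n_f = L - 2N$, is negative-binomially distributed, and the cluster's
p-value is the lower tail

$$P(X \le n_f) = \sum_{x=0}^{n_f} \binom{x+N-1}{N-1} p^N (1-p)^x .$$

A small p-value means the cluster is more compact than the background
predicts. Clusters with $p \le \alpha$ (default $\alpha = 0.01$) are
retained as island candidates. The retention direction deserves a note: the
filter keeps *significant* (low-p) clusters, which is the only direction
consistent with the statistic's meaning — the tail probability of a cluster
this compact arising from background — and with selecting candidates at
$P \le 0.01$. The p-value is evaluated with `stats::pnbinom`; the test
suite cross-checks it against an independent brute-force log-space
summation of the probability mass function to $10^{-10}$ over
$N \le 20$, $n_f \le 200$.

## Stage 2: swarm search inside flank-extended candidates

Significant clusters can be far shorter than a GGF island, so each is
extended by 200 bp on both sides (the GGF minimum length), clipped to the
sequence bounds. Inside each extended region an independent particle swarm
searches over integer pairs (island start $F_s$, island length $F_l$). The
fitness of a feasible window is

$$\mathrm{fitness} = \mathrm{GC} + \mathrm{O/E} + L/W,$$

where $W$ is the candidate-region width; windows violating any GGF
constraint (length $\ge 200$, GC $\ge 0.5$, O/E $\ge 0.6$) receive an
infeasible sentinel ordered below every real fitness. The normalized-length
denominator is the region width rather than a fixed constant so the length
reward is bounded by 1 and comparable across regions of different sizes.

Swarm mechanics follow the canonical formulation: 300 particles, 100
generations, velocity update
$v \leftarrow w v + c_1 r_1 (pbest - x) + c_2 r_2 (gbest - x)$ with
$c_1 = c_2 = 2$ and fresh $r_1, r_2 \sim U(0,1)$ per particle per
dimension, and inertia $w$ annealed linearly from 0.9 to 0.4 across
generations (global exploration first, local refinement last). Choices the
canonical formulation leaves open are fixed as follows:

* **Initialization**: $(F_s, F_l)$ uniform over all valid pairs in the
  region; velocities start at zero.
* **Velocity clamp**: $\pm W$ per dimension; unclamped velocities diverge
  on narrow regions.
* **Integer positions**: round-to-nearest after each update, then clamp
  $F_l$ into $[1, W]$ first and $F_s$ into
  $[\mathrm{start}, \mathrm{end} - F_l]$ second, so the window always stays
  inside the region.
* **Best tracking**: personal and global bests update on strict improvement
  only and only ever hold feasible states; a region in which no feasible
  window is ever visited yields no call. A particle with no feasible
  personal best yet feels no attraction on that term.
* **No early stopping**: exactly 100 generations, keeping runs
  deterministic per seed.
* **Reproducibility**: each region runs on a private random substream
  derived deterministically from (global seed, sequence id, candidate
  ordinal), so results are independent of scheduling and of record order in
  a multi-FASTA.

On regions up to 600 bp the swarm's global best reaches at least 99% of the
exhaustive-search optimum over all (start, length) pairs in at least 18 of
20 seeded runs (the acceptance script recomputes this rate).

## Merging nearby calls

Calls separated by fewer than 100 bp (overlaps included) are candidates for
merging; the merged span's GC and O/E are recomputed from the sequence and
the merge is rolled back if the union fails GGF. The sweep runs left to
right with a successful merge becoming the left operand of the next
comparison, which reaches the fixpoint of chains in one pass. Merging is
applied uniformly, whether or not the constituent calls came from the same
candidate region; `merge_gap = 0` disables it.

## The synthetic benchmark

Real chromosome-scale truth sets require external genome downloads, so the
package ships a generator whose output has the statistical structure the
detector assumes. Background and islands are first-order Markov chains over
A/C/G/T parameterized by a stationary GC fraction and a CpG O/E target: the
C→G transition is set to $\mathrm{oe} \cdot \pi_G$ and the remaining
transition mass is redistributed so the stationary distribution is exactly
$(\pi_A, \pi_C, \pi_G, \pi_T)$ with $\pi_C = \pi_G = \mathrm{gc}/2$. A
first-order chain is the minimal model that can decouple GC content from
CpG frequency — an i.i.d. sampler cannot, and both detector statistics
(the background probability $p$ and O/E) are dinucleotide-level.

Defaults emulate a mammalian-like contrast: 100 kb sequences, background
GC 0.40 with O/E 0.2 (strong CpG suppression), ten planted islands of
500–1500 bp with GC 0.60 and O/E 0.8, separated by at least 500 bp (twice
the flank plus the merge gap) so flank-extended candidates of distinct
truth islands cannot interact. Island/background junctions are hard
switches, keeping base-level truth semantics exact. Every realized island
segment is re-counted and must satisfy GGF, with bounded resampling on
failure. A manifest of generation parameters plus the seed regenerates any
benchmark bit-identically.

What the generator does *not* emulate: repeat elements (notably GC-rich Alu
elements that mimic islands), isochore-scale GC gradients, and methylation
structure. Passing the benchmark therefore demonstrates correct recovery of
islands under the detector's own statistical assumptions, not performance
on real assemblies.

## Evaluation

Predictions are scored base by base against a truth interval set over a
stated span: TP bases covered by both, FP by prediction only, FN by truth
only, TN by neither, computed with an interval sweep (never per-base
arrays). The five summary statistics are accuracy, sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, the performance coefficient
$TP/(TP+FP+FN)$ (Jaccard on bases; span-independent), and the 2×2
correlation coefficient (Matthews form). Cells that reduce to 0/0 are
reported as 0 with a warning rather than NaN so batch summaries stay
numeric. For pipeline self-evaluation the span is the full sequence length;
the standalone evaluator accepts an explicit span and flags it in the
output when inferred from the data.

## Validation problem sizes

The shipped test suite validates the p-value against brute-force summation
on the full $N \le 20$, $n_f \le 200$ grid at five background
probabilities; the cluster sweep against a naive repeated-merge oracle on
1000 random position sets; swarm optimality against exhaustive search on
twenty 600 bp regions; and the full pipeline on 100 kb benchmarks over five
seeds plus a pure-background run. These sizes exercise every code path at
full default swarm settings while keeping the suite fast.

## Known limitations

* **Boundary precision.** The fitness rewards window length (up to the
  region width) alongside GC and O/E, so wherever a window extended into
  flanking background still clears GC ≥ 0.5 and O/E ≥ 0.6 — which is the
  case for the benchmark's island-vs-background contrast, and analytically
  for any island much GC-richer than its surroundings — the *optimal*
  window, not an optimizer artifact, over-reaches the compositional
  boundary by up to the flank. Exhaustive search on small instances
  confirms the swarm is finding the true optimum there. On the default
  benchmark this costs specificity (the acceptance script measures mean
  base-level specificity near 0.96 against sensitivity near 0.99); callers
  needing tighter boundaries should lower the flank or raise the GC/O-E
  floors, at the cost of sensitivity to weak islands.
* Sequences with fewer than two CpGs yield no calls by construction.
* The distance threshold is a percentile of a bimodal gap distribution on
  island-rich input; extremely island-dense sequences push it upward,
  coarsening clusters. The percentile is exposed for such inputs.
* The negative-binomial background assumes a homogeneous CpG rate;
  isochore-aware backgrounds are out of scope.
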