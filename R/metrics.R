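# Base-level evaluation: per-nucleotide 2x2 contingency of predictions
# against a truth interval set, and the five standard summary statistics.

# Sort and coalesce overlapping/adjacent intervals; returns a data.frame
# with start/end.
normalize_intervals <- function(x) {
  if (is.null(x) || nrow(x) == 0L)
    return(data.frame(start = integer(), end = integer()))
  x <- x[order(x$start, x$end), , drop = FALSE]
  if (any(x$end <= x$start)) stop("intervals must satisfy start < end",
                                  call. = FALSE)
  start <- x$start; end <- x$end
  keep_s <- start[1]; keep_e <- end[1]
  os <- integer(0); oe <- integer(0)
  for (i in seq_len(nrow(x))[-1]) {
    if (start[i] <= keep_e) {
      keep_e <- max(keep_e, end[i])
    } else {
      os <- c(os, keep_s); oe <- c(oe, keep_e)
      keep_s <- start[i]; keep_e <- end[i]
    }
  }
  data.frame(start = c(os, keep_s), end = c(oe, keep_e))
}

# Total intersection length of two normalized interval sets (two-pointer
# sweep; never materializes per-base arrays).
intersect_length <- function(a, b) {
  i <- 1L; j <- 1L; tot <- 0
  na <- nrow(a); nb <- nrow(b)
  while (i <= na && j <= nb) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (hi > lo) tot <- tot + (hi - lo)
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  tot
}

#' Base-level contingency table
#'
#' Classifies every base of the evaluated span: TP = bases covered by both
#' truth and prediction, FP = prediction only, FN = truth only, TN =
#' neither. Computed by an interval sweep on the normalized (sorted,
#' coalesced) sets. Intervals are 0-based half-open.
#'
#' @param truth,pred Data frames with `start`, `end` columns (extra columns
#'   ignored), all within `[0, span_length)`.
#' @param span_length Length of the evaluated span in bases.
#' @return List of class `contingency` with `TP`, `FP`, `FN`, `TN`
#'   (summing to `span_length`).
#' @export
base_contingency <- function(truth, pred, span_length) {
  t_n <- normalize_intervals(truth)
  p_n <- normalize_intervals(pred)
  if ((nrow(t_n) && (min(t_n$start) < 0 || max(t_n$end) > span_length)) ||
      (nrow(p_n) && (min(p_n$start) < 0 || max(p_n$end) > span_length)))
    stop("intervals extend outside [0, span_length)", call. = FALSE)
  tp <- intersect_length(t_n, p_n)
  t_tot <- sum(t_n$end - t_n$start)
  p_tot <- sum(p_n$end - p_n$start)
  tab <- list(TP = tp, FP = p_tot - tp, FN = t_tot - tp,
              TN = span_length - t_tot - p_tot + tp)
  class(tab) <- "contingency"
  tab
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    if (num != 0) stop("inconsistent contingency table", call. = FALSE)
    warning(what, ": 0/0 reported as 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Five base-level performance statistics
#'
#' From a 2x2 base contingency table:
#' accuracy `ACC = (TP+TN)/(TP+FP+TN+FN)`, sensitivity `SN = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)`, performance coefficient
#' `PC = TP/(TP+FP+FN)` (Jaccard on bases, span-independent), and the 2x2
#' correlation coefficient (Matthews form)
#' `CC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.
#' Any 0/0 is reported as 0 with a warning so batch summaries never
#' propagate NaN.
#'
#' @param table A `contingency` list (or any list with `TP`, `FP`, `FN`,
#'   `TN`).
#' @return List with `acc`, `sn`, `sp`, `pc` (fractions in \[0, 1\]) and
#'   `cc` (in \[-1, 1\]).
#' @export
performance_metrics <- function(table) {
  tp <- as.double(table$TP); fp <- as.double(table$FP)
  fn <- as.double(table$FN); tn <- as.double(table$TN)
  if (min(tp, fp, fn, tn) < 0) stop("negative cell count", call. = FALSE)
  total <- tp + fp + fn + tn
  acc <- safe_ratio(tp + tn, total, "ACC")
  sn <- safe_ratio(tp, tp + fn, "SN")
  sp <- safe_ratio(tn, tn + fp, "SP")
  pc <- safe_ratio(tp, tp + fp + fn, "PC")
  den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  cc <- if (den == 0) {
    warning("CC: 0/0 reported as 0", call. = FALSE)
    0
  } else {
    (tp * tn - fp * fn) / den
  }
  list(acc = acc, sn = sn, sp = sp, pc = pc, cc = cc)
}

#' Evaluate predictions against a truth set
#'
#' Convenience wrapper building the base contingency table and the five
#' statistics in one call.
#'
#' @inheritParams base_contingency
#' @return List with elements `table` and `metrics`.
#' @export
evaluate_calls <- function(truth, pred, span_length) {
  tab <- base_contingency(truth, pred, span_length)
  list(table = tab, metrics = performance_metrics(tab))
}
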