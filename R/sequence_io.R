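# FASTA input, BED/TSV output. Coordinates are 0-based half-open throughout;
# the human-readable report additionally prints 1-based inclusive coordinates.

#' Read DNA sequences from a FASTA file
#'
#' Reads every entry of a FASTA file into a sequence record. Residues are
#' upcased and any character outside `A/C/G/T/N` (IUPAC ambiguity codes and
#' the like) is mapped to `N`; a single warning reports how many residues
#' were remapped. `N` residues never match a CpG and are excluded from
#' nucleotide counts downstream.
#'
#' @param path Path to a FASTA file.
#' @return A list of sequence records; each record is a list with elements
#'   `id` (first word of the header), `residues` (character scalar over
#'   `A/C/G/T/N`) and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), fa)
#' read_fasta(fa)[[1]]$residues
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L)
    stop("FASTA file contains no sequences: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  n_mapped <- 0L
  records <- lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    bad <- gregexpr("[^ACGTN]", s)[[1]]
    if (bad[1] != -1L) {
      n_mapped <<- n_mapped + length(bad)
      s <- gsub("[^ACGTN]", "N", s)
    }
    list(id = ids[i], residues = s, length = nchar(s))
  })
  if (n_mapped > 0L)
    warning(n_mapped, " ambiguous residue(s) mapped to N", call. = FALSE)
  names(records) <- ids
  records
}

#' Write sequence records to a FASTA file
#'
#' @param records List of sequence records (as from [read_fasta()]) or a
#'   single record.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (!is.null(records$residues)) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1),
                                         "residues"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write island calls as BED6
#'
#' One line per call: chrom, 0-based start, half-open end, name `CpGI_<k>`,
#' score `round(1000 * fitness / 4)` clamped to \[0, 1000\], strand ".".
#' The score mapping is a display convention (the maximum attainable fitness
#' of a homogeneous CpG repeat filling its region is 4); the exact fitness is
#' available in the TSV report.
#'
#' @param calls Data frame of island calls with columns `sequence_id`,
#'   `start`, `end`, `fitness` (as returned by [detect_islands()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write BED file: ", path, call. = FALSE)
    return(invisible(path))
  }
  score <- as.integer(pmin(1000, pmax(0, round(1000 * calls$fitness / 4))))
  bed <- data.frame(
    chrom  = calls$sequence_id,
    start  = as.integer(calls$start),
    end    = as.integer(calls$end),
    name   = paste0("CpGI_", seq_len(nrow(calls))),
    score  = score,
    strand = ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Reads the first three (or more) BED columns. Intended for truth or
#' prediction interval sets; coordinates stay 0-based half-open.
#'
#' @param path Path to a BED file (no header line).
#' @return Data frame with columns `sequence_id`, `start`, `end`, and, when
#'   present, `name`, `score`, `strand`. Zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED file needs >= 3 columns: ", path, call. = FALSE)
  out <- data.frame(sequence_id = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  extras <- c("name", "score", "strand")
  for (k in seq_len(min(ncol(tab) - 3L, 3L))) out[[extras[k]]] <- tab[[k + 3L]]
  out
}

#' Write a per-island TSV report with a summary block
#'
#' Emits one row per island (both 0-based half-open and 1-based inclusive
#' coordinates, length, GC%, O/E, fitness, and the p-value of the source
#' cluster), followed by `#`-prefixed summary lines: island count, total
#' island length, percent coverage of the sequence, average/min/max length,
#' and mean +/- SD of GC% and O/E. With a single island the SDs are reported
#' as 0; with no islands the summary reports count 0 and coverage 0.
#'
#' @param calls Data frame of island calls (columns `sequence_id`, `start`,
#'   `end`, `gc`, `oe`, `fitness`, `source_pvalue`).
#' @param path Output file path.
#' @param seq_length Length of the evaluated sequence in bases, used for the
#'   coverage percentage.
#' @return Invisibly, `path`.
#' @export
write_report <- function(calls, path, seq_length) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c("sequence_id", "start", "end", "start_1based", "end_1based",
              "length", "gc_pct", "oe", "fitness", "p_value")
  writeLines(paste(header, collapse = "\t"), con)
  n <- if (is.null(calls)) 0L else nrow(calls)
  if (n > 0L) {
    len <- calls$end - calls$start
    rows <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%.4f\t%.4f\t%.4f\t%.4g",
                    calls$sequence_id, calls$start, calls$end,
                    calls$start + 1L, calls$end, len,
                    100 * calls$gc, calls$oe, calls$fitness,
                    calls$source_pvalue)
    writeLines(rows, con)
  }
  total <- if (n > 0L) sum(calls$end - calls$start) else 0L
  coverage <- if (seq_length > 0) 100 * total / seq_length else 0
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  sm <- c(
    sprintf("# islands\t%d", n),
    sprintf("# total_length\t%d", total),
    sprintf("# coverage_pct\t%.4f", coverage),
    sprintf("# length_avg\t%.2f", if (n > 0L) mean(calls$end - calls$start) else 0),
    sprintf("# length_min\t%d", if (n > 0L) min(calls$end - calls$start) else 0L),
    sprintf("# length_max\t%d", if (n > 0L) max(calls$end - calls$start) else 0L),
    sprintf("# gc_pct_mean\t%.4f", if (n > 0L) mean(100 * calls$gc) else 0),
    sprintf("# gc_pct_sd\t%.4f", if (n > 0L) sd0(100 * calls$gc) else 0),
    sprintf("# oe_mean\t%.4f", if (n > 0L) mean(calls$oe) else 0),
    sprintf("# oe_sd\t%.4f", if (n > 0L) sd0(calls$oe) else 0)
  )
  writeLines(sm, con)
  invisible(path)
}
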