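#' Genomic intervals
#'
#' Light-weight BED-convention interval table: 0-based half-open
#' `[start, end)` coordinates with a chromosome label and free annotation
#' columns.  Interval overlap and merging are delegated to IRanges.
#'
#' @param chrom chromosome label(s), recycled.
#' @param start integer start (0-based, inclusive).
#' @param end integer end (exclusive); must satisfy `start < end`.
#' @param ... additional annotation columns (recycled).
#' @return a `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start >= end)) stop("intervals must satisfy start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

as_iranges <- function(x) {
  # internal: IRanges are 1-based closed; shift BED half-open accordingly
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Intersect two interval sets
#'
#' All pairs `(i, j)` such that `a[i, ]` and `b[j, ]` lie on the same
#' chromosome and overlap by at least 1 bp under half-open semantics.
#'
#' @param a,b interval tables ([genomic_intervals()] or data.frames with
#'   `chrom`, `start`, `end`).
#' @return a `data.frame` with columns `a_idx`, `b_idx` (row indices into
#'   the inputs).
#' @export
intervals_intersect <- function(a, b) {
  out <- data.frame(a_idx = integer(0), b_idx = integer(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges(a[ia, , drop = FALSE]),
                                  as_iranges(b[ib, , drop = FALSE]),
                                  minoverlap = 1L)
    out <- rbind(out, data.frame(a_idx = ia[S4Vectors::queryHits(hits)],
                                 b_idx = ib[S4Vectors::subjectHits(hits)]))
  }
  out[order(out$a_idx, out$b_idx), , drop = FALSE]
}

#' Merge overlapping intervals
#'
#' Collapses intervals that overlap by at least 1 bp into their union.
#' Bookended (touching) intervals are NOT merged: `[0,10)` and `[10,20)`
#' stay separate, matching the half-open overlap convention used for region
#' construction.
#'
#' @param x an interval table.
#' @return a [genomic_intervals()] table of merged intervals, sorted.
#' @export
intervals_merge <- function(x) {
  if (nrow(x) == 0)
    return(genomic_intervals(character(0), integer(0), integer(1))[0, ])
  pieces <- lapply(split(seq_len(nrow(x)), x$chrom), function(idx) {
    # min.gapwidth = 0 merges overlapping but not bookended ranges
    red <- IRanges::reduce(as_iranges(x[idx, , drop = FALSE]),
                           min.gapwidth = 0L)
    data.frame(chrom = x$chrom[idx[1]],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Read a BED-like TSV
#'
#' Reads `chrom`, `start`, `end` plus any extra columns; no header expected
#' unless the first line contains letters in the start column position.
#'
#' @param path file path.
#' @param col_names optional names for extra columns beyond the first three.
#' @return a [genomic_intervals()] table.
#' @export
read_bed <- function(path, col_names = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names) && ncol(tab) > 3)
    names(tab)[4:(3 + length(col_names))] <- col_names
  class(tab) <- c("genomic_intervals", "data.frame")
  tab
}

#' Write a BED-like TSV
#'
#' @param x an interval table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
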