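#' Genetic map
#'
#' A piecewise-linear genetic map given as anchor points (bp, cM).  Physical
#' positions between anchors are interpolated linearly; positions outside the
#' anchored range are clamped to the terminal anchor's cM value (chromosome
#' ends must still receive genetic positions for EHH integration; clamping is
#' reported via a message when it occurs).
#'
#' @param bp integer vector of anchor physical positions, strictly increasing.
#' @param cM numeric vector of anchor genetic positions, non-decreasing.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(bp, cM) {
  if (length(bp) != length(cM)) stop("bp and cM must have equal length")
  if (length(bp) < 2) stop("a genetic map needs at least 2 anchors")
  bp <- as.numeric(bp)
  cM <- as.numeric(cM)
  o <- order(bp)
  bp <- bp[o]; cM <- cM[o]
  if (any(diff(bp) <= 0)) stop("anchor bp positions must be strictly increasing")
  if (any(diff(cM) < 0)) stop("anchor cM values must be non-decreasing")
  structure(list(bp = bp, cM = cM), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d anchors, %s-%s bp, %.4f-%.4f cM\n",
              length(x$bp), format(min(x$bp), big.mark = ","),
              format(max(x$bp), big.mark = ","), min(x$cM), max(x$cM)))
  invisible(x)
}

#' Interpolate genetic positions
#'
#' Piecewise-linear interpolation of cM values at physical positions, with
#' clamping to the terminal anchors outside the mapped range (`rule = 2` of
#' [stats::approx()], the same interpolation the scan applies to fill
#' unmapped sites).
#'
#' @param map a [genetic_map()].
#' @param positions_bp sorted integer vector of query positions.
#' @return numeric vector of cM values, non-decreasing.
#' @export
interpolate_map <- function(map, positions_bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(positions_bp) == 0) return(numeric(0))
  if (is.unsorted(positions_bp)) stop("query positions must be sorted")
  n_out <- sum(positions_bp < min(map$bp) | positions_bp > max(map$bp))
  if (n_out > 0)
    message(sprintf("interpolate_map: %d position(s) outside the anchored range clamped to terminal cM", n_out))
  stats::approx(map$bp, map$cM, xout = positions_bp, method = "linear",
                rule = 2, ties = "ordered")$y
}

#' Read a genetic map file
#'
#' Reads an Oxford-style 3-column map (`position`, `rate`, `cM`, with a
#' header line) or a 2-column (`position`, `cM`) TSV/whitespace table.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= 3) {
    genetic_map(tab[[1]], tab[[3]])
  } else if (ncol(tab) == 2) {
    genetic_map(tab[[1]], tab[[2]])
  } else {
    stop("genetic map file must have 2 or 3 columns")
  }
}
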