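#' Sliding window grid
#'
#' Fixed-size sliding windows over a span: `[start + k*step, +size)` for
#' every `k` with the window end inside the span.  Defaults give 20-kb
#' windows with 20% overlap (16-kb step).
#'
#' @param span `c(start, end)` 0-based half-open bp span, or a one-row
#'   interval table.
#' @param size window size in bp.
#' @param step step between window starts in bp.
#' @param chrom chromosome label for the output.
#' @return a [genomic_intervals()] table (possibly empty).
#' @export
make_windows <- function(span, size = 20000, step = 16000, chrom = "X") {
  if (is.data.frame(span)) {
    chrom <- span$chrom[1]
    span <- c(span$start[1], span$end[1])
  }
  stopifnot(size > 0, step > 0)
  if (span[2] - span[1] < size)
    return(genomic_intervals("X", 0, 1)[0, ])
  starts <- seq(span[1], span[2] - size, by = step)
  genomic_intervals(chrom, starts, starts + size)
}

#' Window summaries of per-SNP scores
#'
#' Assigns scored SNPs to windows by half-open containment and computes
#' per-window means of the standardized statistics: mean absolute z for the
#' two-sided iHS and nSL, raw mean z for the one-sided iHH12.  Windows with
#' `min_snps` SNPs or fewer are removed.
#'
#' @param windows window table from [make_windows()].
#' @param scores standardized score table from [standardize_scores()].
#' @param min_snps windows with this many SNPs or fewer are dropped
#'   (default 20, i.e. at least 21 SNPs are required).
#' @param absolute named logical: take `|z|` before averaging, per
#'   statistic.
#' @return a `data.frame` with `chrom`, `start`, `end`, `snp_count` and
#'   `mean_ihs`, `mean_nsl`, `mean_ihh12`.
#' @export
summarize_windows <- function(windows, scores, min_snps = 20,
                              absolute = c(ihs = TRUE, nsl = TRUE,
                                           ihh12 = FALSE)) {
  pos0 <- scores$pos - 1L  # SNP bp to 0-based for half-open containment
  res <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- pos0 >= windows$start[i] & pos0 < windows$end[i]
    cnt <- sum(sel)
    one <- function(col, absval) {
      z <- scores[[col]][sel]
      z <- z[!is.na(z)]
      if (absval) z <- abs(z)
      if (length(z) == 0) NA_real_ else mean(z)
    }
    data.frame(chrom = windows$chrom[i], start = windows$start[i],
               end = windows$end[i], snp_count = cnt,
               mean_ihs = one("ihs_std", absolute[["ihs"]]),
               mean_nsl = one("nsl_std", absolute[["nsl"]]),
               mean_ihh12 = one("ihh12_std", absolute[["ihh12"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[out$snp_count > min_snps, , drop = FALSE]
}

#' Critical values from neutral simulations
#'
#' Linear-interpolation empirical quantiles (the default quantile estimator)
#' of simulated neutral window means, per statistic, at the 99th and 99.9th
#' percentiles used as evidence against neutrality.
#'
#' @param sim_windows window summary table of pooled neutral-simulation
#'   windows (from [summarize_windows()]).
#' @param quantiles probabilities of the critical values.
#' @param statistics window mean columns to calibrate.
#' @param min_windows warn when fewer simulated windows are available.
#' @return a `threshold_set`: list of per-statistic named quantile vectors,
#'   with replicate provenance attributes.
#' @export
neutral_thresholds <- function(sim_windows, quantiles = c(0.99, 0.999),
                               statistics = c("mean_ihs", "mean_nsl",
                                              "mean_ihh12"),
                               min_windows = 1000) {
  if (nrow(sim_windows) == 0) stop("no simulated windows supplied")
  if (nrow(sim_windows) < min_windows)
    warning(sprintf("only %d simulated windows; at least %d are recommended for stable tail quantiles",
                    nrow(sim_windows), min_windows))
  th <- lapply(statistics, function(st) {
    x <- sim_windows[[st]]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop(sprintf("no non-missing values for %s", st))
    stats::quantile(x, probs = quantiles, type = 7, names = FALSE)
  })
  names(th) <- statistics
  structure(list(thresholds = th, quantiles = quantiles,
                 n_windows = nrow(sim_windows)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set from %d neutral windows\n", x$n_windows))
  for (st in names(x$thresholds))
    cat(sprintf("  %s: %s\n", st,
                paste(sprintf("q%g=%.4f", x$quantiles * 100,
                              x$thresholds[[st]]), collapse = ", ")))
  invisible(x)
}

#' Call candidate windows
#'
#' Flags windows whose mean score strictly exceeds the neutral critical
#' values; a window exactly at the threshold is not a candidate.
#'
#' @param windows window summary table.
#' @param thresholds a `threshold_set` from [neutral_thresholds()].
#' @return `windows` with logical columns `<stat>_cand99` /
#'   `<stat>_cand999` per statistic.
#' @export
call_candidates <- function(windows, thresholds) {
  for (st in names(thresholds$thresholds)) {
    q <- thresholds$thresholds[[st]]
    short <- sub("^mean_", "", st)
    windows[[paste0(short, "_cand99")]] <-
      !is.na(windows[[st]]) & windows[[st]] > q[1]
    windows[[paste0(short, "_cand999")]] <-
      !is.na(windows[[st]]) & windows[[st]] > q[2]
  }
  windows
}

#' Sweep sharing across populations
#'
#' Builds per-population swept regions as the union of 99th-percentile
#' candidate windows over the three statistics (overlapping windows merged),
#' then groups regions that overlap by at least 1 bp across populations
#' into shared regions and classifies each as `unique` (one population),
#' `continental` (several populations from one continental group) or
#' `cross-continental`.
#'
#' @param candidates named list (one entry per population) of candidate
#'   window tables from [call_candidates()].
#' @param population_groups named character vector mapping population label
#'   to continental group.
#' @return list with `regions` (merged regions with populations, continents
#'   and category) and `proportions` (category shares, summing to 1).
#' @export
shared_sweeps <- function(candidates, population_groups) {
  pops <- names(candidates)
  if (length(pops) < 2) stop("sweep sharing needs at least 2 populations")
  unknown <- setdiff(pops, names(population_groups))
  if (length(unknown) > 0)
    stop(sprintf("unknown population label(s): %s",
                 paste(unknown, collapse = ", ")))
  cand_cols <- c("ihs_cand99", "nsl_cand99", "ihh12_cand99")
  per_pop <- lapply(pops, function(p) {
    w <- candidates[[p]]
    if (is.null(w) || nrow(w) == 0) return(NULL)
    hit <- Reduce(`|`, lapply(cand_cols, function(cc) w[[cc]]))
    if (sum(hit) == 0)
      return(NULL)
    intervals_merge(w[hit, c("chrom", "start", "end"), drop = FALSE])
  })
  names(per_pop) <- pops
  keep <- !vapply(per_pop, is.null, logical(1))
  per_pop <- per_pop[keep]
  if (length(per_pop) == 0)
    return(list(regions = NULL,
                proportions = c(unique = NA, continental = NA,
                                `cross-continental` = NA)))
  all_regs <- do.call(rbind, lapply(names(per_pop), function(p) {
    cbind(per_pop[[p]], population = p, stringsAsFactors = FALSE)
  }))
  # connected components of the >=1 bp overlap graph across populations
  merged <- intervals_merge(all_regs[, c("chrom", "start", "end")])
  ov <- intervals_intersect(merged, all_regs)
  regions <- lapply(seq_len(nrow(merged)), function(i) {
    hits <- ov$b_idx[ov$a_idx == i]
    ps <- sort(unique(all_regs$population[hits]))
    cont <- sort(unique(population_groups[ps]))
    cat <- if (length(ps) == 1) "unique" else if (length(cont) == 1)
      "continental" else "cross-continental"
    data.frame(chrom = merged$chrom[i], start = merged$start[i],
               end = merged$end[i],
               populations = paste(ps, collapse = ","),
               continents = paste(cont, collapse = ","),
               n_populations = length(ps), category = cat,
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, regions)
  tab <- table(factor(regions$category,
                      levels = c("unique", "continental",
                                 "cross-continental")))
  props <- as.vector(tab) / sum(tab)
  names(props) <- names(tab)
  list(regions = regions, proportions = props)
}
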