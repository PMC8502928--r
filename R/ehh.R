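#' Scan parameters
#'
#' Tunable parameters of the haplotype scan.  Defaults follow the scan's
#' standard settings: EHH truncation 0.05, maximum inter-SNP gap 20 kb
#' (a larger gap before truncation invalidates the core site), maximum
#' physical extension 1 Mb for the map-based statistics, maximum extension
#' 200 sites for nSL, MAF filter 5% (strict), and 100 equal-width derived
#' allele frequency bins for standardization.
#'
#' @param truncation EHH value at which curve extension stops; area beyond
#'   the crossing is excluded from the integral.
#' @param max_gap_bp maximum tolerated gap between adjacent SNPs before the
#'   core site is invalidated.
#' @param max_extend_bp maximum physical extension from the core (bp) for
#'   iHS/iHH12.
#' @param max_extend_sites maximum extension in segregating sites for nSL.
#' @param min_maf minor allele frequency filter (strict `>`).
#' @param n_bins number of equal-width DAF bins for standardization.
#' @return a named list of class `scan_params`.
#' @export
scan_params <- function(truncation = 0.05, max_gap_bp = 20000,
                        max_extend_bp = 1000000, max_extend_sites = 200,
                        min_maf = 0.05, n_bins = 100) {
  stopifnot(truncation >= 0, truncation < 1, max_gap_bp > 0,
            max_extend_bp > 0, max_extend_sites > 0,
            min_maf >= 0, min_maf < 0.5, n_bins >= 1)
  structure(list(truncation = truncation, max_gap_bp = max_gap_bp,
                 max_extend_bp = max_extend_bp,
                 max_extend_sites = max_extend_sites,
                 min_maf = min_maf, n_bins = n_bins),
            class = "scan_params")
}

# homozygosity of a class partition: sum_h C(n_h,2) / C(n,2)
ehh_from_counts <- function(counts, pooled = FALSE) {
  m <- sum(counts)
  if (m < 2) return(NA_real_)
  if (pooled && length(counts) >= 2) {
    o <- order(counts, decreasing = TRUE)
    top <- counts[o[1]] + counts[o[2]]
    rest <- counts[o[-(1:2)]]
    num <- top * (top - 1) + sum(rest * (rest - 1))
  } else {
    num <- sum(counts * (counts - 1))
  }
  num / (m * (m - 1))
}

#' EHH decay curve from a core site
#'
#' Extended haplotype homozygosity: the probability that two randomly chosen
#' carrier chromosomes are identical over the interval from the core out to
#' each offset.  Extension proceeds site by site outward and stops when EHH
#' falls below `truncation`, when the maximum extension is reached, when the
#' chromosome end is hit while EHH is still above truncation (curve flagged
#' `edge`), or when an inter-SNP gap exceeds `max_gap_bp` (flagged `gap`).
#'
#' @param hm a [haplotype_matrix()].
#' @param core core site column index.
#' @param carrier_set `"derived"`, `"ancestral"`, `"all"`, or `"pooled2"`
#'   (all haplotypes with the two most frequent haplotype classes pooled, the
#'   EHH12 variant).
#' @param direction `"right"` (increasing bp) or `"left"`.
#' @param distance `"cM"` (genetic map) or `"sites"` (one unit per site,
#'   the nSL convention).
#' @param params a [scan_params()].
#' @return list with `distances` (from core, starting at 0), `ehh`
#'   (starting at 1), `offsets` (site indices), and `status` (`"ok"`,
#'   `"gap"`, `"edge"`, or `"few_carriers"`).
#' @export
ehh_curve <- function(hm, core, carrier_set = c("derived", "ancestral",
                                                "all", "pooled2"),
                      direction = c("right", "left"),
                      distance = c("cM", "sites"),
                      params = scan_params()) {
  carrier_set <- match.arg(carrier_set)
  direction <- match.arg(direction)
  distance <- match.arg(distance)
  al <- hm$alleles
  n_snp <- ncol(al)
  core_al <- al[, core]
  carriers <- switch(carrier_set,
                     derived = which(core_al == 1L),
                     ancestral = which(core_al == 0L),
                     which(rep(TRUE, nrow(al))))
  pooled <- carrier_set == "pooled2"
  m <- length(carriers)
  if (m < 2)
    return(list(distances = numeric(0), ehh = numeric(0),
                offsets = integer(0), status = "few_carriers"))
  if (distance == "cM" && is.null(hm$positions_cM))
    stop("genetic positions required for cM distances; see attach_genetic_map()")

  step <- if (direction == "right") 1L else -1L
  max_ext <- if (distance == "sites") params$max_extend_sites else
    params$max_extend_bp
  split_by_core <- pooled || carrier_set == "all"

  walk <- ehh_walk_cpp(al, carriers, as.integer(core), step,
                       as.numeric(hm$positions_bp), params$truncation,
                       as.numeric(params$max_gap_bp), as.numeric(max_ext),
                       distance == "sites", pooled, split_by_core)
  offs <- walk$offsets
  dists <- if (distance == "sites") abs(offs - core) else
    abs(hm$positions_cM[offs] - hm$positions_cM[core])
  list(distances = dists, ehh = walk$ehh, offsets = offs,
       status = walk$status)
}

#' Integrated EHH
#'
#' Trapezoidal integral of an EHH decay curve against distance, for the two
#' directions summed.  The area below the truncation threshold is excluded:
#' when the curve crosses the threshold between two points, the last
#' trapezoid is cut at the interpolated crossing.
#'
#' @param curve_up,curve_down curves from [ehh_curve()] (either direction
#'   may be `NULL` to integrate one side only).
#' @param truncation EHH cutoff used when the curves were computed.
#' @return the integral (in the curve's distance units), or `NA` if either
#'   supplied curve failed (`gap`/`edge`/`few_carriers`).
#' @export
ihh <- function(curve_up, curve_down = NULL, truncation = 0.05) {
  one <- function(cv) {
    if (is.null(cv)) return(0)
    if (cv$status != "ok") return(NA_real_)
    d <- cv$distances
    e <- cv$ehh
    if (length(d) < 2) return(0)
    area <- 0
    for (i in 2:length(d)) {
      if (e[i] >= truncation) {
        area <- area + (e[i - 1] + e[i]) / 2 * (d[i] - d[i - 1])
      } else {
        dd <- if (e[i - 1] > e[i])
          (e[i - 1] - truncation) / (e[i - 1] - e[i]) * (d[i] - d[i - 1])
        else 0
        area <- area + (e[i - 1] + truncation) / 2 * dd
        break
      }
    }
    area
  }
  a <- one(curve_up)
  b <- one(curve_down)
  a + b
}

ihh_for_carriers <- function(hm, core, carrier_set, distance, params) {
  up <- ehh_curve(hm, core, carrier_set, "right", distance, params)
  dn <- ehh_curve(hm, core, carrier_set, "left", distance, params)
  if (up$status != "ok" || dn$status != "ok") {
    reason <- c(up$status, dn$status)
    reason <- reason[reason != "ok"][1]
    return(list(value = NA_real_, reason = reason))
  }
  list(value = ihh(up, dn, params$truncation), reason = "none")
}

#' Unstandardized iHS
#'
#' Log-ratio of integrated EHH for the ancestral versus derived carrier
#' classes at a core SNP, `ln(iHH_A / iHH_D)`, with distance measured in cM.
#' Unusually long derived haplotypes give negative values.  Missing (with a
#' reason) when either allele class has fewer than two carriers, when an
#' EHH curve hits a gap or the chromosome edge before truncation, or when
#' either integral is zero.
#'
#' @param hm a [haplotype_matrix()] with genetic positions attached.
#' @param core core site column index.
#' @param params a [scan_params()].
#' @return list with `value` and `reason` (`"none"` when scored).
#' @export
ihs_unstd <- function(hm, core, params = scan_params()) {
  log_ihh_ratio(hm, core, "cM", params)
}

#' Unstandardized nSL
#'
#' As [ihs_unstd()] but with distance measured in segregating sites (one
#' unit per site), making the statistic independent of the genetic map; a
#' maximum extension in number of sites applies.
#'
#' @inheritParams ihs_unstd
#' @return list with `value` and `reason`.
#' @export
nsl_unstd <- function(hm, core, params = scan_params()) {
  log_ihh_ratio(hm, core, "sites", params)
}

log_ihh_ratio <- function(hm, core, distance, params) {
  anc <- ihh_for_carriers(hm, core, "ancestral", distance, params)
  der <- ihh_for_carriers(hm, core, "derived", distance, params)
  if (is.na(anc$value) || is.na(der$value)) {
    reason <- c(anc$reason, der$reason)
    reason <- reason[reason != "none"][1]
    return(list(value = NA_real_, reason = reason))
  }
  if (anc$value == 0 || der$value == 0)
    return(list(value = NA_real_, reason = "zero_ihh"))
  list(value = log(anc$value / der$value), reason = "none")
}

#' Unstandardized iHH12
#'
#' Integrated EHH12 at a core SNP: all haplotypes form the carrier set and
#' at each offset the two most frequent haplotype classes are pooled,
#' `EHH12 = [C(n1+n2,2) + sum_{h>=3} C(n_h,2)] / C(n,2)`, integrated against
#' genetic distance in both directions.  Sensitive to both hard and soft
#' sweeps.
#'
#' @inheritParams ihs_unstd
#' @return list with `value` and `reason`.
#' @export
ihh12_unstd <- function(hm, core, params = scan_params()) {
  res <- ihh_for_carriers(hm, core, "pooled2", "cM", params)
  res
}

#' Per-SNP score table
#'
#' Computes unstandardized iHS, nSL and iHH12 (plus derived allele
#' frequency and failure reasons) at every polymorphic site of a haplotype
#' matrix.  Apply [maf_filter()] first; monomorphic sites are scored as
#' missing with reason `low-maf`.
#'
#' @param hm a [haplotype_matrix()] with genetic positions (see
#'   [attach_genetic_map()]; simulated data carry a uniform map).
#' @param params a [scan_params()].
#' @return a `data.frame` with one row per SNP: `chrom`, `pos`, `id`,
#'   `daf`, `ihs_unstd`, `nsl_unstd`, `ihh12_unstd` and per-statistic
#'   failure reasons.
#' @export
site_scores <- function(hm, params = scan_params()) {
  n <- n_snps(hm)
  daf <- derived_freq(hm)
  out <- data.frame(chrom = rep(hm$chrom, n), pos = hm$positions_bp,
                    id = hm$snp_ids, daf = daf,
                    ihs_unstd = NA_real_, nsl_unstd = NA_real_,
                    ihh12_unstd = NA_real_,
                    ihs_reason = "low-maf", nsl_reason = "low-maf",
                    ihh12_reason = "low-maf",
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    if (daf[j] <= 0 || daf[j] >= 1) next
    r1 <- ihs_unstd(hm, j, params)
    r2 <- nsl_unstd(hm, j, params)
    r3 <- ihh12_unstd(hm, j, params)
    out$ihs_unstd[j] <- r1$value; out$ihs_reason[j] <- r1$reason
    out$nsl_unstd[j] <- r2$value; out$nsl_reason[j] <- r2$reason
    out$ihh12_unstd[j] <- r3$value; out$ihh12_reason[j] <- r3$reason
  }
  out
}

#' Standardize scores within derived-allele-frequency bins
#'
#' Z-scores each statistic within equal-width DAF bins so that scores are
#' comparable across frequencies: within each occupied bin,
#' `z = (x - bin mean) / bin SD` with the population (denominator-n)
#' variance.  Bins holding fewer than two non-missing values are set
#' missing.
#'
#' @param scores a score table from [site_scores()].
#' @param n_bins number of equal-width bins on (0, 1).
#' @param statistics columns to standardize (unstandardized score names).
#' @param reference optional score table whose bin means/SDs are used
#'   instead of those of `scores` itself — e.g. a pooled neutral or
#'   genome-wide table, so that a locus enriched in extreme scores does not
#'   deflate its own z-scores.
#' @return `scores` with added `*_std` columns.
#' @export
standardize_scores <- function(scores,
                               n_bins = 100,
                               statistics = c("ihs_unstd", "nsl_unstd",
                                              "ihh12_unstd"),
                               reference = NULL) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores$daf, breaks, include.lowest = TRUE, labels = FALSE)
  ref <- if (is.null(reference)) scores else reference
  ref_bin <- cut(ref$daf, breaks, include.lowest = TRUE, labels = FALSE)
  for (st in statistics) {
    x <- scores[[st]]
    xr <- ref[[st]]
    z <- rep(NA_real_, length(x))
    for (b in unique(bin[!is.na(bin)])) {
      sel <- which(bin == b & !is.na(x))
      if (length(sel) == 0) next
      rsel <- which(ref_bin == b & !is.na(xr))
      if (length(rsel) < 2) next
      mu <- mean(xr[rsel])
      sd_pop <- sqrt(mean((xr[rsel] - mu)^2))
      if (sd_pop == 0) next
      z[sel] <- (x[sel] - mu) / sd_pop
    }
    scores[[sub("_unstd$", "_std", st)]] <- z
  }
  scores
}

#' Windowed Tajima's D
#'
#' Computes Tajima's D in non-overlapping windows (default 10 kb): the
#' difference between mean pairwise diversity and Watterson's estimator,
#' scaled by its standard deviation under the standard neutral model.
#' Windows with no segregating sites have undefined D.
#'
#' @param hm a [haplotype_matrix()].
#' @param window_size window size in bp.
#' @param span optional `c(start, end)` 0-based half-open span to tile
#'   (defaults to the range of the data, floored to the window grid).
#' @return a `data.frame` with `chrom`, `start`, `end`, `S`, `pi`, `D`.
#' @export
tajimas_d <- function(hm, window_size = 10000, span = NULL) {
  n <- n_haplotypes(hm)
  if (n < 4) stop("Tajima's D needs at least 4 haplotypes")
  if (is.null(span)) {
    lo <- floor(min(hm$positions_bp) / window_size) * window_size
    hi <- max(hm$positions_bp) + 1
    span <- c(lo, hi)
  }
  starts <- seq(span[1], span[2] - 1, by = window_size)
  # constants of the D variance (standard neutral-model coefficients)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  dc <- colSums(hm$alleles)
  pos0 <- hm$positions_bp - 1L  # 0-based for half-open windows
  res <- lapply(starts, function(s) {
    in_w <- pos0 >= s & pos0 < s + window_size
    cnt <- dc[in_w]
    cnt <- cnt[cnt > 0 & cnt < n]
    S <- length(cnt)
    pi <- sum(cnt * (n - cnt)) / choose(n, 2)
    D <- if (S == 0) NA_real_ else
      (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
    data.frame(chrom = hm$chrom, start = s, end = s + window_size,
               S = S, pi = pi, D = D, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
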