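event_type_codes <- c(join = 1L, size = 2L, growth = 3L, migration = 4L)

#' Simulate neutral haplotypes under a demographic model
#'
#' Runs the structured coalescent with recombination (compiled engine) under
#' an ms-parameterized [demographic_model()] and returns a batch of
#' replicate haplotype matrices.  Mutations follow the infinite-sites model
#' on a continuous locus; positions are mapped to integer bp on `[1, L]`
#' (rare bp collisions keep the first mutation) and genetic positions are
#' assigned from the model's uniform recombination rate
#' (`cM = bp * rec * 100`).  The result is a deterministic function of
#' `(model, n_reps, seed)`.
#'
#' @param model a [demographic_model()].
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return a `sim_batch`: list with `replicates` (list of
#'   [haplotype_matrix()]), `seed` and `model`.
#' @export
simulate_neutral <- function(model, n_reps, seed) {
  stopifnot(inherits(model, "demographic_model"), n_reps >= 1)
  set.seed(as.integer(seed))
  ev <- model$events
  ev_df <- data.frame(time = as.numeric(ev$time),
                      type = event_type_codes[ev$type],
                      i = as.integer(ev$i),
                      j = as.integer(pmax(ev$j, 1L)),
                      x = as.numeric(ev$x))
  raw <- sim_coalescent_cpp(model$sample_sizes, model$theta, model$rho,
                            model$pop_sizes, model$growth,
                            model$migration, ev_df, as.integer(n_reps))
  labels <- rep(model$deme_names, model$sample_sizes)
  reps <- lapply(raw, function(r) {
    pos <- r$positions
    geno <- r$genotypes
    if (length(pos) == 0) {
      # degenerate: no mutations; keep a 0-column matrix
      return(haplotype_matrix(matrix(0L, length(labels), 2)[, 0, drop = FALSE],
                              integer(0), numeric(0), character(0),
                              labels, "sim"))
    }
    bp <- floor(pos * model$L) + 1L
    keep <- !duplicated(bp)
    bp <- bp[keep]
    geno <- geno[, keep, drop = FALSE]
    haplotype_matrix(geno, bp, positions_cM = bp * model$rec * 100,
                     population_labels = labels, chrom = "sim")
  })
  structure(list(replicates = reps, seed = as.integer(seed), model = model),
            class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  S <- vapply(x$replicates, function(h) ncol(h$alleles), integer(1))
  cat(sprintf("sim_batch: %d replicate(s) of %s bp, seed %d\n",
              length(x$replicates), format(x$model$L, big.mark = ","),
              x$seed))
  cat(sprintf("  segregating sites: mean %.1f (range %d-%d)\n",
              mean(S), min(S), max(S)))
  invisible(x)
}

#' Unfolded site frequency spectrum
#'
#' Counts of segregating sites by derived-allele count (classes 1 to
#' n-1) within a deme or over all haplotypes.  Sites monomorphic in the
#' selected haplotypes do not contribute.
#'
#' @param x a [haplotype_matrix()] or `sim_batch` (replicates pooled).
#' @param deme optional population label(s) to restrict to.
#' @return integer vector of length `n - 1`, named by derived-allele count.
#' @export
sfs <- function(x, deme = NULL) {
  if (inherits(x, "sim_batch")) {
    specs <- lapply(x$replicates, sfs, deme = deme)
    out <- Reduce(`+`, specs)
    return(out)
  }
  stopifnot(inherits(x, "haplotype_matrix"))
  hm <- if (is.null(deme)) x else subset_haplotypes(x, haplotypes = deme)
  n <- n_haplotypes(hm)
  counts <- colSums(hm$alleles)
  counts <- counts[counts > 0 & counts < n]
  out <- tabulate(counts, nbins = n - 1)
  names(out) <- seq_len(n - 1)
  out
}

#' Inject a sweep-like haplotype structure
#'
#' Copies one donor haplotype's alleles within `span_bp` of a core position
#' onto randomly chosen recipient haplotypes until the core's derived allele
#' frequency equals `round(target_freq * n) / n`.  This is a deterministic
#' haplotype-copy device for power testing: it creates the extended
#' haplotype homozygosity structure of an incomplete sweep without
#' simulating selection.  Outside the span recipients are untouched.
#'
#' @param hm a [haplotype_matrix()].
#' @param core_pos target core position in bp (the nearest polymorphic site
#'   is used).
#' @param target_freq desired derived allele frequency at the core, in
#'   (0, 1).
#' @param span_bp half-width of the copied region around the core
#'   (clipped to the locus with a warning if it extends beyond).
#' @param seed integer seed for recipient sampling.
#' @return list with `hm` (modified matrix), `core` (site index) and
#'   `carriers` (row indices of the swept haplotypes).
#' @export
inject_sweep <- function(hm, core_pos, target_freq, span_bp, seed) {
  stopifnot(target_freq > 0, target_freq < 1)
  set.seed(as.integer(seed))
  n <- n_haplotypes(hm)
  bp <- hm$positions_bp
  target <- round(target_freq * n)
  if (target < 1) target <- 1L
  cs <- colSums(hm$alleles)
  # candidate cores: polymorphic sites whose derived count does not already
  # exceed the target (the sweep only raises the core frequency)
  poly <- which(cs > 0 & cs <= target)
  if (length(poly) == 0)
    stop("no polymorphic site with frequency at or below target_freq")
  core <- poly[which.min(abs(bp[poly] - core_pos))]
  lo <- bp[core] - span_bp
  hi <- bp[core] + span_bp
  if (lo < min(bp) || hi > max(bp)) {
    warning("sweep span extends beyond the locus; clipped")
    lo <- max(lo, min(bp)); hi <- min(hi, max(bp))
  }
  cols <- which(bp >= lo & bp <= hi)
  carriers <- which(hm$alleles[, core] == 1L)
  donor <- carriers[sample.int(length(carriers), 1)]
  need <- target - length(carriers)
  recipients <- integer(0)
  if (need > 0) {
    non_carriers <- setdiff(seq_len(n), carriers)
    recipients <- sample(non_carriers, need)
    hm$alleles[recipients, cols] <-
      matrix(hm$alleles[donor, cols], nrow = need, ncol = length(cols),
             byrow = TRUE)
  }
  # carriers other than the donor also receive the donor haplotype over the
  # span so the swept class is a single extended haplotype
  others <- setdiff(carriers, donor)
  if (length(others) > 0) {
    hm$alleles[others, cols] <-
      matrix(hm$alleles[donor, cols], nrow = length(others),
             ncol = length(cols), byrow = TRUE)
  }
  list(hm = hm, core = core, carriers = sort(c(carriers, recipients)))
}

#' Export a simulation batch in ms format
#'
#' Writes the standard ms text layout: a command-style header, then per
#' replicate `//`, `segsites:`, `positions:` (fractions of the locus) and
#' one 0/1 string per haplotype.
#'
#' @param batch a `sim_batch` from [simulate_neutral()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ms <- function(batch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- batch$model
  writeLines(sprintf("sweepscan %d %d -t %.6f -r %.6f %d",
                     sum(m$sample_sizes), length(batch$replicates),
                     m$theta, m$rho, m$L), con)
  writeLines(as.character(batch$seed), con)
  for (hm in batch$replicates) {
    writeLines("", con)
    writeLines("//", con)
    S <- ncol(hm$alleles)
    writeLines(sprintf("segsites: %d", S), con)
    writeLines(paste("positions:",
                     paste(sprintf("%.8f", hm$positions_bp / m$L),
                           collapse = " ")), con)
    apply(hm$alleles, 1, function(row)
      writeLines(paste(row, collapse = ""), con))
  }
  invisible(path)
}
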