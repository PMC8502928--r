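#' Haplotype matrix
#'
#' Container for phased binary haplotypes: a matrix of 0/1 alleles
#' (0 = ancestral, 1 = derived) with one row per haploid chromosome and one
#' column per SNP, plus physical (bp) and genetic (cM) positions and a
#' population label per haplotype.  This is the substrate of every haplotype
#' statistic in the package.
#'
#' @param alleles integer/numeric matrix of 0/1, n_hap x n_snp.
#' @param positions_bp integer vector of physical positions, strictly
#'   increasing.
#' @param positions_cM numeric vector of genetic positions, non-decreasing;
#'   may be `NULL` if no genetic map is attached yet.
#' @param snp_ids character vector of SNP identifiers (defaults to
#'   `pos<bp>`).
#' @param population_labels character vector, one label per haplotype row.
#' @param chrom chromosome name (single string).
#'
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions_bp, positions_cM = NULL,
                             snp_ids = NULL, population_labels = NULL,
                             chrom = "X") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_hap <- nrow(alleles)
  n_snp <- ncol(alleles)
  if (n_hap < 2) stop("haplotype_matrix needs at least 2 haplotypes")
  if (length(positions_bp) != n_snp)
    stop("positions_bp length must equal the number of SNP columns")
  if (anyNA(alleles)) stop("missing alleles are not allowed")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be coded 0/1")
  positions_bp <- as.integer(positions_bp)
  if (n_snp > 1 && any(diff(positions_bp) <= 0))
    stop("positions_bp must be strictly increasing")
  if (!is.null(positions_cM)) {
    if (length(positions_cM) != n_snp)
      stop("positions_cM length must equal the number of SNP columns")
    if (n_snp > 1 && any(diff(positions_cM) < 0))
      stop("positions_cM must be non-decreasing")
  }
  if (is.null(snp_ids)) snp_ids <- paste0("pos", positions_bp)
  if (is.null(population_labels)) population_labels <- rep("pop1", n_hap)
  if (length(population_labels) != n_hap)
    stop("population_labels length must equal the number of haplotype rows")
  structure(
    list(alleles = alleles,
         positions_bp = positions_bp,
         positions_cM = positions_cM,
         snp_ids = as.character(snp_ids),
         population_labels = as.character(population_labels),
         chrom = as.character(chrom)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes x %d SNPs on %s\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom))
  if (ncol(x$alleles) > 0)
    cat(sprintf("  span: %s-%s bp%s\n",
                format(min(x$positions_bp), big.mark = ","),
                format(max(x$positions_bp), big.mark = ","),
                if (is.null(x$positions_cM)) " (no genetic map)" else
                  sprintf(" (%.4f-%.4f cM)", min(x$positions_cM),
                          max(x$positions_cM))))
  tb <- table(x$population_labels)
  cat("  populations:", paste(sprintf("%s (%d)", names(tb), tb),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Number of haplotypes / SNPs
#' @param hm a [haplotype_matrix()].
#' @return integer count.
#' @export
n_haplotypes <- function(hm) nrow(hm$alleles)

#' @rdname n_haplotypes
#' @export
n_snps <- function(hm) ncol(hm$alleles)

#' Subset a haplotype matrix
#'
#' Select haplotype rows (e.g. a single population) and/or SNP columns.
#' Column subsetting preserves position order; monomorphic columns are kept
#' unless `drop_monomorphic = TRUE`.
#'
#' @param hm a [haplotype_matrix()].
#' @param haplotypes row selector: indices, logical mask, or a character
#'   vector of population labels.
#' @param sites column selector (indices or logical mask), or `NULL` for all.
#' @param drop_monomorphic drop columns with a single observed allele after
#'   row subsetting.
#' @return a [haplotype_matrix()].
#' @export
subset_haplotypes <- function(hm, haplotypes = NULL, sites = NULL,
                              drop_monomorphic = FALSE) {
  rows <- seq_len(nrow(hm$alleles))
  if (!is.null(haplotypes)) {
    if (is.character(haplotypes)) {
      rows <- which(hm$population_labels %in% haplotypes)
    } else {
      rows <- rows[haplotypes]
    }
  }
  cols <- seq_len(ncol(hm$alleles))
  if (!is.null(sites)) cols <- cols[sites]
  al <- hm$alleles[rows, cols, drop = FALSE]
  if (drop_monomorphic && ncol(al) > 0) {
    cs <- colSums(al)
    keep <- cs > 0 & cs < nrow(al)
    cols <- cols[keep]
    al <- al[, keep, drop = FALSE]
  }
  haplotype_matrix(al, hm$positions_bp[cols],
                   if (is.null(hm$positions_cM)) NULL else hm$positions_cM[cols],
                   hm$snp_ids[cols], hm$population_labels[rows], hm$chrom)
}

#' Derived allele frequencies
#' @param hm a [haplotype_matrix()].
#' @return numeric vector of per-SNP derived allele frequencies.
#' @export
derived_freq <- function(hm) colMeans(hm$alleles)

#' Minor allele frequency filter
#'
#' Retains SNP columns whose minor allele frequency strictly exceeds
#' `min_maf`; the haplotype rows are unchanged.  A strict inequality is used,
#' so with `min_maf = 0.05` a site at exactly 5% MAF is dropped.
#'
#' @param hm a [haplotype_matrix()].
#' @param min_maf minimum minor allele frequency in `[0, 0.5)`.
#' @return a filtered [haplotype_matrix()].
#' @export
maf_filter <- function(hm, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf < 0.5)
  p <- derived_freq(hm)
  keep <- pmin(p, 1 - p) > min_maf
  subset_haplotypes(hm, sites = keep)
}

#' Attach genetic positions from a map
#'
#' @param hm a [haplotype_matrix()].
#' @param map a [genetic_map()].
#' @return `hm` with `positions_cM` filled by interpolation.
#' @export
attach_genetic_map <- function(hm, map) {
  hm$positions_cM <- interpolate_map(map, hm$positions_bp)
  hm
}
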