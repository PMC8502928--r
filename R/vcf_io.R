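#' Read an ancestral-allele table
#'
#' Two-column TSV mapping a SNP key to its ancestral allele.  Keys may be
#' variant IDs or `chrom:pos` strings (1-based position); alleles must be
#' A/C/G/T (case-insensitive).
#'
#' @param path file path.
#' @return named character vector: `key -> ancestral allele`.
#' @export
read_ancestral_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("ancestral table must have 2 columns: key, allele")
  al <- toupper(trimws(tab[[2]]))
  if (!all(al %in% c("A", "C", "G", "T")))
    stop("ancestral alleles must be A/C/G/T")
  stats::setNames(al, as.character(tab[[1]]))
}

#' Read phased genotypes from a VCF
#'
#' Reads a phased VCF (haploid and/or diploid-phased samples), restricts to
#' biallelic SNPs inside `region`, polarizes alleles against an ancestral
#' allele table (ancestral = 0, derived = 1), and expands samples to
#' haplotypes (two per diploid-phased sample, one per haploid sample, e.g.
#' male X chromosomes).
#'
#' Sites are dropped (with a reported count) when they are absent from the
#' ancestral table or when the ancestral allele matches neither REF nor ALT;
#' duplicated positions keep the first record.  Any unphased diploid
#' genotype is a hard error naming the site.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param ancestral named character vector from [read_ancestral_table()]
#'   (names are variant IDs or `chrom:pos`).
#' @param region optional length-2 numeric `c(start, end)` or a one-row
#'   interval table; 0-based half-open bp bounds (e.g. the X nPAR
#'   `c(2.7e6, 155e6)`).
#' @param populations optional named character vector mapping sample name to
#'   population label.
#' @return a [haplotype_matrix()].
#' @export
read_phased_vcf <- function(path, ancestral, region = NULL,
                            populations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])

  keep <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_not_snp <- sum(!keep)
  if (n_not_snp > 0)
    message(sprintf("read_phased_vcf: dropped %d non-biallelic/non-SNP record(s)", n_not_snp))

  if (!is.null(region)) {
    if (is.data.frame(region)) region <- c(region$start[1], region$end[1])
    pos0 <- pos - 1L  # to 0-based
    in_reg <- pos0 >= region[1] & pos0 < region[2]
    n_out <- sum(keep & !in_reg)
    if (n_out > 0)
      message(sprintf("read_phased_vcf: dropped %d site(s) outside region [%s, %s)",
                      n_out, format(region[1], big.mark = ","),
                      format(region[2], big.mark = ",")))
    keep <- keep & in_reg
  }

  # ancestral lookup by ID, then by chrom:pos
  key_pos <- paste0(chrom, ":", pos)
  anc <- ancestral[id]
  miss <- is.na(anc)
  anc[miss] <- ancestral[key_pos[miss]]
  unknown <- is.na(anc)
  n_unknown <- sum(keep & unknown)
  if (n_unknown > 0)
    message(sprintf("read_phased_vcf: dropped %d site(s) with unknown ancestral state", n_unknown))
  keep <- keep & !unknown

  mismatch <- !unknown & anc != ref & anc != alt
  n_mismatch <- sum(keep & mismatch)
  if (n_mismatch > 0)
    message(sprintf("read_phased_vcf: dropped %d site(s) whose ancestral allele matches neither REF nor ALT", n_mismatch))
  keep <- keep & !mismatch

  # duplicated positions: keep the first
  dup <- duplicated(pos) & keep
  if (any(dup)) {
    warning(sprintf("read_phased_vcf: dropped %d duplicate-position site(s), keeping the first", sum(dup)))
    keep <- keep & !dup
  }

  idx <- which(keep)
  if (length(idx) == 0) stop("no sites retained from VCF")
  idx <- idx[order(pos[idx])]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[idx, , drop = FALSE]
  samples <- colnames(gt)

  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at site %s (sample %s)",
                 key_pos[idx[bad[1]]], samples[bad[2]]))
  }
  if (anyNA(gt) || any(gt %in% c(".", ".|.")))
    stop("missing genotypes are not supported")

  # expand samples to haplotypes
  hap_cols <- list()
  hap_labels <- character(0)
  for (s in samples) {
    g <- gt[, s]
    parts <- strsplit(g, "|", fixed = TRUE)
    plo <- lengths(parts)
    if (!all(plo == plo[1]))
      stop(sprintf("sample %s mixes ploidies across sites", s))
    lab <- if (!is.null(populations) && s %in% names(populations))
      populations[[s]] else "pop1"
    for (k in seq_len(plo[1])) {
      hap_cols[[length(hap_cols) + 1L]] <-
        as.integer(vapply(parts, `[`, character(1), k))
      hap_labels <- c(hap_labels, lab)
    }
  }
  allele_idx <- do.call(cbind, hap_cols)  # n_snp x n_hap of 0/1 (REF/ALT)
  if (anyNA(allele_idx) || !all(allele_idx %in% c(0L, 1L)))
    stop("genotypes must be biallelic 0/1 after filtering")

  # polarize: ancestral allele -> 0
  flip <- anc[idx] == alt[idx]
  allele_idx[flip, ] <- 1L - allele_idx[flip, ]

  haplotype_matrix(t(allele_idx), pos[idx], snp_ids = ifelse(
    id[idx] == "." | is.na(id[idx]), key_pos[idx], id[idx]),
    population_labels = hap_labels, chrom = chrom[idx[1]])
}

#' Write a haplotype matrix as a phased VCF
#'
#' Exports derived/ancestral coded haplotypes as a minimal phased VCF with
#' ancestral alleles as REF (placeholder A) and derived as ALT (placeholder
#' T).  Haplotypes are paired into diploid-phased pseudo-samples when
#' `diploid = TRUE` (requires an even haplotype count), otherwise written as
#' haploid samples.
#'
#' @param hm a [haplotype_matrix()].
#' @param path output path.
#' @param diploid pair consecutive haplotypes into diploid samples.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hm, path, diploid = FALSE) {
  n <- n_haplotypes(hm)
  al <- hm$alleles
  if (diploid) {
    if (n %% 2 != 0) stop("diploid export needs an even number of haplotypes")
    gt <- matrix(paste(al[seq(1, n, 2), , drop = FALSE],
                       al[seq(2, n, 2), , drop = FALSE], sep = "|"),
                 nrow = n / 2)
    samples <- paste0("S", seq_len(n / 2))
  } else {
    gt <- al
    samples <- paste0("H", seq_len(n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", hm$chrom),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(hm$chrom, hm$positions_bp, hm$snp_ids, "A", "T", ".", "PASS",
                "AA=A", "GT", t(gt))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
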