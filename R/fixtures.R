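#' Synthetic annotation fixtures with planted enrichment
#'
#' Generates the toy annotation tables consumed by the downstream
#' enrichment analyses — a gene table, an X-inactivation status table, a
#' cell-type-specific enhancer table and a per-SNP score/deleteriousness
#' table — with a known planted ground truth: escape genes are selected
#' with a configurable odds ratio `omega` relative to inactive genes, and a
#' configurable set of SNPs passes both prioritization filters.  The result
#' is a deterministic function of `(config, seed)`.
#'
#' @param n_escape,n_variable,n_inactive gene counts per XCI status
#'   (defaults 59 escape / 381 inactive, the strongly supported X-linked
#'   universe).
#' @param p_selected baseline probability that an inactive gene is targeted
#'   by selection.
#' @param omega planted odds ratio of selection for escape vs inactive
#'   genes (1 = null).
#' @param span chromosome span `c(start, end)` in bp (0-based half-open;
#'   default the X nPAR).
#' @param gene_length gene span in bp.
#' @param n_enhancers number of base enhancers (each expands into 1-3
#'   cell-line-specific records).
#' @param n_snps rows of the per-SNP score table.
#' @param n_planted_pass SNPs planted to pass both prioritization filters.
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return list with `genes`, `xci`, `enhancers`, `snp_scores`,
#'   `candidate_windows` and `truth` (planted parameters and ids).
#' @export
annotation_fixtures <- function(n_escape = 59, n_variable = 0,
                                n_inactive = 381,
                                p_selected = 0.15, omega = 1,
                                span = c(2.7e6, 155e6),
                                gene_length = 20000,
                                n_enhancers = 60, n_snps = 1000,
                                n_planted_pass = 10,
                                chrom = "X", seed = 1) {
  set.seed(as.integer(seed))
  n_genes <- n_escape + n_variable + n_inactive
  spacing <- floor((span[2] - span[1]) / n_genes)
  if (spacing <= gene_length)
    stop("span too small for the requested gene count and length")
  starts <- span[1] + (seq_len(n_genes) - 1) * spacing +
    floor(stats::runif(n_genes, 0, spacing - gene_length))
  genes <- genomic_intervals(chrom, starts, starts + gene_length,
                             gene = sprintf("G%04d", seq_len(n_genes)))
  status <- sample(rep(c("escape", "variable", "inactive"),
                       c(n_escape, n_variable, n_inactive)))
  xci <- data.frame(gene = genes$gene, chrom = chrom,
                    start = genes$start, end = genes$end,
                    status = status, stringsAsFactors = FALSE)

  # plant selection status: escape genes selected at odds omega times the
  # baseline odds
  base_odds <- p_selected / (1 - p_selected)
  p_escape <- omega * base_odds / (1 + omega * base_odds)
  p_gene <- ifelse(status == "escape", p_escape, p_selected)
  selected <- stats::runif(n_genes) < p_gene
  # one 20-kb candidate window overlapping each selected gene
  cand <- genes[selected, , drop = FALSE]
  candidate_windows <- if (nrow(cand) > 0)
    genomic_intervals(chrom, cand$start, cand$start + 20000) else
      genomic_intervals(chrom, 0, 1)[0, ]

  # enhancers: intergenic records upstream of a target gene; 1-3 cell-line
  # annotations per base enhancer with jittered coordinates
  cells <- c("GM12878", "K562", "HUVEC", "HCT116", "H1")
  enh_rows <- list()
  tg <- sample(genes$gene, n_enhancers, replace = TRUE)
  for (i in seq_len(n_enhancers)) {
    gi <- match(tg[i], genes$gene)
    base_s <- genes$start[gi] - sample(30000:120000, 1)
    base_e <- base_s + sample(800:3000, 1)
    db <- sample(0:4, 1)
    for (k in seq_len(sample(1:3, 1))) {
      jit <- sample(-400:400, 2)
      enh_rows[[length(enh_rows) + 1L]] <- data.frame(
        chrom = chrom, start = max(span[1], base_s + min(jit)),
        end = base_e + max(jit), cell_line = sample(cells, 1),
        target_gene = tg[i], db_support = db, stringsAsFactors = FALSE)
    }
  }
  enhancers <- do.call(rbind, enh_rows)

  # per-SNP standardized scores and deleteriousness, with a planted set
  # passing both prioritization filters
  pos <- sort(sample(seq(span[1] + 1, span[2]), n_snps))
  snp <- data.frame(chrom = chrom, pos = pos,
                    id = sprintf("rs%06d", seq_len(n_snps)),
                    daf = stats::runif(n_snps, 0.05, 0.95),
                    ihs_std = stats::rnorm(n_snps),
                    nsl_std = stats::rnorm(n_snps),
                    ihh12_std = stats::rnorm(n_snps),
                    deleteriousness = round(stats::rexp(n_snps, 1 / 4), 3),
                    stringsAsFactors = FALSE)
  planted <- sample(n_snps, n_planted_pass)
  snp$ihs_std[planted] <- 6 + stats::runif(n_planted_pass)
  snp$deleteriousness[planted] <- 10 + round(stats::runif(n_planted_pass,
                                                          0, 20), 3)
  # keep non-planted SNPs out of the joint pass set: extreme |z| rows that
  # were not planted get sub-cutoff deleteriousness
  for (st in c("ihs_std", "nsl_std", "ihh12_std")) {
    thr <- stats::quantile(abs(snp[[st]]), 0.99, names = FALSE)
    clash <- setdiff(which(abs(snp[[st]]) >= thr &
                             snp$deleteriousness >= 10), planted)
    snp$deleteriousness[clash] <- 9.5
  }

  list(genes = genes, xci = xci, enhancers = enhancers,
       snp_scores = snp, candidate_windows = candidate_windows,
       truth = list(selected_genes = genes$gene[selected],
                    omega = omega, p_selected = p_selected,
                    planted_pass = snp$id[planted]))
}

#' Write annotation fixtures to a directory
#'
#' Dumps the tables of [annotation_fixtures()] as BED-like TSVs plus a
#' ground-truth YAML sidecar.
#'
#' @param fx fixture list from [annotation_fixtures()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(fx$genes, file.path(dir, "genes.bed"))
  utils::write.table(fx$xci, file.path(dir, "xci_status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$enhancers, file.path(dir, "enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$snp_scores, file.path(dir, "snp_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(fx$candidate_windows, file.path(dir, "candidate_windows.bed"))
  yaml::write_yaml(fx$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
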