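#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test computed definitionally: with margins fixed, the
#' p-value is the sum of hypergeometric probabilities of all tables whose
#' probability does not exceed that of the observed table.  The odds ratio
#' is the sample cross-product `(a*d)/(b*c)`; zero cells give 0 or Inf
#' without any continuity correction.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return a `contingency_result`: list with `table`, `odds_ratio`,
#'   `p_value`, `method`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  if (sum(table) == 0) stop("empty table")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("all-zero margin in contingency table")
  a <- table[1, 1]
  p <- fisher_p_support(r1, c1, r1 + r2)[as.character(a)]
  or <- unname(table[1, 1] * table[2, 2])
  bc <- unname(table[1, 2] * table[2, 1])
  odds_ratio <- if (bc == 0 && or == 0) NA_real_ else
    if (bc == 0) Inf else or / bc
  structure(list(table = table, odds_ratio = odds_ratio,
                 p_value = unname(p), method = "fisher"),
            class = "contingency_result")
}

# two-sided Fisher p for every possible a given margins (row1 total r1,
# col1 total c1, grand total N); internal, vectorized over the support
fisher_p_support <- function(r1, c1, N) {
  supp <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- stats::dhyper(supp, c1, N - c1, r1)
  p <- vapply(seq_along(supp), function(i)
    sum(pr[pr <= pr[i] * (1 + 1e-7)]), numeric(1))
  p <- pmin(p, 1)
  names(p) <- supp
  p
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("contingency_result (%s): OR = %s, p = %.4g\n", x$method,
              format(x$odds_ratio, digits = 4), x$p_value))
  print(x$table)
  invisible(x)
}

#' XCI-escape selection enrichment
#'
#' Tests whether genes escaping X inactivation are over-represented among
#' genes targeted by positive selection: a 2x2 table of XCI status (escape /
#' inactive) against selection status (selected / not selected) assessed by
#' Fisher's exact test.  Genes with `variable` status are excluded by
#' default.
#'
#' @param candidate_genes character vector of selected gene ids.
#' @param xci data.frame with columns `gene` and `status` (`escape`,
#'   `variable`, `inactive`).
#' @param include_variable count `variable` genes as escape (`"escape"`),
#'   as inactive (`"inactive"`), or exclude them (`FALSE`, default).
#' @return a `contingency_result` (degenerate margins return p = 1 with an
#'   undefined odds ratio rather than an error).
#' @export
xci_enrichment <- function(candidate_genes, xci, include_variable = FALSE) {
  stopifnot(all(c("gene", "status") %in% names(xci)))
  status <- xci$status
  if (identical(include_variable, "escape")) {
    status[status == "variable"] <- "escape"
  } else if (identical(include_variable, "inactive")) {
    status[status == "variable"] <- "inactive"
  }
  use <- status %in% c("escape", "inactive")
  if (!any(use)) stop("empty gene universe for the XCI contingency table")
  g <- xci$gene[use]
  esc <- status[use] == "escape"
  sel <- g %in% candidate_genes
  tab <- matrix(c(sum(esc & sel), sum(esc & !sel),
                  sum(!esc & sel), sum(!esc & !sel)),
                2, 2, byrow = TRUE,
                dimnames = list(c("escape", "inactive"),
                                c("selected", "not_selected")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(table = tab, odds_ratio = NA_real_,
                          p_value = 1, method = "fisher"),
                     class = "contingency_result"))
  }
  fisher_exact_2x2(tab)
}

#' Prioritize SNPs by selection score and deleteriousness
#'
#' Retains SNPs whose standardized score lies in the extreme tail of the
#' absolute-z distribution for at least one statistic AND whose
#' deleteriousness (PHRED-scaled, CADD-like) meets the cutoff (inclusive).
#' SNPs without a deleteriousness value are excluded with a reported count.
#'
#' @param scores standardized score table ([standardize_scores()]).
#' @param deleteriousness named numeric vector: SNP id -> PHRED score.
#' @param tail_q upper tail mass defining "extreme" per statistic
#'   (default 1%).
#' @param del_cutoff minimum deleteriousness score (default 10, the 1% most
#'   deleterious genome-wide in PHRED scaling).
#' @param statistics standardized columns to use.
#' @return subset of `scores` rows with added `deleteriousness` and
#'   `extreme_in` (comma-joined statistics) columns.
#' @export
prioritize_snps <- function(scores, deleteriousness, tail_q = 0.01,
                            del_cutoff = 10,
                            statistics = c("ihs_std", "nsl_std",
                                           "ihh12_std")) {
  del <- deleteriousness[scores$id]
  n_missing <- sum(is.na(del))
  if (n_missing > 0)
    message(sprintf("prioritize_snps: %d SNP(s) without deleteriousness score excluded", n_missing))
  extreme <- matrix(FALSE, nrow(scores), length(statistics),
                    dimnames = list(NULL, statistics))
  for (st in statistics) {
    z <- abs(scores[[st]])
    thr <- stats::quantile(z, 1 - tail_q, na.rm = TRUE, names = FALSE)
    extreme[, st] <- !is.na(z) & z >= thr
  }
  keep <- rowSums(extreme) > 0 & !is.na(del) & del >= del_cutoff
  out <- scores[keep, , drop = FALSE]
  out$deleteriousness <- del[keep]
  out$extreme_in <- apply(extreme[keep, , drop = FALSE], 1, function(r)
    paste(statistics[r], collapse = ","))
  rownames(out) <- NULL
  out
}

#' Partition candidate windows by gene overlap
#'
#' Labels each window `genic` (fully covered by gene spans), `intergenic`
#' (no overlap) or `partial` (both genic and intergenic bp), and optionally
#' counts SNPs per context within each window.
#'
#' @param candidates window table (`chrom`, `start`, `end`).
#' @param genes gene interval table.
#' @param snp_pos optional integer vector of SNP positions (1-based bp) to
#'   classify within each window.
#' @return `candidates` with added `context` and (when `snp_pos` is given)
#'   `n_snps_genic` / `n_snps_intergenic` columns.
#' @export
partition_windows <- function(candidates, genes, snp_pos = NULL) {
  if (nrow(genes) > 0) {
    gmerged <- intervals_merge(genes[, c("chrom", "start", "end")])
  } else {
    gmerged <- genes
  }
  context <- character(nrow(candidates))
  n_genic <- integer(nrow(candidates))
  n_inter <- integer(nrow(candidates))
  snp0 <- if (is.null(snp_pos)) NULL else snp_pos - 1L
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$start[i]; e <- candidates$end[i]
    cov <- 0
    if (nrow(gmerged) > 0) {
      g <- gmerged[gmerged$chrom == candidates$chrom[i], , drop = FALSE]
      ov_s <- pmax(g$start, s); ov_e <- pmin(g$end, e)
      cov <- sum(pmax(0, ov_e - ov_s))
    }
    context[i] <- if (cov == 0) "intergenic" else
      if (cov >= e - s) "genic" else "partial"
    if (!is.null(snp0)) {
      inside <- snp0[snp0 >= s & snp0 < e]
      if (nrow(gmerged) > 0) {
        g <- gmerged[gmerged$chrom == candidates$chrom[i], , drop = FALSE]
        in_gene <- vapply(inside, function(p)
          any(p >= g$start & p < g$end), logical(1))
      } else {
        in_gene <- rep(FALSE, length(inside))
      }
      n_genic[i] <- sum(in_gene)
      n_inter[i] <- sum(!in_gene)
    }
  }
  candidates$context <- context
  if (!is.null(snp_pos)) {
    candidates$n_snps_genic <- n_genic
    candidates$n_snps_intergenic <- n_inter
  }
  candidates
}

#' Functional-element overlap proportions and odds
#'
#' For each prioritized SNP set (e.g. per statistic) and context, the
#' proportion of SNPs falling inside annotated functional elements, compared
#' with a background SNP set through an odds ratio
#' `odds(set) / odds(background)`.
#'
#' @param snp_sets named list of integer vectors of SNP positions (1-based
#'   bp).
#' @param elements functional element interval table.
#' @param background integer vector of background SNP positions.
#' @param chrom chromosome of the positions.
#' @return data.frame with `set`, `n`, `proportion`, `background_proportion`
#'   and `odds_ratio`.
#' @export
functional_overlap_odds <- function(snp_sets, elements, background,
                                    chrom = "X") {
  if (length(background) == 0) stop("empty background SNP set")
  el <- elements[elements$chrom == chrom, , drop = FALSE]
  in_el <- function(pos) {
    if (length(pos) == 0) return(logical(0))
    if (nrow(el) == 0) return(rep(FALSE, length(pos)))
    p0 <- pos - 1L
    vapply(p0, function(p) any(p >= el$start & p < el$end), logical(1))
  }
  pb <- mean(in_el(background))
  rows <- lapply(names(snp_sets), function(nm) {
    hit <- in_el(snp_sets[[nm]])
    p <- if (length(hit) == 0) NA_real_ else mean(hit)
    or <- if (is.na(p) || p %in% c(0, 1) || pb %in% c(0, 1))
      NA_real_ else (p / (1 - p)) / (pb / (1 - pb))
    if (!is.na(p) && pb > 0 && pb < 1 && p == 0) or <- 0
    if (!is.na(p) && pb > 0 && pb < 1 && p == 1) or <- Inf
    data.frame(set = nm, n = length(hit), proportion = p,
               background_proportion = pb, odds_ratio = or,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus enhancers from cell-type-specific annotations
#'
#' Collapses multiple cell-type-specific enhancer records into unique
#' coordinates: records sharing a target gene are merged when their
#' intervals overlap or when the scan-grid windows they cover are
#' contiguous.  A merged record spans (min start, max end), takes the union
#' of cell lines and the maximum database support.  Output intervals are
#' pairwise disjoint within each gene and the operation is idempotent.
#'
#' @param annotations data.frame with `chrom`, `start`, `end`, `cell_line`,
#'   `target_gene`, `db_support`.
#' @param window_size,step scan window grid defining "contiguous windows"
#'   (defaults 20 kb / 16 kb).
#' @return consensus enhancer data.frame (`chrom`, `start`, `end`,
#'   `cell_lines`, `target_gene`, `db_support`, `n_records`).
#' @export
consensus_enhancers <- function(annotations, window_size = 20000,
                                step = 16000) {
  need <- c("chrom", "start", "end", "cell_line", "target_gene",
            "db_support")
  stopifnot(all(need %in% names(annotations)))
  win_range <- function(s, e) {
    # indices k of grid windows [k*step, k*step + window_size) overlapped
    lo <- ceiling((s - window_size) / step + 1e-9)
    hi <- floor((e - 1) / step)
    c(max(0, lo), hi)
  }
  out <- list()
  for (g in unique(annotations$target_gene)) {
    rec <- annotations[annotations$target_gene == g, , drop = FALSE]
    rec <- rec[order(rec$start, rec$end), , drop = FALSE]
    cl_start <- rec$start[1]; cl_end <- rec$end[1]
    cl_lines <- strsplit(as.character(rec$cell_line[1]), ",")[[1]]
    cl_db <- rec$db_support[1]
    cl_n <- 1L
    cl_w <- win_range(cl_start, cl_end)
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        chrom = rec$chrom[1], start = cl_start, end = cl_end,
        cell_lines = paste(sort(unique(cl_lines)), collapse = ","),
        target_gene = g, db_support = cl_db, n_records = cl_n,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(rec))[-1]) {
      w <- win_range(rec$start[k], rec$end[k])
      overlaps <- rec$start[k] < cl_end
      window_contig <- w[1] <= cl_w[2] + 1L
      if (overlaps || window_contig) {
        cl_end <- max(cl_end, rec$end[k])
        cl_lines <- c(cl_lines,
                      strsplit(as.character(rec$cell_line[k]), ",")[[1]])
        cl_db <- max(cl_db, rec$db_support[k])
        cl_n <- cl_n + 1L
        cl_w <- c(cl_w[1], max(cl_w[2], w[2]))
      } else {
        flush()
        cl_start <- rec$start[k]; cl_end <- rec$end[k]
        cl_lines <- strsplit(as.character(rec$cell_line[k]), ",")[[1]]
        cl_db <- rec$db_support[k]
        cl_n <- 1L
        cl_w <- w
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$target_gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Association between enhancer and target-gene selection
#'
#' 2x2 contingency of enhancer selection status (overlap of any candidate
#' window by >= 1 bp) against target-gene selection status, assessed by a
#' Pearson chi-squared test without continuity correction, with observed
#' vs expected cell counts and mean enhancer-to-gene distances per cell.
#' Top hits are restricted to enhancers supported by at least `min_db`
#' databases.
#'
#' @param consensus consensus enhancer table ([consensus_enhancers()]).
#' @param candidate_windows candidate window interval table.
#' @param candidate_genes character vector of selected gene ids.
#' @param genes gene interval table with `gene` id column (for distances).
#' @param min_db minimum database support for top-hit extraction.
#' @return list with `result` (a `contingency_result`, chi-squared),
#'   `observed`, `expected`, `distances` (mean bp per cell), `top_hits`.
#' @export
enhancer_selection_association <- function(consensus, candidate_windows,
                                           candidate_genes, genes,
                                           min_db = 3) {
  ov <- intervals_intersect(consensus, candidate_windows)
  enh_sel <- seq_len(nrow(consensus)) %in% ov$a_idx
  gene_sel <- consensus$target_gene %in% candidate_genes
  tab <- matrix(c(sum(enh_sel & gene_sel), sum(enh_sel & !gene_sel),
                  sum(!enh_sel & gene_sel), sum(!enh_sel & !gene_sel)),
                2, 2, byrow = TRUE,
                dimnames = list(c("enh_selected", "enh_not"),
                                c("gene_selected", "gene_not")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count < 1; consider the exact test")
  suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
  res <- structure(list(table = tab, odds_ratio = {
    bc <- tab[1, 2] * tab[2, 1]
    if (bc == 0) if (tab[1, 1] * tab[2, 2] == 0) NA_real_ else Inf
    else tab[1, 1] * tab[2, 2] / bc
  }, p_value = unname(ct$p.value), method = "chi-squared",
  statistic = unname(ct$statistic)), class = "contingency_result")
  # mean enhancer <-> target gene distance per cell
  gidx <- match(consensus$target_gene, genes$gene)
  dist <- rep(NA_real_, nrow(consensus))
  ok <- !is.na(gidx)
  dist[ok] <- pmax(0, pmax(genes$start[gidx[ok]] - consensus$end[ok],
                           consensus$start[ok] - genes$end[gidx[ok]]))
  cell <- ifelse(enh_sel, ifelse(gene_sel, "YY", "YN"),
                 ifelse(gene_sel, "NY", "NN"))
  distances <- tapply(dist, factor(cell, levels = c("YY", "YN", "NY", "NN")),
                      mean, na.rm = TRUE)
  top <- consensus[enh_sel & gene_sel & consensus$db_support >= min_db, ,
                   drop = FALSE]
  list(result = res, observed = tab, expected = expected,
       distances = distances, top_hits = top)
}
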