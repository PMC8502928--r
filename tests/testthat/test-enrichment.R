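test_that("Fisher exact test: hand cases, symmetry, and agreement with stats::fisher.test", {
  r <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  # [[1,9],[11,3]] against explicit hypergeometric enumeration
  tab <- matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE)
  r2 <- fisher_exact_2x2(tab)
  probs <- sapply(0:10, function(a)
    choose(12, a) * choose(12, 10 - a) / choose(24, 10))
  p_hand <- sum(probs[probs <= probs[2] * (1 + 1e-7)])
  expect_equal(r2$p_value, p_hand, tolerance = 1e-12)
  expect_equal(r2$odds_ratio, (1 * 3) / (9 * 11))

  set.seed(17)
  for (k in 1:50) {
    t4 <- matrix(rpois(4, 6) + 1, 2, 2)
    ours <- fisher_exact_2x2(t4)
    ref <- stats::fisher.test(t4)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    # swapping both rows and both columns leaves p unchanged
    sw <- t4[2:1, 2:1]
    expect_equal(fisher_exact_2x2(sw)$p_value, ours$p_value,
                 tolerance = 1e-12)
  }

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
  # zero cells: cross-product odds ratio without continuity correction
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 1, 2), 2, 2,
                                       byrow = TRUE))$odds_ratio, Inf)
})

test_that("XCI enrichment builds the escape/inactive x selected table", {
  xci <- data.frame(gene = paste0("G", 1:8),
                    status = c("escape", "escape", "inactive", "inactive",
                               "inactive", "variable", "escape", "inactive"),
                    stringsAsFactors = FALSE)
  res <- xci_enrichment(c("G1", "G3"), xci)
  expect_equal(unname(res$table["escape", "selected"]), 1)
  expect_equal(unname(res$table["inactive", "not_selected"]), 3)
  expect_equal(sum(res$table), 7)  # variable excluded

  # degenerate margin: every gene selected -> p = 1, OR undefined
  res2 <- xci_enrichment(xci$gene, xci)
  expect_equal(res2$p_value, 1)
  expect_true(is.na(res2$odds_ratio))

  expect_error(xci_enrichment("G1", data.frame(gene = "G9",
                                               status = "variable")),
               "empty gene universe")
})

test_that("SNP prioritization applies both filters with the documented boundaries", {
  set.seed(23)
  n <- 500
  sc <- data.frame(chrom = "X", pos = seq_len(n) * 100,
                   id = sprintf("s%03d", seq_len(n)), daf = 0.5,
                   ihs_std = rnorm(n), nsl_std = rnorm(n),
                   ihh12_std = rnorm(n))
  del <- stats::setNames(rep(20, n), sc$id)
  # deleteriousness boundary: score 9.9 excluded, 10 retained (inclusive)
  thr99 <- stats::quantile(abs(sc$ihs_std), 0.995, names = FALSE)
  top <- which(abs(sc$ihs_std) >= thr99)[1]
  del[sc$id[top]] <- 9.9
  pr <- prioritize_snps(sc, del)
  expect_false(sc$id[top] %in% pr$id)
  del[sc$id[top]] <- 10
  pr2 <- prioritize_snps(sc, del)
  expect_true(sc$id[top] %in% pr2$id)
  # del_cutoff 0: retention driven by the tail alone
  pr3 <- prioritize_snps(sc, del, del_cutoff = 0)
  for (st in c("ihs_std", "nsl_std", "ihh12_std")) {
    thr <- stats::quantile(abs(sc[[st]]), 0.99, names = FALSE)
    expect_true(all(sc$id[abs(sc[[st]]) >= thr] %in% pr3$id))
  }
  # missing deleteriousness: excluded with a message
  expect_message(pr4 <- prioritize_snps(sc, del[1:400]),
                 "without deleteriousness")
  expect_true(all(pr4$id %in% sc$id[1:400]))
})

test_that("window partition labels match brute-force point checks", {
  genes <- genomic_intervals("X", c(1000, 50000), c(30000, 60000),
                             gene = c("G1", "G2"))
  w <- data.frame(chrom = "X", start = c(2000, 25000, 70000),
                  end = c(22000, 45000, 90000))
  snps <- c(2500, 21000, 28000, 29999, 31000, 44000, 75000)
  out <- partition_windows(w, genes, snp_pos = snps)
  expect_equal(out$context, c("genic", "partial", "intergenic"))
  # brute-force SNP context check for the partial window [25000, 45000)
  in_w <- snps - 1 >= 25000 & snps - 1 < 45000
  in_g <- sapply(snps - 1, function(p)
    (p >= 1000 & p < 30000) | (p >= 50000 & p < 60000))
  expect_equal(out$n_snps_genic[2], sum(in_w & in_g))
  expect_equal(out$n_snps_intergenic[2], sum(in_w & !in_g))
  # empty gene list: everything intergenic
  out2 <- partition_windows(w, genes[0, ])
  expect_equal(out2$context, rep("intergenic", 3))
})

test_that("functional overlap proportions and planted odds recovery", {
  el <- genomic_intervals("X", c(0), c(1e6))
  snp_sets <- list(a = c(10, 20), b = c(5000))
  out <- functional_overlap_odds(snp_sets, el, background = c(1, 2, 3))
  expect_true(all(out$proportion == 1))

  el2 <- genomic_intervals("X", 1000, 2000)
  out2 <- functional_overlap_odds(list(a = c(5000, 6000)), el2,
                                  background = c(1500, 5000))
  expect_equal(out2$proportion, 0)
  expect_equal(out2$odds_ratio, 0)
  expect_error(functional_overlap_odds(snp_sets, el, background = numeric(0)),
               "empty background")

  # planted 2x enrichment: elements cover 25% of the chromosome; the test
  # set hits them at 2x the background odds
  set.seed(31)
  L <- 1e6
  el3 <- genomic_intervals("X", seq(0, L - 1, by = 40000),
                           seq(0, L - 1, by = 40000) + 10000)
  p_bg <- 0.25
  odds_t <- 2 * p_bg / (1 - p_bg)
  p_t <- odds_t / (1 + odds_t)
  draw <- function(n, p_in) {
    inside <- runif(n) < p_in
    pos <- integer(n)
    base <- sample(seq(0, L - 40000, by = 40000), n, replace = TRUE)
    pos[inside] <- base[inside] + sample.int(10000, sum(inside), TRUE)
    pos[!inside] <- base[!inside] + 10000 +
      sample.int(30000, sum(!inside), TRUE)
    pos
  }
  ors <- replicate(60, {
    functional_overlap_odds(list(t = draw(400, p_t)), el3,
                            background = draw(2000, p_bg))$odds_ratio
  })
  expect_lt(abs(mean(log(ors)) - log(2)), 0.15)
})

test_that("consensus enhancers: merging rules, hand fixture, idempotence", {
  # two same-gene records sharing 1 bp merge into one span
  ann <- data.frame(chrom = "X", start = c(100, 999), end = c(1000, 1500),
                    cell_line = c("K562", "H1"), target_gene = "G1",
                    db_support = c(1, 3), stringsAsFactors = FALSE)
  out <- consensus_enhancers(ann)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$end, 1500)
  expect_equal(out$cell_lines, "H1,K562")
  expect_equal(out$db_support, 3)

  # 6 records -> 3 consensus: G1 gets an overlap merge plus a distant
  # record; G2 gets a chain of window-contiguous records merged into one
  fix <- data.frame(
    chrom = "X",
    start = c(1000, 2500, 37000, 1000, 17000, 33000),
    end = c(3000, 4000, 39000, 3000, 18000, 34000),
    cell_line = c("K562", "H1", "HUVEC", "K562", "GM12878", "H1"),
    target_gene = c("G1", "G1", "G1", "G2", "G2", "G2"),
    db_support = c(1, 2, 4, 0, 3, 1), stringsAsFactors = FALSE)
  out2 <- consensus_enhancers(fix)
  expect_equal(nrow(out2), 3)
  g1 <- out2[out2$target_gene == "G1", ]
  expect_equal(sort(g1$start), c(1000, 37000))
  g2 <- out2[out2$target_gene == "G2", ]
  expect_equal(nrow(g2), 1)
  expect_equal(g2$end, 34000)
  expect_equal(g2$db_support, 3)
  # same coordinates, different genes: not merged (G1 vs G2 at 1000-3000)

  # idempotence and per-gene disjointness
  again <- consensus_enhancers(
    data.frame(chrom = out2$chrom, start = out2$start, end = out2$end,
               cell_line = out2$cell_lines, target_gene = out2$target_gene,
               db_support = out2$db_support, stringsAsFactors = FALSE))
  expect_equal(nrow(again), nrow(out2))
  expect_equal(again$start, out2$start)
  expect_equal(again$end, out2$end)
  for (g in unique(out2$target_gene)) {
    gg <- out2[out2$target_gene == g, ]
    if (nrow(gg) > 1) {
      gg <- gg[order(gg$start), ]
      expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    }
  }
})

test_that("enhancer-gene association: chi-squared arithmetic and extremes", {
  # hand check of the statistic on [[10,20],[30,40]]
  tab <- matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - exp_tab)^2 / exp_tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), stat_hand, tolerance = 1e-12)

  genes <- genomic_intervals("X", seq(0, 39) * 100000 + 50000,
                             seq(0, 39) * 100000 + 60000,
                             gene = sprintf("G%02d", 1:40))
  cons <- data.frame(chrom = "X",
                     start = genes$start - 30000, end = genes$start - 29000,
                     cell_lines = "K562", target_gene = genes$gene,
                     db_support = rep(c(0, 3), 20), n_records = 1,
                     stringsAsFactors = FALSE)
  # perfectly associated fixture: enhancers of selected genes overlap
  # candidate windows, others do not
  sel <- genes$gene[1:20]
  cand_win <- genomic_intervals("X", cons$start[1:20], cons$end[1:20])
  res <- enhancer_selection_association(cons, cand_win, sel, genes)
  expect_lt(res$result$p_value, 1e-8)
  expect_gt(res$observed["enh_selected", "gene_selected"],
            res$expected["enh_selected", "gene_selected"])
  expect_true(all(res$top_hits$db_support >= 3))
  expect_true(all(res$top_hits$target_gene %in% sel))
})
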