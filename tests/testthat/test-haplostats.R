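params_default <- scan_params()

test_that("EHH decay matches direct pair counting on hand cases", {
  # 4 identical carrier haplotypes: EHH stays 1 to the end of the locus
  al <- matrix(1L, 4, 5)
  al[, 3] <- c(1L, 1L, 1L, 1L)
  hm <- haplotype_matrix(rbind(al, matrix(0L, 2, 5)),
                         c(10, 20, 30, 40, 50) * 100,
                         cumsum(rep(0.01, 5)))
  cv <- ehh_curve(hm, 3, "derived", "right", "cM", params_default)
  expect_true(all(cv$ehh == 1))
  expect_equal(cv$status, "edge")  # still fully homozygous at the edge

  # carriers split 2/2 at the first flanking site: EHH = 2/6
  al2 <- matrix(0L, 4, 3)
  al2[, 2] <- 1L                  # core: all carriers derived
  al2[, 3] <- c(1L, 1L, 0L, 0L)   # 2/2 split
  hm2 <- haplotype_matrix(al2, c(100, 200, 300), c(0.01, 0.02, 0.03))
  cv2 <- ehh_curve(hm2, 2, "derived", "right", "cM", params_default)
  expect_equal(cv2$ehh[2], 2 / 6)

  # carriers all distinct at the flanking site: EHH = 0 and extension stops
  al4 <- matrix(c(0L, 0L, 1L, 1L, 1L, 0L), 2, 3)
  hm4 <- haplotype_matrix(rbind(al4, c(0L, 0L, 0L)), c(100, 200, 300),
                          c(0.01, 0.02, 0.03))
  cv4 <- ehh_curve(hm4, 2, "derived", "right", "cM", params_default)
  expect_equal(cv4$ehh, c(1, 0))
  expect_equal(cv4$status, "ok")

  # fewer than 2 carriers
  cv5 <- ehh_curve(hm4, 2, "ancestral", "right", "cM",
                   params_default)
  expect_equal(cv5$status, "few_carriers")
})

test_that("EHH curves are monotone non-increasing outward (property)", {
  set.seed(21)
  for (k in 1:40) {
    hm <- random_hm(sample(4:12, 1), sample(5:25, 1))
    core <- sample(n_snps(hm), 1)
    for (cs in c("derived", "ancestral", "pooled2")) {
      for (dir in c("left", "right")) {
        cv <- ehh_curve(hm, core, cs, dir, "cM", params_default)
        if (length(cv$ehh) > 1) expect_true(all(diff(cv$ehh) <= 1e-12))
      }
    }
  }
})

test_that("iHH integration: trapezoid with truncation crossing", {
  mk <- function(d, e) list(distances = d, ehh = e, offsets = seq_along(d),
                            status = "ok")
  # single interval from 1 to 0.5 over 0.1 cM
  expect_equal(ihh(mk(c(0, 0.1), c(1, 0.5)), NULL, 0.05), 0.075)
  # zero-length extension
  expect_equal(ihh(mk(0, 1), NULL, 0.05), 0)
  # EHH == 1 over 1 cM on each side, step to zero at the boundary: area 2.0
  up <- mk(c(0, 0.5, 1.0, 1.0 + 1e-9), c(1, 1, 1, 0))
  expect_equal(ihh(up, up, 0.05), 2, tolerance = 1e-6)
  # area below the truncation value is excluded: descent 1 -> 0 over 1 cM
  # crosses 0.05 at d = 0.95; area = trapezoid down to the crossing
  cv <- mk(c(0, 1), c(1, 0))
  expect_equal(ihh(cv, NULL, 0.05), (1 + 0.05) / 2 * 0.95)
  # failed curve propagates as missing
  bad <- mk(c(0, 0.1), c(1, 0.9)); bad$status <- "gap"
  expect_true(is.na(ihh(bad, NULL, 0.05)))
})

test_that("iHS is zero for symmetric decay and antisymmetric under allele relabeling", {
  # symmetric toy: ancestral and derived classes have mirror-image decay
  al <- rbind(
    matrix(c(0L, 1L, 0L), 2, 3, byrow = TRUE),
    matrix(c(1L, 1L, 1L), 2, 3, byrow = TRUE),
    matrix(c(0L, 0L, 0L), 2, 3, byrow = TRUE),
    matrix(c(1L, 0L, 1L), 2, 3, byrow = TRUE))
  hm <- haplotype_matrix(al, c(100, 200, 300), c(0.01, 0.02, 0.03))
  # truncation above the terminal EHH so the short locus is not an edge case
  r <- ihs_unstd(hm, 2, scan_params(truncation = 0.4))
  expect_equal(r$value, 0)

  set.seed(31)
  for (k in 1:25) {
    hm <- random_hm(sample(6:14, 1), sample(8:30, 1))
    core <- sample(n_snps(hm), 1)
    dc <- sum(hm$alleles[, core])
    if (dc < 2 || dc > n_haplotypes(hm) - 2) next
    a <- ihs_unstd(hm, core)
    flipped <- hm
    flipped$alleles[, core] <- 1L - flipped$alleles[, core]
    b <- ihs_unstd(flipped, core)
    if (is.na(a$value)) {
      expect_true(is.na(b$value))
    } else {
      expect_equal(a$value, -b$value, tolerance = 1e-12)
    }
    # nSL antisymmetry and map independence
    an <- nsl_unstd(hm, core)
    bn <- nsl_unstd(flipped, core)
    if (!is.na(an$value)) expect_equal(an$value, -bn$value,
                                       tolerance = 1e-12)
    doubled <- hm
    doubled$positions_cM <- hm$positions_cM * 2
    dn <- nsl_unstd(doubled, core)
    expect_equal(an$value, dn$value)
    # iHH12 invariant under core allele relabeling
    h1 <- ihh12_unstd(hm, core)
    h2 <- ihh12_unstd(flipped, core)
    expect_equal(h1$value, h2$value)
  }
})

test_that("long derived haplotypes give negative iHS with the oracle magnitude", {
  # derived carriers share a long homozygous core region; ancestral carriers
  # break up immediately.  Both classes split completely near the locus ends
  # so neither curve fails at the edge.
  set.seed(5)
  n_snp <- 20
  core <- 10
  split_a <- c(0L, 0L, 1L, 1L)
  split_b <- c(0L, 1L, 0L, 1L)
  derived <- matrix(rep(rbinom(n_snp, 1, 0.5), 4), 4, n_snp, byrow = TRUE)
  ancestral <- matrix(rbinom(4 * n_snp, 1, 0.5), 4, n_snp)
  derived[, 2] <- split_a; derived[, 1] <- split_b
  derived[, 19] <- split_a; derived[, 20] <- split_b
  ancestral[, 2] <- split_a; ancestral[, 1] <- split_b
  ancestral[, 19] <- split_a; ancestral[, 20] <- split_b
  derived[, core] <- 1L
  ancestral[, core] <- 0L
  al <- rbind(derived, ancestral)
  hm <- haplotype_matrix(al, sort(sample.int(1e5, n_snp)),
                         cumsum(runif(n_snp, 0.001, 0.01)))
  got <- ihs_unstd(hm, core)
  want <- oracle_ihs(hm, core, params_default)
  expect_false(is.na(got$value))
  expect_lt(got$value, 0)
  expect_equal(got$value, want, tolerance = 1e-12)
})

test_that("EHH12 pools the two most frequent haplotype classes", {
  # classes {3,3,2} over the core + flank: EHH12 = [C(6,2)+C(2,2)]/C(8,2)
  al <- rbind(matrix(rep(c(1L, 1L), 3), 3, 2, byrow = TRUE),
              matrix(rep(c(1L, 0L), 3), 3, 2, byrow = TRUE),
              matrix(rep(c(0L, 1L), 2), 2, 2, byrow = TRUE))
  hm <- haplotype_matrix(al, c(100, 200), c(0.01, 0.02))
  cv <- ehh_curve(hm, 1, "pooled2", "right", "cM", params_default)
  expect_equal(cv$ehh[2], (choose(6, 2) + choose(2, 2)) / choose(8, 2))
  # two core classes, otherwise identical: pooled EHH12 stays 1 throughout
  al2 <- matrix(rep(c(1L, 0L, 1L), 8), 8, 3, byrow = TRUE)
  al2[1:4, 2] <- 1L
  hm2 <- haplotype_matrix(al2, c(100, 200, 300), c(0, 0.05, 0.1))
  cv2 <- ehh_curve(hm2, 2, "pooled2", "right", "cM", params_default)
  expect_true(all(cv2$ehh == 1))
})

test_that("statistics match the exhaustive pair-counting oracle on random matrices", {
  set.seed(77)
  p <- scan_params(max_gap_bp = 1e9)  # no gaps in dense toys
  checked <- 0
  for (k in 1:60) {
    hm <- random_hm(sample(4:16, 1), sample(6:40, 1))
    core <- sample(n_snps(hm), 1)
    got_i <- ihs_unstd(hm, core, p)$value
    want_i <- oracle_ihs(hm, core, p)
    expect_equal(got_i, want_i, tolerance = 1e-12)
    got_n <- nsl_unstd(hm, core, p)$value
    want_n <- oracle_nsl(hm, core, p)
    expect_equal(got_n, want_n, tolerance = 1e-12)
    got_h <- ihh12_unstd(hm, core, p)$value
    want_h <- oracle_ihh12(hm, core, p)
    expect_equal(got_h, want_h, tolerance = 1e-12)
    if (!is.na(want_i)) checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("gap handling invalidates the core site", {
  al <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
  al[, 2] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  hm <- haplotype_matrix(al, c(1000, 2000, 40000, 41000),
                         c(0.001, 0.002, 0.04, 0.041))
  p <- scan_params(max_gap_bp = 20000)
  cv <- ehh_curve(hm, 2, "derived", "right", "cM", p)
  if (length(cv$ehh) == 1 || cv$ehh[length(cv$ehh)] >= p$truncation)
    expect_equal(cv$status, "gap")
  r <- ihs_unstd(hm, 2, p)
  expect_true(is.na(r$value))
  expect_true(r$reason %in% c("gap", "edge"))
})

test_that("standardization gives per-bin mean 0 and variance 1", {
  # single bin holding {0, 2} -> {-1, +1} with denominator-n variance
  sc <- data.frame(chrom = "X", pos = c(1, 2), id = c("a", "b"),
                   daf = c(0.5, 0.5), ihs_unstd = c(0, 2),
                   nsl_unstd = NA_real_, ihh12_unstd = NA_real_)
  out <- standardize_scores(sc, n_bins = 1)
  expect_equal(out$ihs_std, c(-1, 1))

  set.seed(13)
  n <- 10000
  sc2 <- data.frame(chrom = "X", pos = seq_len(n), id = as.character(seq_len(n)),
                    daf = runif(n, 0.01, 0.99),
                    ihs_unstd = rnorm(n, 5, 3),
                    nsl_unstd = rnorm(n, -2, 0.5),
                    ihh12_unstd = rexp(n))
  out2 <- standardize_scores(sc2, n_bins = 50)
  bins <- cut(out2$daf, seq(0, 1, length.out = 51), include.lowest = TRUE)
  for (st in c("ihs_std", "nsl_std", "ihh12_std")) {
    agg_m <- tapply(out2[[st]], bins, mean)
    agg_v <- tapply(out2[[st]], bins, function(z)
      mean((z - mean(z))^2))
    agg_m <- agg_m[!is.na(agg_m)]
    agg_v <- agg_v[!is.na(agg_v)]
    expect_true(all(abs(agg_m) < 1e-12))
    expect_true(all(abs(agg_v - 1) < 1e-12))
  }
  # whole-table moments approach (0, 1)
  expect_lt(abs(mean(out2$ihs_std)), 0.05)
  expect_lt(abs(stats::var(out2$ihs_std) - 1), 0.05)

  # bins with fewer than 2 values go missing
  sc3 <- data.frame(chrom = "X", pos = 1:3, id = c("a", "b", "c"),
                    daf = c(0.05, 0.52, 0.55),
                    ihs_unstd = c(1, 2, 3),
                    nsl_unstd = NA_real_, ihh12_unstd = NA_real_)
  out3 <- standardize_scores(sc3, n_bins = 10)
  expect_true(is.na(out3$ihs_std[1]))
  expect_false(anyNA(out3$ihs_std[2:3]))
})

test_that("reference standardization uses the reference bin moments", {
  ref <- data.frame(chrom = "X", pos = 1:4, id = letters[1:4],
                    daf = rep(0.5, 4), ihs_unstd = c(0, 2, 0, 2),
                    nsl_unstd = NA_real_, ihh12_unstd = NA_real_)
  sc <- ref[1:2, ]
  sc$ihs_unstd <- c(3, -1)
  out <- standardize_scores(sc, n_bins = 1, reference = ref)
  expect_equal(out$ihs_std, c((3 - 1) / 1, (-1 - 1) / 1))
})

test_that("windowed Tajima's D matches an independent evaluation", {
  # n = 4 haplotypes, 3 segregating sites with derived counts {1, 1, 2}
  al <- cbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
  hm <- haplotype_matrix(al, c(1001, 2001, 3001))
  got <- tajimas_d(hm, window_size = 10000, span = c(0, 10000))
  # independent evaluation of the published formula
  n <- 4; S <- 3
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pairs <- combn(n, 2)
  pi_hand <- mean(apply(pairs, 2, function(pr)
    sum(al[pr[1], ] != al[pr[2], ])))
  D_hand <- (pi_hand - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got$S, S)
  expect_equal(got$pi, pi_hand)
  expect_equal(got$D, D_hand, tolerance = 1e-12)

  # empty window: D undefined
  got2 <- tajimas_d(hm, window_size = 10000, span = c(0, 20000))
  expect_equal(got2$S[2], 0)
  expect_true(is.na(got2$D[2]))

  # all singletons: excess of rare variants, D < 0
  al3 <- matrix(0L, 6, 5)
  for (j in 1:5) al3[j, j] <- 1L
  hm3 <- haplotype_matrix(al3, seq(100, 500, by = 100))
  got3 <- tajimas_d(hm3, window_size = 10000, span = c(0, 10000))
  expect_lt(got3$D, 0)
})
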