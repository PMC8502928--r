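# Independent brute-force oracles for the haplotype statistics: every EHH
# value is obtained by exhaustive pair enumeration over the extended
# interval, and integrals by an explicit trapezoid loop.  Shares no code
# with the package implementation.

oracle_pair_ehh <- function(al, rows, cols, pooled = FALSE) {
  m <- length(rows)
  if (m < 2) return(NA_real_)
  seqs <- apply(al[rows, cols, drop = FALSE], 1, paste, collapse = "")
  if (pooled) {
    cnt <- sort(table(seqs), decreasing = TRUE)
    if (length(cnt) >= 2) {
      top <- cnt[1] + cnt[2]
      num <- choose(top, 2) + sum(choose(cnt[-(1:2)], 2))
    } else {
      num <- choose(cnt[1], 2)
    }
    return(as.numeric(num / choose(m, 2)))
  }
  same <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (seqs[i] == seqs[j]) same <- same + 1
  }
  same / choose(m, 2)
}

# walk outward replicating the documented stopping rules, EHH by brute force
oracle_curve <- function(hm, core, carrier_set, direction, distance,
                         params) {
  al <- hm$alleles
  n_snp <- ncol(al)
  rows <- switch(carrier_set,
                 derived = which(al[, core] == 1),
                 ancestral = which(al[, core] == 0),
                 seq_len(nrow(al)))
  pooled <- carrier_set == "pooled2"
  if (length(rows) < 2)
    return(list(d = numeric(0), e = numeric(0), status = "few_carriers"))
  step <- if (direction == "right") 1 else -1
  bp <- hm$positions_bp
  dist_at <- function(j) if (distance == "sites") abs(j - core) else
    abs(hm$positions_cM[j] - hm$positions_cM[core])
  max_ext <- if (distance == "sites") params$max_extend_sites else
    params$max_extend_bp
  d <- 0
  e <- oracle_pair_ehh(al, rows, core:core, pooled)
  status <- "ok"
  j <- core
  repeat {
    if (e[length(e)] < params$truncation) break
    jn <- j + step
    if (jn < 1 || jn > n_snp) {
      if (e[length(e)] > 0) status <- "edge"
      break
    }
    if (abs(bp[jn] - bp[j]) > params$max_gap_bp) { status <- "gap"; break }
    ext <- if (distance == "sites") abs(jn - core) else
      abs(bp[jn] - bp[core])
    if (ext > max_ext) break
    cols <- min(core, jn):max(core, jn)
    e <- c(e, oracle_pair_ehh(al, rows, cols, pooled))
    d <- c(d, dist_at(jn))
    j <- jn
  }
  list(d = d, e = e, status = status)
}

oracle_area <- function(d, e, trunc) {
  if (length(d) < 2) return(0)
  area <- 0
  for (i in 2:length(d)) {
    if (e[i] >= trunc) {
      area <- area + (e[i - 1] + e[i]) / 2 * (d[i] - d[i - 1])
    } else {
      dd <- if (e[i - 1] > e[i])
        (e[i - 1] - trunc) / (e[i - 1] - e[i]) * (d[i] - d[i - 1]) else 0
      area <- area + (e[i - 1] + trunc) / 2 * dd
      break
    }
  }
  area
}

oracle_ihh_both <- function(hm, core, carrier_set, distance, params) {
  up <- oracle_curve(hm, core, carrier_set, "right", distance, params)
  dn <- oracle_curve(hm, core, carrier_set, "left", distance, params)
  if (up$status != "ok" || dn$status != "ok") return(NA_real_)
  oracle_area(up$d, up$e, params$truncation) +
    oracle_area(dn$d, dn$e, params$truncation)
}

oracle_ihs <- function(hm, core, params, distance = "cM") {
  a <- oracle_ihh_both(hm, core, "ancestral", distance, params)
  d <- oracle_ihh_both(hm, core, "derived", distance, params)
  if (is.na(a) || is.na(d) || a == 0 || d == 0) return(NA_real_)
  log(a / d)
}

oracle_nsl <- function(hm, core, params) oracle_ihs(hm, core, params, "sites")

oracle_ihh12 <- function(hm, core, params) {
  oracle_ihh_both(hm, core, "pooled2", "cM", params)
}

# random small haplotype matrix with a genetic map
random_hm <- function(n_hap, n_snp, p = 0.4) {
  al <- matrix(rbinom(n_hap * n_snp, 1, p), n_hap, n_snp)
  # ensure no column fixed at the same allele in every row unrealistically:
  # monomorphic columns are allowed (flagged by scoring)
  bp <- sort(sample.int(5e5, n_snp))
  cm <- cumsum(runif(n_snp, 0, 0.02))
  haplotype_matrix(al, bp, cm)
}

# minimal phased VCF text for I/O tests
write_toy_vcf <- function(path, chrom, pos, ref, alt, gt_rows,
                          samples = NULL, ids = NULL) {
  n_s <- length(strsplit(gt_rows[1], "\t")[[1]])
  if (is.null(samples)) samples <- paste0("S", seq_len(n_s))
  if (is.null(ids)) ids <- rep(".", length(pos))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  chrom, pos, ids, ref, alt, gt_rows)
  writeLines(c(hdr, rows), path)
  path
}

# session-level cache so expensive simulation batches are built once
.sweepscan_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sweepscan_test_cache)) {
    assign(key, force(expr), envir = .sweepscan_test_cache)
  }
  get(key, envir = .sweepscan_test_cache)
}

# unstandardized per-replicate scores for one deme of a batch
batch_unstd_scores <- function(batch, pop) {
  lapply(seq_along(batch$replicates), function(r) {
    hm <- subset_haplotypes(batch$replicates[[r]], haplotypes = pop,
                            drop_monomorphic = TRUE)
    hm <- maf_filter(hm, 0.05)
    sc <- site_scores(hm)
    sc$replicate <- r
    sc
  })
}

# windows for each replicate, standardized against a pooled reference table
# (the genome-wide normalization convention: bin moments from all neutral
# replicates pooled)
batch_windows <- function(score_list, reference, L) {
  win <- make_windows(c(0, L), 20000, 16000, chrom = "sim")
  out <- list()
  for (sc in score_list) {
    z <- standardize_scores(sc, reference = reference)
    sw <- summarize_windows(win, z, min_snps = 20)
    if (nrow(sw) > 0) {
      sw$replicate <- sc$replicate[1]
      out[[length(out) + 1]] <- sw
    }
  }
  do.call(rbind, out)
}

# shared neutral calibration set (AFR deme of the X model, desk scale):
# 30 replicates of the 600-kb locus give > 1000 pooled windows
calibration_afr <- function() {
  cached("calib_afr", {
    model <- x_chromosome_model()
    batch <- simulate_neutral(model, 30, seed = 424242)
    scores <- batch_unstd_scores(batch, "AFR")
    pooled <- do.call(rbind, scores)
    windows <- batch_windows(scores, pooled, model$L)
    list(model = model, pooled_scores = pooled, windows = windows,
         thresholds = neutral_thresholds(windows))
  })
}
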