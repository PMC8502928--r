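#' Default pipeline configuration
#'
#' All tunable constants of the scan in one auditable list, at their
#' standard values: MAF > 5%, 20-kb maximum gap, EHH truncation 0.05, 100
#' DAF bins, 20-kb windows with 16-kb step retaining windows with more than
#' 20 SNPs, 99th/99.9th percentile critical values, the three-population
#' X-chromosome demographic preset with 254 calibration replicates of a
#' 600-kb locus.  `demo_config()` is the same configuration at desk scale
#' for quick end-to-end runs.
#'
#' @param outdir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @return a nested named list.
#' @export
default_config <- function(outdir = "sweepscan_out", seed = 1) {
  list(
    mode = "synthetic",
    input = list(vcf = NULL, ancestral = NULL, map = NULL,
                 genes = NULL, xci = NULL, enhancers = NULL),
    params = list(min_maf = 0.05, max_gap_bp = 20000, truncation = 0.05,
                  n_bins = 100, max_extend_bp = 1000000,
                  max_extend_sites = 200),
    windows = list(size = 20000, step = 16000, min_snps = 20),
    quantiles = c(0.99, 0.999),
    demography = list(preset = "x_chromosome", L = 600000),
    synthetic = list(scan_reps = 8, calibration_reps = 254,
                     sweep = NULL),
    enrichment = list(omega = 1, p_selected = 0.15, del_cutoff = 10,
                      tail_q = 0.01, min_db = 3),
    seed = seed,
    outdir = outdir)
}

#' @rdname default_config
#' @export
demo_config <- function(outdir = tempfile("sweepscan_demo"), seed = 1) {
  cfg <- default_config(outdir, seed)
  # full 600-kb locus (shorter loci leave too few scored iHS sites: the
  # EHH curves rarely decay below truncation before the locus edge), but
  # few replicates
  cfg$synthetic$scan_reps <- 1
  cfg$synthetic$calibration_reps <- 3
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks ranges, window geometry, unknown keys and input-file existence;
#' returns findings without mutating the configuration.
#'
#' @param config configuration list.
#' @return data.frame with `level` (`error`/`warning`) and `message`;
#'   zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, msg)
    f[[length(f) + 1L]] <<- data.frame(level = level, message = msg,
                                       stringsAsFactors = FALSE)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    add("error", paste("unknown configuration key(s):",
                       paste(unknown, collapse = ", ")))
  p <- config$params
  if (!is.null(p)) {
    if (p$min_maf < 0 || p$min_maf >= 0.5)
      add("error", "params$min_maf must lie in [0, 0.5)")
    if (p$truncation < 0 || p$truncation >= 1)
      add("error", "params$truncation must lie in [0, 1)")
    if (p$max_gap_bp <= 0) add("error", "params$max_gap_bp must be positive")
  }
  w <- config$windows
  if (!is.null(w) && w$step > w$size)
    add("warning", "window step exceeds window size: windows will not tile the span")
  q <- config$quantiles
  if (!is.null(q) && (any(q <= 0) || any(q >= 1) || is.unsorted(q)))
    add("error", "quantiles must be increasing and inside (0, 1)")
  if (identical(config$mode, "files")) {
    for (nm in c("vcf", "ancestral", "map")) {
      path <- config$input[[nm]]
      if (is.null(path) || !file.exists(path))
        add("error", sprintf("input$%s missing or not found", nm))
    }
  }
  if (length(f) == 0)
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, f)
}

#' Read / write a configuration file
#' @param path YAML file path.
#' @return for `read_config`, the configuration list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

score_population <- function(hm, pop, params) {
  sub <- subset_haplotypes(hm, haplotypes = pop, drop_monomorphic = TRUE)
  n_in <- n_snps(sub)
  sub <- maf_filter(sub, params$min_maf)
  message(sprintf("  [%s] %d SNPs polymorphic, %d after MAF > %g",
                  pop, n_in, n_snps(sub), params$min_maf))
  sp <- scan_params(truncation = params$truncation,
                    max_gap_bp = params$max_gap_bp,
                    max_extend_bp = params$max_extend_bp,
                    max_extend_sites = params$max_extend_sites,
                    min_maf = params$min_maf, n_bins = params$n_bins)
  sc <- site_scores(sub, sp)
  standardize_scores(sc, n_bins = params$n_bins)
}

windows_from_batch <- function(batch, pop, cfg) {
  out <- list()
  for (r in seq_along(batch$replicates)) {
    hm <- batch$replicates[[r]]
    if (n_snps(hm) == 0) next
    sc <- score_population(hm, pop, cfg$params)
    win <- make_windows(c(0, batch$model$L), cfg$windows$size,
                        cfg$windows$step, chrom = hm$chrom)
    sw <- summarize_windows(win, sc, min_snps = cfg$windows$min_snps)
    if (nrow(sw) > 0) {
      sw$replicate <- r
      out[[length(out) + 1L]] <- sw
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Run the end-to-end scan
#'
#' Orchestrates the full pipeline from one configuration: data ingestion
#' (or neutral simulation in synthetic mode), per-population scoring and
#' standardization, window summaries, neutral calibration, candidate
#' calling, cross-population sweep sharing, and the annotation enrichment
#' analyses.  All stage outputs are written to `config$outdir` together
#' with a run manifest; per-stage record counts are reported as messages.
#'
#' @param config configuration list (see [default_config()]); validated
#'   first, and any `error` finding aborts the run.
#' @return (invisibly) list with `scores`, `windows`, `thresholds`,
#'   `candidates`, `shared`, `enrichment`, `manifest`.
#' @export
run_scan <- function(config = demo_config()) {
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stop(paste("invalid configuration:\n",
               paste(findings$message[findings$level == "error"],
                     collapse = "\n ")))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  if (identical(config$mode, "synthetic")) {
    model <- x_chromosome_model(L = config$demography$L)
    pops <- model$deme_names
    message(sprintf("stage simulate: %d scan + %d calibration replicates of %s bp",
                    config$synthetic$scan_reps,
                    config$synthetic$calibration_reps,
                    format(model$L, big.mark = ",")))
    scan_batch <- simulate_neutral(model, config$synthetic$scan_reps, seed)
    calib_batch <- simulate_neutral(model, config$synthetic$calibration_reps,
                                    seed + 1000L)
    if (!is.null(config$synthetic$sweep)) {
      sw <- config$synthetic$sweep
      for (r in seq_along(scan_batch$replicates)) {
        inj <- inject_sweep(scan_batch$replicates[[r]],
                            core_pos = sw$core_pos,
                            target_freq = sw$target_freq,
                            span_bp = sw$span_bp, seed = seed + 2000L + r)
        scan_batch$replicates[[r]] <- inj$hm
      }
    }
    message("stage score: per-population site scores")
    scores <- list()
    cand <- list()
    thresholds <- list()
    for (pop in pops) {
      calib_win <- windows_from_batch(calib_batch, pop, config)
      thresholds[[pop]] <- neutral_thresholds(
        calib_win, config$quantiles,
        min_windows = min(1000, nrow(calib_win)))
      scan_win <- windows_from_batch(scan_batch, pop, config)
      sc_tab <- do.call(rbind, lapply(seq_along(scan_batch$replicates),
        function(r) {
          hm <- scan_batch$replicates[[r]]
          if (n_snps(hm) == 0) return(NULL)
          s <- score_population(hm, pop, config$params)
          s$replicate <- r
          s
        }))
      scores[[pop]] <- sc_tab
      cand[[pop]] <- call_candidates(scan_win, thresholds[[pop]])
      utils::write.table(sc_tab,
                         file.path(config$outdir,
                                   sprintf("scores_%s.tsv", pop)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(cand[[pop]],
                file.path(config$outdir, sprintf("windows_%s.bed", pop)))
      yaml::write_yaml(
        list(population = pop, quantiles = config$quantiles,
             n_windows = thresholds[[pop]]$n_windows,
             calibration_replicates = config$synthetic$calibration_reps,
             seed = seed + 1000L,
             thresholds = lapply(thresholds[[pop]]$thresholds, as.list)),
        file.path(config$outdir, sprintf("thresholds_%s.yaml", pop)))
      n99 <- sum(cand[[pop]]$ihs_cand99 | cand[[pop]]$nsl_cand99 |
                   cand[[pop]]$ihh12_cand99)
      message(sprintf("  [%s] %d windows retained, %d candidate at q99",
                      pop, nrow(cand[[pop]]), n99))
    }
    groups <- stats::setNames(pops, pops)
    shared <- shared_sweeps(cand, groups)
    if (!is.null(shared$regions))
      utils::write.table(shared$regions,
                         file.path(config$outdir, "shared_regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    message("stage enrich: annotation fixtures and contingency analyses")
    fx <- annotation_fixtures(omega = config$enrichment$omega,
                              p_selected = config$enrichment$p_selected,
                              seed = seed + 3000L)
    sel_genes <- fx$truth$selected_genes
    enr <- list(
      xci = xci_enrichment(sel_genes, fx$xci),
      prioritized = prioritize_snps(
        fx$snp_scores,
        stats::setNames(fx$snp_scores$deleteriousness, fx$snp_scores$id),
        tail_q = config$enrichment$tail_q,
        del_cutoff = config$enrichment$del_cutoff),
      consensus = consensus_enhancers(fx$enhancers,
                                      config$windows$size,
                                      config$windows$step))
    enr$association <- enhancer_selection_association(
      enr$consensus, fx$candidate_windows, sel_genes, fx$genes,
      min_db = config$enrichment$min_db)
    write_fixtures(fx, file.path(config$outdir, "fixtures"))
    utils::write.table(enr$consensus,
                       file.path(config$outdir, "consensus_enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr_summary <- data.frame(
      analysis = c("xci_escape", "enhancer_gene"),
      method = c(enr$xci$method, enr$association$result$method),
      odds_ratio = c(enr$xci$odds_ratio, enr$association$result$odds_ratio),
      p_value = c(enr$xci$p_value, enr$association$result$p_value))
    utils::write.table(enr_summary,
                       file.path(config$outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop_if_missing <- function(x, nm)
      if (is.null(x)) stop(sprintf("file mode requires input$%s", nm))
    inp <- config$input
    stop_if_missing(inp$vcf, "vcf"); stop_if_missing(inp$ancestral, "ancestral")
    stop_if_missing(inp$map, "map")
    anc <- read_ancestral_table(inp$ancestral)
    hm <- read_phased_vcf(inp$vcf, anc, populations = inp$populations)
    hm <- attach_genetic_map(hm, read_genetic_map(inp$map))
    message(sprintf("stage ingest: %d haplotypes x %d SNPs", n_haplotypes(hm),
                    n_snps(hm)))
    pops <- unique(hm$population_labels)
    scores <- lapply(stats::setNames(pops, pops), function(p)
      score_population(hm, p, config$params))
    span <- c(floor(min(hm$positions_bp - 1) / config$windows$step) *
                config$windows$step, max(hm$positions_bp))
    win <- make_windows(span, config$windows$size, config$windows$step,
                        chrom = hm$chrom)
    model <- x_chromosome_model(L = config$demography$L)
    calib_batch <- simulate_neutral(model, config$synthetic$calibration_reps,
                                    seed + 1000L)
    thresholds <- list(); cand <- list()
    for (pop in pops) {
      calib_win <- windows_from_batch(calib_batch,
                                      model$deme_names[1], config)
      thresholds[[pop]] <- neutral_thresholds(
        calib_win, config$quantiles,
        min_windows = min(1000, nrow(calib_win)))
      sw <- summarize_windows(win, scores[[pop]],
                              min_snps = config$windows$min_snps)
      cand[[pop]] <- call_candidates(sw, thresholds[[pop]])
      utils::write.table(scores[[pop]],
                         file.path(config$outdir,
                                   sprintf("scores_%s.tsv", pop)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(cand[[pop]],
                file.path(config$outdir, sprintf("windows_%s.bed", pop)))
    }
    shared <- if (length(pops) >= 2)
      shared_sweeps(cand, stats::setNames(pops, pops)) else NULL
    enr <- NULL
  }

  cfg_path <- file.path(config$outdir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list(
      populations = names(scores),
      snps_scored = vapply(scores, nrow, integer(1)),
      windows_retained = vapply(cand, nrow, integer(1)),
      candidates_q99 = vapply(cand, function(w)
        sum(w$ihs_cand99 | w$nsl_cand99 | w$ihh12_cand99), integer(1))))
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(list(scores = scores, thresholds = thresholds,
                 candidates = cand, shared = shared, enrichment = enr,
                 manifest = manifest))
}
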