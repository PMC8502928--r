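#' Demographic model in ms units
#'
#' A multi-deme coalescent model in the ms/msms convention: time in units of
#' `4*n_ref` generations, deme sizes relative to `n_ref`, exponential growth
#' rates per `4*n_ref` generations, and a migration matrix whose entry
#' `[i, j]` is `4*n_ref*m_ij` (the per-lineage backward migration rate from
#' deme i to deme j).  The locus-wide mutation and recombination parameters
#' are always derived from the per-generation rates:
#' `theta = 4*n_ref*mu*L` and `rho = 4*n_ref*rec*L`.
#'
#' @param n_ref reference effective population size (haploid-equivalent
#'   chromosomes, as in ms `-N`).
#' @param sample_sizes integer vector of sampled chromosomes per deme.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination rate per bp per generation.
#' @param L locus length in bp.
#' @param pop_sizes present-day deme sizes relative to `n_ref`.
#' @param growth exponential growth rates (per `4*n_ref` generations).
#' @param migration square migration matrix (ms `-ma` convention), zeros on
#'   the diagonal.
#' @param events `data.frame` with columns `time`, `type` (one of `join`,
#'   `size`, `growth`, `migration`), `i`, `j`, `x`; times non-decreasing.
#'   `join`: lineages of deme `i` move to deme `j` and migration involving
#'   `i` stops.  `size`: deme `i` set to relative size `x`, growth reset.
#'   `growth`: growth rate of deme `i` set to `x`.  `migration`: entry
#'   `[i, j]` set to `x`.
#' @param deme_names labels for the demes.
#' @param generation_time generation time in years (metadata only).
#' @return an object of class `demographic_model` with derived `theta` and
#'   `rho`.
#' @export
demographic_model <- function(n_ref, sample_sizes, mu, rec, L,
                              pop_sizes = rep(1, length(sample_sizes)),
                              growth = rep(0, length(sample_sizes)),
                              migration = matrix(0, length(sample_sizes),
                                                 length(sample_sizes)),
                              events = NULL,
                              deme_names = paste0("pop", seq_along(sample_sizes)),
                              generation_time = 30) {
  k <- length(sample_sizes)
  stopifnot(n_ref > 0, mu >= 0, rec >= 0, L > 0, all(sample_sizes > 0),
            length(pop_sizes) == k, length(growth) == k,
            nrow(migration) == k, ncol(migration) == k)
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), type = character(0),
                         i = integer(0), j = integer(0), x = numeric(0))
  } else {
    stopifnot(all(c("time", "type", "i", "j", "x") %in% names(events)))
    if (is.unsorted(events$time))
      stop("event times must be non-decreasing")
    if (!all(events$type %in% c("join", "size", "growth", "migration")))
      stop("unknown event type")
  }
  structure(list(n_ref = n_ref,
                 sample_sizes = as.integer(sample_sizes),
                 mu = mu, rec = rec, L = as.integer(L),
                 theta = 4 * n_ref * mu * L,
                 rho = 4 * n_ref * rec * L,
                 pop_sizes = pop_sizes, growth = growth,
                 migration = migration, events = events,
                 deme_names = deme_names,
                 generation_time = generation_time),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: %d deme(s), n_ref = %g\n",
              length(x$sample_sizes), x$n_ref))
  cat(sprintf("  samples: %s (total %d chromosomes)\n",
              paste(sprintf("%s=%d", x$deme_names, x$sample_sizes),
                    collapse = ", "), sum(x$sample_sizes)))
  cat(sprintf("  locus: %s bp, theta = %.4f, rho = %.4f\n",
              format(x$L, big.mark = ","), x$theta, x$rho))
  if (nrow(x$events) > 0)
    cat(sprintf("  %d demographic event(s), last at t = %g\n",
                nrow(x$events), max(x$events$time)))
  invisible(x)
}

#' Per-population X-chromosome sample sizes
#'
#' The 1000 Genomes phase 3 chromosome counts per population used to derive
#' pooled continental sample sizes (arithmetic mean of the five populations
#' in each continental group, rounded to the nearest integer).
#'
#' @return named list of named integer vectors, one per continental group.
#' @export
x_population_counts <- function() {
  list(AFR = c(ESN = 145, GWD = 171, LWK = 154, MSL = 128, YRI = 164),
       EUR = c(CEU = 149, FIN = 160, GBR = 136, IBS = 160, TSI = 161),
       ASI = c(CDX = 142, CHB = 160, CHS = 158, JPT = 152, KHV = 152))
}

#' Pooled continental sample sizes
#'
#' Rounded arithmetic mean of per-population chromosome counts within each
#' continental group.
#'
#' @param counts list of named numeric vectors (default
#'   [x_population_counts()]).
#' @return named integer vector of pooled sizes.
#' @export
pooled_sample_sizes <- function(counts = x_population_counts()) {
  vapply(counts, function(v) as.integer(round(mean(v))), integer(1))
}

#' Three-population X-chromosome neutral model
#'
#' The preset neutral demographic model for the human X chromosome: three
#' continental demes (AFR, EUR, ASI) with present relative sizes 2.204,
#' 3.2542 and 7.4055, exponential growth 56.61 and 96 per 4N units in EUR
#' and ASI, symmetric migration (AFR-EUR 0.3542, AFR-ASI 0.1462, EUR-ASI
#' 1.3562 in 4Nm units), the ASI-EUR merger at t = 0.0464 (EUR size to
#' 0.2939, AFR-EUR migration to 4.9314 both ways), the EUR-AFR merger at
#' t = 0.14022, and the ancestral AFR size change to 1 at t = 0.364.
#' Reference size 10,538.25 reflects the 3/4 autosomal effective size of
#' the X; mutation rate 1.25e-8 and recombination rate 1.3e-8 per bp per
#' generation on a 600-kb locus give theta = 316.1475 and rho = 328.7934.
#'
#' The pooled ASI sample size follows the simulation command (149) rather
#' than the rounded mean of the per-population counts (153); see
#' [pooled_sample_sizes()].
#'
#' @param L locus length in bp.
#' @param sample_sizes chromosomes sampled per deme (AFR, EUR, ASI).
#' @return a [demographic_model()].
#' @export
x_chromosome_model <- function(L = 600000,
                               sample_sizes = c(AFR = 152, EUR = 153,
                                                ASI = 149)) {
  mig <- matrix(0, 3, 3)
  mig[1, 2] <- 0.3542; mig[2, 1] <- 0.3542
  mig[1, 3] <- 0.1462; mig[3, 1] <- 0.1462
  mig[2, 3] <- 1.3562; mig[3, 2] <- 1.3562
  events <- data.frame(
    time = c(0.0464, 0.0464, 0.0464, 0.0464, 0.14022, 0.364),
    type = c("join", "size", "migration", "migration", "join", "size"),
    i = c(3L, 2L, 1L, 2L, 2L, 1L),
    j = c(2L, 0L, 2L, 1L, 1L, 0L),
    x = c(0, 0.2939, 4.9314, 4.9314, 0, 1),
    stringsAsFactors = FALSE)
  demographic_model(n_ref = 10538.25,
                    sample_sizes = sample_sizes,
                    mu = 1.25e-8, rec = 1.3e-8, L = L,
                    pop_sizes = c(2.204, 3.2542, 7.4055),
                    growth = c(0, 56.61, 96),
                    migration = mig, events = events,
                    deme_names = c("AFR", "EUR", "ASI"),
                    generation_time = 30)
}

#' Single-deme constant-size model
#'
#' Reduction of the simulator to the standard neutral coalescent: one deme
#' of constant size, useful for closed-form checks (Watterson's segregating
#' sites, the 1/i site frequency spectrum).
#'
#' @param n_sample sampled chromosomes.
#' @param theta locus-wide `4*N*mu*L`.
#' @param rho locus-wide `4*N*r*L`.
#' @param L locus length in bp.
#' @return a [demographic_model()].
#' @export
constant_size_model <- function(n_sample, theta, rho = 0, L = 100000) {
  n_ref <- 10000
  demographic_model(n_ref = n_ref, sample_sizes = n_sample,
                    mu = theta / (4 * n_ref * L),
                    rec = rho / (4 * n_ref * L), L = L)
}
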