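## Pooled-sequencing simulation and the read-span Q statistics feeding the
## frequency-estimation error covariance.

#' Pool-seq simulation configuration
#'
#' Reads are error-free copies of haplotype segments.  The number of reads
#' mapping to individual k is Poisson with mean `lambda_k`, itself drawn
#' from a log-normal with log-scale variance `Vx` (0 = every individual
#' equally likely to be sampled) and location `mu_x = log(E[lambda]) -
#' Vx/2` so the target coverage is matched in expectation.  Read start
#' positions are uniform on the region.
#'
#' @param coverage expected number of reads spanning a site.
#' @param read_length read length in bp.
#' @param Vx variance of the log sampling intensity (overdispersion).
#' @return object of class `poolseq_config`.
#' @export
poolseq_config <- function(coverage, read_length, Vx = 0) {
  stopifnot(coverage > 0, read_length >= 1, Vx >= 0)
  structure(list(coverage = coverage, read_length = read_length, Vx = Vx),
            class = "poolseq_config")
}

#' Simulate pooled sequencing of a population
#'
#' @param panel a [haplotype_panel()] (or plain haplotype matrix plus
#'   `positions`).
#' @param cfg a [poolseq_config()].
#' @param region_length region size in bp (defaults to the span of the
#'   panel positions).
#' @return list of class `poolseq_result` with `freq_est` (NA at
#'   zero-coverage loci), `O` (read-span counts, `O[i,i]` = coverage at i),
#'   `Q = O_ij / (O_i O_j)`, `covered` (logical), `n_reads`.
#' @export
simulate_poolseq <- function(panel, cfg, region_length = NULL) {
  stopifnot(inherits(cfg, "poolseq_config"))
  if (inherits(panel, "haplotype_panel")) {
    H <- panel$haplotypes; pos <- panel$positions
  } else {
    H <- as.matrix(panel$haplotypes); pos <- panel$positions
  }
  N <- nrow(H) %/% 2L
  nL <- ncol(H)
  if (is.null(region_length)) region_length <- max(pos) + 1

  # read starts uniform on [-read_length, region_length): every locus has
  # the same expected coverage (reads may overhang the region ends)
  n_reads_target <- cfg$coverage * (region_length + cfg$read_length) / cfg$read_length
  lambda_mean <- n_reads_target / N
  mu_x <- log(lambda_mean) - cfg$Vx / 2
  lambda <- if (cfg$Vx > 0)
    stats::rlnorm(N, meanlog = mu_x, sdlog = sqrt(cfg$Vx))
  else rep(lambda_mean, N)
  reads_per_ind <- stats::rpois(N, lambda)
  R_tot <- sum(reads_per_ind)

  ind <- rep.int(seq_len(N), reads_per_ind)
  hap_row <- 2L * (ind - 1L) + sample(1:2, R_tot, replace = TRUE)
  start <- stats::runif(R_tot, -cfg$read_length, region_length)
  lo <- findInterval(start, pos) + 1L
  hi <- findInterval(start + cfg$read_length - 1e-9, pos)

  ref_count <- numeric(nL)
  cov_count <- numeric(nL)
  O <- matrix(0, nL, nL)
  span <- hi >= lo
  for (r in which(span)) {
    idx <- lo[r]:hi[r]
    cov_count[idx] <- cov_count[idx] + 1
    ref_count[idx] <- ref_count[idx] + H[hap_row[r], idx]
    O[idx, idx] <- O[idx, idx] + 1
  }
  covered <- cov_count > 0
  freq_est <- ifelse(covered, ref_count / cov_count, NA_real_)
  Q <- matrix(0, nL, nL)
  oc <- tcrossprod(cov_count)
  pos_o <- O > 0 & oc > 0
  Q[pos_o] <- O[pos_o] / oc[pos_o]
  structure(list(freq_est = freq_est, O = O, Q = Q, covered = covered,
                 n_reads = R_tot, coverage = cov_count),
            class = "poolseq_result")
}

#' Expected number of segregating sites spanned by a read
#'
#' `read_length * n_sites / region_length`; about 2.5 for 150-bp reads
#' over 827,200 sites on a 50-Mb chromosome, the density the read-length
#' defaults emulate.
#'
#' @param read_length read length in bp.
#' @param n_sites number of segregating sites in the region.
#' @param region_length region size in bp.
#' @return expected spanned sites per read.
#' @export
expected_sites_per_read <- function(read_length, n_sites, region_length) {
  stopifnot(read_length > 0, n_sites >= 0, region_length > 0)
  read_length * n_sites / region_length
}

#' Attach simulated pool-seq observations to an experiment
#'
#' Replaces the exact start/end allele frequencies of each replicate of an
#' [run_experiment()] result (run with `keep_haplotypes = TRUE`) by
#' pool-seq estimates, and attaches the corresponding Q matrices.  Loci
#' with zero coverage in any replicate/time point are dropped everywhere
#' (their panel columns included) so the locus sets stay aligned.
#'
#' @param sim an `experiment_result` with haplotypes kept.
#' @param cfg a [poolseq_config()].
#' @return list with `panel` (possibly subset), `data` (an
#'   [experiment_data()] with `Q_start`/`Q_end` per replicate), `kept`
#'   (logical over the original loci).
#' @export
poolseq_experiment <- function(sim, cfg) {
  stopifnot(inherits(sim, "experiment_result"))
  if (is.null(sim$replicates[[1L]]$haps_start))
    stop("run_experiment() must be called with keep_haplotypes = TRUE")
  region <- sim$config$region_length
  pos <- sim$panel$positions
  M <- length(sim$replicates)
  ps <- lapply(sim$replicates, function(r) {
    s <- simulate_poolseq(list(haplotypes = r$haps_start, positions = pos),
                          cfg, region)
    e <- simulate_poolseq(list(haplotypes = r$haps_end, positions = pos),
                          cfg, region)
    list(start = s, end = e)
  })
  kept <- Reduce(`&`, lapply(ps, function(x) x$start$covered & x$end$covered))
  panel <- subset_panel(sim$panel, kept)
  reps <- lapply(ps, function(x) {
    list(p_start = x$start$freq_est[kept],
         p_end = x$end$freq_est[kept],
         Q_start = 1 / x$start$coverage[kept],
         Q_end = 1 / x$end$coverage[kept])
  })
  list(panel = panel,
       data = experiment_data(reps, p0 = compute_dosages(panel)$p),
       kept = kept)
}
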