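## Canned parameter-recovery studies at desk scale.  These are the
## package's own validation experiments: each runs the full pipeline
## (forward simulation -> projection -> REML -> VA estimate) under fixed
## study conditions and returns one row per simulated experiment.  The
## methods vignette discusses how the conditions scale down the
## full-sized simulation study they mirror.

study_seed <- function(seed, i) (seed %% 1000000L) * 1000L + i

#' Null-calibration study: effects detached from allele frequency
#'
#' Simplified simulations (neutral history, effects attached at random
#' with respect to allele) at desk scale: 500 loci, populations of 200,
#' 5 replicates observed over 3 generations, E[|eta|] = 0.03.  As in the
#' full-sized study this mirrors, the batch pools runs spanning the
#' simulated VA range (the non-neutral fraction sweeps 0.15-1, true VA
#' roughly 0.01-0.1); with effects detached from alleles the
#' diversity-power exponent and the frequency-effect coefficient are both
#' 0 and the residual variance is near 1.
#'
#' @param n_sims number of simulated experiments.
#' @param seed base seed; each run uses a derived sub-seed.
#' @return data.frame with one row per run: `frac_selected`, `va_true`,
#'   `va_hat`, `p_alpha`, `beta1`, `residual_variance`.
#' @export
study_null_calibration <- function(n_sims = 20, seed = 1) {
  NE <- experiment_effective_size(200)
  fracs <- seq(0.15, 1, length.out = n_sims)
  out <- lapply(seq_len(n_sims), function(i) {
    sim <- run_experiment(sim_config(n_loci = 500, N0 = 200,
                                     n_replicates = 5, n_generations = 3,
                                     dfe = dfe_config(scale = 0.09,
                                                      frac_neutral = 1 - fracs[i]),
                                     seed = study_seed(seed, i)))
    fit <- vafit(sim$panel, sim$data, generations = 3, Ne = NE)
    data.frame(frac_selected = fracs[i], va_true = sim$truth$VA_true,
               va_hat = fit$estimate$va,
               p_alpha = fit$fit$p_alpha, beta1 = fit$fit$beta1,
               residual_variance = fit$fit$residual_variance)
  })
  do.call(rbind, out)
}

#' Recovery study: estimated versus true VA across a range
#'
#' Simplified simulations spanning true VA of roughly 0.01 to 0.1 by
#' varying the fraction of non-neutral loci (E[|eta|] = 0.03, 10
#' replicates, 3 generations, 500 loci, populations of 200).
#'
#' @inheritParams study_null_calibration
#' @return data.frame with `frac_selected`, `va_true`, `va_hat`,
#'   `p_alpha`, `residual_variance`.
#' @export
study_recovery <- function(n_sims = 24, seed = 1) {
  NE <- experiment_effective_size(200)
  fracs <- seq(0.1, 1, length.out = n_sims)
  out <- lapply(seq_len(n_sims), function(i) {
    sim <- run_experiment(sim_config(n_loci = 500, N0 = 200,
                                     n_replicates = 10, n_generations = 3,
                                     dfe = dfe_config(scale = 0.09,
                                                      frac_neutral = 1 - fracs[i]),
                                     seed = study_seed(seed, 100L + i)))
    fit <- vafit(sim$panel, sim$data, generations = 3, Ne = NE)
    data.frame(frac_selected = fracs[i], va_true = sim$truth$VA_true,
               va_hat = fit$estimate$va, p_alpha = fit$fit$p_alpha,
               residual_variance = fit$fit$residual_variance)
  })
  do.call(rbind, out)
}

#' Pool-seq correction study
#'
#' Simplified simulations re-observed through simulated pooled
#' sequencing, fitted with and without the frequency-estimation error
#' covariance.  Conditions: 300 loci on 100 kb (about 2.4 segregating
#' sites per 800-bp read), populations of 100, 5 replicates, all loci
#' non-neutral with E[|eta|] = 0.027, and coverage 10x, which at this
#' population size reproduces the sampling-error-to-drift variance ratio
#' of a 100x experiment on populations of 1,000.
#'
#' @inheritParams study_null_calibration
#' @param coverage expected reads per site.
#' @return data.frame with `va_true`, `va_with` (error structure fitted),
#'   `va_without`, `sigma2_o`.
#' @export
study_poolseq <- function(n_sims = 8, seed = 1, coverage = 10) {
  NE <- experiment_effective_size(100)
  out <- lapply(seq_len(n_sims), function(i) {
    sim <- run_experiment(sim_config(n_loci = 300, region_length = 1e5,
                                     N0 = 100, n_replicates = 5,
                                     n_generations = 3,
                                     dfe = dfe_config(scale = 0.09,
                                                      frac_neutral = 0),
                                     seed = study_seed(seed, 200L + i)),
                          keep_haplotypes = TRUE)
    ps <- poolseq_experiment(sim, poolseq_config(coverage = coverage,
                                                 read_length = 800))
    fw <- vafit(ps$panel, ps$data, generations = 3, Ne = NE)
    fo <- vafit(ps$panel, ps$data, generations = 3, Ne = NE,
                use_poolseq = FALSE)
    data.frame(va_true = sim$truth$VA_true, va_with = fw$estimate$va,
               va_without = fo$estimate$va, sigma2_o = fw$fit$sigma2_o)
  })
  do.call(rbind, out)
}

#' Selected-history study: sign recovery at mutation-selection balance
#'
#' Experiments whose base populations evolved under selection (a
#' scaled-down selected burn-in with deleterious mutations attached to
#' derived alleles).  At mutation-selection-drift balance the fitted
#' diversity-power exponent is negative and the frequency-effect
#' coefficient positive.
#'
#' @inheritParams study_null_calibration
#' @return data.frame with `va_true`, `va_hat`, `p_alpha`, `beta1`,
#'   `residual_variance`.
#' @export
study_selected <- function(n_sims = 10, seed = 1) {
  NE <- experiment_effective_size(200)
  out <- lapply(seq_len(n_sims), function(i) {
    sim <- run_experiment(sim_config(n_loci = 500, N0 = 200,
                                     n_replicates = 10, n_generations = 3,
                                     history_mode = "selected-burnin",
                                     dfe = dfe_config(scale = 0.066,
                                                      frac_neutral = 0.5),
                                     seed = study_seed(seed, 300L + i)))
    fit <- vafit(sim$panel, sim$data, generations = 3, Ne = NE)
    data.frame(va_true = sim$truth$VA_true, va_hat = fit$estimate$va,
               p_alpha = fit$fit$p_alpha, beta1 = fit$fit$beta1,
               residual_variance = fit$fit$residual_variance)
  })
  do.call(rbind, out)
}
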