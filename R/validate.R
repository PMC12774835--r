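#' End-to-end consistency report
#'
#' Runs the package's fast analytic self-checks and a small simulated
#' parameter-recovery round trip, returning a machine-readable report.
#' Checks: the dominance mapping, the DFE mean, the equivalence of the
#' average-effect and allele-frequency-change forms of VA on random
#' panels, the exactness of the gametic/nongametic split, the whitening
#' invariant of a fitted model, and the sign/magnitude sanity of a small
#' null simulation.
#'
#' @param seed integer seed.
#' @param n_loci,N,n_replicates,n_generations scale of the simulated check.
#' @return list of class `validation_report`; each element has `pass`,
#'   `value` and `detail`.
#' @export
validate_pipeline <- function(seed = 1, n_loci = 120, N = 80,
                              n_replicates = 4, n_generations = 2) {
  set.seed(seed)
  rep_item <- function(pass, value, detail)
    list(pass = isTRUE(pass), value = value, detail = detail)
  out <- list(seed = seed)

  out$dominance_mapping <- rep_item(
    isTRUE(all.equal(dominance_to_h(c(0.5, 0.9)), c(0.25, 0.05))),
    dominance_to_h(c(0.5, 0.9)), "h = (1 - |kappa|)/2 at |kappa| = 0.5, 0.9")

  m <- 0.3 * 0.066
  out$dfe_mean <- rep_item(abs(m - 0.02) < 5e-3, m,
                           "gamma mean shape*scale near 0.02")

  eq_err <- max(vapply(1:20, function(i) {
    H <- matrix(rbinom(40 * 12, 1, 0.5), 40, 12)
    pan <- haplotype_panel(H, seq_len(12) * 100)
    dos <- compute_dosages(pan)
    L <- compute_L(dos)
    a <- rnorm(12)
    abs(va_from_alpha(a, L) - va_from_deltap(drop(L %*% a), L))
  }, numeric(1)))
  out$va_identity <- rep_item(eq_err < 1e-10, eq_err,
                              "alpha'L alpha == dp' L^- dp for dp = L alpha")

  H <- matrix(rbinom(60 * 15, 1, 0.4), 60, 15)
  pan <- haplotype_panel(H, seq_len(15) * 50)
  dec <- decompose_L(pan)
  split_err <- max(abs(dec$L - dec$L1 - dec$L2))
  out$ld_split <- rep_item(split_err < 1e-12, split_err, "L = L' + L'' exact")

  sim <- run_experiment(sim_config(n_loci = n_loci, N0 = N,
                                   n_replicates = n_replicates,
                                   n_generations = n_generations,
                                   seed = seed + 1))
  fit <- vafit(sim$panel, sim$data, generations = n_generations,
               Ne = experiment_effective_size(N))
  out$whitening <- rep_item(fit$whitening_error < 1e-8, fit$whitening_error,
                            "P (L~0 o M) P' = I in a fitted model")
  out$fit_sane <- rep_item(
    fit$fit$converged && fit$fit$residual_variance > 0.3 &&
      fit$fit$residual_variance < 3,
    fit$fit$residual_variance,
    "fit converged with residual variance of order 1")
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("vafit validation report (seed", x$seed, ")\n")
  for (nm in setdiff(names(x), "seed")) {
    it <- x[[nm]]
    cat(sprintf("  [%s] %-18s %s (value %s)\n",
                if (it$pass) "ok" else "FAIL", nm, it$detail,
                paste(signif(unlist(it$value), 4), collapse = ", ")))
  }
  invisible(x)
}
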