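## Top-level model: from a phased base-population panel plus replicated
## allele-frequency changes to a bias-corrected estimate of the additive
## genetic variance for relative fitness.

#' Replicated allele-frequency-change data
#'
#' Bundles the per-replicate start/end allele-frequency vectors of an
#' evolve-and-resequence experiment.  All vectors must be on the same locus
#' set (and order) as the base panel.
#'
#' @param replicates list with one element per replicate; each element a
#'   list with components `p_start` and `p_end` (frequencies in `[0, 1]`)
#'   and optionally `Q_start`, `Q_end` (pool-seq read-span matrices or
#'   inverse-coverage vectors).
#' @param p0 base-population reference-allele frequencies.
#' @return object of class `experiment_data`.
#' @export
experiment_data <- function(replicates, p0) {
  stopifnot(length(replicates) >= 1L)
  nL <- length(p0)
  for (m in seq_along(replicates)) {
    r <- replicates[[m]]
    if (length(r$p_start) != nL || length(r$p_end) != nL)
      stop(sprintf("replicate %d: frequency vectors do not match the locus set", m))
    if (any(r$p_start < 0 | r$p_start > 1 | r$p_end < 0 | r$p_end > 1, na.rm = TRUE))
      stop(sprintf("replicate %d: frequencies outside [0, 1]", m))
  }
  structure(list(replicates = replicates, p0 = as.numeric(p0),
                 q0 = 1 - as.numeric(p0)), class = "experiment_data")
}

#' Estimate the additive genetic variance for fitness
#'
#' `vafit()` is the main entry point.  From a phased base-population
#' haplotype panel and per-replicate allele-frequency changes, it (i)
#' computes the base diversity matrix `L0` and its gametic/nongametic
#' decomposition, (ii) predicts the decay of L under drift and
#' recombination over the observation window, (iii) projects the
#' allele-frequency changes onto the non-null subspace of `L0`, whitened by
#' the expected drift covariance, (iv) fits the REML mixed model for the
#' distribution of average effects ([reml_fit()]), and (v) converts the fit
#' into a bias-corrected estimate of VA in the base population
#' ([estimate_va()]).
#'
#' @param panel a [haplotype_panel()] of the base population; if unphased,
#'   the nongametic part of L is assumed absent (with a warning).
#' @param data an [experiment_data()] object (or a bare list of replicates,
#'   in which case `p0` is taken from the panel).
#' @param generations number of generations over which allele-frequency
#'   change was recorded (`tau_m - tm`); ignored when `design` is given.
#' @param Ne effective size governing the decay of L; defaults to the
#'   census size implied by `N_census`.
#' @param NE effective size governing drift variance; defaults to `Ne`.
#' @param N_census census size of each replicate population (used only to
#'   default `Ne`).
#' @param t_start first observed generation (default 1: replicates founded
#'   from the base population by one round of reproduction; larger values
#'   are accepted with a warning, as changes in L shared across replicates
#'   before `t_start` violate the independence assumption).
#' @param design optional [drift_design()] (shared) or list of designs per
#'   replicate, overriding `generations`/`Ne`/`NE`/`t_start`.
#' @param r_bar uniform crossover rate per bp per generation, used when the
#'   panel has no genetic map.
#' @param p_alpha_bounds,p_alpha_fixed outer search interval for the power
#'   exponent, or a fixed value.
#' @param use_poolseq fit the pool-seq error structure when `Q` matrices
#'   are present in the data (default `TRUE`).
#' @param rel_tol relative eigenvalue threshold for the retained subspace.
#' @return an object of class `vafit`; see [print.vafit()],
#'   [summary.vafit()], [coef.vafit()].
#' @examples
#' sim <- run_experiment(sim_config(n_loci = 80, N0 = 60, n_replicates = 3,
#'                                  n_generations = 2, seed = 1))
#' fit <- vafit(sim$panel, sim$data, generations = 2, N_census = 60)
#' print(fit)
#' @export
vafit <- function(panel, data, generations = NULL, Ne = NULL, NE = NULL,
                  N_census = NULL, t_start = 1L, design = NULL, r_bar = NULL,
                  p_alpha_bounds = c(-2, 1), p_alpha_fixed = NULL,
                  use_poolseq = TRUE, rel_tol = 1e-10) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!inherits(data, "experiment_data"))
    data <- experiment_data(data, p0 = compute_dosages(panel)$p)
  M <- length(data$replicates)

  dos <- compute_dosages(panel)
  L0 <- compute_L(dos)
  decomp <- if (panel$phased) decompose_L(panel) else L0

  if (!is.null(panel$map_pos)) {
    r_matrix <- pairwise_recombination(panel$positions, map_pos = panel$map_pos)
  } else if (!is.null(r_bar)) {
    r_matrix <- pairwise_recombination(panel$positions, r_bar = r_bar)
  } else {
    stop("supply a genetic map in the panel or a uniform rate via r_bar")
  }

  if (is.null(design)) {
    if (is.null(generations)) stop("supply generations or design")
    if (is.null(Ne)) {
      if (is.null(N_census)) stop("supply Ne or N_census")
      Ne <- N_census
    }
    if (is.null(NE)) NE <- Ne
    design <- drift_design(t_start = t_start, t_end = t_start + generations,
                           Ne = Ne, NE = NE)
  }
  designs <- if (inherits(design, "drift_design")) rep(list(design), M) else design
  stopifnot(length(designs) == M)
  if (any(vapply(designs, function(d) d$t_start, integer(1L)) > 1L))
    warning(paste("t_start > 1: changes in L before the first observation are",
                  "shared across replicates and may violate independence;",
                  "founding replicates at generation 1 is preferable"))
  shared_design <- all(vapply(designs[-1L], identical, logical(1L), designs[[1L]]))

  # per-design structures (computed once when shared)
  uniq <- if (shared_design) 1L else seq_len(M)
  systems <- lapply(designs[uniq], function(d) ld_system(decomp, r_matrix, d))
  bases <- lapply(systems, build_projection, L0 = L0, rel_tol = rel_tol)
  sys_of <- function(m) systems[[if (shared_design) 1L else m]]
  basis_of <- function(m) bases[[if (shared_design) 1L else m]]

  # whitening invariant, asserted in every fit
  whitening_err <- max(vapply(seq_along(systems), function(i) {
    W <- bases[[i]]$P %*% systems[[i]]$drift_cov %*% t(bases[[i]]$P)
    max(abs(W - diag(nrow(W))))
  }, numeric(1L)))
  if (whitening_err > 1e-8)
    warning(sprintf("whitening invariant violated: max |P D P' - I| = %.3g",
                    whitening_err))

  pq <- data$p0 - data$q0
  y_list <- vector("list", M); x_list <- vector("list", M)
  for (m in seq_len(M)) {
    dp <- data$replicates[[m]]$p_end - data$replicates[[m]]$p_start
    y_list[[m]] <- project_changes(dp, basis_of(m))
    x_list[[m]] <- fixed_design(basis_of(m), sys_of(m)$scriptL, data$p0, data$q0)
  }

  L0_diag <- diag(L0)
  Z_builder <- function(p_alpha) {
    lapply(uniq, function(i)
      random_structure(bases[[i]], systems[[i]]$scriptL, L0_diag, p_alpha)) ->
      Zu
    if (shared_design) rep(Zu, M) else Zu
  }

  have_Q <- use_poolseq && all(vapply(data$replicates, function(r)
    !is.null(r$Q_start) && !is.null(r$Q_end), logical(1L)))
  E_list <- NULL
  if (have_Q) {
    E_list <- lapply(seq_len(M), function(m) {
      d <- designs[[m]]; sys <- sys_of(m)
      sl_start <- predicted_N_matrix(d$t_start, r_matrix, d$Ne) * sys$L_tilde0
      sl_end <- predicted_N_matrix(d$t_end, r_matrix, d$Ne) * sys$L_tilde0
      poolseq_error_structure(basis_of(m), sl_start, sl_end,
                              data$replicates[[m]]$Q_start,
                              data$replicates[[m]]$Q_end)
    })
  }

  fit <- reml_fit(y_list, x_list, Z_builder, E_list = E_list,
                  p_alpha_bounds = p_alpha_bounds,
                  p_alpha_fixed = p_alpha_fixed,
                  shared = if (is.null(E_list)) NULL else FALSE)
  est <- estimate_va(fit, L0, data$p0)

  NE_assumed <- designs[[1L]]$NE[designs[[1L]]$t_end]
  structure(list(fit = fit, estimate = est, L0 = L0, p0 = data$p0,
                 y = y_list, x = x_list, designs = designs,
                 Z = Z_builder(fit$p_alpha),
                 whitening_error = whitening_err,
                 NE_assumed = NE_assumed,
                 NE_implied = NE_assumed / fit$residual_variance,
                 n_loci = length(data$p0), n_replicates = M,
                 rank = basis_of(1L)$rank, poolseq = have_Q,
                 call = match.call()),
            class = "vafit")
}

#' @export
print.vafit <- function(x, ...) {
  cat("Additive genetic variance for fitness (evolve-and-resequence fit)\n")
  cat(sprintf("  loci: %d; replicates: %d; retained subspace rank: %d%s\n",
              x$n_loci, x$n_replicates, x$rank,
              if (x$poolseq) "; pool-seq error structure" else ""))
  cat(sprintf("  VA-hat = %.5g  (trace %.5g + corrected quadratic %.5g)\n",
              x$estimate$va, x$estimate$trace_term, x$estimate$quad_term))
  cat(sprintf("  p_alpha = %.3f, beta1 = %.4g, residual variance = %.3f\n",
              x$fit$p_alpha, x$fit$beta1, x$fit$residual_variance))
  invisible(x)
}

#' Summary of a vafit model
#' @param object a `vafit` object.
#' @param ... unused.
#' @export
summary.vafit <- function(object, ...) {
  f <- object$fit; e <- object$estimate
  out <- list(
    coefficients = c(p_alpha = f$p_alpha, sigma2_alpha = f$sigma2_alpha,
                     beta1 = f$beta1, S_alpha = f$S_alpha,
                     residual_variance = f$residual_variance,
                     sigma2_o = f$sigma2_o),
    va = c(va = e$va, trace_term = e$trace_term, quad_term = e$quad_term,
           quad_term_raw = e$quad_term_raw, va_uncorrected = e$va_uncorrected),
    loglik = f$loglik, converged = f$converged,
    whitening_error = object$whitening_error,
    NE_assumed = object$NE_assumed, NE_implied = object$NE_implied,
    n_replicates = object$n_replicates, rank = object$rank)
  class(out) <- "summary.vafit"
  out
}

#' @export
print.summary.vafit <- function(x, ...) {
  cat("REML parameter estimates:\n")
  print(round(x$coefficients, 6))
  cat("\nVA decomposition:\n")
  print(signif(x$va, 6))
  cat(sprintf("\nREML loglik %.3f; whitening error %.2g; NE implied %.1f (assumed %.1f)\n",
              x$loglik, x$whitening_error, x$NE_implied, x$NE_assumed))
  invisible(x)
}

#' @export
coef.vafit <- function(object, ...) {
  f <- object$fit
  c(p_alpha = f$p_alpha, sigma2_alpha = f$sigma2_alpha, beta1 = f$beta1,
    residual_variance = f$residual_variance, sigma2_o = f$sigma2_o,
    va = object$estimate$va)
}

#' @export
logLik.vafit <- function(object, ...) {
  val <- object$fit$loglik
  attr(val, "df") <- 3 + (object$fit$sigma2_o > 0)
  attr(val, "nobs") <- object$fit$n_obs
  class(val) <- "logLik"
  val
}

#' Whitened residuals of a vafit model
#'
#' Projected allele-frequency changes minus the fitted fixed effect, per
#' replicate.  Under a correct drift model and no selection these are
#' approximately i.i.d. with variance `sigma2_alpha * diag(ZZ') + phi`.
#'
#' @param object a `vafit` object.
#' @param ... unused.
#' @return list of numeric vectors, one per replicate.
#' @export
residuals.vafit <- function(object, ...) {
  b <- object$fit$beta1
  mapply(function(y, x) y - b * x, object$y, object$x, SIMPLIFY = FALSE)
}

#' Simulate projected changes from a fitted model
#'
#' Parametric draws of the stacked projected allele-frequency changes from
#' the fitted mean and covariance (fixed effect + random locus effects +
#' residual).  Useful for parametric-bootstrap checks.
#'
#' @param object a `vafit` object.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of length `nsim`; each element a list of per-replicate
#'   projected change vectors.
#' @export
simulate.vafit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- object$fit
  M <- object$n_replicates
  # rebuild the shared random factor at the fitted p_alpha
  L0d <- diag(object$L0)
  out <- vector("list", nsim)
  sd_a <- sqrt(max(f$sigma2_alpha, 0))
  keep <- L0d > 0
  for (s in seq_len(nsim)) {
    u <- stats::rnorm(sum(keep)) * sd_a * L0d[keep]^(f$p_alpha / 2)
    # per-replicate: x beta + P scriptL D^{p/2} u + N(0, phi)
    out[[s]] <- lapply(seq_len(M), function(m) {
      x <- object$x[[m]]
      x * f$beta1 + drop(object$Z[[m]] %*% u) +
        stats::rnorm(length(x), sd = sqrt(f$residual_variance))
    })
  }
  out
}

#' Diagnostic plot of a vafit model
#'
#' Normal QQ plot of the standardized whitened residuals; under a correct
#' drift model these should be close to standard normal.
#'
#' @param x a `vafit` object.
#' @param ... passed to [stats::qqnorm()].
#' @export
plot.vafit <- function(x, ...) {
  r <- unlist(residuals(x)) / sqrt(x$fit$residual_variance)
  stats::qqnorm(r, main = "Whitened residuals", ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}
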