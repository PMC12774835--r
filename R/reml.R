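## Restricted maximum likelihood for the projected allele-frequency-change
## mixed model:
##
##   y ~ N( X beta1,  sigma2_alpha * F F' + phi * I + sigma2_o * blockdiag(E_m) )
##
## with y the stacked projected changes, X the stacked fixed-design column,
## F the stacked random-effect factors Z_m(p_alpha), and E_m the optional
## pool-seq error blocks.  beta1 is profiled by GLS; the variance
## components are reduced to ratios gamma1 = sigma2_alpha/phi and
## gamma2 = sigma2_o/phi with phi profiled analytically; the power
## exponent p_alpha is maximized in an outer one-dimensional search.

# ---- general evaluator ------------------------------------------------------

# -2 * restricted log-likelihood profiled over (beta, phi), up to an
# additive constant.  G = F F' (K x K), Ebd = blockdiag(E_m) or NULL.
neg2_reml_general <- function(gamma1, gamma2, y, x, G, Ebd) {
  K <- length(y)
  V0 <- gamma1 * G
  if (!is.null(Ebd)) V0 <- V0 + gamma2 * Ebd
  diag(V0) <- diag(V0) + 1
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(value = Inf))
  logdet <- 2 * sum(log(diag(R)))
  M <- backsolve(R, forwardsolve(t(R), cbind(y, x)))
  yv <- M[, 1L]; xv <- M[, 2L]
  a <- sum(x * xv)
  has_beta <- a > 1e-12 * max(sum(x^2), 1e-300)
  if (has_beta) {
    b <- sum(x * yv)
    beta <- b / a
    rss <- sum(y * yv) - b^2 / a
    df <- K - 1L
    val <- df * log(rss / df) + logdet + log(a)
  } else {
    beta <- 0
    rss <- sum(y * yv)
    df <- K
    val <- df * log(rss / df) + logdet
  }
  phi <- rss / df
  list(value = val, beta = beta, phi = phi, a = a, df = df, has_beta = has_beta)
}

# ---- fast evaluator (shared design, no pool-seq term) -----------------------

# Replicates are exchangeable when they share x0 and Z0 and there is no
# pool-seq block: the selection covariance is gamma1 * (J_M kron G0), so
# the model splits into the replicate-average mode (covariance
# phi * (gamma1 * M * G0 + I), mean sqrt(M) x0 beta) and (M-1)*K0
# i.i.d. N(0, phi) contrast modes.  One eigendecomposition of G0 per
# p_alpha makes every inner evaluation O(K0).
fast_context <- function(y_list, x0, Z0) {
  M <- length(y_list)
  K0 <- length(x0)
  Y <- matrix(unlist(y_list), nrow = K0)
  ybar <- rowMeans(Y)
  e <- eigen(tcrossprod(Z0), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  Q <- e$vectors
  list(M = M, K0 = K0, K = M * K0,
       yt = drop(crossprod(Q, sqrt(M) * ybar)),
       xt = drop(crossprod(Q, sqrt(M) * x0)),
       lam = lam,
       ss_contrast = sum(Y^2) - M * sum(ybar^2))
}

neg2_reml_fast <- function(gamma1, ctx) {
  w <- 1 + gamma1 * ctx$M * ctx$lam
  yt <- ctx$yt; xt <- ctx$xt
  a <- sum(xt^2 / w)
  has_beta <- a > 1e-12 * max(sum(xt^2), 1e-300)
  logdet <- sum(log(w))
  if (has_beta) {
    b <- sum(xt * yt / w)
    beta <- b / a
    rss <- sum((yt - xt * beta)^2 / w) + ctx$ss_contrast
    df <- ctx$K - 1L
    val <- df * log(rss / df) + logdet + log(a)
  } else {
    beta <- 0
    rss <- sum(yt^2 / w) + ctx$ss_contrast
    df <- ctx$K
    val <- df * log(rss / df) + logdet
  }
  phi <- rss / df
  list(value = val, beta = beta, phi = phi, a = a, df = df, has_beta = has_beta)
}

# ---- inner optimization over variance ratios --------------------------------

# gamma1 on a log grid refined by optimize(); the sigma2_alpha = 0 boundary
# is checked explicitly.
LOG_GAMMA_RANGE <- c(-34, 12)

inner_fit_fast <- function(ctx) {
  f <- function(s) neg2_reml_fast(exp(s), ctx)$value
  opt <- stats::optimize(f, LOG_GAMMA_RANGE, tol = 1e-4)
  cand <- neg2_reml_fast(exp(opt$minimum), ctx)
  zero <- neg2_reml_fast(0, ctx)
  if (zero$value <= cand$value + 1e-8) {
    c(zero, list(gamma1 = 0, gamma2 = 0))
  } else {
    c(cand, list(gamma1 = exp(opt$minimum), gamma2 = 0))
  }
}

inner_fit_general <- function(y, x, G, Ebd) {
  if (is.null(Ebd)) {
    f <- function(s) neg2_reml_general(exp(s), 0, y, x, G, NULL)$value
    opt <- stats::optimize(f, LOG_GAMMA_RANGE, tol = 1e-4)
    cand <- neg2_reml_general(exp(opt$minimum), 0, y, x, G, NULL)
    zero <- neg2_reml_general(0, 0, y, x, G, NULL)
    if (zero$value <= cand$value + 1e-8) c(zero, list(gamma1 = 0, gamma2 = 0))
    else c(cand, list(gamma1 = exp(opt$minimum), gamma2 = 0))
  } else {
    f2 <- function(par) neg2_reml_general(exp(par[1L]), exp(par[2L]),
                                          y, x, G, Ebd)$value
    best <- NULL
    for (start in list(c(-8, 0), c(-14, 0))) {
      o <- stats::optim(start, f2, method = "Nelder-Mead",
                        control = list(reltol = 1e-7, maxit = 300))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # sigma2_alpha = 0 boundary, gamma2 free
    fb <- function(s2) neg2_reml_general(0, exp(s2), y, x, G, Ebd)$value
    ob <- stats::optimize(fb, LOG_GAMMA_RANGE, tol = 1e-4)
    if (ob$objective <= best$value + 1e-8) {
      cand <- neg2_reml_general(0, exp(ob$minimum), y, x, G, Ebd)
      c(cand, list(gamma1 = 0, gamma2 = exp(ob$minimum)))
    } else {
      g <- exp(best$par)
      cand <- neg2_reml_general(g[1L], g[2L], y, x, G, Ebd)
      c(cand, list(gamma1 = g[1L], gamma2 = g[2L]))
    }
  }
}

# ---- full REML fit ----------------------------------------------------------

#' REML fit of the projected allele-frequency-change model
#'
#' Fits, by restricted maximum likelihood, the linear mixed model for
#' stacked projected allele-frequency changes: fixed effect `beta1` on the
#' projected `scriptL (p0 - q0)` column, a random locus effect with
#' variance `sigma2_alpha * L0_ii^p_alpha` inducing the between-replicate
#' covariance, a residual (drift-scale) variance `phi` with expectation 1
#' under a correct drift model, and optionally a pool-seq error variance
#' `sigma2_o` on supplied per-replicate error blocks.  Conditional on
#' `p_alpha` the problem is a standard mixed model (solved with profiled
#' GLS and analytic profiling of `phi`); `p_alpha` itself is maximized by a
#' bounded one-dimensional search.
#'
#' @param y_list list of projected change vectors, one per replicate.
#' @param x_list list of fixed-design vectors (see [fixed_design()]).
#' @param Z_builder function(p_alpha) returning the list of per-replicate
#'   random factors `Z_m` (see [random_structure()]).
#' @param E_list optional list of pool-seq error blocks (see
#'   [poolseq_error_structure()]); when supplied, `sigma2_o` is fitted.
#' @param p_alpha_bounds search interval for the power exponent.
#' @param p_alpha_fixed fix `p_alpha` instead of estimating it.
#' @param shared set `TRUE` when all replicates share the same design and
#'   structures (enables a fast exchangeable-replicate solver); detected
#'   automatically when `x_list` entries are identical.
#' @return object of class `va_model_fit` with elements `p_alpha`,
#'   `sigma2_alpha`, `beta1`, `S_alpha`, `residual_variance`, `sigma2_o`,
#'   `loglik`, `converged`, `n_obs`, `df`.
#' @export
reml_fit <- function(y_list, x_list, Z_builder, E_list = NULL,
                     p_alpha_bounds = c(-2, 1), p_alpha_fixed = NULL,
                     shared = NULL) {
  M <- length(y_list)
  stopifnot(M == length(x_list), M >= 2L)
  if (M < 3L) warning("fewer than 3 replicates: variance components are weakly identified")
  if (is.null(shared)) {
    shared <- is.null(E_list) && M > 1L &&
      all(vapply(x_list[-1L], function(x)
        isTRUE(all.equal(x, x_list[[1L]], tolerance = 1e-12)), logical(1L)))
  }
  K <- sum(lengths(y_list))

  inner_at <- function(p_alpha) {
    Zs <- Z_builder(p_alpha)
    if (!is.list(Zs)) Zs <- rep(list(Zs), M)
    if (shared) {
      ctx <- fast_context(y_list, x_list[[1L]], Zs[[1L]])
      c(inner_fit_fast(ctx), list(ctx = ctx))
    } else {
      y <- unlist(y_list, use.names = FALSE)
      x <- unlist(x_list, use.names = FALSE)
      Fm <- do.call(rbind, Zs)
      G <- tcrossprod(Fm)
      Ebd <- NULL
      if (!is.null(E_list)) {
        Ebd <- matrix(0, K, K)
        off <- 0L
        for (m in seq_len(M)) {
          km <- length(y_list[[m]])
          idx <- off + seq_len(km)
          Ebd[idx, idx] <- E_list[[m]]
          off <- off + km
        }
      }
      c(inner_fit_general(y, x, G, Ebd), list(ctx = NULL))
    }
  }

  if (!is.null(p_alpha_fixed)) {
    p_hat <- p_alpha_fixed
    outer_conv <- TRUE
  } else {
    prof <- function(p) inner_at(p)$value
    op <- stats::optimize(prof, p_alpha_bounds, tol = 1e-2)
    p_hat <- op$minimum
    outer_conv <- TRUE
  }
  fit <- inner_at(p_hat)

  phi <- fit$phi
  sigma2_alpha <- fit$gamma1 * phi
  sigma2_o <- if (is.null(E_list)) 0 else fit$gamma2 * phi
  S_alpha <- if (fit$has_beta) phi / fit$a else 0
  # full REML log-likelihood at the optimum (constants included)
  loglik <- -0.5 * (fit$value + fit$df * (1 + log(2 * pi)))
  structure(list(p_alpha = p_hat, sigma2_alpha = sigma2_alpha,
                 beta1 = fit$beta, S_alpha = S_alpha,
                 residual_variance = phi, sigma2_o = sigma2_o,
                 loglik = loglik, converged = outer_conv && is.finite(fit$value),
                 boundary_sigma2_alpha = fit$gamma1 == 0,
                 n_obs = K, df = fit$df, n_replicates = M, shared = shared),
            class = "va_model_fit")
}

#' @export
print.va_model_fit <- function(x, ...) {
  cat("Projected allele-frequency-change REML fit\n")
  cat(sprintf("  replicates: %d, projected observations: %d\n",
              x$n_replicates, x$n_obs))
  cat(sprintf("  p_alpha        = %8.4f\n", x$p_alpha))
  cat(sprintf("  sigma2_alpha   = %8.4g%s\n", x$sigma2_alpha,
              if (x$boundary_sigma2_alpha) " (boundary)" else ""))
  cat(sprintf("  beta1          = %8.4g (sampling var %.3g)\n",
              x$beta1, x$S_alpha))
  cat(sprintf("  residual var   = %8.4f (drift-model expectation 1)\n",
              x$residual_variance))
  if (x$sigma2_o > 0)
    cat(sprintf("  sigma2_o       = %8.4f\n", x$sigma2_o))
  cat(sprintf("  REML loglik    = %.3f\n", x$loglik))
  invisible(x)
}

#' Bias-corrected VA estimate from a model fit
#'
#' Combines the fitted average-effect distribution with the
#' base-population diversity matrix: the random (trace) component is
#' `sigma2_alpha * sum_i L0_ii^(p_alpha + 1)` over segregating loci, and
#' the fixed (quadratic) component is `beta1^2 * (p0-q0)' L0 (p0-q0)`
#' corrected downward by its sampling-error bias
#' `S_alpha * (p0-q0)' L0 (p0-q0)`.  The corrected quadratic term may be
#' negative; it is reported as-is so the estimator stays unbiased in the
#' mean (both raw and corrected values are returned).
#'
#' @param fit a `va_model_fit` from [reml_fit()].
#' @param L0 base-population diversity matrix.
#' @param p0 base-population reference-allele frequencies.
#' @return list of class `va_estimate` with `va`, `trace_term`,
#'   `quad_term`, `quad_term_raw`, `quad_correction`, `va_uncorrected`.
#' @export
estimate_va <- function(fit, L0, p0) {
  stopifnot(inherits(fit, "va_model_fit"))
  d <- diag(L0)
  seg <- d > 0
  trace_term <- fit$sigma2_alpha * sum(d[seg]^(fit$p_alpha + 1))
  xpq <- p0 - (1 - p0)
  qf <- drop(crossprod(xpq, L0 %*% xpq))
  quad_raw <- fit$beta1^2 * qf
  corr <- fit$S_alpha * qf
  structure(list(va = trace_term + quad_raw - corr,
                 trace_term = trace_term,
                 quad_term = quad_raw - corr,
                 quad_term_raw = quad_raw,
                 quad_correction = corr,
                 va_uncorrected = trace_term + quad_raw),
            class = "va_estimate")
}

#' @export
print.va_estimate <- function(x, ...) {
  cat(sprintf("VA estimate: %.5g\n", x$va))
  cat(sprintf("  trace (random) term : %.5g\n", x$trace_term))
  cat(sprintf("  quadratic (fixed)   : %.5g (raw %.5g, bias correction %.5g)\n",
              x$quad_term, x$quad_term_raw, x$quad_correction))
  invisible(x)
}
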