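## Diversity / LD matrices and exact average-effect identities on a fully
## observed base population.

# population covariance (divisor n, not n-1) of the columns of X about
# `center` (defaults to column means)
pop_cov <- function(X, Y = X, center_x = colMeans(X), center_y = colMeans(Y)) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, center_x, check.margin = FALSE)
  Yc <- sweep(Y, 2L, center_y, check.margin = FALSE)
  crossprod(Xc, Yc) / n
}

#' Diversity/LD matrix L of genotype dosages
#'
#' `L` is the nL x nL population covariance matrix (divisor N) of the
#' dosages `c` across individuals: diagonal elements are the dosage
#' variances at each locus, off-diagonals the dosage covariances, which are
#' proportional to linkage disequilibria.
#'
#' @param dosages a `genotype_dosages` object (see [compute_dosages()]) or a
#'   plain N x nL dosage matrix.
#' @return symmetric nL x nL matrix.
#' @export
compute_L <- function(dosages) {
  c_mat <- if (inherits(dosages, "genotype_dosages")) dosages$c else as.matrix(dosages)
  if (nrow(c_mat) < 2L) {
    # a single individual has zero dosage variance by definition
    L <- matrix(0, ncol(c_mat), ncol(c_mat))
    dimnames(L) <- list(colnames(c_mat), colnames(c_mat))
    return(L)
  }
  L <- pop_cov(c_mat)
  (L + t(L)) / 2
}

#' Gametic / nongametic decomposition of L
#'
#' Splits L into a gametic-phase part `L1` ("L prime"), half the population
#' covariance of allele indicators over the 2N haploid gametic
#' contributions, and a nongametic part `L2` ("L double prime") from the
#' cross-covariances between the two gametic contributions within diploids.
#' All covariances are centred on the pooled allele frequency p so that
#' `L = L1 + L2` holds exactly.  Diagonals of `L1` are proportional to
#' gametic gene diversity; diagonals of `L2` to the additive
#' Hardy-Weinberg disequilibrium coefficients.
#'
#' @param panel a phased [haplotype_panel()].
#' @return list of class `ld_decomposition` with `L`, `L1` (gametic), `L2`
#'   (nongametic), `p`.
#' @export
decompose_L <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!panel$phased)
    stop("panel is unphased: the gametic/nongametic split of L is unavailable")
  H <- panel$haplotypes
  N <- nrow(H) %/% 2L
  G1 <- H[seq(1L, 2L * N, by = 2L), , drop = FALSE]
  G2 <- H[seq(2L, 2L * N, by = 2L), , drop = FALSE]
  p <- colMeans(H)
  # L' = (1/2) * covariance over all 2N gametic rows, centred on p
  L1 <- (pop_cov(G1, G1, p, p) + pop_cov(G2, G2, p, p)) / 4
  # L'' = (1/4) * [cov(g1_i, g2_j) + cov(g2_i, g1_j)], centred on p
  C12 <- pop_cov(G1, G2, p, p)
  L2 <- (C12 + t(C12)) / 4
  L1 <- (L1 + t(L1)) / 2
  L <- compute_L(compute_dosages(panel))
  structure(list(L = L, L1 = L1, L2 = L2, p = p), class = "ld_decomposition")
}

# Moore-Penrose pseudoinverse restricted to the numerically non-null
# eigenspace (relative threshold on eigenvalues).
pinv_sym <- function(A, rel_tol = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > rel_tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  U <- e$vectors[, keep, drop = FALSE]
  U %*% (t(U) / e$values[keep])
}

#' Exact average effects in a fully observed population
#'
#' Fisher's average effects for relative fitness are the multiple-regression
#' coefficients of relative fitness on the dosages: `alpha = L^- COV(c, w)`,
#' with a Moore-Penrose pseudoinverse on the non-null eigenspace of L when
#' nL exceeds the rank of the dosage matrix.
#'
#' @param dosages `genotype_dosages` or N x nL dosage matrix.
#' @param w relative fitnesses (rescaled internally to mean 1).
#' @param rel_tol relative eigenvalue threshold of the pseudoinverse.
#' @return numeric vector alpha of length nL.
#' @export
average_effects_exact <- function(dosages, w, rel_tol = 1e-10) {
  c_mat <- if (inherits(dosages, "genotype_dosages")) dosages$c else as.matrix(dosages)
  w <- as.numeric(w)
  stopifnot(length(w) == nrow(c_mat))
  w <- w / mean(w)
  L <- compute_L(c_mat)
  covcw <- drop(pop_cov(c_mat, matrix(w, ncol = 1L)))
  drop(pinv_sym(L, rel_tol) %*% covcw)
}

#' Additive genetic variance from average effects or expected change
#'
#' `va_from_alpha()` evaluates `VA = alpha' L alpha`, the variance of
#' breeding values.  `va_from_deltap()` evaluates the equivalent
#' `VA = E[dp]' L^- E[dp]`, defined on the column space of L; a component of
#' `E[dp]` outside the column space (beyond `tol` relative) triggers a
#' warning and is projected away.
#'
#' @param alpha average effects.
#' @param L diversity matrix.
#' @param deltap expected allele-frequency change due to selection.
#' @param rel_tol eigenvalue threshold of the pseudoinverse.
#' @param tol relative tolerance on the out-of-column-space component.
#' @return nonnegative scalar VA.
#' @export
va_from_alpha <- function(alpha, L) {
  drop(crossprod(alpha, L %*% alpha))
}

#' @rdname va_from_alpha
#' @export
va_from_deltap <- function(deltap, L, rel_tol = 1e-10, tol = 1e-6) {
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  keep <- e$values > rel_tol * max(e$values, 0)
  U <- e$vectors[, keep, drop = FALSE]
  proj <- drop(U %*% crossprod(U, deltap))
  resid <- sqrt(sum((deltap - proj)^2))
  if (resid > tol * max(sqrt(sum(deltap^2)), .Machine$double.eps)) {
    warning(sprintf(
      "E[dp] has a component outside the column space of L (|resid| = %.3g); projecting",
      resid))
  }
  z <- crossprod(U, deltap) / sqrt(e$values[keep])
  drop(crossprod(z))
}

#' Average effect for log fitness under dominance
#'
#' Converts a locus effect on log absolute fitness `eta` and a dominance
#' degree `kappa` into the average effect for log fitness,
#' `eta_a = eta * (1 + kappa * (q - p))`.
#'
#' @param eta effects on log absolute fitness.
#' @param kappa dominance degrees in `[-1, 1]` (0 additive, -1 the
#'   reference allele fully recessive... sign convention as in
#'   [sample_dfe()]).
#' @param p reference-allele frequencies.
#' @return vector of average effects for log fitness.
#' @export
eta_to_average_effect <- function(eta, kappa, p) {
  eta * (1 + kappa * ((1 - p) - p))
}

#' Dominance coefficient h implied by |kappa|
#'
#' Under the within-locus scheme the heterozygote contributes
#' `(1 + kappa) * eta / 2` to log fitness.  For a deleterious allele with
#' selection coefficient `s = |eta|` and heterozygous fitness written
#' `1 - h s`, this implies `h = (1 - |kappa|) / 2`:
#' `|kappa| = 0.5` gives h = 0.25 and `|kappa| = 0.9` gives h = 0.05, while
#' `kappa = 0` is codominance (h = 0.5).
#'
#' @param kappa_abs `|kappa|` in `[0, 1]`.
#' @return dominance coefficient h.
#' @export
dominance_to_h <- function(kappa_abs) {
  if (any(kappa_abs < 0) || any(kappa_abs > 1))
    stop("|kappa| must lie in [0, 1]")
  (1 - kappa_abs) / 2
}

#' Genic/genetic decomposition of the selection response
#'
#' Writes `L = B R B` with B the diagonal matrix of dosage standard
#' deviations and R the correlation matrix, and splits the expected
#' response `L alpha` into the direct response at each locus,
#' `dSp = B^2 alpha`, and the response through linkage disequilibrium with
#' other loci, `dLp = B (R - I) B alpha`.  The additive genic variance is
#' `Va = alpha' B^2 alpha`; the additive genetic variance
#' `VA = alpha' L alpha` additionally captures the LD contributions.
#'
#' @param alpha average effects.
#' @param L diversity matrix (or an `ld_decomposition`, whose `L` is used).
#' @return list with `Va`, `VA`, `dSp`, `dLp`, `B` (vector of standard
#'   deviations) and `R`.
#' @export
genic_decomposition <- function(alpha, L) {
  if (inherits(L, "ld_decomposition")) L <- L$L
  b <- sqrt(pmax(diag(L), 0))
  R <- diag(ncol(L))
  pos <- b > 0
  if (any(pos))
    R[pos, pos] <- L[pos, pos, drop = FALSE] / tcrossprod(b[pos])
  dSp <- b^2 * alpha
  dLp <- drop(L %*% alpha) - dSp
  list(Va = sum(alpha^2 * b^2), VA = va_from_alpha(alpha, L),
       dSp = dSp, dLp = dLp, B = b, R = R)
}

#' Variance-effective population size from offspring-number variance
#'
#' `NE = 4 N / (2 + Vo)`, where N is the census size and Vo the variance in
#' offspring number in the absence of additive fitness variance.  Poisson
#' (Wright-Fisher-like) reproduction has Vo = 2 and NE = N.
#'
#' @param N census population size.
#' @param Vo neutral offspring-number variance.
#' @return effective size NE.
#' @export
effective_size <- function(N, Vo) {
  stopifnot(N >= 1, Vo >= 0)
  4 * N / (2 + Vo)
}
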