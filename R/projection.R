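## Projection of allele-frequency changes onto the non-null subspace of L0,
## whitened with respect to the expected drift covariance.

#' Whitening projection onto the non-null subspace of L0
#'
#' Let `U_L` hold the eigenvectors of `L0` with retained eigenvalues
#' (relative threshold `rel_tol`).  The expected drift covariance of the
#' reduced allele-frequency changes is `A = U_L' (L_tilde0 o M) U_L`; with
#' `A = U2 D2^2 U2'` its eigendecomposition, the projection
#' `P = D2^{-1} U2' U_L'` makes projected changes i.i.d. with unit variance
#' under drift: `P (L_tilde0 o M) P' = I`.
#'
#' @param ld an `ld_system` (see [ld_system()]) for one replicate design.
#' @param L0 base-population diversity matrix.
#' @param rel_tol relative eigenvalue threshold for retaining directions of
#'   `L0`; directions of the reduced drift matrix that are numerically
#'   singular are likewise dropped (a message reports the count).
#' @return object of class `projection_basis` with the projection matrix
#'   `P` (rank x nL), `U_L`, and the retained rank.
#' @export
build_projection <- function(ld, L0, rel_tol = 1e-10) {
  stopifnot(inherits(ld, "ld_system"))
  eL <- eigen((L0 + t(L0)) / 2, symmetric = TRUE)
  keepL <- eL$values > rel_tol * max(eL$values, 0)
  U_L <- eL$vectors[, keepL, drop = FALSE]
  A <- crossprod(U_L, ld$drift_cov %*% U_L)
  eA <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keepA <- eA$values > rel_tol * max(eA$values, 0)
  if (sum(!keepA) > 0L)
    message(sprintf("dropping %d numerically singular drift direction(s)",
                    sum(!keepA)))
  U2 <- eA$vectors[, keepA, drop = FALSE]
  d2 <- sqrt(eA$values[keepA])
  P <- (t(U2) / d2) %*% t(U_L)
  structure(list(P = P, U_L = U_L, rank = length(d2), d2 = d2),
            class = "projection_basis")
}

#' Project allele-frequency changes
#'
#' @param deltap allele-frequency change vector (length nL) or a matrix
#'   with one column per replicate.
#' @param basis a `projection_basis` from [build_projection()].
#' @return projected change(s): vector of length `basis$rank`, or matrix.
#' @export
project_changes <- function(deltap, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  dp <- as.matrix(deltap)
  if (nrow(dp) != ncol(basis$P)) stop("locus dimension mismatch with projection")
  out <- basis$P %*% dp
  if (ncol(out) == 1L) drop(out) else out
}

#' Fixed-effect design column of a replicate
#'
#' The mean model for the average effects is
#' `mu_alpha = beta1 * (p0 - q0)`, so the projected mean of replicate m is
#' `beta1 * P scriptL_m (p0 - q0)`; this returns the design column
#' `x_m = P scriptL_m (p0 - q0)`.
#'
#' @param basis `projection_basis`.
#' @param scriptL summed predicted LD matrix of the replicate.
#' @param p0,q0 base-population reference/alternative allele frequencies.
#' @return numeric vector of length `basis$rank`.
#' @export
fixed_design <- function(basis, scriptL, p0, q0 = 1 - p0) {
  drop(basis$P %*% (scriptL %*% (p0 - q0)))
}

#' Random-effect factor of a replicate
#'
#' The variance model for the average effects is
#' `V_alpha = sigma2_alpha * diag(L0_ii^p_alpha)` (the diagonal variant).
#' The projected between-replicate covariance block is then
#' `sigma2_alpha * Z_m Z_n'` with factor
#' `Z_m = P scriptL_m diag(L0_ii^(p_alpha / 2))`.  Loci with nonpositive
#' diversity are excluded from the factor (they carry no information and
#' the power is undefined there).
#'
#' @param basis `projection_basis`.
#' @param scriptL summed predicted LD matrix of the replicate.
#' @param L0_diag diagonal of L0 (per-locus dosage variances).
#' @param p_alpha power exponent linking average-effect variance to
#'   diversity.
#' @return matrix `Z_m` (rank x n_retained_loci).
#' @export
random_structure <- function(basis, scriptL, L0_diag, p_alpha) {
  keep <- L0_diag > 0
  if (!all(keep) && p_alpha != 0)
    warning(sprintf("excluding %d zero-diversity locus/loci from the random structure",
                    sum(!keep)))
  w <- L0_diag[keep]^(p_alpha / 2)
  # scriptL %*% diag(w), restricted to retained loci
  Zcols <- sweep(scriptL[, keep, drop = FALSE], 2L, w, `*`, check.margin = FALSE)
  basis$P %*% Zcols
}

#' Pool-seq error covariance block of a replicate
#'
#' Frequency-estimation noise from pooled sequencing at the two
#' observation time points adds, per replicate, the covariance
#' `E_m = 2 sigma2_o * P (scriptL_tm o Q_tm + scriptL_tau o Q_tau) P'`.
#' By default only the diagonal of each Hadamard product is used (the
#' approximate covariance structure); `Q` diagonals are inverse coverages.
#'
#' @param basis `projection_basis`.
#' @param scriptL_start,scriptL_end predicted LD matrices at the first and
#'   last observed generations (from `predicted_scriptL()$per_gen`).
#' @param Q_start,Q_end read-span Q matrices at the two time points (dense
#'   or diagonal vectors of inverse coverage); zero-coverage loci must
#'   already be masked.
#' @param diagonal use the diagonal approximation (default TRUE).
#' @return symmetric rank x rank matrix to be scaled by `sigma2_o`.
#' @export
poolseq_error_structure <- function(basis, scriptL_start, scriptL_end,
                                    Q_start, Q_end, diagonal = TRUE) {
  had <- function(sl, Q) {
    if (is.null(dim(Q))) {            # Q supplied as diagonal vector
      if (diagonal) diag(diag(sl) * Q) else stop("dense Q required for full structure")
    } else if (diagonal) {
      diag(diag(sl) * diag(Q))
    } else {
      sl * Q
    }
  }
  S <- had(scriptL_start, Q_start) + had(scriptL_end, Q_end)
  E <- 2 * basis$P %*% S %*% t(basis$P)
  (E + t(E)) / 2
}
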