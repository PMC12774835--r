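test_that("the projection whitens the drift covariance", {
  set.seed(20)
  for (i in 1:5) {
    s <- random_system(n_hap = sample(20:50, 1), n_loci = sample(6:14, 1))
    W <- s$basis$P %*% s$sys$drift_cov %*% t(s$basis$P)
    expect_lt(max(abs(W - diag(nrow(W)))), 1e-8)
  }
})

test_that("retained rank is bounded by the haplotype count", {
  set.seed(21)
  pan <- random_panel(10, 25)   # nL > 2N
  dec <- decompose_L(pan)
  r <- pairwise_recombination(pan$positions, r_bar = 1e-8)
  sys <- ld_system(dec, r, drift_design(1, 3, 50))
  basis <- build_projection(sys, compute_L(compute_dosages(pan)))
  expect_lte(basis$rank, 10)
})

test_that("diagonal systems give a projection diagonal up to sign", {
  # L0 full-rank diagonal and a constant drift weight: P must align with
  # the coordinate axes (one nonzero entry per row)
  L0 <- diag(c(0.21, 0.12, 0.05, 0.17))
  sys <- list(drift_cov = L0 * 0.01, L_tilde0 = L0,
              scriptL = L0, M = matrix(0.01, 4, 4),
              design = drift_design(1, 2, 50))
  class(sys) <- "ld_system"
  basis <- build_projection(sys, L0)
  nonzero_per_row <- rowSums(abs(basis$P) > 1e-8)
  expect_equal(unname(nonzero_per_row), rep(1, 4))
  W <- basis$P %*% sys$drift_cov %*% t(basis$P)
  expect_lt(max(abs(W - diag(4))), 1e-10)
})

test_that("projection maps zero and null-space changes to zero", {
  set.seed(22)
  s <- random_system(n_hap = 10, n_loci = 14)  # rank-deficient L0
  expect_equal(project_changes(numeric(14), s$basis), rep(0, s$basis$rank))
  eL <- eigen(s$L0, symmetric = TRUE)
  null_vec <- eL$vectors[, 14]
  expect_lt(max(abs(project_changes(null_vec, s$basis))), 1e-6)
  expect_error(project_changes(numeric(5), s$basis), "mismatch")
})

test_that("the fixed design column is P scriptL (p0 - q0)", {
  set.seed(23)
  s <- random_system()
  nL <- ncol(s$L0)
  # p0 = q0 = 0.5 everywhere: no information about the coefficient
  expect_equal(fixed_design(s$basis, s$sys$scriptL, rep(0.5, nL)),
               rep(0, s$basis$rank))
  p0 <- compute_dosages(s$panel)$p
  x1 <- fixed_design(s$basis, s$sys$scriptL, p0)
  expect_equal(fixed_design(s$basis, 2 * s$sys$scriptL, p0), 2 * x1)
  # diagonal scriptL: elementwise-scaled projection of p0 - q0
  D <- diag(seq_len(nL) / 10)
  expect_equal(fixed_design(s$basis, D, p0),
               drop(s$basis$P %*% (diag(D) * (2 * p0 - 1))))
})

test_that("random structure blocks match the hand-computed formula", {
  set.seed(24)
  s <- random_system()
  L0d <- diag(s$L0)
  # p_alpha = 0: Z = P scriptL, block = P scriptL scriptL' P'
  Z0 <- random_structure(s$basis, s$sys$scriptL, L0d, 0)
  expect_equal(Z0, s$basis$P %*% s$sys$scriptL, tolerance = 1e-12)
  # p_alpha = -1: each locus weighted by 1 / L0_ii
  Zm1 <- random_structure(s$basis, s$sys$scriptL, L0d, -1)
  block <- tcrossprod(Zm1)
  expected <- s$basis$P %*% s$sys$scriptL %*% diag(1 / L0d) %*%
    t(s$sys$scriptL) %*% t(s$basis$P)
  expect_equal(block, expected, tolerance = 1e-10)
  # two-locus toy, everything diagonal: enumerate the formula by hand
  L0 <- diag(c(0.2, 0.1))
  sys <- list(drift_cov = L0 * 0.02, scriptL = diag(c(0.18, 0.09)))
  class(sys) <- "ld_system"
  basis <- build_projection(sys, L0)
  Z <- random_structure(basis, sys$scriptL, diag(L0), -1)
  V <- tcrossprod(Z)
  Vhand <- matrix(0, 2, 2)
  P <- basis$P
  for (i in 1:2) for (j in 1:2) {
    Vhand[i, j] <- sum(P[i, ] * diag(sys$scriptL) * diag(L0)^-1 *
                         diag(sys$scriptL) * P[j, ])
  }
  expect_equal(V, Vhand, tolerance = 1e-12)
  # zero-diversity loci are excluded with a warning
  L0d2 <- L0d; L0d2[1] <- 0
  expect_warning(random_structure(s$basis, s$sys$scriptL, L0d2, -1),
                 "zero-diversity")
})

test_that("pool-seq error blocks scale with inverse coverage", {
  set.seed(25)
  s <- random_system()
  nL <- ncol(s$L0)
  slA <- s$sys$scriptL
  slB <- 0.9 * slA
  # infinite coverage: no error
  E0 <- poolseq_error_structure(s$basis, slA, slB, rep(0, nL), rep(0, nL))
  expect_equal(E0, matrix(0, s$basis$rank, s$basis$rank))
  # diagonal approximation: 2 P diag(scriptL_ii / cov) P' summed over the
  # two time points
  Q <- rep(1 / 100, nL)
  E <- poolseq_error_structure(s$basis, slA, slB, Q, Q)
  Ehand <- 2 * s$basis$P %*% diag((diag(slA) + diag(slB)) / 100) %*% t(s$basis$P)
  expect_equal(E, Ehand, tolerance = 1e-12)
  # doubling coverage halves the block
  E2 <- poolseq_error_structure(s$basis, slA, slB, Q / 2, Q / 2)
  expect_equal(E2, E / 2, tolerance = 1e-12)
  expect_equal(E, t(E))
})
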