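test_that("dosages follow the two-haplotype average and column means give p", {
  # one individual heterozygous at every locus
  pan <- panel_of(c(1, 1, 1), c(0, 0, 0))
  d <- compute_dosages(pan)
  expect_equal(unname(d$c[1, ]), c(0.5, 0.5, 0.5))
  expect_equal(unname(d$p), c(0.5, 0.5, 0.5))

  # monomorphic column of ones, plus the (0,0),(0,1),(1,1) genotype ladder
  pan <- panel_of(c(1, 0), c(1, 0), c(1, 0), c(1, 1), c(1, 1), c(1, 1))
  d <- compute_dosages(pan)
  expect_equal(unname(d$c[, 1]), c(1, 1, 1))
  expect_equal(unname(d$p[1]), 1)
  expect_equal(unname(d$c[, 2]), c(0, 0.5, 1))
  expect_equal(unname(d$p[2]), 0.5)
  expect_true(all(d$c %in% c(0, 0.5, 1)))
  expect_equal(unname(colMeans(d$c)), unname(d$p))

  expect_error(haplotype_panel(matrix(0, 3, 2), c(1, 2)), "even")
})

test_that("L is the population covariance of dosages", {
  pan <- panel_of(c(0, 1), c(0, 1), c(0, 1), c(1, 1), c(1, 1), c(1, 1))
  L <- compute_L(compute_dosages(pan))
  # dosage column (0, 0.5, 1) over N = 3: population variance 1/6
  expect_equal(L[1, 1], 1 / 6)
  # monomorphic second locus: zero row and column
  expect_equal(unname(L[2, ]), c(0, 0))
  # perfectly coupled loci: off-diagonal equals both diagonals
  pan2 <- panel_of(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  L2 <- compute_L(compute_dosages(pan2))
  expect_equal(L2[1, 2], L2[1, 1])
  expect_equal(L2[1, 2], L2[2, 2])
  # symmetric PSD on random panels
  set.seed(1)
  L3 <- compute_L(compute_dosages(random_panel(40, 8)))
  expect_equal(L3, t(L3))
  expect_true(min(eigen(L3, symmetric = TRUE, only.values = TRUE)$values) > -1e-12)
})

test_that("gametic/nongametic split is exact and matches hand enumeration", {
  set.seed(2)
  for (i in 1:5) {
    pan <- random_panel(30, 7)
    dec <- decompose_L(pan)
    expect_equal(dec$L, dec$L1 + dec$L2, tolerance = 1e-12)
  }
  # one individual with coupling haplotypes 11/00: enumerating the two
  # gametes about p = (0.5, 0.5) gives L' = +1/8 off-diagonal; L for a
  # single individual is 0, so L'' must be -1/8
  pan <- panel_of(c(1, 1), c(0, 0))
  dec <- decompose_L(pan)
  expect_equal(dec$L1[1, 2], 1 / 8)
  expect_equal(dec$L2[1, 2], -1 / 8)
  expect_equal(dec$L[1, 2], 0)
})

test_that("random union of gametes leaves nongametic disequilibria near zero", {
  set.seed(3)
  # draw 2N haplotypes, pair them at random: Hardy-Weinberg expectation
  n_hap <- 4000
  p <- c(0.3, 0.6, 0.5)
  H <- matrix(rbinom(n_hap * 3, 1, rep(p, each = n_hap)), n_hap, 3)
  pan <- haplotype_panel(H[sample(n_hap), ], c(100, 200, 300))
  dec <- decompose_L(pan)
  # elements of L'' are averages of ~N products bounded by 1/4:
  # 3 MC standard errors ~ 3 * 0.25 / sqrt(N)
  expect_true(max(abs(dec$L2)) < 3 * 0.25 / sqrt(n_hap / 2))
})

test_that("average effects reproduce an independent least-squares fit", {
  set.seed(4)
  # constant fitness: alpha = 0
  pan <- random_panel(20, 4)
  d <- compute_dosages(pan)
  expect_equal(average_effects_exact(d, rep(1, 10)), rep(0, 4))

  # single segregating locus: simple regression slope
  pan1 <- random_panel(24, 1)
  d1 <- compute_dosages(pan1)
  w <- exp(rnorm(12)); w <- w / mean(w)
  slope <- cov(d1$c[, 1], w) / var(d1$c[, 1])
  expect_equal(average_effects_exact(d1, w), slope, tolerance = 1e-10)

  # full-rank multi-locus panel: matches OLS of w on the dosage columns
  pan2 <- random_panel(60, 3)
  d2 <- compute_dosages(pan2)
  w2 <- exp(rnorm(30)); w2 <- w2 / mean(w2)
  a <- average_effects_exact(d2, w2)
  ols <- unname(coef(lm(w2 ~ d2$c))[-1])
  expect_equal(unname(a), ols, tolerance = 1e-8)

  # fitted values reproduce the best linear predictor: residual orthogonal
  # to every dosage column
  resid <- w2 - mean(w2) - drop(scale(d2$c, scale = FALSE) %*% a)
  expect_lt(max(abs(crossprod(scale(d2$c, scale = FALSE), resid))), 1e-10)
})

test_that("the two VA forms agree and equal the breeding-value variance", {
  set.seed(5)
  expect_equal(va_from_alpha(numeric(4), diag(4)), 0)
  for (i in 1:20) {
    pan <- random_panel(30, 6)
    L <- compute_L(compute_dosages(pan))
    a <- rnorm(6)
    v1 <- va_from_alpha(a, L)
    v2 <- va_from_deltap(drop(L %*% a), L)
    expect_equal(v1, v2, tolerance = 1e-10)
  }
  # VA equals the directly enumerated variance of breeding values
  pan <- random_panel(40, 5)
  d <- compute_dosages(pan)
  w <- exp(rnorm(20)); w <- w / mean(w)
  a <- average_effects_exact(d, w)
  u <- drop(d$c %*% a)
  expect_equal(va_from_alpha(a, compute_L(d)),
               mean((u - mean(u))^2), tolerance = 1e-10)
  # component outside the column space triggers a warning and projection
  pan2 <- random_panel(8, 10)  # nL > N: L rank-deficient
  L2 <- compute_L(compute_dosages(pan2))
  null_vec <- eigen(L2, symmetric = TRUE)$vectors[, 10]
  expect_warning(va_from_deltap(null_vec, L2), "column space")
})

test_that("log-fitness effects map to average effects under dominance", {
  expect_equal(eta_to_average_effect(0.1, 0, 0.3), 0.1)
  expect_equal(eta_to_average_effect(0.1, -0.7, 0.5), 0.1)
  expect_equal(eta_to_average_effect(-0.03, -0.5, 0.9), -0.042)
})

test_that("dominance degree converts to the classical h coefficient", {
  expect_equal(dominance_to_h(0.5), 0.25)
  expect_equal(dominance_to_h(0.9), 0.05)
  expect_equal(dominance_to_h(0), 0.5)
  expect_error(dominance_to_h(1.2), "kappa")
})

test_that("genic/genetic decomposition conserves the response", {
  set.seed(6)
  # no LD: linked response zero, VA equals genic variance
  L <- diag(c(0.1, 0.2, 0.15))
  a <- c(0.5, -0.2, 0.1)
  g <- genic_decomposition(a, L)
  expect_equal(g$dLp, rep(0, 3))
  expect_equal(g$VA, g$Va)
  expect_equal(g$Va, sum(a^2 * diag(L)))
  # with LD: direct + linked responses add to L alpha
  pan <- random_panel(30, 5)
  L2 <- compute_L(compute_dosages(pan))
  a2 <- rnorm(5)
  g2 <- genic_decomposition(a2, L2)
  expect_equal(g2$dSp + g2$dLp, drop(L2 %*% a2), tolerance = 1e-12)
  expect_equal(g2$VA, va_from_alpha(a2, L2), tolerance = 1e-12)
})

test_that("VA is invariant to flipping reference-allele labels", {
  set.seed(7)
  pan <- random_panel(40, 6)
  d <- compute_dosages(pan)
  w <- exp(rnorm(20)); w <- w / mean(w)
  a <- average_effects_exact(d, w)
  va <- va_from_alpha(a, compute_L(d))
  flipped <- flip_reference(pan, c(2, 5))
  d2 <- compute_dosages(flipped)
  a2 <- average_effects_exact(d2, w)
  expect_equal(a2[c(2, 5)], -a[c(2, 5)], tolerance = 1e-10)
  expect_equal(va_from_alpha(a2, compute_L(d2)), va, tolerance = 1e-10)
})

test_that("effective size follows 4N/(2+Vo)", {
  expect_equal(effective_size(500, 2), 500)
  expect_equal(effective_size(500, 0), 1000)
  expect_equal(effective_size(1000, 6), 500)
})
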