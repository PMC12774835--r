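# synthetic shared-design structures for exercising the REML engine
make_structures <- function(K0 = 25, nL = 15, M = 4, seed = 1) {
  set.seed(seed)
  x0 <- rnorm(K0, sd = 0.5)
  B <- matrix(rnorm(K0 * nL, sd = 0.3), K0, nL)
  L0d <- runif(nL, 0.02, 0.25)
  list(K0 = K0, nL = nL, M = M, x0 = x0, B = B, L0d = L0d,
       Zfun = function(p) B %*% diag(L0d^(p / 2)))
}

sim_y <- function(st, beta = 0, sigma2_alpha = 0, phi = 1, p_alpha = 0) {
  Z <- st$Zfun(p_alpha)
  u <- rnorm(st$nL, sd = sqrt(sigma2_alpha))
  lapply(seq_len(st$M), function(m)
    st$x0 * beta + drop(Z %*% u) + rnorm(st$K0, sd = sqrt(phi)))
}

test_that("pure-noise data give residual variance 1 and null effects", {
  st <- make_structures(seed = 30)
  set.seed(31)
  fits <- lapply(1:25, function(i)
    reml_fit(sim_y(st), rep(list(st$x0), st$M), st$Zfun))
  phi <- vapply(fits, `[[`, numeric(1), "residual_variance")
  beta <- vapply(fits, `[[`, numeric(1), "beta1")
  s2a <- vapply(fits, `[[`, numeric(1), "sigma2_alpha")
  expect_lt(abs(mean(phi) - 1), 0.1)
  expect_lt(abs(mean(beta)), 3 * sd(beta) / sqrt(length(beta)))
  # the variance attributed to the random term is a small fraction of phi
  G <- tcrossprod(st$Zfun(0))
  expect_lt(mean(s2a) * mean(diag(G)), 0.2)
})

test_that("doubling the data quadruples the residual variance under drift", {
  st <- make_structures(seed = 32)
  set.seed(33)
  y <- sim_y(st)
  f1 <- reml_fit(y, rep(list(st$x0), st$M), st$Zfun)
  f2 <- reml_fit(lapply(y, `*`, 2), rep(list(st$x0), st$M), st$Zfun)
  expect_equal(f2$residual_variance / f1$residual_variance, 4,
               tolerance = 0.05)
})

test_that("Wald intervals for the fixed effect have near-nominal coverage", {
  st <- make_structures(K0 = 30, nL = 12, M = 5, seed = 34)
  set.seed(35)
  beta_true <- 0.3
  hits <- vapply(1:120, function(i) {
    y <- sim_y(st, beta = beta_true, sigma2_alpha = 0.02, phi = 1)
    f <- reml_fit(y, rep(list(st$x0), st$M), st$Zfun, p_alpha_fixed = 0)
    half <- 1.96 * sqrt(f$S_alpha)
    abs(f$beta1 - beta_true) <= half
  }, logical(1))
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.995)
})

test_that("fast exchangeable and general solvers agree", {
  st <- make_structures(seed = 36)
  set.seed(37)
  y <- sim_y(st, beta = 0.2, sigma2_alpha = 0.05)
  x_list <- rep(list(st$x0), st$M)
  f_fast <- reml_fit(y, x_list, st$Zfun, shared = TRUE)
  f_gen <- reml_fit(y, x_list, st$Zfun, shared = FALSE)
  expect_true(f_fast$shared)
  expect_false(f_gen$shared)
  expect_equal(f_fast$beta1, f_gen$beta1, tolerance = 1e-3)
  expect_equal(f_fast$residual_variance, f_gen$residual_variance,
               tolerance = 1e-3)
  expect_equal(f_fast$p_alpha, f_gen$p_alpha, tolerance = 0.05)
  expect_equal(f_fast$loglik, f_gen$loglik, tolerance = 1e-2)
})

test_that("VA assembly combines trace and corrected quadratic terms", {
  L0 <- diag(c(0.1, 0.2, 0.25))
  p0 <- c(0.6, 0.8, 0.5)
  null_fit <- structure(list(p_alpha = 0, sigma2_alpha = 0, beta1 = 0,
                             S_alpha = 0, residual_variance = 1,
                             sigma2_o = 0), class = "va_model_fit")
  expect_equal(estimate_va(null_fit, L0, p0)$va, 0)
  # p_alpha = 0: trace term reduces to sigma2_alpha * Tr(L0)
  f2 <- null_fit; f2$sigma2_alpha <- 0.003
  expect_equal(estimate_va(f2, L0, p0)$trace_term, 0.003 * sum(diag(L0)))
  # quadratic pieces follow beta^2 and the sampling-variance correction
  f3 <- null_fit; f3$beta1 <- 0.05; f3$S_alpha <- 4e-4
  est <- estimate_va(f3, L0, p0)
  qf <- drop(crossprod(2 * p0 - 1, L0 %*% (2 * p0 - 1)))
  expect_equal(est$quad_term_raw, 0.05^2 * qf)
  expect_equal(est$quad_correction, 4e-4 * qf)
  expect_equal(est$va, est$trace_term + est$quad_term)
  expect_equal(est$va_uncorrected - est$va, est$quad_correction)
})

test_that("the sampling-error correction removes the null quadratic bias", {
  st <- make_structures(K0 = 30, nL = 12, M = 5, seed = 38)
  set.seed(39)
  L0 <- diag(st$L0d)
  p0 <- runif(st$nL, 0.2, 0.8)
  qf <- drop(crossprod(2 * p0 - 1, L0 %*% (2 * p0 - 1)))
  res <- t(vapply(1:40, function(i) {
    y <- sim_y(st, beta = 0, sigma2_alpha = 0, phi = 1)
    f <- reml_fit(y, rep(list(st$x0), st$M), st$Zfun, p_alpha_fixed = 0)
    est <- estimate_va(f, L0, p0)
    c(raw = est$quad_term_raw, corrected = est$quad_term)
  }, numeric(2)))
  expect_gt(mean(res[, "raw"]), 0)
  # corrected values are centred at zero, raw ones are biased upward
  expect_lt(abs(mean(res[, "corrected"])),
            3 * sd(res[, "corrected"]) / sqrt(nrow(res)) + 1e-8)
  expect_lt(mean(res[, "corrected"]), mean(res[, "raw"]))
})

test_that("degenerate fixed designs are handled without a fixed effect", {
  st <- make_structures(seed = 40)
  set.seed(41)
  y <- sim_y(st)
  f <- reml_fit(y, rep(list(rep(0, st$K0)), st$M), st$Zfun)
  expect_equal(f$beta1, 0)
  expect_equal(f$S_alpha, 0)
  expect_true(is.finite(f$loglik))
})
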