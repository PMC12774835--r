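test_that("DFE draws follow the gamma mixture and the dominance sign rule", {
  set.seed(50)
  cfg <- dfe_config(shape = 0.3, scale = 0.066, frac_neutral = 0.3,
                    ben_to_del_ratio = 0.1, kappa_abs = 0.5)
  d <- sample_dfe(cfg, 20000)
  nonzero <- d$eta != 0
  expect_equal(mean(abs(d$eta[nonzero])), 0.3 * 0.066, tolerance = 0.05)
  expect_equal(mean(!nonzero), 0.3, tolerance = 0.02)
  expect_equal(mean(d$eta > 0) / mean(d$eta < 0), 0.1, tolerance = 0.12)
  expect_true(all(d$kappa[nonzero] == sign(d$eta[nonzero]) * 0.5))
  expect_true(all(d$kappa[!nonzero] == 0))
  # all-neutral mixture
  d0 <- sample_dfe(dfe_config(frac_neutral = 1), 100)
  expect_true(all(d0$eta == 0))
  # random-allele attachment balances the signs
  dr <- sample_dfe(dfe_config(frac_neutral = 0), 20000, random_sign = TRUE)
  expect_equal(mean(dr$eta > 0), 0.5, tolerance = 0.02)
})

test_that("standing variation is segregating with a rare-skewed spectrum", {
  cfg <- sim_config(n_loci = 120, N0 = 60, seed = 51)
  set.seed(51)
  pan <- generate_standing_variation(cfg)
  f <- colMeans(pan$haplotypes)
  expect_equal(ncol(pan$haplotypes), 120)
  expect_true(all(f > 0 & f < 1))
  minor <- pmin(f, 1 - f)
  expect_lt(mean(minor), 0.3)   # neutral spectrum is skewed toward rare
  expect_true(all(diff(pan$positions) > 0))
})

test_that("tree-sequence style import is a pass-through", {
  H <- matrix(rbinom(40, 1, 0.5), 8, 5)
  pan <- panel_from_matrix(H, c(10, 20, 30, 40, 50))
  expect_equal(unname(pan$haplotypes), H)
})

test_that("log-fitness follows the within-locus dominance scheme", {
  # single locus: reference homozygote scores eta, het (1+kappa)*eta/2
  pan <- panel_of(c(1), c(1), c(1), c(0), c(0), c(0), positions = 100)
  f <- fitness_of(pan, eta = -0.1, kappa = -0.5, noise = FALSE)
  expect_equal(f$Y, c(-0.1, -0.025, 0))
  expect_equal(f$w, exp(f$Y) / mean(exp(f$Y)), tolerance = 1e-12)
  expect_equal(mean(f$w), 1)
  # no effects: genotypic value zero for everyone
  f0 <- fitness_of(pan, eta = 0, kappa = 0, noise = FALSE)
  expect_equal(f0$Y, c(0, 0, 0))
})

test_that("reproduction copies, selects and drifts as a Wright-Fisher model", {
  set.seed(52)
  pan <- random_panel(20, 6)
  # map length zero: every offspring haplotype is a copy of a parental one
  off <- reproduce(pan, map_length = 0, region_length = 1e6)
  par_rows <- apply(pan$haplotypes, 1, paste, collapse = "")
  off_rows <- apply(off$haplotypes, 1, paste, collapse = "")
  expect_true(all(off_rows %in% par_rows))
  # an overwhelming parent dominates the gamete pool
  W <- c(1e9, rep(1e-9, 9))
  off2 <- reproduce(pan, W = W, map_length = 0, region_length = 1e6)
  top <- apply(pan$haplotypes[1:2, , drop = FALSE], 1, paste, collapse = "")
  expect_gt(mean(off_rows_2 <- apply(off2$haplotypes, 1, paste,
                                     collapse = "") %in% top), 0.95)
  expect_error(reproduce(pan, W = rep(0, 10)), "zero")
})

test_that("neutral reproduction drifts at the p(1-p)/(2NE) rate", {
  set.seed(53)
  pan <- random_panel(60, 8)
  p0 <- compute_dosages(pan)$p
  n_rep <- 300
  dp2 <- matrix(0, n_rep, 8)
  for (i in seq_len(n_rep)) {
    off <- reproduce(pan, map_length = 0.5, region_length = 1e6)
    dp2[i, ] <- colMeans(off$haplotypes) - p0
  }
  v_obs <- apply(dp2, 2, function(x) mean(x^2))
  v_exp <- p0 * (1 - p0) / (2 * effective_size(30, 2))
  # pooled over loci, the ratio should sit within Monte-Carlo error
  ratio <- sum(v_obs) / sum(v_exp)
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / n_rep))
})

test_that("experiments are deterministic and bookkeep their own truth", {
  cfg <- sim_config(n_loci = 80, N0 = 50, n_replicates = 3,
                    n_generations = 2, seed = 54)
  sim1 <- run_experiment(cfg)
  sim2 <- run_experiment(cfg)
  expect_identical(sim1$panel$haplotypes, sim2$panel$haplotypes)
  expect_identical(sim1$data$replicates, sim2$data$replicates)
  expect_identical(sim1$truth, sim2$truth)
  # base frequencies consistent with stored genomes
  expect_equal(sim1$data$p0, unname(colMeans(compute_dosages(sim1$panel)$c)))
  # VA_true equals the enumerated breeding-value variance
  d <- compute_dosages(sim1$panel)
  u <- drop(d$c %*% sim1$truth$alpha)
  expect_equal(sim1$truth$VA_true, mean((u - mean(u))^2), tolerance = 1e-10)
  # recorded frequency trajectories start at the base frequencies
  for (m in 1:3) expect_equal(unname(sim1$freq[[m]][, 1]),
                              unname(sim1$data$p0))
})

test_that("all-neutral experiments have zero true VA", {
  sim <- run_experiment(sim_config(n_loci = 60, N0 = 40, n_replicates = 2,
                                   n_generations = 1,
                                   dfe = dfe_config(frac_neutral = 1),
                                   seed = 55))
  expect_equal(sim$truth$VA_true, 0)
  expect_true(all(abs(sim$eta) == 0))
})

test_that("a single strong locus moves in the direction of its effect", {
  set.seed(56)
  cfg <- sim_config(n_loci = 40, N0 = 80, n_replicates = 2,
                    n_generations = 2, dfe = dfe_config(frac_neutral = 1),
                    seed = 56)
  sim0 <- run_experiment(cfg)   # scaffolding only; rebuild with one effect
  pan <- sim0$panel
  p <- compute_dosages(pan)$p
  target <- which.min(abs(p - 0.5))[1]
  eta <- numeric(length(p)); eta[target] <- 0.8
  dp <- replicate(30, {
    W <- fitness_of(pan, eta, noise = FALSE)$W
    off <- reproduce(pan, W = W, map_length = 2, region_length = 1e6)
    colMeans(off$haplotypes)[target] - p[target]
  })
  expect_gt(mean(dp), 0)
})

test_that("the simulated replicate effective size matches its derivation", {
  expect_equal(experiment_effective_size(200), 200 * exp(-1))
  expect_equal(experiment_effective_size(100, 0), 100)
})
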