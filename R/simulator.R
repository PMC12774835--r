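## Self-contained forward-time generator of base populations and
## replicated evolve-and-resequence experiments.

#' Simulation configuration
#'
#' Defaults target desk scale while keeping the structure of a typical
#' Drosophila-style evolve-and-resequence experiment: a single contiguous
#' region, an experiment map length of 2 morgans, replicates of constant
#' census size observed over 3 generations.  `history_mode
#' "neutral-simplified"` equilibrates the ancestral population under
#' neutrality and attaches effects at random with respect to allele
#' (null relationship between frequency and effect); `"selected-burnin"`
#' appends a forward phase with selection and non-neutral mutation so that
#' the base population sits near mutation-selection-drift balance, with
#' effects attached to derived alleles.
#'
#' @param n_loci target number of segregating loci in the base panel.
#' @param region_length region size in bp.
#' @param N0 base-population size (diploids).
#' @param n_replicates number of replicate populations.
#' @param N_rep census size of each replicate.
#' @param n_generations generations of selection over which change is
#'   recorded (`tau_m - tm`).
#' @param map_length_experiment map length (morgans) during the experiment.
#' @param map_length_history map length (morgans) during the history phase.
#' @param history_mode `"neutral-simplified"` or `"selected-burnin"`.
#' @param burnin_factor neutral equilibration lasts `burnin_factor * N0`
#'   generations.
#' @param selected_generations length of the selected history phase
#'   (selected-burnin mode only).
#' @param dfe a [dfe_config()].
#' @param theta_factor safety multiplier on the mutation rate used to hit
#'   `n_loci` segregating sites.
#' @param seed integer seed driving the whole pipeline.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 500, region_length = 1e6, N0 = 200,
                       n_replicates = 5, N_rep = N0, n_generations = 3,
                       map_length_experiment = 2, map_length_history = 0.5,
                       history_mode = c("neutral-simplified", "selected-burnin"),
                       burnin_factor = 4, selected_generations = 5 * N0,
                       dfe = dfe_config(frac_neutral = 0.5),
                       theta_factor = 1.7, seed = NULL) {
  history_mode <- match.arg(history_mode)
  stopifnot(n_loci > 0, region_length > 0, N0 > 1, n_replicates >= 1,
            N_rep > 1, n_generations >= 1, map_length_experiment >= 0,
            map_length_history >= 0, burnin_factor > 0)
  structure(list(n_loci = as.integer(n_loci), region_length = region_length,
                 N0 = as.integer(N0), n_replicates = as.integer(n_replicates),
                 N_rep = as.integer(N_rep),
                 n_generations = as.integer(n_generations),
                 map_length_experiment = map_length_experiment,
                 map_length_history = map_length_history,
                 history_mode = history_mode,
                 burnin_generations = as.integer(ceiling(burnin_factor * N0)),
                 selected_generations = as.integer(selected_generations),
                 dfe = dfe, theta_factor = theta_factor, seed = seed),
            class = "sim_config")
}

# per-generation population-total mutation rate U targeting
# E[segregating sites] = 2 U a_(2N-1) ~ theta_factor * n_target
# (Watterson, with the whole population as the sample)
target_mu <- function(n_target, N, theta_factor) {
  a <- sum(1 / seq_len(2L * N - 1L))
  theta_factor * n_target / (2 * a)
}

#' Generate standing neutral variation
#'
#' Runs a forward-time neutral Wright-Fisher burn-in with infinite-sites
#' mutation on the region for `burnin_factor * N0` generations (long
#' enough to approach mutation-drift equilibrium), then takes the
#' population as the ancestral gene pool.  Segregating sites are
#' subsampled to `n_loci` columns at random.  For users who want an exact
#' coalescent history, [panel_from_matrix()] imports externally generated
#' haplotypes instead.
#'
#' @param cfg a [sim_config()].
#' @param map_length map length (morgans) during the burn-in; defaults to
#'   the history map length.
#' @return a [haplotype_panel()] (map set to the experiment map length).
#' @export
generate_standing_variation <- function(cfg, map_length = cfg$map_length_history) {
  mu <- target_mu(cfg$n_loci, cfg$N0, cfg$theta_factor)
  empty <- matrix(0L, 2L * cfg$N0, 0L)
  res <- wf_sim_cpp(empty, numeric(0), numeric(0), numeric(0),
                    cfg$region_length, map_length,
                    cfg$burnin_generations, cfg$N0, cfg$burnin_generations,
                    FALSE, mu, numeric(0), numeric(0),
                    10L, FALSE, -1L)
  finish_panel(res, cfg)
}

# order sites by position, subsample to n_loci, attach the experiment map
finish_panel <- function(res, cfg, keep_eta = FALSE) {
  H <- res$haplotypes
  pos <- res$positions
  f <- colMeans(H)
  seg <- which(f > 0 & f < 1)
  if (length(seg) < cfg$n_loci)
    stop(sprintf(paste("only %d segregating sites generated for a target of %d;",
                       "increase theta_factor or burn-in length"),
                 length(seg), cfg$n_loci))
  eta <- res$eta; kappa <- res$kappa
  if (keep_eta) {
    sel <- seg[eta[seg] != 0]
    neu <- setdiff(seg, sel)
    n_neu <- cfg$n_loci - length(sel)
    if (n_neu < 0) { # more selected sites than the target: subsample them
      sel <- sort(sample(sel, cfg$n_loci))
      keep <- sel
    } else {
      keep <- sort(c(sel, sample(neu, n_neu)))
    }
  } else {
    keep <- sort(sample(seg, cfg$n_loci))
  }
  ord <- keep[order(pos[keep])]
  H <- H[, ord, drop = FALSE]
  pos <- pos[ord]
  panel <- haplotype_panel(H, pos,
                           map_pos = pos / cfg$region_length * cfg$map_length_experiment)
  attr(panel, "eta") <- eta[ord]
  attr(panel, "kappa") <- kappa[ord]
  panel
}

#' Fitness of each individual in a panel
#'
#' Log absolute fitness is additive across loci with the within-locus
#' dominance scheme (0, `(1+kappa) eta / 2`, `eta` for 0, 1, 2 copies of
#' allele 1), plus standard-normal environmental noise; absolute fitness
#' is its exponential and relative fitness is rescaled to mean 1.
#'
#' @param panel a [haplotype_panel()] (or plain haplotype matrix).
#' @param eta,kappa per-locus effects and dominance degrees.
#' @param noise add the environmental noise term (default TRUE).
#' @return list of class `fitness_assignment` with `Y` (genotypic log
#'   fitness, noise-free), `logW`, `W`, `w` (relative, mean 1).
#' @export
fitness_of <- function(panel, eta, kappa = rep(0, length(eta)), noise = TRUE) {
  H <- if (inherits(panel, "haplotype_panel")) panel$haplotypes else as.matrix(panel)
  N <- nrow(H) %/% 2L
  G <- H[seq(1L, 2L * N, 2L), , drop = FALSE] + H[seq(2L, 2L * N, 2L), , drop = FALSE]
  het <- G == 1L
  hom <- G == 2L
  Y <- drop(hom %*% eta) + drop(het %*% ((1 + kappa) * eta / 2))
  logW <- Y + if (noise) stats::rnorm(N) else 0
  W <- exp(logW - max(logW))
  structure(list(Y = Y, logW = logW, W = W, w = W / mean(W)),
            class = "fitness_assignment")
}

#' One round of Wright-Fisher reproduction
#'
#' Each of `N_out` offspring draws two parents independently with
#' probability proportional to absolute fitness (selfing permitted); each
#' gamete is a recombinant of the parent's two haplotypes with a Poisson
#' number of crossovers on the genetic map and no interference.  No new
#' mutations arise.
#'
#' @param panel a [haplotype_panel()].
#' @param W absolute fitnesses (default: neutral, all equal).
#' @param map_length total map length in morgans (default from the panel
#'   map).
#' @param N_out number of offspring.
#' @param region_length region size in bp (default: span of positions).
#' @return a new [haplotype_panel()] of the offspring.
#' @export
reproduce <- function(panel, W = NULL, map_length = NULL, N_out = n_individuals(panel),
                      region_length = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  N <- n_individuals(panel)
  if (is.null(W)) W <- rep(1, N)
  if (is.null(region_length)) region_length <- max(panel$positions) + 1
  if (is.null(map_length)) {
    map_length <- if (is.null(panel$map_pos)) 0 else
      diff(range(panel$map_pos)) * region_length / diff(range(panel$positions))
  }
  H <- wf_next_gen_cpp(panel$haplotypes, panel$positions, region_length,
                       map_length, W, N_out)
  haplotype_panel(H, panel$positions, panel$map_pos, panel$phased, panel$loci)
}

#' Run a replicated evolve-and-resequence experiment
#'
#' Builds a base population (neutral-simplified or selected-burnin
#' history), records its exact average effects and true VA, founds
#' `n_replicates` populations by one selection-free round of reproduction
#' each (`tm = 1`), and evolves each with selection for `n_generations`,
#' recording genome-wide allele frequencies every generation.  No new
#' mutations occur during the experiment.
#'
#' @param cfg a [sim_config()].
#' @param keep_haplotypes also return the replicate haplotypes at the
#'   first and last observed generations (needed for pool-seq simulation).
#' @return list of class `experiment_result` with `panel` (base), `eta`,
#'   `kappa`, `data` (an [experiment_data()]), `freq` (per replicate, loci
#'   x generations matrix), `truth` (alpha, VA_true, Va_true), and
#'   optionally `haps_start`/`haps_end` per replicate.
#' @export
run_experiment <- function(cfg, keep_haplotypes = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  if (cfg$history_mode == "neutral-simplified") {
    ancestral <- generate_standing_variation(cfg)
    dfe_draw <- sample_dfe(cfg$dfe, cfg$n_loci, random_sign = TRUE)
    eta <- dfe_draw$eta; kappa <- dfe_draw$kappa
    # one selection-free round establishes the base population
    base <- reproduce(ancestral, map_length = cfg$map_length_experiment,
                      N_out = cfg$N0, region_length = cfg$region_length)
  } else {
    base <- selected_history(cfg)
    eta <- attr(base, "eta"); kappa <- attr(base, "kappa")
  }

  # drop loci fixed in the base itself (monomorphic columns carry nothing)
  p_base <- colMeans(base$haplotypes)
  seg <- p_base > 0 & p_base < 1
  base <- subset_panel(base, seg)
  eta <- eta[seg]; kappa <- kappa[seg]

  dos <- compute_dosages(base)
  fit_exp <- fitness_of(base, eta, kappa, noise = FALSE)
  w_expected <- exp(fit_exp$Y - max(fit_exp$Y))
  w_expected <- w_expected / mean(w_expected)
  alpha <- average_effects_exact(dos, w_expected)
  L0 <- compute_L(dos)
  gd <- genic_decomposition(alpha, L0)

  reps <- vector("list", cfg$n_replicates)
  freq <- vector("list", cfg$n_replicates)
  for (m in seq_len(cfg$n_replicates)) {
    res <- wf_sim_cpp(base$haplotypes, base$positions, eta, kappa,
                      cfg$region_length, cfg$map_length_experiment,
                      cfg$n_generations + 1L, cfg$N_rep,
                      1L,            # founding round without selection
                      TRUE, 0, numeric(0), numeric(0), 0L, TRUE,
                      if (keep_haplotypes) 1L else -1L)
    fmat <- do.call(cbind, res$freq)
    colnames(fmat) <- paste0("gen", seq_len(ncol(fmat)) - 1L)
    freq[[m]] <- fmat
    reps[[m]] <- list(p_start = fmat[, 2L], p_end = fmat[, ncol(fmat)])
    if (keep_haplotypes) {
      reps[[m]]$haps_start <- res$haplotypes_keep
      reps[[m]]$haps_end <- res$haplotypes
    }
  }

  structure(list(panel = base, eta = eta, kappa = kappa,
                 data = experiment_data(lapply(reps, function(r)
                   r[c("p_start", "p_end")]), p0 = dos$p),
                 replicates = reps, freq = freq,
                 truth = list(alpha = alpha, VA_true = gd$VA, Va_true = gd$Va),
                 config = cfg),
            class = "experiment_result")
}

# selected history: neutral equilibration, then a forward phase with
# selection and non-neutral mutation (effects attached to derived alleles)
selected_history <- function(cfg) {
  # selection (direct and background) depresses diversity relative to the
  # neutral expectation, so aim the mutation rate higher
  mu <- target_mu(cfg$n_loci, cfg$N0, 1.7 * cfg$theta_factor)
  n_gen_total <- cfg$burnin_generations + cfg$selected_generations
  pool_n <- stats::qpois(0.999, mu * n_gen_total) + 100L
  pool <- sample_dfe(cfg$dfe, pool_n, random_sign = FALSE)
  empty <- matrix(0L, 2L * cfg$N0, 0L)
  res <- wf_sim_cpp(empty, numeric(0), numeric(0), numeric(0),
                    cfg$region_length, cfg$map_length_history,
                    n_gen_total, cfg$N0,
                    cfg$burnin_generations,  # selection off while equilibrating
                    TRUE, mu, pool$eta, pool$kappa, 10L, FALSE, -1L)
  panel <- finish_panel(res, cfg, keep_eta = TRUE)
  base <- reproduce(panel, map_length = cfg$map_length_experiment,
                    N_out = cfg$N0, region_length = cfg$region_length)
  attr(base, "eta") <- attr(panel, "eta")
  attr(base, "kappa") <- attr(panel, "kappa")
  base
}

#' Effective size of a simulated replicate population
#'
#' Under the simulator's reproduction scheme each offspring draws two
#' parents independently with probability proportional to absolute
#' fitness, so a parent's gamete count is close to Binomial(2N, w/N) and
#' the neutral offspring-number variance is `Vo = 2 + 4 Var(w)`.  The
#' environmental noise on log fitness (standard normal by default) alone
#' gives `Var(w) = exp(v) - 1`, hence `Vo = 4 exp(v) - 2` and
#' `NE = 4N / (2 + Vo) = N exp(-v)`: about `N / e` with unit noise
#' variance.  This is the `NE` (and, absent linked selection, `Ne`) that
#' the drift model of [vafit()] should be given for simulated data.
#'
#' @param N census size of the replicate.
#' @param env_noise_var variance of the environmental noise on log
#'   fitness (the simulator uses 1).
#' @return effective population size.
#' @export
experiment_effective_size <- function(N, env_noise_var = 1) {
  effective_size(N, Vo = 2 + 4 * (exp(env_noise_var) - 1))
}

#' Subset a panel to a set of loci
#' @param panel a [haplotype_panel()].
#' @param keep logical or integer index of loci to keep.
#' @return a new [haplotype_panel()].
#' @export
subset_panel <- function(panel, keep) {
  haplotype_panel(panel$haplotypes[, keep, drop = FALSE],
                  panel$positions[keep],
                  if (is.null(panel$map_pos)) NULL else panel$map_pos[keep],
                  panel$phased, panel$loci[keep])
}

#' Import a panel from a plain haplotype matrix
#'
#' Pass-through hook for haplotypes generated externally (e.g. by a
#' coalescent simulator): rows are haplotypes, columns loci.
#'
#' @param haplotypes 0/1 matrix, rows = haplotypes.
#' @param positions physical positions (bp).
#' @param map_pos optional cumulative map positions (morgans).
#' @return a [haplotype_panel()].
#' @export
panel_from_matrix <- function(haplotypes, positions, map_pos = NULL) {
  haplotype_panel(haplotypes, positions, map_pos)
}
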