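# small panel builders used across tests

# panel from explicit haplotype rows (one row per haplotype)
panel_of <- function(..., positions = NULL, map_pos = NULL) {
  H <- rbind(...)
  if (is.null(positions)) positions <- seq_len(ncol(H)) * 100
  haplotype_panel(H, positions, map_pos)
}

# random panel: independent loci, frequencies drawn uniform
random_panel <- function(n_hap, n_loci, map_morgans = NULL) {
  n_hap <- 2L * ceiling(n_hap / 2)   # whole diploids
  p <- runif(n_loci, 0.15, 0.85)
  H <- matrix(rbinom(n_hap * n_loci, 1, rep(p, each = n_hap)), n_hap, n_loci)
  # ensure every column segregates
  for (j in which(colSums(H) %in% c(0, n_hap))) H[1:2, j] <- c(0, 1)
  pos <- sort(sample(1e6, n_loci))
  mp <- if (is.null(map_morgans)) NULL else pos / 1e6 * map_morgans
  haplotype_panel(H, pos, mp)
}

# a small ld_system + projection on a random panel
random_system <- function(n_hap = 40, n_loci = 12, t_end = 4, Ne = 100,
                          map_morgans = 1) {
  pan <- random_panel(n_hap, n_loci, map_morgans)
  dec <- decompose_L(pan)
  r <- pairwise_recombination(pan$positions, map_pos = pan$map_pos)
  des <- drift_design(1, t_end, Ne)
  sys <- ld_system(dec, r, des)
  L0 <- compute_L(compute_dosages(pan))
  list(panel = pan, decomp = dec, r = r, design = des, sys = sys, L0 = L0,
       basis = build_projection(sys, L0))
}
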