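## Predicted evolution of the diversity matrix L under drift and
## recombination, and the induced drift covariance of allele-frequency
## change.

#' Haldane's mapping function
#'
#' Recombination probability between two sites `g` base pairs apart under a
#' uniform crossover rate `r_bar` per base pair per generation (no
#' interference): `(1 - exp(-2 g r_bar)) / 2`.  More generally
#' [haldane_from_map()] maps a genetic distance `d` in morgans to
#' `(1 - exp(-2 d)) / 2`.
#'
#' @param g physical distance in base pairs (>= 0).
#' @param r_bar crossover rate per base pair per generation.
#' @return recombination probability in `[0, 0.5)`.
#' @export
haldane_recombination <- function(g, r_bar) {
  stopifnot(all(g >= 0), all(r_bar >= 0))
  (1 - exp(-2 * g * r_bar)) / 2
}

#' @rdname haldane_recombination
#' @param d genetic distance in morgans.
#' @export
haldane_from_map <- function(d) (1 - exp(-2 * abs(d))) / 2

#' Pairwise recombination probabilities between loci
#'
#' Builds the symmetric nL x nL matrix of per-generation recombination
#' probabilities, either from cumulative map positions (morgans) via
#' Haldane's function, or from a uniform per-bp crossover rate applied to
#' physical distances.
#'
#' @param positions physical positions in bp, sorted increasing.
#' @param map_pos cumulative map positions in morgans (overrides `r_bar`).
#' @param r_bar uniform crossover rate per bp per generation.
#' @return nL x nL matrix with zero diagonal and entries in `[0, 0.5)`.
#' @export
pairwise_recombination <- function(positions, map_pos = NULL, r_bar = NULL) {
  positions <- as.numeric(positions)
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("positions must be sorted strictly increasing")
  if (!is.null(map_pos)) {
    stopifnot(length(map_pos) == length(positions))
    d <- abs(outer(map_pos, map_pos, "-"))
    r <- haldane_from_map(d)
  } else if (!is.null(r_bar)) {
    g <- abs(outer(positions, positions, "-"))
    r <- haldane_recombination(g, r_bar)
  } else {
    stop("supply either map_pos or r_bar")
  }
  diag(r) <- 0
  r
}

#' Drift design of an experimental replicate
#'
#' Records the observation window and the effective-size histories that
#' drive the decay of L (`Ne`) and the drift variance of allele frequency
#' (`NE`).  Generation 0 is the base population; replicates founded from it
#' by one round of reproduction have `t_start = 1`.  Histories are indexed
#' from generation 0, so `Ne_history[k]` is the size acting on the
#' transition from generation `k - 1` to `k`... i.e. element 1 covers the
#' founding round.
#'
#' @param t_start first observed generation (tm >= 1).
#' @param t_end last observed generation (tau_m > tm).
#' @param Ne effective size(s) for L decay; recycled to `t_end` values.
#' @param NE effective size(s) for drift variance; defaults to `Ne`.
#' @return object of class `drift_design`.
#' @export
drift_design <- function(t_start = 1L, t_end, Ne, NE = Ne) {
  t_start <- as.integer(t_start); t_end <- as.integer(t_end)
  stopifnot(t_start >= 1L, t_end > t_start, all(Ne > 0), all(NE > 0))
  Ne <- rep_len(as.numeric(Ne), t_end)
  NE <- rep_len(as.numeric(NE), t_end)
  structure(list(t_start = t_start, t_end = t_end, Ne = Ne, NE = NE),
            class = "drift_design")
}

#' Drift-and-recombination weighted base LD matrix
#'
#' `L_tilde0 = L0' + (r / (1 - r)) o L0''` (elementwise), the combination
#' of the gametic and nongametic parts of the base-population L whose
#' Hadamard decay predicts L in later generations.  Since the diagonal of
#' `r` is zero, the diagonal of `L_tilde0` equals that of `L0'`.  Without a
#' gametic/nongametic split (unphased data) the whole of `L0` is used in
#' place of `L0'` with `L0'' = 0`, with a warning.
#'
#' @param decomp an `ld_decomposition` from [decompose_L()], or a plain
#'   matrix taken as L0 (triggering the unphased fallback).
#' @param r_matrix pairwise recombination probabilities.
#' @return nL x nL matrix `L_tilde0`.
#' @export
build_L_tilde0 <- function(decomp, r_matrix) {
  if (!inherits(decomp, "ld_decomposition")) {
    warning("no gametic/nongametic split available: using L_tilde0 = L0")
    return(as.matrix(decomp))
  }
  stopifnot(all(r_matrix < 1))
  decomp$L1 + (r_matrix / (1 - r_matrix)) * decomp$L2
}

#' Predicted Hadamard decay matrix N_t
#'
#' Element ij is `(1 - r_ij)^t * prod_{k=0}^{t-1} (1 - 1/(2 Ne_k))`: the
#' joint survival of a two-locus association over `t` generations of
#' recombination and drift.  `t = 0` gives the all-ones matrix.
#'
#' @param t generations elapsed since the base population (>= 0).
#' @param r_matrix pairwise recombination probabilities.
#' @param Ne_history per-generation effective sizes (length >= t); element
#'   k covers the transition into generation k.
#' @return matrix with entries in `(0, 1]`.
#' @export
predicted_N_matrix <- function(t, r_matrix, Ne_history) {
  stopifnot(t >= 0)
  if (t == 0L) return(matrix(1, nrow(r_matrix), ncol(r_matrix)))
  stopifnot(length(Ne_history) >= t)
  drift <- prod(1 - 1 / (2 * Ne_history[seq_len(t)]))
  (1 - r_matrix)^t * drift
}

#' Accumulated drift weight matrix M(m)
#'
#' `M(m) = sum_{t = tm}^{tau_m - 1} M_t o N_t` with `M_t = (1 - r)/NE_t`,
#' so that the expected drift covariance of the allele-frequency change of
#' replicate m is `L_tilde0 o M(m)`.
#'
#' @param design a [drift_design()].
#' @param r_matrix pairwise recombination probabilities.
#' @return nL x nL matrix.
#' @export
drift_weight_matrix <- function(design, r_matrix) {
  stopifnot(inherits(design, "drift_design"))
  M <- matrix(0, nrow(r_matrix), ncol(r_matrix))
  for (t in seq(design$t_start, design$t_end - 1L)) {
    Nt <- predicted_N_matrix(t, r_matrix, design$Ne)
    # NE[t + 1] is the size acting on the transition t -> t + 1
    M <- M + ((1 - r_matrix) / design$NE[t + 1L]) * Nt
  }
  M
}

#' Predicted per-generation and summed LD matrices
#'
#' The predicted diversity matrix in generation t is
#' `scriptL_t = N_t o L_tilde0`; the selection-response kernel of a
#' replicate observed from tm to tau_m is the sum
#' `scriptL_m = sum_{t=tm}^{tau_m - 1} scriptL_t`.
#'
#' @param design a [drift_design()].
#' @param L_tilde0 matrix from [build_L_tilde0()].
#' @param r_matrix pairwise recombination probabilities.
#' @return list with `per_gen` (named list over t) and `sum`.
#' @export
predicted_scriptL <- function(design, L_tilde0, r_matrix) {
  stopifnot(inherits(design, "drift_design"))
  ts <- seq(design$t_start, design$t_end - 1L)
  per_gen <- lapply(ts, function(t)
    predicted_N_matrix(t, r_matrix, design$Ne) * L_tilde0)
  names(per_gen) <- paste0("t", ts)
  list(per_gen = per_gen, sum = Reduce(`+`, per_gen))
}

#' Assemble the LD system of an experiment
#'
#' Convenience wrapper computing, for one replicate design, everything the
#' inference needs: `L_tilde0`, the summed predicted LD matrix
#' `scriptL_m`, the drift weight `M(m)` and the expected drift covariance
#' `L_tilde0 o M(m)`.
#'
#' @param decomp `ld_decomposition` (or plain L0 matrix, unphased fallback).
#' @param r_matrix pairwise recombination probabilities.
#' @param design a [drift_design()].
#' @return list of class `ld_system`.
#' @export
ld_system <- function(decomp, r_matrix, design) {
  Lt0 <- build_L_tilde0(decomp, r_matrix)
  sl <- predicted_scriptL(design, Lt0, r_matrix)
  M <- drift_weight_matrix(design, r_matrix)
  structure(list(L_tilde0 = Lt0, scriptL = sl$sum, scriptL_per_gen = sl$per_gen,
                 M = M, drift_cov = Lt0 * M, design = design),
            class = "ld_system")
}
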