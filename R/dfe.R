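#' Distribution of fitness effects (DFE) configuration
#'
#' Effects on log absolute fitness are drawn from a three-part mixture: a
#' point mass at 0 (neutral loci), a reflected gamma distribution
#' (deleterious), and a gamma distribution (beneficial), the two gamma
#' parts sharing `shape` and `scale` so that the mean absolute non-neutral
#' effect is `shape * scale` (0.02 at the default shape 0.3, scale 0.066).
#' Dominance takes a single magnitude `|kappa|` with sign matched to the
#' effect (deleterious alleles recessive): `kappa_i = sign(eta_i) * |kappa|`.
#'
#' @param shape,scale gamma parameters of the non-neutral effect magnitude.
#' @param frac_neutral mixture weight of the point mass at 0.
#' @param ben_to_del_ratio ratio of beneficial to deleterious mutation
#'   rates (0 = none beneficial).
#' @param kappa_abs dominance magnitude in `[0, 1]` (0 additive).
#' @return object of class `dfe_config`.
#' @export
dfe_config <- function(shape = 0.3, scale = 0.066, frac_neutral = 0,
                       ben_to_del_ratio = 0, kappa_abs = 0) {
  stopifnot(shape > 0, scale > 0, frac_neutral >= 0, frac_neutral <= 1,
            ben_to_del_ratio >= 0, kappa_abs >= 0, kappa_abs <= 1)
  structure(list(shape = shape, scale = scale, frac_neutral = frac_neutral,
                 ben_to_del_ratio = ben_to_del_ratio, kappa_abs = kappa_abs),
            class = "dfe_config")
}

#' Draw fitness effects and dominance degrees from the DFE
#'
#' @param cfg a [dfe_config()].
#' @param n number of loci.
#' @param random_sign additionally flip the sign of each non-neutral
#'   effect (and its kappa) with probability 1/2, detaching effects from
#'   allele identity (the "random-allele" assignment of simplified
#'   settings).
#' @return list with `eta` and `kappa` vectors of length n.
#' @export
sample_dfe <- function(cfg, n, random_sign = FALSE) {
  stopifnot(inherits(cfg, "dfe_config"))
  comp <- stats::runif(n)
  w_ben <- (1 - cfg$frac_neutral) * cfg$ben_to_del_ratio / (1 + cfg$ben_to_del_ratio)
  w_del <- (1 - cfg$frac_neutral) / (1 + cfg$ben_to_del_ratio)
  eta <- numeric(n)
  del <- comp < w_del
  ben <- comp >= w_del & comp < w_del + w_ben
  eta[del] <- -stats::rgamma(sum(del), shape = cfg$shape, scale = cfg$scale)
  eta[ben] <- stats::rgamma(sum(ben), shape = cfg$shape, scale = cfg$scale)
  if (random_sign) {
    flip <- stats::runif(n) < 0.5
    eta[flip] <- -eta[flip]
  }
  kappa <- sign(eta) * cfg$kappa_abs
  list(eta = eta, kappa = kappa)
}
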