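#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` holds the phased genomes of a base population: a
#' `2N x nL` matrix of reference-allele indicators together with physical
#' positions and (optionally) cumulative map positions.  Consecutive pairs
#' of rows (1,2), (3,4), ... are the two gametic contributions of the N
#' diploid individuals.
#'
#' @param haplotypes integer/numeric matrix with entries in \{0, 1\}; rows are
#'   haplotypes (an even number), columns are biallelic loci.  A 1 denotes
#'   the reference allele.
#' @param positions physical coordinates in base pairs, strictly increasing.
#' @param map_pos cumulative map positions in morgans, nondecreasing;
#'   `NULL` if no map is available (a uniform rate can be supplied later).
#' @param phased logical; `FALSE` downgrades the panel so that the
#'   gametic/nongametic split of L is unavailable (entries are still stored
#'   pairwise but the pairing carries no phase information).
#' @param loci optional character vector of locus identifiers.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, positions, map_pos = NULL,
                            phased = TRUE, loci = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype count must be even (two gametic contributions per individual)")
  if (!all(haplotypes %in% c(0, 1)))
    stop("haplotypes must be 0/1 reference-allele indicators")
  nL <- ncol(haplotypes)
  positions <- as.numeric(positions)
  if (length(positions) != nL) stop("length(positions) != number of loci")
  if (nL > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (!is.null(map_pos)) {
    map_pos <- as.numeric(map_pos)
    if (length(map_pos) != nL) stop("length(map_pos) != number of loci")
    if (nL > 1L && any(diff(map_pos) < 0))
      stop("map positions must be nondecreasing")
  }
  if (is.null(loci)) loci <- paste0("L", seq_len(nL), "_", positions)
  storage.mode(haplotypes) <- "double"
  colnames(haplotypes) <- loci
  structure(list(haplotypes = haplotypes, positions = positions,
                 map_pos = map_pos, phased = isTRUE(phased), loci = loci),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d individuals (%d haplotypes), %d loci%s\n",
              nrow(x$haplotypes) / 2L, nrow(x$haplotypes), ncol(x$haplotypes),
              if (x$phased) "" else " (unphased)"))
  p <- colMeans(x$haplotypes)
  seg <- sum(p > 0 & p < 1)
  cat(sprintf("  segregating loci: %d; span: %s bp; map: %s\n",
              seg, format(diff(range(x$positions))),
              if (is.null(x$map_pos)) "none"
              else sprintf("%.4g morgans", diff(range(x$map_pos)))))
  invisible(x)
}

#' Number of diploid individuals in a panel
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$haplotypes) %/% 2L

#' Genotype dosages of a haplotype panel
#'
#' The dosage of individual k at locus i is the proportion of reference
#' alleles it carries, `c[k, i] in \{0, 0.5, 1\}`.  Reference-allele
#' frequencies `p` are the column means of `c`.
#'
#' @param panel a [haplotype_panel()].
#' @return a list of class `genotype_dosages` with elements `c` (N x nL
#'   matrix), `p` and `q = 1 - p`.
#' @export
compute_dosages <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$haplotypes
  N <- nrow(H) %/% 2L
  c_mat <- (H[seq(1L, 2L * N, by = 2L), , drop = FALSE] +
            H[seq(2L, 2L * N, by = 2L), , drop = FALSE]) / 2
  p <- colMeans(c_mat)
  structure(list(c = c_mat, p = p, q = 1 - p), class = "genotype_dosages")
}

#' Flip the reference-allele labelling of selected loci
#'
#' The method is invariant to which allele is called "reference": flipping
#' column i maps p to q and negates the corresponding average effect.  Used
#' mainly in invariance tests.
#'
#' @param panel a [haplotype_panel()].
#' @param which integer or logical index of columns to flip.
#' @return a new `haplotype_panel`.
#' @export
flip_reference <- function(panel, which) {
  H <- panel$haplotypes
  H[, which] <- 1 - H[, which]
  haplotype_panel(H, panel$positions, panel$map_pos, panel$phased, panel$loci)
}
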