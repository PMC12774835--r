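## File formats: phased VCF / haplotype TSV readers, frequency tables,
## recombination maps, matrix export.  Locus identity is
## (chrom, pos, ref, alt); joins are by identifier, never row order.

#' Read a base population from a phased VCF or haplotype TSV
#'
#' VCF input requires biallelic SNP records and `GT` fields; "|"-separated
#' genotypes are taken as phased, while any "/" separator downgrades the
#' panel to unphased (L cannot then be split into gametic and nongametic
#' parts) with a warning.  TSV input is a plain matrix with one row per
#' haplotype and a header of locus identifiers; positions are parsed from
#' identifiers of the form `chrom_pos_ref_alt` or supplied separately.
#'
#' @param path path to a `.vcf` (or `.vcf.gz`) or `.tsv` file.
#' @param positions optional physical positions (TSV input only).
#' @param map_pos optional cumulative map positions in morgans.
#' @return a [haplotype_panel()].
#' @export
read_base_population <- function(path, positions = NULL, map_pos = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_vcf_panel(path, map_pos)
  } else {
    read_haplotypes_tsv(path, positions, map_pos)
  }
}

read_vcf_panel <- function(path, map_pos = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  if (any(multi))
    stop("non-biallelic/non-SNP records: ",
         paste(fix[multi, "CHROM"], fix[multi, "POS"], sep = ":", collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- !any(grepl("/", gt))
  if (!phased)
    warning("unphased genotypes ('/' separators): gametic/nongametic split of L disabled")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (any(!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))))
    stop("genotypes must be biallelic 0/1 calls")
  # rows of gt are loci, columns samples; REF allele indicator = 1 - allele code
  H <- rbind2_interleave(1 - matrix(as.numeric(a1), nrow(gt)),
                         1 - matrix(as.numeric(a2), nrow(gt)))
  positions <- as.numeric(fix[, "POS"])
  ord <- order(positions)
  loci <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
                sep = "_")[ord]
  haplotype_panel(H[, ord, drop = FALSE], positions[ord],
                  if (is.null(map_pos)) NULL else map_pos[ord],
                  phased = phased, loci = loci)
}

# interleave per-sample first/second haplotypes into consecutive row pairs
rbind2_interleave <- function(A1t, A2t) {
  n_samp <- ncol(A1t)
  H <- matrix(0, 2L * n_samp, nrow(A1t))
  H[seq(1L, 2L * n_samp, 2L), ] <- t(A1t)
  H[seq(2L, 2L * n_samp, 2L), ] <- t(A2t)
  H
}

read_haplotypes_tsv <- function(path, positions = NULL, map_pos = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  H <- as.matrix(tab)
  loci <- colnames(H)
  if (is.null(positions)) {
    parts <- strsplit(loci, "_")
    positions <- suppressWarnings(vapply(parts, function(x)
      as.numeric(x[[min(2L, length(x))]]), numeric(1)))
    if (anyNA(positions)) positions <- seq_along(loci)
  }
  ord <- order(positions)
  haplotype_panel(H[, ord, drop = FALSE], positions[ord],
                  if (is.null(map_pos)) NULL else map_pos[ord],
                  loci = loci[ord])
}

#' Write a haplotype panel to TSV
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @export
write_haplotypes_tsv <- function(panel, path) {
  tab <- as.data.frame(panel$haplotypes)
  names(tab) <- panel$loci
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-replicate allele-frequency tables
#'
#' TSV with a `locus` identifier column and one column per time point
#' (e.g. `p_start`, `p_end`).  Rows are joined to the panel's locus set by
#' identifier; loci missing from the table, or with any NA frequency, are
#' masked (returned in `masked`) with a message.
#'
#' @param path file path.
#' @param loci character vector of panel locus identifiers.
#' @return list with `p` (matrix loci x time points, NA where masked) and
#'   `masked` (logical).
#' @export
read_frequency_table <- function(path, loci) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"locus" %in% names(tab)) stop("frequency table needs a 'locus' column")
  vals <- as.matrix(tab[, setdiff(names(tab), "locus"), drop = FALSE])
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("frequencies outside [0, 1]")
  idx <- match(loci, tab$locus)
  p <- vals[idx, , drop = FALSE]
  rownames(p) <- loci
  masked <- is.na(idx) | apply(is.na(p), 1L, any)
  if (any(masked))
    message(sprintf("%d locus/loci masked (missing or NA in %s)",
                    sum(masked), basename(path)))
  list(p = p, masked = masked)
}

#' Write a matrix to TSV (debugging export)
#' @param m matrix.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Read a recombination map and interpolate at panel positions
#'
#' TSV with columns `position_bp` and `map_morgans` (cumulative).  Map
#' positions at the panel's loci are obtained by linear interpolation,
#' constant beyond the map's ends.
#'
#' @param path file path.
#' @param positions physical positions to interpolate at.
#' @return numeric vector of cumulative map positions (morgans).
#' @export
read_map_tsv <- function(path, positions) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("position_bp", "map_morgans") %in% names(tab)))
    stop("map table needs columns position_bp and map_morgans")
  stats::approx(tab$position_bp, tab$map_morgans, xout = positions,
                rule = 2)$y
}

#' Export Q matrix as triplets
#'
#' Writes only the nonzero read-span entries `(i, j, Q_ij)`; pairs farther
#' apart than a read length never co-occur on a read and are omitted.
#'
#' @param Q dense Q matrix.
#' @param path output path.
#' @export
write_q_triplets <- function(Q, path) {
  idx <- which(Q != 0 & upper.tri(Q, diag = TRUE), arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1L], j = idx[, 2L],
                                Q = Q[idx]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
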