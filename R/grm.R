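#' Genomic relationship matrix (Yang's estimator) and FGRM
#'
#' Builds the SNP-based relationship matrix of Yang and co-workers. With
#' dosages `x` (count of A1), allele frequency `p` per SNP and sums over
#' SNPs non-missing for the pair/individual:
#' off-diagonal `g_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' diagonal `g_jj = 1 + mean_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i))`. Genomic inbreeding is `FGRM = g_jj - 1`, which ranges
#' from -1 (fully heterozygous relative to the assumed frequencies) to
#' infinity, and is sensitive to the allele frequencies used. Monomorphic
#' SNPs are excluded from the sums; missing genotypes are handled
#' pairwise-complete.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param freqs optional per-SNP A1 frequencies (base-population estimates);
#'   by default frequencies are estimated from the analyzed sample, which is
#'   the usual driver of slightly negative mean FGRM in real data.
#' @return list with `g` (animal x animal matrix), `fgrm` (named vector),
#'   `freqs` (frequencies used, NA for excluded monomorphic SNPs),
#'   `n_snp_used`.
#' @export
grm_yang <- function(panel, freqs = NULL) {
  X <- panel$geno
  storage.mode(X) <- "double"
  p <- if (is.null(freqs)) colMeans(X, na.rm = TRUE) / 2 else as.numeric(freqs)
  if (length(p) != ncol(X)) stop("freqs length must match SNP count")
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM undefined")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  v <- 2 * pp * (1 - pp)
  M <- !is.na(Xp)
  Z <- sweep(Xp, 2L, 2 * pp)
  Z <- sweep(Z, 2L, sqrt(v), "/")
  Z[!M] <- 0
  num <- tcrossprod(Z)
  den <- tcrossprod(M * 1)
  G <- num / den
  ## Yang diagonal
  Td <- (Xp^2 - sweep(Xp, 2L, 1 + 2 * pp, "*") +
           matrix(2 * pp^2, nrow(Xp), ncol(Xp), byrow = TRUE)) /
    matrix(v, nrow(Xp), ncol(Xp), byrow = TRUE)
  Td[!M] <- NA
  diag(G) <- 1 + rowMeans(Td, na.rm = TRUE)
  fgrm <- diag(G) - 1
  names(fgrm) <- rownames(X)
  pout <- rep(NA_real_, ncol(X)); pout[poly] <- pp
  list(g = G, fgrm = fgrm, freqs = pout, n_snp_used = sum(poly))
}

#' Summary of genomic inbreeding coefficients
#'
#' Mean, SD, min and max of a per-animal inbreeding vector, reported in
#' percent (the layout of published genomic-inbreeding tables).
#'
#' @param x numeric vector of per-animal coefficients (proportions).
#' @return named list `mean`, `sd`, `min`, `max`, all in percent.
#' @export
inbreeding_pct_summary <- function(x) {
  x <- x[!is.na(x)]
  list(mean = 100 * mean(x),
       sd = if (length(x) > 1) 100 * stats::sd(x) else 0,
       min = 100 * min(x), max = 100 * max(x))
}

#' Export a GRM as text
#'
#' Writes the square matrix and a lower-triangle `(id1, id2, value)` table.
#' @param g square relationship matrix with dimnames.
#' @param prefix output path prefix; writes `prefix.grm.txt` and
#'   `prefix.grm.lower.txt`.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(g, prefix) {
  utils::write.table(format(g, digits = 10), paste0(prefix, ".grm.txt"),
                     quote = FALSE, sep = "\t")
  ix <- which(lower.tri(g, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(id1 = rownames(g)[ix[, 1]], id2 = colnames(g)[ix[, 2]],
                    value = g[ix])
  utils::write.table(tab, paste0(prefix, ".grm.lower.txt"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(prefix)
}
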