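#' Haplotype r-squared between two indicator vectors
#'
#' Squared correlation of allele indicators on phased haplotypes:
#' r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B)).
#' Returns `NA` when either site is monomorphic.
#'
#' @param a,b binary vectors over the same haplotypes.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
hap_r2 <- function(a, b) {
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(a * b)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# All-pairs r2 matrix over the columns of a binary haplotype matrix.
# Monomorphic columns give NA rows/columns.
hap_r2_matrix <- function(ind) {
  p <- colMeans(ind)
  poly <- p > 0 & p < 1
  r2 <- matrix(NA_real_, ncol(ind), ncol(ind))
  if (any(poly)) {
    cc <- suppressWarnings(stats::cor(ind[, poly, drop = FALSE]))
    r2[poly, poly] <- cc^2
  }
  r2
}
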