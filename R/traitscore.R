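#' Greedy LD clumping of GWAS records
#'
#' Iterates the records with `p <= p_max` in order of ascending p value and
#' keeps a record unless it has haplotype r-squared above `r2_max` with an
#' already-kept record within `window_kb` on the same contig.
#'
#' @param gwas data.frame with columns `id`, `contig`, `pos`,
#'   `effect_allele`, `beta`, `p`.
#' @param panel phased [haplotype_panel()] used for LD; GWAS records whose
#'   site is absent from the panel are dropped with a message.
#' @param p_max GWAS p-value threshold.
#' @param r2_max clumping r-squared (default 0.5).
#' @param window_kb clumping window in kb (default 250).
#' @return The retained GWAS records (ascending p), with a `site` column.
#' @export
clump <- function(gwas, panel, p_max, r2_max = 0.5, window_kb = 250) {
  stopifnot(all(c("id", "contig", "pos", "beta", "p") %in% names(gwas)))
  require_phased(panel, "clump")
  if (any(gwas$p <= 0 | gwas$p > 1)) stop("p values must be in (0, 1]")
  gwas <- gwas[gwas$p <= p_max, , drop = FALSE]
  gwas$site <- match(paste(gwas$contig, gwas$pos),
                     paste(panel$contig, panel$pos))
  if (anyNA(gwas$site)) {
    message(sum(is.na(gwas$site)), " GWAS record(s) absent from panel dropped")
    gwas <- gwas[!is.na(gwas$site), , drop = FALSE]
  }
  gwas <- gwas[order(gwas$p, gwas$contig, gwas$pos), , drop = FALSE]
  if (nrow(gwas) == 0) {
    warning("no GWAS records pass the p threshold")
    rownames(gwas) <- NULL
    return(gwas)
  }
  kept <- integer(0)
  for (i in seq_len(nrow(gwas))) {
    ok <- TRUE
    for (k in kept) {
      if (gwas$contig[k] != gwas$contig[i]) next
      if (abs(gwas$pos[k] - gwas$pos[i]) > window_kb * 1000) next
      r2 <- hap_r2(panel$geno[, gwas$site[i]], panel$geno[, gwas$site[k]])
      if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- gwas[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean 2-beta-f polygenic summary
#'
#' `(sum_i 2 beta_i f_i) / n` over the n SNPs with a non-missing effect
#' allele frequency: the expected average polygenic contribution of the
#' trait in a population with frequencies `f`.
#'
#' @param f effect-allele frequencies (may contain `NA`; excluded pairwise).
#' @param beta aligned GWAS effect sizes.
#' @return list: `value`, `n_used`, `n_missing`.
#' @export
mean_2bf <- function(f, beta) {
  stopifnot(length(f) == length(beta))
  ok <- !is.na(f) & !is.na(beta)
  if (sum(ok) == 0) stop("no SNP with defined frequency")
  list(value = sum(2 * beta[ok] * f[ok]) / sum(ok),
       n_used = sum(ok), n_missing = sum(!ok))
}

#' Trait divergence D between two ancestries
#'
#' Computes mean 2-beta-f under the source-1 and source-2 ancestral
#' frequencies, a permutation null in which each SNP's frequency is drawn
#' independently from its two ancestral values with probability 1/2, and
#' `D = (mean2bf_src1 - mean2bf_src2) / (P97.5 - P2.5)` of the null. Only
#' SNPs with both frequencies defined enter; `|D| > 1` therefore means the
#' observed ancestry contrast exceeds the central 95% width of the
#' frequency-shuffling null.
#'
#' @param f_src1,f_src2 aligned ancestral effect-allele frequencies.
#' @param beta aligned GWAS effect sizes.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed making the null reproducible.
#' @param null one permuted mean-2-beta-f per replicate (`"mean"`, the
#'   default) or a permuted src1-minus-src2 difference per replicate
#'   (`"difference"`).
#' @return An object of class `trait_score`: `mean2bf_src1`, `mean2bf_src2`,
#'   `p2.5`, `p97.5`, `d`, `n_used`, `n_dropped`, `n_perm`, `seed`. `d` is
#'   `NA` (flagged via `degenerate = TRUE`) when the null has zero width.
#' @export
trait_d <- function(f_src1, f_src2, beta, n_perm = 1000, seed,
                    null = c("mean", "difference")) {
  stopifnot(length(f_src1) == length(f_src2),
            length(f_src1) == length(beta), n_perm >= 1)
  null <- match.arg(null)
  if (missing(seed)) stop("an explicit seed is required")
  ok <- !is.na(f_src1) & !is.na(f_src2) & !is.na(beta)
  n <- sum(ok)
  if (n == 0) stop("no SNP with both ancestral frequencies defined")
  f1 <- f_src1[ok]; f2 <- f_src2[ok]; b <- beta[ok]
  m1 <- sum(2 * b * f1) / n
  m2 <- sum(2 * b * f2) / n
  set.seed(seed)
  # the null draws from the unordered pair {f1, f2} per SNP, so an exchange
  # of the two ancestry labels reproduces the identical null (and flips D)
  lo <- pmin(f1, f2); hi <- pmax(f1, f2)
  pick <- matrix(stats::runif(n_perm * n) < 0.5, n_perm, n)
  fmat <- matrix(lo, n_perm, n, byrow = TRUE)
  fmat[pick] <- matrix(hi, n_perm, n, byrow = TRUE)[pick]
  perm <- as.numeric(fmat %*% (2 * b)) / n
  if (null == "difference") {
    gmat <- matrix(hi, n_perm, n, byrow = TRUE)
    gmat[pick] <- matrix(lo, n_perm, n, byrow = TRUE)[pick]
    perm <- perm - as.numeric(gmat %*% (2 * b)) / n
  }
  q <- stats::quantile(perm, c(0.025, 0.975), names = FALSE, type = 7)
  width <- q[2] - q[1]
  degenerate <- width <= 0
  structure(
    list(mean2bf_src1 = m1, mean2bf_src2 = m2, p2.5 = q[1], p97.5 = q[2],
         d = if (degenerate && m1 != m2) NA_real_ else
           if (degenerate) 0 else (m1 - m2) / width,
         degenerate = degenerate, n_used = n, n_dropped = sum(!ok),
         n_perm = n_perm, seed = seed, null = null),
    class = "trait_score")
}

#' @export
print.trait_score <- function(x, ...) {
  cat(sprintf(
    "trait_score: mean2bf src1 = %.4g, src2 = %.4g, null 95%% = [%.4g, %.4g], D = %.3g (n = %d)\n",
    x$mean2bf_src1, x$mean2bf_src2, x$p2.5, x$p97.5, x$d, x$n_used))
  invisible(x)
}

#' Harmonize GWAS effect alleles to a frequency table
#'
#' Matches GWAS records to an [ancestral_freqs()] table by contig and
#' position, flips frequencies where the effect allele is the reference
#' allele, and drops strand-ambiguous (A/T, C/G) SNPs and records whose
#' effect allele matches neither panel allele.
#'
#' @param gwas GWAS records with `effect_allele`.
#' @param freqs an `ancestral_freqs` table.
#' @return `gwas` with `f_sample`, `f_src1`, `f_src2` columns aligned to
#'   the effect allele.
#' @export
harmonize_effects <- function(gwas, freqs) {
  stopifnot(inherits(freqs, "ancestral_freqs"),
            "effect_allele" %in% names(gwas))
  idx <- match(paste(gwas$contig, gwas$pos), paste(freqs$contig, freqs$pos))
  keep <- !is.na(idx)
  if (any(!keep))
    message(sum(!keep), " GWAS record(s) without frequency estimates dropped")
  gwas <- gwas[keep, , drop = FALSE]; idx <- idx[keep]
  pair <- paste(pmin(freqs$ref[idx], freqs$alt[idx]),
                pmax(freqs$ref[idx], freqs$alt[idx]))
  ambiguous <- pair %in% c("A T", "C G")
  if (any(ambiguous)) {
    warning(sum(ambiguous), " strand-ambiguous SNP(s) dropped")
    gwas <- gwas[!ambiguous, , drop = FALSE]; idx <- idx[!ambiguous]
  }
  is_alt <- gwas$effect_allele == freqs$alt[idx]
  is_ref <- gwas$effect_allele == freqs$ref[idx]
  if (any(!is_alt & !is_ref)) {
    warning(sum(!is_alt & !is_ref),
            " record(s) whose effect allele matches neither panel allele dropped")
    keep2 <- is_alt | is_ref
    gwas <- gwas[keep2, , drop = FALSE]; idx <- idx[keep2]
    is_alt <- is_alt[keep2]
  }
  flip <- function(f) ifelse(is_alt, f, 1 - f)
  gwas$f_sample <- flip(freqs$f_sample[idx])
  gwas$f_src1 <- flip(freqs$f_src1[idx])
  gwas$f_src2 <- flip(freqs$f_src2[idx])
  rownames(gwas) <- NULL
  gwas
}
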