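#' Phased haplotype panel
#'
#' The central in-memory container: a binary haplotype-by-site matrix with
#' 1-based positions, per-site alleles and a sample-to-population mapping.
#' Each diploid sample contributes two consecutive rows when the source
#' genotypes are phased.
#'
#' @param geno integer matrix, haplotypes in rows, sites in columns; entries
#'   0 (reference allele), 1 (alternate allele) or `NA` (missing). Missing
#'   entries are tolerated only for dosage-based operations.
#' @param contig character vector of contig ids, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param ref,alt character vectors of reference / alternate alleles.
#' @param samples data.frame with columns `sample` and `population`.
#' @param hap_sample integer vector mapping each haplotype row to a row of
#'   `samples`. Defaults to two consecutive haplotypes per sample.
#' @param phased logical; whether rows are true phased haplotypes. Unphased
#'   data may still be used for dosage-only operations (e.g. JAS, S*), and
#'   haplotype-dependent operations refuse it.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(geno, contig, pos, ref = NULL, alt = NULL,
                            samples = NULL, hap_sample = NULL, phased = TRUE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_site <- ncol(geno)
  n_hap <- nrow(geno)
  contig <- as.character(contig)
  if (length(contig) == 1L) contig <- rep(contig, n_site)
  pos <- as.integer(pos)
  stopifnot(length(contig) == n_site, length(pos) == n_site)
  if (any(!is.na(geno) & geno != 0L & geno != 1L))
    stop("haplotype matrix entries must be 0, 1 or NA")
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("T", n_site)
  if (is.null(samples)) {
    if (n_hap %% 2L != 0L)
      stop("odd number of haplotypes requires an explicit sample mapping")
    samples <- data.frame(
      sample = sprintf("ind%03d", seq_len(n_hap / 2L)),
      population = "pop1", stringsAsFactors = FALSE)
  }
  if (is.null(hap_sample)) {
    if (n_hap != 2L * nrow(samples))
      stop("hap_sample must be supplied when haplotypes != 2 * samples")
    hap_sample <- rep(seq_len(nrow(samples)), each = 2L)
  }
  stopifnot(length(hap_sample) == n_hap,
            all(hap_sample >= 1L & hap_sample <= nrow(samples)))
  ord <- order(contig, pos)
  structure(
    list(geno = geno[, ord, drop = FALSE], contig = contig[ord],
         pos = pos[ord], ref = as.character(ref)[ord],
         alt = as.character(alt)[ord], samples = samples,
         hap_sample = as.integer(hap_sample), phased = isTRUE(phased)),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes (%d samples, %d population(s)), %d sites on %d contig(s)%s\n",
    nrow(x$geno), nrow(x$samples), length(unique(x$samples$population)),
    ncol(x$geno), length(unique(x$contig)),
    if (x$phased) "" else " [unphased]"))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$geno)

#' Subset a panel by site index and/or haplotype index
#'
#' @param panel a [haplotype_panel()].
#' @param sites integer or logical index over sites (columns).
#' @param haps integer or logical index over haplotype rows.
#' @return A `haplotype_panel` restricted to the selection.
#' @export
subset_panel <- function(panel, sites = NULL, haps = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(sites)) sites <- seq_len(ncol(panel$geno))
  if (is.null(haps)) haps <- seq_len(nrow(panel$geno))
  keep_samp <- sort(unique(panel$hap_sample[haps]))
  haplotype_panel(
    panel$geno[haps, sites, drop = FALSE],
    contig = panel$contig[sites], pos = panel$pos[sites],
    ref = panel$ref[sites], alt = panel$alt[sites],
    samples = panel$samples[keep_samp, , drop = FALSE],
    hap_sample = match(panel$hap_sample[haps], keep_samp),
    phased = panel$phased)
}

#' Per-individual dosage of a chosen allele
#'
#' Sums the two haplotype rows of each sample, yielding diploid dosages in
#' 0..2 of the allele named per site ("ref" or "alt"). `NA` haplotype entries
#' propagate to `NA` dosages.
#'
#' @param panel a [haplotype_panel()].
#' @param allele character vector (recycled) of "ref"/"alt" per site.
#' @return numeric matrix, samples x sites.
#' @export
allele_dosage <- function(panel, allele = "alt") {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- rep_len(allele, ncol(panel$geno))
  ind <- panel$geno
  flip <- allele == "ref"
  if (any(flip)) ind[, flip] <- 1L - ind[, flip, drop = FALSE]
  rowsum(ind, group = panel$hap_sample, reorder = TRUE)
}

# Indicator matrix (haplotypes x selected sites) of a per-site chosen allele.
allele_indicator <- function(panel, sites, allele) {
  ind <- panel$geno[, sites, drop = FALSE]
  flip <- allele == "ref"
  if (any(flip)) ind[, flip] <- 1L - ind[, flip, drop = FALSE]
  ind
}

# Guard used by every haplotype-r2 operation.
require_phased <- function(panel, op) {
  if (!isTRUE(panel$phased))
    stop(sprintf("operation '%s' requires phased haplotypes; panel is unphased", op))
  if (anyNA(panel$geno))
    stop(sprintf("operation '%s' requires complete haplotypes; panel has missing entries", op))
  invisible(TRUE)
}
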