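#' Classify haplotypes around a focal site by marker presence
#'
#' A haplotype is labeled `source1` when it carries at least one marker
#' allele at a marker inside the closed window
#' `[pos - flank_bp, pos + flank_bp]` (the focal site included if it is
#' itself a marker), and `source2` otherwise. Markers called at a strict
#' AMI threshold should be used here, since false-positive markers
#' contaminate the source-1 haplotype class.
#'
#' @param panel a phased [haplotype_panel()].
#' @param markers a `marker_set` on the panel's coordinates.
#' @param focal_pos 1-based focal position.
#' @param focal_contig contig of the focal site (defaults to the panel's
#'   single contig).
#' @param flank_bp half-width of the window (default 10,000).
#' @return character vector over haplotypes, `"source1"`/`"source2"`.
#' @export
classify_window_haplotypes <- function(panel, markers, focal_pos,
                                       focal_contig = NULL, flank_bp = 1e4) {
  require_phased(panel, "classify_window_haplotypes")
  if (is.null(focal_contig)) {
    focal_contig <- unique(panel$contig)
    if (length(focal_contig) != 1)
      stop("focal_contig must be given for a multi-contig panel")
  }
  if (!any(markers$contig == focal_contig))
    warning("no markers on contig ", focal_contig, "; all haplotypes source2")
  mk <- markers[markers$contig == focal_contig &
                  markers$pos >= focal_pos - flank_bp &
                  markers$pos <= focal_pos + flank_bp, , drop = FALSE]
  if (nrow(mk) == 0) return(rep("source2", nrow(panel$geno)))
  ind <- allele_indicator(panel, mk$site, mk$marker_allele)
  ifelse(rowSums(ind) > 0, "source1", "source2")
}

#' Ancestral allele frequencies from classified haplotypes
#'
#' For every panel site whose minor allele frequency exceeds `maf_min`,
#' haplotypes are partitioned by [classify_window_haplotypes()] and the
#' alternate-allele frequency is computed separately within the
#' source-1-derived and source-2 haplotype classes. An empty class yields
#' `NA` (not 0), so downstream statistics can drop the site rather than be
#' biased toward zero.
#'
#' @inheritParams classify_window_haplotypes
#' @param maf_min minimum minor allele frequency (default 0.01, exclusive).
#' @return data.frame of class `ancestral_freqs`: `contig`, `pos`, `ref`,
#'   `alt`, `f_sample`, `f_src1`, `f_src2`, `n_hap_src1`, `n_hap_src2`.
#'   Frequencies refer to the alternate allele.
#' @export
ancestral_freqs <- function(panel, markers, maf_min = 0.01, flank_bp = 1e4) {
  require_phased(panel, "ancestral_freqs")
  n_hap <- nrow(panel$geno)
  f_all <- colMeans(panel$geno)
  keep <- pmin(f_all, 1 - f_all) > maf_min
  res <- data.frame(contig = panel$contig[keep], pos = panel$pos[keep],
                    ref = panel$ref[keep], alt = panel$alt[keep],
                    f_sample = f_all[keep], f_src1 = NA_real_,
                    f_src2 = NA_real_, n_hap_src1 = NA_integer_,
                    n_hap_src2 = NA_integer_, stringsAsFactors = FALSE)
  sites <- which(keep)
  for (ctg in unique(res$contig)) {
    mk <- markers[markers$contig == ctg, , drop = FALSE]
    rows <- which(res$contig == ctg)
    # per-haplotype positions of carried marker alleles on this contig
    carried <- if (nrow(mk) > 0) {
      ind <- allele_indicator(panel, mk$site, mk$marker_allele)
      apply(ind, 1, function(v) mk$pos[v == 1L], simplify = FALSE)
    } else {
      rep(list(numeric(0)), n_hap)
    }
    # src1[h, j]: haplotype h carries a marker within +/- flank of site j
    src1 <- matrix(FALSE, n_hap, length(rows))
    p <- res$pos[rows]
    for (h in seq_len(n_hap)) {
      mpos <- carried[[h]]
      if (length(mpos) == 0) next
      lo <- findInterval(p - flank_bp - 1, mpos)   # markers strictly below window
      hi <- findInterval(p + flank_bp, mpos)       # markers <= pos + flank
      src1[h, ] <- hi > lo
    }
    g <- panel$geno[, sites[rows], drop = FALSE]
    n1 <- colSums(src1)
    n2 <- n_hap - n1
    c1 <- colSums(g * src1)
    res$f_src1[rows] <- ifelse(n1 > 0, c1 / n1, NA_real_)
    res$f_src2[rows] <- ifelse(n2 > 0, (colSums(g) - c1) / n2, NA_real_)
    res$n_hap_src1[rows] <- as.integer(n1)
    res$n_hap_src2[rows] <- as.integer(n2)
  }
  rownames(res) <- NULL
  class(res) <- c("ancestral_freqs", "data.frame")
  res
}
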