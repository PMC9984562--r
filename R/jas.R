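#' Greedy sliding-window LD pruning of a marker set
#'
#' Within each window of `window_sites` consecutive markers (per contig),
#' any pair with haplotype r-squared above `r2_max` loses its later-position
#' member; the window then advances by `step_sites`. The keep-rule (earlier
#' position wins) makes the result deterministic; the pruned set is always a
#' subset of the input.
#'
#' @param markers a `marker_set` (or any data.frame with `contig`, `pos`,
#'   `site`, `marker_allele`).
#' @param panel the [haplotype_panel()] defining LD.
#' @param window_sites window width in marker count (default 1000).
#' @param step_sites step in marker count (default 200).
#' @param r2_max maximum tolerated r-squared (default 0.8).
#' @return The pruned `marker_set`.
#' @export
ld_prune <- function(markers, panel, window_sites = 1000, step_sites = 200,
                     r2_max = 0.8) {
  require_phased(panel, "ld_prune")
  stopifnot(all(c("contig", "pos", "site", "marker_allele") %in% names(markers)),
            window_sites >= 2, step_sites >= 1)
  keep_all <- logical(0)
  out_rows <- integer(0)
  for (ctg in unique(markers$contig)) {
    rows <- which(markers$contig == ctg)
    rows <- rows[order(markers$pos[rows])]
    ind <- allele_indicator(panel, markers$site[rows],
                            markers$marker_allele[rows])
    keep <- rep(TRUE, length(rows))
    start <- 1L
    repeat {
      end <- min(start + window_sites - 1L, length(rows))
      w <- which(keep)
      w <- w[w >= start & w <= end]
      if (length(w) >= 2) {
        r2 <- hap_r2_matrix(ind[, w, drop = FALSE])
        for (a in seq_along(w)) {
          if (!keep[w[a]]) next
          for (b in seq_along(w)) {
            if (b <= a || !keep[w[b]]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[w[b]] <- FALSE
          }
        }
      }
      if (end >= length(rows)) break
      start <- start + step_sites
    }
    out_rows <- c(out_rows, rows[keep])
  }
  out <- markers[sort(out_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-individual ancestry score from marker dosages (JAS)
#'
#' The score of an individual is its total marker-allele count divided by
#' twice the number of markers with a non-missing genotype in that
#' individual, giving a value in \[0, 1\] that estimates the source-1
#' ancestry fraction. Individuals with no usable marker are excluded with a
#' warning.
#'
#' @param dosages numeric matrix, individuals x markers, entries in 0..2 or
#'   `NA` (missing); built with [allele_dosage()] or [marker_dosages()].
#' @return data.frame of class `jas_table`: `individual`, `n_markers`
#'   (non-missing), `count`, `jas`.
#' @export
jas_score <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%03d", seq_len(nrow(dosages)))
  if (any(!is.na(dosages) & !(dosages %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  n_used <- rowSums(!is.na(dosages))
  cnt <- rowSums(dosages, na.rm = TRUE)
  if (any(n_used == 0))
    warning(sum(n_used == 0), " individual(s) with no usable marker excluded")
  keep <- n_used > 0
  out <- data.frame(individual = rownames(dosages)[keep],
                    n_markers = n_used[keep], count = cnt[keep],
                    jas = cnt[keep] / (2 * n_used[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("jas_table", "data.frame")
  out
}

#' Marker-allele dosages of a panel's individuals
#'
#' @param panel a [haplotype_panel()] containing the marker sites.
#' @param markers a `marker_set`; markers are matched by contig and
#'   position, and unmatched markers are dropped with a message.
#' @return numeric matrix, individuals x markers, of marker-allele dosages.
#' @export
marker_dosages <- function(panel, markers) {
  stopifnot(inherits(panel, "haplotype_panel"))
  idx <- match(paste(markers$contig, markers$pos),
               paste(panel$contig, panel$pos))
  if (anyNA(idx))
    message(sum(is.na(idx)), " marker(s) absent from panel dropped")
  keep <- !is.na(idx)
  dos <- allele_dosage(subset_panel(panel, sites = idx[keep]),
                       allele = markers$marker_allele[keep])
  rownames(dos) <- panel$samples$sample
  dos
}

#' Mean JAS per group
#'
#' @param jas a `jas_table`.
#' @param groups data.frame with columns `individual` and `group`; every
#'   scored individual must be mapped.
#' @return data.frame `group`, `n`, `mean_jas`; empty groups are omitted
#'   with a warning.
#' @export
jas_group_summary <- function(jas, groups) {
  stopifnot(inherits(jas, "jas_table"),
            all(c("individual", "group") %in% names(groups)))
  g <- groups$group[match(jas$individual, groups$individual)]
  if (anyNA(g)) stop("unmapped individual(s): ",
                     paste(utils::head(jas$individual[is.na(g)], 5), collapse = ", "))
  lv <- unique(groups$group)
  empty <- setdiff(lv, g)
  if (length(empty) > 0)
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  agg <- stats::aggregate(jas$jas, by = list(group = g),
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  data.frame(group = agg$group, n = as.integer(agg$x[, "n"]),
             mean_jas = agg$x[, "mean"], stringsAsFactors = FALSE)
}

#' Pearson correlation between group summaries and a covariate
#'
#' Wraps `stats::cor.test` (two-sided t test on df = n - 2).
#'
#' @param x,y aligned numeric vectors (n >= 3, finite, non-constant).
#' @return list of class `correlation_result`: `r`, `df`, `p`, `n`.
#' @export
jas_correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.4f (df = %d, two-sided p = %.3g)\n",
              x$r, x$df, x$p))
  invisible(x)
}
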