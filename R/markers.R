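#' Find target-population-specific variants
#'
#' A variant is specific when one of its alleles is present in the target
#' panel but absent from every reference panel. Both alleles are examined,
#' so a reference allele that is absent from all references (alternate
#' fixed there) is detected symmetrically.
#'
#' Sites absent from a reference panel's site list are treated as "specific
#' allele absent there" when the site falls inside that panel's covered
#' range on the contig (between its first and last site); sites outside
#' every reference's covered range are excluded, with a message.
#'
#' @param target a [haplotype_panel()] of the admixed target population.
#' @param references a single [haplotype_panel()] or a list of them.
#' @return data.frame of class `specific_variants`: `contig`, `pos`, `site`
#'   (column index into `target`), `ref`, `alt`, `specific_allele`
#'   (`"ref"`/`"alt"`), `target_count` (specific-allele count in target).
#' @export
find_specific_variants <- function(target, references) {
  stopifnot(inherits(target, "haplotype_panel"))
  if (inherits(references, "haplotype_panel")) references <- list(references)
  stopifnot(length(references) >= 1,
            all(vapply(references, inherits, TRUE, "haplotype_panel")))
  key_t <- paste(target$contig, target$pos)
  alt_ok <- rep(TRUE, length(key_t))   # alt allele absent from all refs so far
  ref_ok <- rep(TRUE, length(key_t))
  covered <- rep(FALSE, length(key_t))
  for (rf in references) {
    if (anyNA(rf$geno))
      stop("reference panels must have complete genotypes")
    key_r <- paste(rf$contig, rf$pos)
    idx <- match(key_t, key_r)
    hit <- !is.na(idx)
    if (any(hit)) {
      same <- target$ref[hit] == rf$ref[idx[hit]] &
        target$alt[hit] == rf$alt[idx[hit]]
      if (!all(same)) stop("allele mismatch between target and reference at shared sites")
      cnt_alt <- colSums(rf$geno)[idx[hit]]
      n_hap_r <- nrow(rf$geno)
      alt_ok[hit] <- alt_ok[hit] & cnt_alt == 0L
      ref_ok[hit] <- ref_ok[hit] & cnt_alt == n_hap_r
    }
    # a covered-but-unobserved site is monomorphic reference in this panel:
    # its alt allele is absent there, but its ref allele is not
    rng <- tapply(rf$pos, rf$contig, range)
    in_rng <- vapply(seq_along(key_t), function(i) {
      r <- rng[[target$contig[i]]]
      !is.null(r) && target$pos[i] >= r[1] && target$pos[i] <= r[2]
    }, TRUE)
    ref_ok[!hit & in_rng] <- FALSE
    covered <- covered | hit | in_rng
  }
  if (any(!covered))
    message(sum(!covered), " target site(s) outside all reference ranges excluded")
  cnt_alt_t <- colSums(target$geno == 1L, na.rm = TRUE)
  cnt_ref_t <- colSums(target$geno == 0L, na.rm = TRUE)
  is_spec_alt <- covered & alt_ok & cnt_alt_t > 0L
  is_spec_ref <- covered & ref_ok & cnt_ref_t > 0L & !is_spec_alt
  keep <- which(is_spec_alt | is_spec_ref)
  out <- data.frame(
    contig = target$contig[keep], pos = target$pos[keep], site = keep,
    ref = target$ref[keep], alt = target$alt[keep],
    specific_allele = ifelse(is_spec_alt[keep], "alt", "ref"),
    target_count = ifelse(is_spec_alt[keep], cnt_alt_t[keep], cnt_ref_t[keep]),
    stringsAsFactors = FALSE)
  class(out) <- c("specific_variants", "data.frame")
  out
}

#' Typed simulation variants as a specific-variant set
#'
#' Adapter from the simulator's truth table to the marker pipeline: the
#' derived allele (coded as the alternate allele) is the specific allele.
#'
#' @param typed a `typed_variants` table from [type_specific_variants()].
#' @param sim the `sim_panel` it came from.
#' @return A `specific_variants` data.frame carrying the truth `type` column.
#' @export
as_specific_variants <- function(typed, sim) {
  stopifnot(inherits(typed, "typed_variants"), inherits(sim, "sim_panel"))
  out <- data.frame(
    contig = typed$contig, pos = typed$pos, site = typed$site,
    ref = sim$panel$ref[typed$site], alt = sim$panel$alt[typed$site],
    specific_allele = "alt", target_count = typed$target_count,
    type = typed$type, stringsAsFactors = FALSE)
  class(out) <- c("specific_variants", "data.frame")
  out
}

#' Count LD partners among specific variants
#'
#' For every specific variant, counts the other specific variants on the
#' same contig whose haplotype r-squared with it (computed between the
#' specific alleles on the phased panel) exceeds `r2_cut`, within either a
#' symmetric window of `ld_window_bp` around the focal position
#' (`pairing = "radius"`) or the same fixed non-overlapping bin of width
#' `ld_window_bp` (`pairing = "bin"`).
#'
#' @param spec a `specific_variants` table.
#' @param panel the [haplotype_panel()] whose haplotypes define LD (usually
#'   the target panel the variants were found in).
#' @param ld_window_bp pairing window in bp (default 1 Mb).
#' @param r2_cut r-squared cutoff (default 0.01, exclusive: `r2 > r2_cut`).
#' @param pairing `"radius"` (default) or `"bin"`.
#' @return `spec` with a `partner_count` column, class `ld_stats`; pairs
#'   with undefined r-squared (monomorphic site) are skipped.
#' @export
count_ld_partners <- function(spec, panel, ld_window_bp = 1e6, r2_cut = 0.01,
                              pairing = c("radius", "bin")) {
  pairing <- match.arg(pairing)
  cnt <- ld_partner_profile(spec, panel, ld_window_bp, r2_cut, pairing)
  spec$partner_count <- cnt[, 1L]
  class(spec) <- c("ld_stats", class(spec)[!class(spec) %in% "ld_stats"])
  spec
}

# Partner counts for one or many r2 cutoffs in a single r2-matrix pass.
# Returns a matrix: variants x cutoffs. Shared by count_ld_partners and the
# r2-cutoff sweep, which would otherwise recompute the r2 matrix per cutoff.
ld_partner_profile <- function(spec, panel, ld_window_bp = 1e6,
                               r2_cut = 0.01, pairing = "radius") {
  stopifnot(inherits(spec, "specific_variants"))
  require_phased(panel, "count_ld_partners")
  if (!all(spec$site >= 1 & spec$site <= ncol(panel$geno)))
    stop("specific variants not present in panel")
  counts <- matrix(0L, nrow(spec), length(r2_cut))
  for (ctg in unique(spec$contig)) {
    rows <- which(spec$contig == ctg)
    ind <- allele_indicator(panel, spec$site[rows], spec$specific_allele[rows])
    r2 <- hap_r2_matrix(ind)
    pos <- spec$pos[rows]
    near <- if (pairing == "radius") {
      abs(outer(pos, pos, "-")) <= ld_window_bp
    } else {
      b <- (pos - 1) %/% ld_window_bp
      outer(b, b, "==")
    }
    diag(near) <- FALSE
    for (k in seq_along(r2_cut)) {
      hit <- !is.na(r2) & r2 > r2_cut[k] & near
      counts[rows, k] <- as.integer(rowSums(hit))
    }
  }
  counts
}

#' Specific-variant density per contig with low-density masking
#'
#' The per-contig density (specific variants per kb) is the AMI denominator.
#' To flag likely artifact regions, the contig is cut into `bin_bp` bins and
#' bins whose density falls below (mean - 1 sd) of that contig's bin
#' densities are masked; masked bins are excluded from AMI calling.
#'
#' @param spec a `specific_variants` table.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param bin_bp masking bin width (default 1 Mb).
#' @param sd_type `"population"` (n denominator, default) or `"sample"`
#'   (n - 1) for the bin-density standard deviation.
#' @return An object of class `density_profile`: `$contigs` (contig,
#'   n_specific, length_bp, density per kb) and `$bins` (contig, start, end,
#'   1-based inclusive, density, masked).
#' @export
density_profile <- function(spec, contig_lengths, bin_bp = 1e6,
                            sd_type = c("population", "sample")) {
  stopifnot(inherits(spec, "specific_variants"))
  sd_type <- match.arg(sd_type)
  if (is.null(names(contig_lengths)) || anyNA(names(contig_lengths)))
    stop("contig_lengths must be named by contig")
  if (!all(unique(spec$contig) %in% names(contig_lengths)))
    stop("missing contig lengths for some specific variants")
  ctgs <- names(contig_lengths)
  contigs <- data.frame(
    contig = ctgs,
    n_specific = as.integer(table(factor(spec$contig, levels = ctgs))),
    length_bp = as.numeric(contig_lengths), stringsAsFactors = FALSE)
  contigs$density <- contigs$n_specific / (contigs$length_bp / 1000)
  if (any(contigs$n_specific == 0L))
    warning("contig(s) with zero specific variants: ",
            paste(contigs$contig[contigs$n_specific == 0L], collapse = ", "))
  bins <- do.call(rbind, lapply(ctgs, function(ctg) {
    len <- contig_lengths[[ctg]]
    starts <- seq(1, len, by = bin_bp)
    ends <- pmin(starts + bin_bp - 1, len)
    p <- spec$pos[spec$contig == ctg]
    n <- as.integer(table(factor((p - 1) %/% bin_bp + 1,
                                 levels = seq_along(starts))))
    dens <- n / ((ends - starts + 1) / 1000)
    mu <- mean(dens)
    sdv <- if (sd_type == "population") {
      sqrt(mean((dens - mu)^2))
    } else {
      stats::sd(dens)
    }
    masked <- if (is.na(sdv)) rep(FALSE, length(dens)) else dens < mu - sdv
    data.frame(contig = ctg, start = starts, end = ends, density = dens,
               masked = masked, stringsAsFactors = FALSE)
  }))
  structure(list(contigs = contigs, bins = bins, bin_bp = bin_bp,
                 sd_type = sd_type),
            class = "density_profile")
}

#' Ancestry-marker index (AMI)
#'
#' AMI of a specific variant is its LD partner count divided by the
#' per-contig specific-variant density per kb, so that the partner count is
#' normalized for each contig. Variants falling in masked low-density bins,
#' or on contigs with zero density, are dropped.
#'
#' @param ld an `ld_stats` table from [count_ld_partners()].
#' @param dens a [density_profile()] built from the same variant set.
#' @return `ld` with `density` and `ami` columns, class `ami_table`.
#' @export
compute_ami <- function(ld, dens) {
  stopifnot(inherits(ld, "ld_stats"), inherits(dens, "density_profile"))
  dmap <- stats::setNames(dens$contigs$density, dens$contigs$contig)
  if (!all(ld$contig %in% names(dmap)))
    stop("density profile does not cover all contigs")
  d <- dmap[ld$contig]
  if (any(d == 0)) {
    warning(sum(d == 0), " variant(s) on zero-density contig(s) dropped")
  }
  mask <- dens$bins[dens$bins$masked, , drop = FALSE]
  in_mask <- rep(FALSE, nrow(ld))
  for (i in seq_len(nrow(mask))) {
    in_mask <- in_mask | (ld$contig == mask$contig[i] &
                            ld$pos >= mask$start[i] & ld$pos <= mask$end[i])
  }
  keep <- d > 0 & !in_mask
  out <- ld[keep, , drop = FALSE]
  out$density <- unname(d[keep])
  out$ami <- out$partner_count / out$density
  class(out) <- c("ami_table", class(ld)[!class(ld) %in% "ami_table"])
  rownames(out) <- NULL
  out
}

#' Call ancestry markers above an AMI threshold
#'
#' @param ami an `ami_table`.
#' @param threshold AMI cutoff; variants with `ami > threshold` are called.
#' @return data.frame of class `marker_set`: `contig`, `pos`, `ref`, `alt`,
#'   `marker_allele` (`"ref"`/`"alt"`), `partner_count`, `density`, `ami`,
#'   plus `site` when present.
#' @export
call_markers <- function(ami, threshold) {
  stopifnot(inherits(ami, "ami_table"), is.numeric(threshold),
            length(threshold) == 1, threshold >= 0 || is.infinite(threshold))
  keep <- ami$ami > threshold
  cols <- intersect(c("contig", "pos", "site", "ref", "alt",
                      "specific_allele", "partner_count", "density", "ami"),
                    names(ami))
  out <- ami[keep, cols, drop = FALSE]
  names(out)[names(out) == "specific_allele"] <- "marker_allele"
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  class(out) <- c("marker_set", "data.frame")
  out
}
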