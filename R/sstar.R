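#' S* scoring configuration
#'
#' Chain-scoring constants of the classical S* statistic: a pair of
#' candidate sites at distance d contributes `match_bonus + d` when the
#' individual's dosages agree, `mismatch_penalty * |dosage difference|`
#' when they disagree, and is excluded (`-Inf`) when `d < min_pair_bp`.
#'
#' @param match_bonus bonus for a dosage-matched pair (default 5000).
#' @param mismatch_penalty penalty per unit dosage difference (default
#'   -10000).
#' @param min_pair_bp minimum pair distance in bp (default 10).
#' @param window_bp analysis window width (default 50,000).
#' @return list of class `sstar_config`.
#' @export
sstar_config <- function(match_bonus = 5000, mismatch_penalty = -10000,
                         min_pair_bp = 10, window_bp = 50000) {
  stopifnot(min_pair_bp >= 0, window_bp >= 1, mismatch_penalty <= 0)
  structure(list(match_bonus = match_bonus,
                 mismatch_penalty = mismatch_penalty,
                 min_pair_bp = min_pair_bp, window_bp = window_bp),
            class = "sstar_config")
}

#' S* chain score for one individual
#'
#' Dynamic program over the individual's candidate sites (sites carrying an
#' allele absent from the reference panel), maximizing the chain score
#' `S(j) = max over i < j of (max(S(i), 0) + s(i, j))` with the pair score
#' from [sstar_config()]; the reported S* is `max(0, max_j S(j))`, and 0
#' when fewer than two candidate sites exist.
#'
#' @param dosages candidate-allele dosages (1 or 2) at the candidate sites.
#' @param positions sorted 1-based positions of the candidate sites.
#' @param config an [sstar_config()].
#' @return S* score (numeric, >= 0).
#' @export
sstar_score <- function(dosages, positions, config = sstar_config()) {
  stopifnot(inherits(config, "sstar_config"),
            length(dosages) == length(positions))
  n <- length(positions)
  if (n >= 2 && is.unsorted(positions, strictly = FALSE))
    stop("positions must be sorted")
  if (n < 2) return(0)
  s_chain <- numeric(n)
  s_chain[1] <- 0
  best <- 0
  for (j in 2:n) {
    cand <- -Inf
    for (i in 1:(j - 1)) {
      d <- positions[j] - positions[i]
      if (d < config$min_pair_bp) next
      pair <- if (dosages[i] == dosages[j]) config$match_bonus + d else
        config$mismatch_penalty * abs(dosages[i] - dosages[j])
      cand <- max(cand, max(s_chain[i], 0) + pair)
    }
    s_chain[j] <- cand
    best <- max(best, cand)
  }
  max(0, best)
}

# Candidate allele per site: the allele absent from the reference panel
# ("alt", "ref" or NA when both alleles segregate there).
sstar_candidate_allele <- function(reference) {
  cnt <- colSums(reference$geno)
  n <- nrow(reference$geno)
  ifelse(cnt == 0L, "alt", ifelse(cnt == n, "ref", NA_character_))
}

#' Windowed S* over a target panel
#'
#' Cuts each contig into non-overlapping windows of `config$window_bp`,
#' determines each target individual's candidate sites (sites where the
#' individual carries at least one allele absent from the reference panel),
#' and computes the S* chain score per individual per window.
#'
#' @param panel target [haplotype_panel()] (diploid dosages are used, so an
#'   unphased panel is accepted).
#' @param reference reference [haplotype_panel()] on the same sites.
#' @param config an [sstar_config()].
#' @return data.frame of class `sstar_table`: `contig`, `window_start`,
#'   `window_end` (1-based inclusive), `individual`, `n_sites`, `sstar`,
#'   plus per-window `sstar_max` repeated on each row.
#' @export
sstar_windows <- function(panel, reference, config = sstar_config()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(reference, "haplotype_panel"))
  if (!identical(paste(panel$contig, panel$pos),
                 paste(reference$contig, reference$pos)))
    stop("target and reference panels must be aligned on the same sites")
  cand <- sstar_candidate_allele(reference)
  rows <- list()
  w <- config$window_bp
  for (ctg in unique(panel$contig)) {
    on_ctg <- which(panel$contig == ctg & !is.na(cand))
    if (length(on_ctg) == 0) next
    dos <- allele_dosage(subset_panel(panel, sites = on_ctg),
                         allele = cand[on_ctg])
    pos <- panel$pos[on_ctg]
    win <- (pos - 1) %/% w
    for (wk in sort(unique(win))) {
      in_w <- win == wk
      p_w <- pos[in_w]
      scores <- vapply(seq_len(nrow(dos)), function(ind) {
        dvec <- dos[ind, in_w]
        use <- !is.na(dvec) & dvec > 0
        sstar_score(dvec[use], p_w[use], config)
      }, numeric(1))
      n_sites <- vapply(seq_len(nrow(dos)), function(ind) {
        dvec <- dos[ind, in_w]
        sum(!is.na(dvec) & dvec > 0)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, window_start = wk * w + 1,
        window_end = (wk + 1) * w, individual = panel$samples$sample,
        n_sites = as.integer(n_sites), sstar = scores,
        sstar_max = max(scores), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(), window_start = numeric(),
                      window_end = numeric(), individual = character(),
                      n_sites = integer(), sstar = numeric(),
                      sstar_max = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("sstar_table", "data.frame")
  out
}

# Diplotype ancestry group of each admixed individual in each window:
# "hom2", "het" or "hom1" by the majority ancestry of each haplotype
# within the window.
window_diplotype_groups <- function(sim, window_bp) {
  tr <- sim$tracts
  L <- sim$model$seq_len_bp
  starts <- seq(0, L - 1, by = window_bp)
  n_hap <- length(group_haps(sim, "admixed"))
  out <- matrix("", n_hap / 2L, length(starts))
  hap_src1 <- matrix(0, n_hap, length(starts))
  for (k in seq_along(starts)) {
    ws <- starts[k]; we <- min(ws + window_bp, L)
    ov <- pmin(tr$end, we) - pmax(tr$start, ws)
    sel <- ov > 0 & tr$source == 1L
    s1 <- rowsum(ov[sel], tr$hap[sel])
    hap_src1[as.integer(rownames(s1)) + 1L, k] <- s1
  }
  hap_is_1 <- hap_src1 > (window_bp / 2)
  grp <- hap_is_1[seq(1, n_hap, 2), , drop = FALSE] +
    hap_is_1[seq(2, n_hap, 2), , drop = FALSE]
  structure(c("hom2", "het", "hom1")[grp + 1L],
            dim = dim(grp),
            window_start = starts + 1)
}

#' Two-scenario S* separability contrast
#'
#' Runs the S* experiment under two demographies - typically an
#' archaic-scale divergence (e.g. split 40,000 generations ago, 4%
#' source-1 ancestry) and a recent divergence (split 1,200 generations
#' ago, 12%) - and summarizes, per scenario, how well S* separates
#' individuals who are homozygous for source-1-derived haplotypes in a
#' window from the remaining individuals (ROC AUC), together with the
#' Spearman correlation between a window's S*max and its count of true
#' source-1-derived (type 1) variants over windows overlapping a source-1
#' tract.
#'
#' @param model_a,model_b two [demography_model()] objects.
#' @param n_rep replicates per scenario (default 10).
#' @param base_seed integer seed.
#' @param config an [sstar_config()].
#' @return list of class `sstar_contrast` with one entry per scenario:
#'   `$windows` (per individual-window rows with `group`), `$auc` (hom
#'   source-1 vs rest), `$auc_carrier` (source-1 carriers vs hom source-2),
#'   `$spearman`, `$group_summary` (median/mean S* by diplotype group).
#' @export
sstar_scenario_contrast <- function(model_a, model_b, n_rep = 10, base_seed,
                                    config = sstar_config()) {
  if (missing(base_seed)) stop("an explicit base_seed is required")
  run_one <- function(model, seed_off) {
    set.seed(base_seed + seed_off)
    seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
    out_dir <- tempfile("sstar_contrast")
    dirs <- simulate_panels(model, seeds, out_dir = out_dir)
    on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
    all_w <- list()
    for (i in seq_along(dirs)) {
      sim <- read_sim_panel(dirs[[i]])
      target <- group_panel(sim, "admixed")
      reference <- group_panel(sim, "source2_modern")
      sw <- sstar_windows(target, reference, config)
      grp <- window_diplotype_groups(sim, config$window_bp)
      wk <- (sw$window_start - 1) %/% config$window_bp + 1L
      ind <- match(sw$individual, target$samples$sample)
      sw$group <- grp[cbind(ind, wk)]
      # count of true type-1 variants per window, over windows touching a
      # source-1 tract
      typed <- type_specific_variants(sim)
      t1_win <- (typed$pos[typed$type == 1L] - 1) %/% config$window_bp + 1L
      n_t1 <- tabulate(t1_win, nbins = max(wk))
      touched <- vapply(seq_len(max(wk)), function(k) {
        any(grp[, k] != "hom2")
      }, TRUE)
      sw$n_type1 <- n_t1[wk]
      sw$tract_window <- touched[wk]
      sw$rep <- i
      all_w[[i]] <- sw
    }
    w <- do.call(rbind, all_w)
    auc <- if (any(w$group == "hom1") && any(w$group != "hom1")) {
      roc_analysis(w$sstar, w$group == "hom1")$auc
    } else NA_real_
    # the contrast the original S* experiment draws: individuals carrying a
    # source-1-derived haplotype in the window versus hom-source-2 ones
    auc_carrier <- if (any(w$group != "hom2") && any(w$group == "hom2")) {
      roc_analysis(w$sstar, w$group != "hom2")$auc
    } else NA_real_
    wm <- w[!duplicated(paste(w$rep, w$contig, w$window_start)) &
              w$tract_window, , drop = FALSE]
    spearman <- if (nrow(wm) >= 3 && stats::sd(wm$n_type1) > 0 &&
                    stats::sd(wm$sstar_max) > 0) {
      stats::cor(wm$n_type1, wm$sstar_max, method = "spearman")
    } else NA_real_
    gs <- stats::aggregate(w$sstar, by = list(group = w$group),
                           FUN = function(v) c(n = length(v), mean = mean(v),
                                               median = stats::median(v)))
    list(windows = w, auc = auc, auc_carrier = auc_carrier,
         spearman = spearman,
         group_summary = data.frame(group = gs$group,
                                    n = as.integer(gs$x[, "n"]),
                                    mean = gs$x[, "mean"],
                                    median = gs$x[, "median"]))
  }
  structure(list(scenario_a = run_one(model_a, 0L),
                 scenario_b = run_one(model_b, 1L),
                 config = config, n_rep = n_rep, base_seed = base_seed),
            class = "sstar_contrast")
}

#' @export
print.sstar_contrast <- function(x, ...) {
  cat(sprintf(
    paste0("sstar_contrast (%d replicates/scenario):\n",
           "  scenario A: carrier AUC = %.3f, hom1 AUC = %.3f, Spearman(S*max, type-1 count) = %.3f\n",
           "  scenario B: carrier AUC = %.3f, hom1 AUC = %.3f, Spearman = %.3f\n"),
    x$n_rep, x$scenario_a$auc_carrier, x$scenario_a$auc,
    x$scenario_a$spearman, x$scenario_b$auc_carrier, x$scenario_b$auc,
    x$scenario_b$spearman))
  invisible(x)
}
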