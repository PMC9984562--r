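# Independent brute-force oracles used to cross-check the implementation.

# All-pairs LD partner count by direct evaluation of the r2 formula,
# independent of count_ld_partners / hap_r2_matrix.
brute_partner_counts <- function(ind, pos, window_bp, r2_cut) {
  n <- ncol(ind)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || abs(pos[i] - pos[j]) > window_bp) next
      pa <- mean(ind[, i]); pb <- mean(ind[, j])
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) next
      pab <- mean(ind[, i] * ind[, j])
      r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
      if (r2 > r2_cut) cnt[i] <- cnt[i] + 1L
    }
  }
  cnt
}

# S* by exhaustive maximization over all ordered site subsets (>= 2 sites).
brute_sstar <- function(dosages, positions, config = sstar_config()) {
  n <- length(positions)
  if (n < 2) return(0)
  pair_score <- function(i, j) {
    d <- positions[j] - positions[i]
    if (d < config$min_pair_bp) return(-Inf)
    if (dosages[i] == dosages[j]) config$match_bonus + d
    else config$mismatch_penalty * abs(dosages[i] - dosages[j])
  }
  best <- 0
  subsets <- unlist(lapply(2:n, function(k) {
    utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)
  for (s in subsets) {
    sc <- sum(vapply(seq_len(length(s) - 1),
                     function(t) pair_score(s[t], s[t + 1]), numeric(1)))
    best <- max(best, sc)
  }
  max(0, best)
}

# Trapezoidal AUC by direct probability comparison (Mann-Whitney), an
# independent check of the threshold-sweep implementation.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Small deterministic random panel for property tests.
random_panel <- function(n_hap = 20, n_site = 40, seed = 1,
                         contig = "chr1", max_pos = 2e6) {
  set.seed(seed)
  geno <- matrix(rbinom(n_hap * n_site, 1, runif(n_site, 0.05, 0.95)),
                 n_hap, n_site, byrow = FALSE)
  pos <- sort(sample.int(max_pos, n_site))
  haplotype_panel(geno, contig = contig, pos = pos)
}

tiny_panels <- amitools:::fixture_tiny_panels
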