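test_that("clumping keeps the smaller-p member of linked pairs", {
  # sites 1,2 identical (r2 = 1); site 3 independent
  g <- cbind(c(1L, 1L, 0L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L, 1L, 0L),
             c(1L, 0L, 1L, 0L, 0L, 1L))
  panel <- haplotype_panel(g, contig = "chr1", pos = c(100L, 200L, 300L))
  gwas <- data.frame(id = c("a", "b", "c"), contig = "chr1",
                     pos = c(100L, 200L, 300L), effect_allele = "T",
                     beta = 0.1, p = c(1e-5, 1e-4, 1e-3))
  kept <- clump(gwas, panel, p_max = 0.01)
  expect_equal(kept$id, c("a", "c"))
  # single record below threshold
  expect_equal(clump(gwas[3, ], panel, p_max = 0.01)$id, "c")
  # p threshold cuts before clumping
  expect_equal(clump(gwas, panel, p_max = 5e-5)$id, "a")
  expect_warning(clump(gwas, panel, p_max = 1e-9), "no GWAS records")
  # records outside the window are never clumped away
  gwas2 <- gwas; gwas2$pos <- c(100L, 200L, 300L)
  kept2 <- clump(gwas2, panel, p_max = 0.01, window_kb = 0.05)
  expect_equal(nrow(kept2), 3)
})

test_that("mean 2-beta-f evaluates the polygenic sum", {
  expect_equal(mean_2bf(0.5, 1)$value, 1.0)
  expect_equal(mean_2bf(c(0, 0, 0), c(1, 2, 3))$value, 0.0)
  m <- mean_2bf(c(0.2, 0.5), c(0.5, -1))
  expect_equal(m$value, -0.4)  # (2*0.5*0.2 + 2*(-1)*0.5) / 2
  # pairwise exclusion of missing frequencies
  m2 <- mean_2bf(c(0.2, NA, 0.5), c(0.5, 9, -1))
  expect_equal(m2$value, -0.4)
  expect_equal(m2$n_missing, 1)
  expect_error(mean_2bf(NA_real_, 1), "no SNP")
  # linearity in beta and in f
  set.seed(4)
  f <- runif(20); b <- rnorm(20)
  expect_equal(mean_2bf(f, 2 * b)$value, 2 * mean_2bf(f, b)$value)
  expect_equal(mean_2bf(2 * f, b)$value, 2 * mean_2bf(f, b)$value)
})

test_that("D is zero under identical frequencies and flips sign under label swap", {
  set.seed(8)
  f <- runif(30, 0.1, 0.9)
  b <- rnorm(30)
  same <- trait_d(f, f, b, n_perm = 100, seed = 42)
  expect_equal(same$d, 0)
  expect_true(same$degenerate)

  f2 <- pmin(pmax(f + rnorm(30, 0, 0.2), 0), 1)
  ab <- trait_d(f, f2, b, n_perm = 500, seed = 42)
  ba <- trait_d(f2, f, b, n_perm = 500, seed = 42)
  expect_equal(ab$d, -ba$d)
  expect_equal(ab$p97.5 - ab$p2.5, ba$p97.5 - ba$p2.5)  # null width unchanged
  # determinism under a fixed seed
  again <- trait_d(f, f2, b, n_perm = 500, seed = 42)
  expect_identical(ab, again)
  # null distribution centred between the two ancestry means
  mid <- (ab$mean2bf_src1 + ab$mean2bf_src2) / 2
  expect_true(ab$p2.5 <= mid && mid <= ab$p97.5)
  expect_true((ab$d > 0) == (ab$mean2bf_src1 > ab$mean2bf_src2))
})

test_that("null calibration: |D| > 1 is rare when ancestries are exchangeable", {
  set.seed(17)
  n_traits <- 200
  exceed <- logical(n_traits)
  for (t in seq_len(n_traits)) {
    n <- 40
    f1 <- runif(n); f2 <- runif(n); b <- rnorm(n)
    d <- trait_d(f1, f2, b, n_perm = 300, seed = 1000 + t)$d
    exceed[t] <- abs(d) > 1
  }
  # the observed contrast is itself a draw from the null, so it should
  # exceed the central 95% width only rarely (binomial slack on 200 trials)
  expect_lt(mean(exceed), 0.12)
})

test_that("a large-effect extreme-frequency SNP amplifies |D| under strict p", {
  set.seed(23)
  n <- 50
  f1 <- runif(n, 0.3, 0.7); f2 <- f1 + rnorm(n, 0, 0.02)
  b <- rnorm(n, 0, 0.05)
  p <- runif(n, 1e-3, 1e-2)
  # one rs964184-like SNP: huge beta, extreme ancestry contrast, tiny p
  f1[1] <- 0.94; f2[1] <- 0.18; b[1] <- 0.16; p[1] <- 1e-20
  d_loose <- abs(trait_d(f1[p < 1e-2], f2[p < 1e-2], b[p < 1e-2],
                         n_perm = 500, seed = 5)$d)
  d_strict <- abs(trait_d(f1[p < 1e-4], f2[p < 1e-4], b[p < 1e-4],
                          n_perm = 500, seed = 5)$d)
  expect_gt(d_strict, d_loose)
})

test_that("effect alleles are harmonized onto the frequency table", {
  fq <- data.frame(contig = "chr1", pos = c(100L, 200L, 300L, 400L),
                   ref = c("A", "A", "A", "C"), alt = c("G", "C", "T", "G"),
                   f_sample = c(0.5, 0.4, 0.3, 0.2),
                   f_src1 = c(0.9, 0.8, 0.7, 0.6),
                   f_src2 = c(0.1, 0.2, 0.3, 0.4),
                   n_hap_src1 = 10L, n_hap_src2 = 10L)
  class(fq) <- c("ancestral_freqs", "data.frame")
  gwas <- data.frame(id = c("s1", "s2", "s3", "s4"), contig = "chr1",
                     pos = c(100L, 200L, 300L, 400L),
                     effect_allele = c("G", "A", "T", "T"),
                     beta = 1, p = 0.001)
  expect_warning(h <- harmonize_effects(gwas, fq), "ambiguous|neither")
  # s1: effect = alt, frequencies unchanged
  expect_equal(h$f_src1[h$id == "s1"], 0.9)
  # s2: effect = ref, frequencies flipped
  expect_equal(h$f_src1[h$id == "s2"], 1 - 0.8)
  # s3 is A/T ambiguous, s4 matches neither allele: both dropped
  expect_false(any(c("s3", "s4") %in% h$id))
})
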