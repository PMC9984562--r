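make_marker_df <- function(panel, sites, allele = "alt") {
  mk <- data.frame(contig = panel$contig[sites], pos = panel$pos[sites],
                   site = sites, ref = panel$ref[sites],
                   alt = panel$alt[sites], marker_allele = allele,
                   stringsAsFactors = FALSE)
  class(mk) <- c("marker_set", "data.frame")
  mk
}

test_that("LD pruning keeps one of each high-LD pair, earlier position first", {
  # markers 1 and 2 identical (r2 = 1), marker 3 independent
  g <- cbind(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L),
             c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  panel <- haplotype_panel(g, contig = "chr1", pos = c(100L, 200L, 300L))
  mk <- make_marker_df(panel, 1:3)
  pruned <- ld_prune(mk, panel, window_sites = 10, step_sites = 2,
                     r2_max = 0.8)
  expect_equal(pruned$pos, c(100, 300))

  # all mutually identical: exactly one survivor
  g2 <- matrix(rep(c(1L, 1L, 0L, 0L), 4), ncol = 4)
  panel2 <- haplotype_panel(g2, contig = "chr1",
                            pos = c(10L, 20L, 30L, 40L))
  pruned2 <- ld_prune(make_marker_df(panel2, 1:4), panel2,
                      window_sites = 10, step_sites = 2, r2_max = 0.8)
  expect_equal(pruned2$pos, 10)

  # all independent: all survive
  set.seed(5)
  panel3 <- random_panel(n_hap = 40, n_site = 6, seed = 5)
  mk3 <- make_marker_df(panel3, 1:6)
  pruned3 <- ld_prune(mk3, panel3, window_sites = 6, step_sites = 2,
                      r2_max = 0.999)
  expect_true(nrow(pruned3) >= 5)  # near-independent random markers
  expect_true(all(pruned3$pos %in% mk3$pos))
})

test_that("pruning is deterministic and returns a subset", {
  panel <- random_panel(n_hap = 30, n_site = 25, seed = 11)
  mk <- make_marker_df(panel, 1:25)
  p1 <- ld_prune(mk, panel, window_sites = 8, step_sites = 3, r2_max = 0.5)
  p2 <- ld_prune(mk, panel, window_sites = 8, step_sites = 3, r2_max = 0.5)
  expect_identical(p1, p2)
  expect_true(all(p1$pos %in% mk$pos))
  # surviving pairs within one window respect the r2 bound
  ind <- amitools:::allele_indicator(panel, p1$site, p1$marker_allele)
  r2 <- amitools:::hap_r2_matrix(ind)
  diag(r2) <- NA
  near <- abs(outer(seq_len(nrow(p1)), seq_len(nrow(p1)), "-")) < 8
  expect_true(all(r2[near & !is.na(r2)] <= 0.5))
})

test_that("JAS is marker-allele count over twice the usable markers", {
  dos <- rbind(ind_a = c(2, 2, 2), ind_b = c(0, 0, 0), ind_c = c(0, 1, 2),
               ind_d = c(NA, 1, 2))
  jas <- jas_score(dos)
  expect_equal(jas$jas[jas$individual == "ind_a"], 1.0)
  expect_equal(jas$jas[jas$individual == "ind_b"], 0.0)
  expect_equal(jas$jas[jas$individual == "ind_c"], 0.5)  # 3 / (2 * 3)
  # missing marker shrinks the denominator, not the score basis
  expect_equal(jas$jas[jas$individual == "ind_d"], 3 / 4)
  expect_equal(jas$n_markers[jas$individual == "ind_d"], 2)
  expect_warning(jas_score(rbind(c(NA, NA))), "no usable marker")
  expect_error(jas_score(rbind(c(3, 0))), "dosages")
})

test_that("JAS is invariant to marker order and individual duplication", {
  set.seed(21)
  dos <- matrix(rbinom(60, 2, 0.3), 10, 6,
                dimnames = list(sprintf("i%02d", 1:10), NULL))
  j1 <- jas_score(dos)
  j2 <- jas_score(dos[, sample(6)])
  expect_equal(j1$jas, j2$jas)
  j3 <- jas_score(rbind(dos, dup = dos[3, , drop = FALSE]))
  expect_equal(j3$jas[11], j1$jas[3])
})

test_that("marker dosages map panel genotypes onto marker alleles", {
  p <- tiny_panels()$target
  mk <- make_marker_df(p, c(1, 3, 5))
  dos <- marker_dosages(p, mk)
  expect_equal(dim(dos), c(10, 3))
  expect_equal(unname(dos[1, ]), c(2, 2, 2))  # haps 1-2 carry all three
  expect_equal(unname(dos[2, ]), c(0, 0, 0))
  mk_ref <- make_marker_df(p, 4, allele = "ref")
  dos_ref <- marker_dosages(p, mk_ref)
  # haps 3:6 carry alt at site 4, so individuals 2 and 3 have ref dosage 0
  expect_equal(unname(dos_ref[, 1]), c(2, 0, 0, 2, 2, 2, 2, 2, 2, 2))
})

test_that("group summaries average within groups and flag empty groups", {
  jas <- structure(data.frame(individual = c("a", "b", "c"),
                              n_markers = 3L, count = 1L,
                              jas = c(0.2, 0.4, 0.9)),
                   class = c("jas_table", "data.frame"))
  groups <- data.frame(individual = c("a", "b", "c"),
                       group = c("g1", "g1", "g2"))
  gs <- jas_group_summary(jas, groups)
  expect_equal(gs$mean_jas[gs$group == "g1"], 0.3)
  expect_equal(gs$mean_jas[gs$group == "g2"], 0.9)
  expect_equal(gs$n, c(2L, 1L))
  groups2 <- rbind(groups, data.frame(individual = "zz", group = "g3"))
  expect_warning(jas_group_summary(jas, groups2), "empty group")
  expect_error(jas_group_summary(jas, groups[1:2, ]), "unmapped")
})

test_that("correlation wraps cor.test with df = n - 2", {
  x <- seq_len(10)
  r <- jas_correlate(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(r$df, 8)
  r2 <- jas_correlate(x, -x)
  expect_equal(r2$r, -1)
  set.seed(2)
  x45 <- rnorm(45); y45 <- x45 + rnorm(45)
  r3 <- jas_correlate(x45, y45)
  expect_equal(r3$df, 43)
  ct <- cor.test(x45, y45)
  expect_equal(r3$p, ct$p.value)
  expect_equal(r3$r, unname(ct$estimate))
  expect_error(jas_correlate(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(jas_correlate(1:2, 2:3), "at least 3")
})
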