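#' Deterministic toy datasets for tests and examples
#'
#' Writes a small, hand-checkable dataset into `dir`:
#'
#' * `tiny-panel` - `target.vcf` (10 diploid samples) and `reference.vcf`
#'   (10 samples) on a 1 kb contig `chr1`. Three target-specific variants
#'   at 100/500/900 bp sit in perfect LD on the same two haplotypes, so
#'   with per-contig density 3/kb each has AMI = 2/3; two further sites
#'   are shared with the reference and a reference-only alternate allele
#'   exercises the allele-symmetry rule.
#' * `tiny-markers` - `markers.tsv`: the three specific variants above as a
#'   called marker set.
#' * `tiny-gwas` - `gwas.tsv`: two records with betas (0.5, -1) whose
#'   source-1 frequencies (0.2, 0.5) give mean 2-beta-f = -0.4.
#' * `sim-replicate` - one reduced-scale simulated replicate
#'   (`rep_<seed>/`) under the default demography with a 100 kb contig and
#'   40 haplotypes per group.
#'
#' @param kind one of `"tiny-panel"`, `"tiny-markers"`, `"tiny-gwas"`,
#'   `"sim-replicate"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed (only `sim-replicate` is stochastic, but the
#'   seed is recorded for all kinds).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture <- function(kind, dir = tempfile("fixture"), seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(
    kind,
    "tiny-panel" = {
      p <- fixture_tiny_panels()
      c(target = write_haplotype_panel(
          p$target, file.path(dir, "target.vcf"),
          contig_lengths = c(chr1 = 1000)),
        reference = write_haplotype_panel(
          p$reference, file.path(dir, "reference.vcf"),
          contig_lengths = c(chr1 = 1000)))
    },
    "tiny-markers" = {
      mk <- data.frame(contig = "chr1", pos = c(100L, 500L, 900L),
                       ref = "A", alt = "G", marker_allele = "alt",
                       partner_count = 2L, density = 3, ami = 2 / 3,
                       stringsAsFactors = FALSE)
      class(mk) <- c("marker_set", "data.frame")
      c(markers = write_marker_set(mk, file.path(dir, "markers.tsv")))
    },
    "tiny-gwas" = {
      gw <- data.frame(id = c("rs1", "rs2"), contig = "chr1",
                       pos = c(100L, 500L), effect_allele = "G",
                       beta = c(0.5, -1), p = c(1e-6, 1e-5),
                       f_src1 = c(0.2, 0.5), stringsAsFactors = FALSE)
      c(gwas = write_tsv(gw, file.path(dir, "gwas.tsv")))
    },
    "sim-replicate" = {
      model <- demography_model(seq_len_bp = 1e5, n_hap_per_group = 40)
      dirs <- simulate_panels(model, seed, out_dir = dir)
      c(replicate = unname(dirs[1]))
    },
    stop("unknown fixture kind: ", kind))
  invisible(files)
}

# The tiny target/reference panels behind the tiny-panel fixture.
# Returned in memory so tests can also use them without file I/O.
fixture_tiny_panels <- function() {
  n_hap <- 20L
  empty <- integer(n_hap)
  carrier <- function(rows) { v <- integer(n_hap); v[rows] <- 1L; v }
  # sites: 100/500/900 specific (perfect LD, haps 1-2); 300 shared; 700 ref
  # allele absent from target is exercised from the reference side
  # allele pairs chosen strand-unambiguous so GWAS harmonization works
  target <- haplotype_panel(
    cbind(carrier(1:2), carrier(c(5, 9, 13)), carrier(1:2),
          carrier(3:6), carrier(1:2)),
    contig = "chr1", pos = c(100L, 300L, 500L, 700L, 900L),
    ref = c("A", "C", "A", "G", "A"), alt = c("G", "T", "G", "A", "G"),
    samples = data.frame(sample = sprintf("tgt%02d", 1:10),
                         population = "target"))
  reference <- haplotype_panel(
    cbind(empty, carrier(c(2, 8)), empty, carrier(1:12), empty),
    contig = "chr1", pos = c(100L, 300L, 500L, 700L, 900L),
    ref = c("A", "C", "A", "G", "A"), alt = c("G", "T", "G", "A", "G"),
    samples = data.frame(sample = sprintf("ref%02d", 1:10),
                         population = "reference"))
  list(target = target, reference = reference)
}
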