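#' Two-source admixture demography
#'
#' Describes the simulated history: a source-1 lineage (e.g. the Jomon
#' lineage) splits from a source-2 lineage (e.g. continental East Asians)
#' `split_gen` generations ago; the modern admixed population is the
#' continuation of the source-1 lineage, which receives one-way migration
#' from source-2 between `adm_start_gen` and `adm_end_gen` generations ago.
#' The constant per-generation migration rate `m` is derived so that the
#' final source-1 ancestry fraction equals `alpha`:
#' `(1 - m)^G = alpha` with `G = adm_start_gen - adm_end_gen`, i.e.
#' `m = 1 - alpha^(1/G)`.
#'
#' Defaults reproduce a mainland-Japanese-like history: split 1,200
#' generations ago, admixture between 120 and 80 generations ago, 12%
#' residual source-1 ancestry, diploid Ne of 5,000 per population, mutation
#' rate 1.2e-8 and recombination rate 1.3e-8 per bp per generation, 1 Mb
#' contigs and 200 sampled haplotypes per group.
#'
#' @param split_gen population split time, generations before present.
#' @param adm_start_gen,adm_end_gen bounds of the admixture interval in
#'   generations before present (`adm_end_gen < adm_start_gen < split_gen`).
#' @param alpha final source-1 ancestry fraction of the admixed population,
#'   in (0, 1\]; `alpha = 1` means no migration.
#' @param ne diploid effective population size (all populations).
#' @param mu mutation rate per bp per generation.
#' @param rho recombination rate per bp per generation.
#' @param seq_len_bp simulated contig length in bp.
#' @param n_hap_per_group haplotypes sampled per group (must be even; two
#'   per diploid individual).
#'
#' @return An object of class `demography_model`, including the derived
#'   per-generation migration rate `m`.
#' @export
#' @examples
#' demography_model()$m            # ~0.0516 for alpha = 0.12 over 40 gen
#' demography_model(alpha = 0.5, adm_start_gen = 81)$m  # exactly 0.5
demography_model <- function(split_gen = 1200, adm_start_gen = 120,
                             adm_end_gen = 80, alpha = 0.12, ne = 5000,
                             mu = 1.2e-8, rho = 1.3e-8, seq_len_bp = 1e6,
                             n_hap_per_group = 200) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  if (!(adm_end_gen < adm_start_gen))
    stop("admixture interval is empty: need adm_end_gen < adm_start_gen")
  if (!(adm_start_gen < split_gen))
    stop("admixture must begin after the split: need adm_start_gen < split_gen")
  if (adm_end_gen < 0) stop("adm_end_gen must be >= 0")
  if (mu < 0 || rho < 0) stop("rates must be >= 0")
  if (ne <= 0) stop("ne must be positive")
  if (seq_len_bp < 1) stop("seq_len_bp must be >= 1")
  if (n_hap_per_group < 2 || n_hap_per_group %% 2 != 0)
    stop("n_hap_per_group must be a positive even number")
  g <- adm_start_gen - adm_end_gen
  m <- 1 - alpha^(1 / g)
  stopifnot(m >= 0, m < 1)
  structure(
    list(split_gen = split_gen, adm_start_gen = adm_start_gen,
         adm_end_gen = adm_end_gen, alpha = alpha, ne = ne, mu = mu,
         rho = rho, seq_len_bp = seq_len_bp,
         n_hap_per_group = as.integer(n_hap_per_group), m = m),
    class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf(paste0(
    "demography_model: split %g gen, admixture %g-%g gen,",
    " alpha = %g (m = %.6g/gen), Ne = %g\n",
    "  mu = %g, rho = %g, %g bp, %d haplotypes/group\n"),
    x$split_gen, x$adm_start_gen, x$adm_end_gen, x$alpha, x$m, x$ne,
    x$mu, x$rho, x$seq_len_bp, x$n_hap_per_group))
  invisible(x)
}
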