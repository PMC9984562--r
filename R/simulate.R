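#' Simulate admixture replicates with ancestry truth
#'
#' Runs the bundled msprime driver once for a batch of replicates. Four
#' groups of `n_hap_per_group` haplotypes are sampled: the modern admixed
#' population, modern source-2, and both sources at `adm_start_gen`
#' generations ago. Each replicate directory contains the biallelic site
#' table with per-mutation origin (population and time in generations), the
#' ancestry tracts of the modern admixed haplotypes (0-based half-open bp,
#' BED convention), and a JSON echo of the model.
#'
#' Identical `(model, seed)` pairs produce bit-identical replicates.
#'
#' @param model a [demography_model()].
#' @param seeds integer vector of replicate seeds (each >= 1, < 2^31).
#' @param out_dir directory to hold `rep_<seed>/` subdirectories.
#' @param python path to the python interpreter with msprime available.
#' @return Character vector of replicate directories, invisibly named by seed.
#' @export
simulate_panels <- function(model, seeds, out_dir = tempfile("admixsim"),
                            python = Sys.which("python")) {
  stopifnot(inherits(model, "demography_model"))
  seeds <- as.integer(seeds)
  if (length(seeds) < 1 || anyNA(seeds) || any(seeds < 1))
    stop("seeds must be positive integers")
  if (anyDuplicated(seeds)) stop("replicate seeds must be distinct")
  if (python == "") stop("python interpreter not found on PATH")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    model = list(split_gen = model$split_gen,
                 adm_start_gen = model$adm_start_gen,
                 adm_end_gen = model$adm_end_gen, alpha = model$alpha,
                 ne = model$ne, mu = model$mu, rho = model$rho,
                 seq_len_bp = model$seq_len_bp,
                 n_hap_per_group = model$n_hap_per_group),
    seeds = I(seeds), out_dir = out_dir)  # I() keeps length-1 seed vectors as JSON arrays
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path), add = TRUE)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "admixsim.py", package = "amitools",
                        mustWork = TRUE)
  status <- system2(python, c(shQuote(script), shQuote(cfg_path)),
                    stdout = FALSE, stderr = "")
  if (status != 0) stop("msprime driver failed with exit status ", status)
  dirs <- file.path(out_dir, sprintf("rep_%d", seeds))
  if (!all(dir.exists(dirs))) stop("simulation output incomplete")
  invisible(stats::setNames(dirs, seeds))
}

#' Read one simulated replicate
#'
#' @param rep_dir a replicate directory written by [simulate_panels()].
#' @return An object of class `sim_panel`: a [haplotype_panel()] in `$panel`
#'   (populations `admixed`, `source2_modern`, `source1_ancient`,
#'   `source2_ancient`), plus `$mutations` (per-site origin population
#'   `ADM`/`CON`/`ANC` and origin time), `$tracts` (hap, start, end, source;
#'   0-based half-open), `$model` and `$seed`.
#' @export
read_sim_panel <- function(rep_dir) {
  meta <- jsonlite::read_json(file.path(rep_dir, "meta.json"),
                              simplifyVector = TRUE)
  sites <- utils::read.delim(file.path(rep_dir, "sites.tsv"),
                             colClasses = c("integer", "character",
                                            "numeric", "character"))
  tracts <- utils::read.delim(file.path(rep_dir, "tracts.tsv"))
  n_hap <- 4L * meta$n_hap_per_group
  if (nrow(sites) > 0) {
    # vapply over sites gives one raw column per site: haplotypes x sites
    geno <- matrix(0L, nrow = n_hap, ncol = nrow(sites))
    raw <- vapply(sites$haps, charToRaw, raw(n_hap), USE.NAMES = FALSE)
    geno[raw == charToRaw("1")] <- 1L
  } else {
    geno <- matrix(integer(), nrow = n_hap, ncol = 0)
  }
  groups <- rep(meta$groups, each = meta$n_hap_per_group)
  n_ind <- n_hap / 2L
  samples <- data.frame(
    sample = sprintf("%s_%03d", rep(meta$groups, each = meta$n_hap_per_group / 2L),
                     rep(seq_len(meta$n_hap_per_group / 2L), 4L)),
    population = rep(meta$groups, each = meta$n_hap_per_group / 2L),
    stringsAsFactors = FALSE)
  # placeholder alleles; A/G keeps simulated records strand-unambiguous
  panel <- haplotype_panel(
    geno, contig = "sim", pos = sites$pos,
    ref = rep("A", nrow(sites)), alt = rep("G", nrow(sites)),
    samples = samples, hap_sample = rep(seq_len(n_ind), each = 2L))
  model <- demography_model(
    split_gen = meta$split_gen, adm_start_gen = meta$adm_start_gen,
    adm_end_gen = meta$adm_end_gen, alpha = meta$alpha, ne = meta$ne,
    mu = meta$mu, rho = meta$rho, seq_len_bp = meta$seq_len_bp,
    n_hap_per_group = meta$n_hap_per_group)
  structure(
    list(panel = panel,
         mutations = data.frame(pos = sites$pos, origin_pop = sites$origin_pop,
                                origin_time = sites$origin_time,
                                stringsAsFactors = FALSE),
         tracts = tracts, model = model, seed = meta$seed),
    class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel (seed %s): %d biallelic sites, %d haplotypes\n",
              x$seed, ncol(x$panel$geno), nrow(x$panel$geno)))
  print(x$model)
  invisible(x)
}

#' Haplotype rows belonging to one sampling group
#'
#' @param sim a `sim_panel`.
#' @param group one of `"admixed"`, `"source2_modern"`, `"source1_ancient"`,
#'   `"source2_ancient"`.
#' @return Integer vector of haplotype row indices.
#' @export
group_haps <- function(sim, group) {
  stopifnot(inherits(sim, "sim_panel"))
  which(sim$panel$samples$population[sim$panel$hap_sample] == group)
}

#' Extract one sampling group as a standalone panel
#'
#' @inheritParams group_haps
#' @return A [haplotype_panel()] restricted to that group's haplotypes.
#' @export
group_panel <- function(sim, group) {
  subset_panel(sim$panel, haps = group_haps(sim, group))
}

#' True source-1 ancestry fraction per admixed haplotype
#'
#' Fraction of each modern admixed haplotype covered by source-1 ancestry
#' tracts.
#'
#' @param sim a `sim_panel`.
#' @return Numeric vector, one entry per modern admixed haplotype (0-based
#'   tract haplotype ids mapped to order of appearance).
#' @export
tract_source1_fraction <- function(sim) {
  stopifnot(inherits(sim, "sim_panel"))
  tr <- sim$tracts
  len <- (tr$end - tr$start) * (tr$source == 1L)
  out <- rowsum(len, tr$hap)
  as.numeric(out) / sim$model$seq_len_bp
}

#' True source-1 allele frequency per site among admixed haplotypes
#'
#' Uses the recorded ancestry tracts: at each site, the frequency of the
#' derived allele among the modern admixed haplotypes whose local ancestry
#' at that position is source-1 (and source-2 respectively). `NA` where no
#' haplotype of that ancestry overlaps the site.
#'
#' @param sim a `sim_panel`.
#' @return data.frame with `pos`, `f_true_1`, `f_true_2`, `n_hap_1`, `n_hap_2`.
#' @export
tract_true_freqs <- function(sim) {
  stopifnot(inherits(sim, "sim_panel"))
  adm <- group_haps(sim, "admixed")
  pos <- sim$panel$pos
  n_hap <- length(adm)
  # ancestry matrix: haplotype x site, TRUE where local ancestry is source-1
  anc <- matrix(FALSE, n_hap, length(pos))
  tr <- sim$tracts[sim$tracts$source == 1L, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    # tracts are 0-based half-open; positions 1-based
    hit <- pos > tr$start[i] & pos <= tr$end[i]
    anc[tr$hap[i] + 1L, hit] <- TRUE
  }
  g <- sim$panel$geno[adm, , drop = FALSE]
  n1 <- colSums(anc)
  n2 <- n_hap - n1
  f1 <- ifelse(n1 > 0, colSums(g * anc) / n1, NA_real_)
  f2 <- ifelse(n2 > 0, colSums(g * !anc) / n2, NA_real_)
  data.frame(pos = pos, f_true_1 = f1, f_true_2 = f2,
             n_hap_1 = n1, n_hap_2 = n2)
}

#' Type the admixed-population-specific variants of a replicate
#'
#' A variant is *specific* when its derived allele is carried by at least
#' one modern admixed haplotype and by none of the modern source-2
#' haplotypes. Specific variants are then classified from the recorded
#' mutation origin:
#'
#' * type 1 - arose on the source-1 lineage before admixture began, or in
#'   the common ancestral population before the split;
#' * type 2 - arose on the source-2 lineage (after the split) and entered
#'   the admixed population through migration while being lost from the
#'   sampled modern source-2 panel;
#' * type 3 - arose in the admixed population after the onset of admixture.
#'
#' @param sim a `sim_panel`.
#' @return data.frame of class `typed_variants`: `contig`, `pos`,
#'   `site` (column index into the panel), `target_count` (derived-allele
#'   count among modern admixed haplotypes), `type`, `origin_pop`,
#'   `origin_time`.
#' @export
type_specific_variants <- function(sim) {
  stopifnot(inherits(sim, "sim_panel"))
  if (anyNA(sim$mutations$origin_pop) ||
      any(!sim$mutations$origin_pop %in% c("ADM", "CON", "ANC")))
    stop("mutation with unknown origin population; truth labeling incomplete")
  adm <- group_haps(sim, "admixed")
  con <- group_haps(sim, "source2_modern")
  cnt_adm <- colSums(sim$panel$geno[adm, , drop = FALSE])
  cnt_con <- colSums(sim$panel$geno[con, , drop = FALSE])
  specific <- cnt_adm > 0L & cnt_con == 0L
  # drop variants monomorphic within the admixed sample after conditioning
  polymorphic <- cnt_adm < length(adm)
  keep <- which(specific & polymorphic)
  mut <- sim$mutations[keep, , drop = FALSE]
  mdl <- sim$model
  type <- ifelse(
    mut$origin_pop == "CON", 2L,
    ifelse(mut$origin_pop == "ANC" | mut$origin_time >= mdl$adm_start_gen,
           1L, 3L))
  out <- data.frame(contig = "sim", pos = mut$pos, site = keep,
                    target_count = cnt_adm[keep], type = type,
                    origin_pop = mut$origin_pop,
                    origin_time = mut$origin_time,
                    stringsAsFactors = FALSE)
  class(out) <- c("typed_variants", "data.frame")
  out
}
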