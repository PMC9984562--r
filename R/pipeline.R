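#' Simulated AMI validation experiment
#'
#' Runs `n_rep` independent 1-contig replicates under `model`, extracts and
#' truth-types the admixed-population-specific variants of each, computes
#' each variant's AMI (partner count within `ld_window_bp` at each r-squared
#' cutoff, divided by the replicate's specific-variant density per kb), and
#' pools variants across replicates. The pooled scores and truth labels
#' feed [roc_analysis()] to measure how well AMI separates source-1-derived
#' (type 1) variants from the rest and to place the Youden calling
#' threshold.
#'
#' Replicates are simulated and processed in chunks; temporary simulation
#' output is deleted as it is consumed.
#'
#' @param model a [demography_model()].
#' @param n_rep number of replicates.
#' @param base_seed integer; replicate seeds are drawn deterministically
#'   from this seed, so identical inputs reproduce identical output.
#' @param r2_cuts one or more r-squared cutoffs (default 0.01).
#' @param ld_window_bp LD pairing window (default 1 Mb).
#' @param chunk_size replicates per msprime invocation.
#' @param progress print a note per chunk to standard error.
#' @param per_replicate optional `function(sim, ami_table)` called once per
#'   replicate with the replicate's `sim_panel` and its scored `ami_table`
#'   (at the `score_cut` cutoff, truth `type` column included) before the
#'   replicate's simulation output is deleted; its results are returned in
#'   `$extra`. Used for downstream per-replicate analyses (marker calling,
#'   frequency recovery, JAS) without re-simulating.
#' @param score_cut the r-squared cutoff (one of `r2_cuts`) at which the
#'   callback's `ami_table` is scored; defaults to 0.01 when present,
#'   otherwise the first cutoff.
#' @return An object of class `ami_experiment`: `$ami` (matrix, pooled
#'   variants x cutoffs), `$type` (truth 1/2/3), `$rep` (replicate index),
#'   `$pos`, `$r2_cuts`, `$seeds`, `$model`.
#' @export
ami_sim_experiment <- function(model, n_rep, base_seed, r2_cuts = 0.01,
                               ld_window_bp = 1e6, chunk_size = 50,
                               progress = FALSE, per_replicate = NULL,
                               score_cut = if (0.01 %in% r2_cuts) 0.01 else
                                 r2_cuts[1]) {
  stopifnot(inherits(model, "demography_model"), n_rep >= 1)
  k_score <- match(score_cut, r2_cuts)
  if (is.na(k_score)) stop("score_cut must be one of r2_cuts")
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  ami <- vector("list", n_rep)
  type <- vector("list", n_rep)
  pos <- vector("list", n_rep)
  extra <- if (is.null(per_replicate)) NULL else vector("list", n_rep)
  chunks <- split(seq_len(n_rep), ceiling(seq_len(n_rep) / chunk_size))
  for (ch in chunks) {
    out_dir <- tempfile("ami_experiment")
    dirs <- simulate_panels(model, seeds[ch], out_dir = out_dir)
    for (j in seq_along(ch)) {
      i <- ch[j]
      sim <- read_sim_panel(dirs[[j]])
      typed <- type_specific_variants(sim)
      spec <- as_specific_variants(typed, sim)
      adm <- group_panel(sim, "admixed")
      cnt <- ld_partner_profile(spec, adm, ld_window_bp = ld_window_bp,
                                r2_cut = r2_cuts)
      dens <- nrow(spec) / (model$seq_len_bp / 1000)
      ami[[i]] <- if (dens > 0) cnt / dens else cnt * NA_real_
      type[[i]] <- spec$type
      pos[[i]] <- spec$pos
      if (!is.null(per_replicate)) {
        tab <- spec
        tab$partner_count <- cnt[, k_score]
        tab$density <- dens
        tab$ami <- ami[[i]][, k_score]
        class(tab) <- c("ami_table", "ld_stats", class(spec))
        extra[[i]] <- per_replicate(sim, tab)
      }
    }
    unlink(out_dir, recursive = TRUE)
    if (progress)
      message(sprintf("ami_sim_experiment: %d/%d replicates done",
                      max(ch), n_rep))
  }
  structure(
    list(ami = do.call(rbind, ami), type = unlist(type), pos = unlist(pos),
         rep = rep(seq_len(n_rep), vapply(type, length, 1L)),
         r2_cuts = r2_cuts, seeds = seeds, model = model, extra = extra),
    class = "ami_experiment")
}

#' @export
print.ami_experiment <- function(x, ...) {
  cat(sprintf(
    "ami_experiment: %d replicates, %d pooled specific variants (type 1: %d)\n",
    length(x$seeds), length(x$type), sum(x$type == 1L)))
  invisible(x)
}

#' ROC of an AMI experiment at one cutoff
#'
#' @param experiment an `ami_experiment`.
#' @param r2_cut which cutoff column to score (must be one of the
#'   experiment's `r2_cuts`).
#' @return A `roc_result` for type-1 versus type-2/3.
#' @export
experiment_roc <- function(experiment, r2_cut = experiment$r2_cuts[1]) {
  stopifnot(inherits(experiment, "ami_experiment"))
  k <- match(r2_cut, experiment$r2_cuts)
  if (is.na(k)) stop("r2_cut was not evaluated in this experiment")
  roc_analysis(experiment$ami[, k], experiment$type == 1L)
}
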