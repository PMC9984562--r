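#' Read a VCF into a haplotype panel
#'
#' Parses GT fields with vcfR, keeping biallelic SNP records only
#' (multiallelic or indel records are skipped with a message). Phased
#' genotypes yield two haplotype rows per sample; if any heterozygote is
#' unphased the panel is marked unphased and haplotype-dependent operations
#' (LD, classification) will refuse it, while dosage-based operations still
#' work. Missing genotypes become `NA` haplotype entries.
#'
#' @param path VCF file (plain text or gzipped).
#' @param population population label to assign (single value or one per
#'   sample).
#' @return A [haplotype_panel()]. Contig lengths parsed from
#'   `##contig` header lines are attached as attribute `contig_lengths`.
#' @export
read_haplotype_panel <- function(path, population = "pop1") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok))
    message(sum(!ok), " non-biallelic-SNP record(s) skipped")
  if (sum(ok) == 0) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("malformed VCF: no GT field in ", path)
  gt <- gt[ok, , drop = FALSE]
  n_site <- sum(ok); n_samp <- ncol(gt)
  unphased_het <- grepl("/", gt, fixed = TRUE) &
    substr(gt, 1, 1) != substr(gt, 3, 3)
  phased <- !any(unphased_het, na.rm = TRUE)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_int <- function(a) {
    x <- suppressWarnings(as.integer(a))
    x[!a %in% c("0", "1")] <- NA_integer_
    x
  }
  geno <- matrix(NA_integer_, 2L * n_samp, n_site)
  geno[seq(1, 2 * n_samp, 2), ] <- t(matrix(to_int(a1), n_site, n_samp))
  geno[seq(2, 2 * n_samp, 2), ] <- t(matrix(to_int(a2), n_site, n_samp))
  samples <- data.frame(sample = colnames(gt),
                        population = rep_len(population, n_samp),
                        stringsAsFactors = FALSE)
  panel <- haplotype_panel(
    geno, contig = fix[ok, "CHROM"], pos = as.integer(fix[ok, "POS"]),
    ref = ref[ok], alt = alt[ok], samples = samples,
    hap_sample = rep(seq_len(n_samp), each = 2L), phased = phased)
  meta <- grep("^##contig=<", v@meta, value = TRUE)
  ids <- sub(".*[<,]ID=([^,>]+).*", "\\1", meta)
  has_len <- grepl("length=[0-9]+", meta)
  if (any(has_len)) {
    lens <- as.numeric(sub(".*length=([0-9]+).*", "\\1", meta[has_len]))
    attr(panel, "contig_lengths") <- stats::setNames(lens, ids[has_len])
  }
  panel
}

#' Write a haplotype panel as a plain-text VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @param contig_lengths optional named vector written into `##contig`
#'   header lines (defaults to the maximum position per contig).
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path, contig_lengths = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ctgs <- unique(panel$contig)
  if (is.null(contig_lengths))
    contig_lengths <- tapply(panel$pos, panel$contig, max)[ctgs]
  sep <- if (panel$phased) "|" else "/"
  n_samp <- nrow(panel$samples)
  hap1 <- panel$geno[seq(1, 2 * n_samp, 2), , drop = FALSE]
  hap2 <- panel$geno[seq(2, 2 * n_samp, 2), , drop = FALSE]
  fmt <- function(h) ifelse(is.na(h), ".", as.character(h))
  gt <- matrix(paste0(fmt(hap1), sep, fmt(hap2)), n_samp, ncol(panel$geno))
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ctgs,
            as.integer(contig_lengths[ctgs])),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample), collapse = "\t"))
  body <- paste(panel$contig, panel$pos, ".", panel$ref, panel$alt, ".",
                "PASS", ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a data.frame as TSV with fixed numeric rendering
#'
#' Deterministic output: column order as given, doubles rendered at a fixed
#' number of significant digits, `NA` written literally.
#'
#' @param df data.frame.
#' @param path output file.
#' @param digits significant digits for double columns.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a marker set as TSV
#'
#' Columns: contig, pos, ref, alt, marker_allele, partner_count, density,
#' ami. An empty marker set yields a header-only file.
#'
#' @param markers a `marker_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_set <- function(markers, path) {
  cols <- c("contig", "pos", "ref", "alt", "marker_allele",
            "partner_count", "density", "ami")
  write_tsv(markers[, intersect(cols, names(markers)), drop = FALSE], path)
}

#' Read a marker set TSV
#'
#' @param path a TSV written by [write_marker_set()].
#' @param panel optional [haplotype_panel()]; when given, a `site` column
#'   mapping each marker to a panel column is restored.
#' @return A `marker_set` data.frame.
#' @export
read_marker_set <- function(path, panel = NULL) {
  mk <- read_tsv(path)
  if (!is.null(panel)) {
    mk$site <- match(paste(mk$contig, mk$pos),
                     paste(panel$contig, panel$pos))
    if (anyNA(mk$site))
      message(sum(is.na(mk$site)), " marker(s) not present in panel")
  }
  class(mk) <- c("marker_set", "data.frame")
  mk
}

#' Write a JSON summary with run metadata
#'
#' @param x a named list of results (must be JSON-representable).
#' @param path output file.
#' @param seed optional seed to record.
#' @param config optional configuration list; a stable hash of it is
#'   recorded.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path, seed = NULL, config = NULL) {
  meta <- list(package = "amitools",
               version = as.character(utils::packageVersion("amitools")))
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(config))
    meta$config_hash <- config_hash(config)
  jsonlite::write_json(c(list(meta = meta), x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# Stable digest of a configuration list (md5 of its canonical JSON).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a simulation configuration file
#'
#' YAML or JSON file with the [demography_model()] fields plus `n_rep` (or
#' an explicit `seeds` vector) and `seed`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return list with `$model` (a `demography_model`), `$seeds`, `$seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  model_args <- cfg[intersect(names(cfg), names(formals(demography_model)))]
  model <- do.call(demography_model, model_args)
  seeds <- cfg$seeds
  if (is.null(seeds)) {
    if (is.null(cfg$seed) || is.null(cfg$n_rep))
      stop("config needs either `seeds` or both `seed` and `n_rep`")
    set.seed(cfg$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_rep)
  }
  list(model = model, seeds = as.integer(seeds), seed = cfg$seed)
}

#' Ancestry tracts as BED text
#'
#' Writes the simulator's ancestry tracts in BED convention (0-based,
#' half-open), one row per tract with the haplotype id as the name column
#' and the source (1/2) as the score column.
#'
#' @param sim a `sim_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracts_bed <- function(sim, path) {
  stopifnot(inherits(sim, "sim_panel"))
  tr <- sim$tracts
  writeLines(sprintf("%s\t%d\t%d\thap%d\t%d", "sim", tr$start, tr$end,
                     tr$hap, tr$source), path)
  invisible(path)
}
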