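#' Outgroup f3 statistic
#'
#' `f3(O; A, B) = mean over sites of (f_O - f_A)(f_O - f_B)`: the shared
#' drift of A and B relative to the outgroup O. Sites with any missing
#' frequency are dropped (count reported). No block-jackknife standard
#' error or small-sample bias correction is applied; values are point
#' estimates.
#'
#' @param f_a,f_b,f_o aligned allele-frequency vectors. Frequencies for a
#'   single diploid individual are allele dosages divided by 2.
#' @return list of class `f3_result`: `f3`, `n_sites`, `n_dropped`.
#' @export
outgroup_f3 <- function(f_a, f_b, f_o) {
  stopifnot(length(f_a) == length(f_b), length(f_a) == length(f_o))
  ok <- !is.na(f_a) & !is.na(f_b) & !is.na(f_o)
  if (sum(ok) == 0) stop("no site with all three frequencies defined")
  structure(
    list(f3 = mean((f_o[ok] - f_a[ok]) * (f_o[ok] - f_b[ok])),
         n_sites = sum(ok), n_dropped = sum(!ok)),
    class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.6g over %d sites (%d dropped)\n",
              x$f3, x$n_sites, x$n_dropped))
  invisible(x)
}

#' Pairwise outgroup f3 matrix
#'
#' @param freqs data.frame (or matrix) of per-site allele frequencies, one
#'   column per population; may contain `NA`.
#' @param outgroup name of the outgroup column.
#' @return list of class `f3_matrix`: `$f3` (symmetric matrix over the
#'   non-outgroup populations), `$n_sites` (per-pair retained site counts),
#'   `$outgroup`.
#' @export
pairwise_f3_matrix <- function(freqs, outgroup) {
  freqs <- as.data.frame(freqs)
  if (!outgroup %in% names(freqs)) stop("outgroup column not found")
  pops <- setdiff(names(freqs), outgroup)
  if (length(pops) < 2) stop("need at least two non-outgroup populations")
  f3 <- matrix(NA_real_, length(pops), length(pops),
               dimnames = list(pops, pops))
  n <- f3
  for (i in seq_along(pops)) {
    for (j in i:length(pops)) {
      res <- outgroup_f3(freqs[[pops[i]]], freqs[[pops[j]]],
                         freqs[[outgroup]])
      f3[i, j] <- f3[j, i] <- res$f3
      n[i, j] <- n[j, i] <- res$n_sites
    }
  }
  structure(list(f3 = f3, n_sites = n, outgroup = outgroup),
            class = "f3_matrix")
}

#' @export
print.f3_matrix <- function(x, ...) {
  cat(sprintf("pairwise outgroup f3 (outgroup: %s)\n", x$outgroup))
  print(round(x$f3, 6))
  invisible(x)
}
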