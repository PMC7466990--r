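#' Expected heterozygosity per locus and population
#'
#' Computes gene diversity for every (locus, population) cell and the
#' per-population mean across loci. The default is the unbiased
#' (sample-size corrected) estimator
#' \deqn{H_E = \frac{2n}{2n-1}\,(1 - p^2 - q^2)}
#' with `n` the number of non-missing diploid genotypes and `p` the
#' alternate-allele frequency in the cell; `unbiased = FALSE` gives the
#' naive `2pq` used in oracle comparisons. Cells with no non-missing
#' genotype are undefined (`NA`) and are dropped from the mean (their
#' count is reported); loci monomorphic within a population contribute
#' `H_E = 0` to that population's mean, i.e. averaging is across all
#' defined loci, not just polymorphic ones.
#'
#' @param gm a [genotype_matrix].
#' @param popmap a [population_map] covering the individuals of `gm`.
#' @param unbiased apply the `2n/(2n-1)` correction (default `TRUE`).
#' @return A `het_table`: list with `per_locus` (loci x populations matrix),
#'   `means` (named vector), `n_defined` and `n_undefined` per population.
#' @export
expected_heterozygosity <- function(gm, popmap, unbiased = TRUE) {
  popmap <- population_map(as.data.frame(popmap))
  .check_popmap_covers(gm, popmap)
  pops <- unique(popmap$population[popmap$individual %in% gm$individuals])
  he <- sapply(pops, function(p) {
    ind <- intersect(.pop_individuals(popmap, p), gm$individuals)
    d <- gm$dosages[, ind, drop = FALSE]
    n <- rowSums(!is.na(d))
    freq <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    h <- 2 * freq * (1 - freq)
    if (unbiased) h <- h * ifelse(n > 0, 2 * n / (2 * n - 1), NA_real_)
    h
  })
  he <- matrix(he, nrow = n_loci(gm), dimnames = list(NULL, pops))
  structure(list(
    per_locus = he,
    means = colMeans(he, na.rm = TRUE),
    n_defined = colSums(!is.na(he)),
    n_undefined = colSums(is.na(he))
  ), class = "het_table")
}

#' @export
print.het_table <- function(x, ...) {
  print(data.frame(population = names(x$means), mean_HE = round(x$means, 4),
                   n_loci = x$n_defined, row.names = NULL))
  invisible(x)
}

#' Welch two-sample t-test on per-population summaries
#'
#' Compares two groups of per-population mean heterozygosities (or any
#' population-level summaries) with the unequal-variance t-test and
#' Welch-Satterthwaite degrees of freedom. The test unit is the
#' population, not the locus.
#'
#' @param x,y numeric vectors (one value per population), each of length
#'   at least 2.
#' @return A `welch_test` list: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 populations per group")
  if (var(x) == 0 && var(y) == 0) {
    stop("degenerate variance: both groups are constant")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4f, df = %.3f, p = %.3g (means %.4f vs %.4f)\n",
              x$t, x$df, x$p_value, x$mean_x, x$mean_y))
  invisible(x)
}
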