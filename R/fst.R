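#' Pairwise Weir-Cockerham F_ST between populations
#'
#' Computes the Weir & Cockerham (1984) theta estimator for every pair of
#' populations, combining loci as a ratio of sums
#' (\eqn{\sum a / \sum (a+b+c)}), the standard multi-locus practice.
#' For a pair, loci with no genotyped individual in one of the two
#' populations (or with fewer than 2 genotyped individuals in total) are
#' skipped and counted. Small negative estimates are possible and left
#' uncorrected. A pair with no usable locus gets `NA` and is flagged.
#'
#' @param gm a [genotype_matrix].
#' @param popmap a [population_map].
#' @return An `fst_matrix`: list with `fst` (symmetric matrix, zero
#'   diagonal), `n_loci` (loci used per pair) and `populations`.
#' @export
pairwise_fst <- function(gm, popmap) {
  popmap <- population_map(as.data.frame(popmap))
  .check_popmap_covers(gm, popmap)
  pops <- unique(popmap$population[popmap$individual %in% gm$individuals])
  if (length(pops) < 2) stop("need at least two populations")
  np <- length(pops)
  fst <- matrix(0, np, np, dimnames = list(pops, pops))
  nl <- matrix(0L, np, np, dimnames = list(pops, pops))
  stats <- lapply(pops, function(p) {
    ind <- intersect(.pop_individuals(popmap, p), gm$individuals)
    d <- gm$dosages[, ind, drop = FALSE]
    n <- rowSums(!is.na(d))
    list(n = n,
         p = ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, rowSums(d == 1L, na.rm = TRUE) / n, NA_real_))
  })
  names(stats) <- pops
  for (i in seq_len(np - 1)) {
    for (j in seq((i + 1), np)) {
      abc <- .wc84_components(stats[[i]], stats[[j]])
      use <- abc$use
      nl[i, j] <- nl[j, i] <- sum(use)
      denom <- sum(abc$a[use] + abc$b[use] + abc$c[use])
      fst[i, j] <- fst[j, i] <-
        if (sum(use) == 0 || denom == 0) NA_real_ else sum(abc$a[use]) / denom
    }
  }
  structure(list(fst = fst, n_loci = nl, populations = pops),
            class = "fst_matrix")
}

# Weir & Cockerham (1984) per-locus variance components for two
# populations, vectorised over loci. s1, s2: lists with n (diploid sample
# size), p (alt frequency), h (observed het fraction) per locus.
.wc84_components <- function(s1, s2) {
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  use <- n1 > 0 & n2 > 0 & (n1 + n2) > 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- nbar / nc *
    (s2v - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # monomorphic-in-pair loci carry no information; their components are 0
  mono <- !is.na(pbar) & (pbar == 0 | pbar == 1)
  a[mono] <- b[mono] <- cc[mono] <- 0
  use <- use & !is.na(a) & !is.na(b) & !is.na(cc) & is.finite(nc) & nc > 0
  list(a = a, b = b, c = cc, use = use)
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham F_ST:\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Mean pairwise F_ST between two groups of populations
#'
#' Convenience summary: the average of the pairwise F_ST entries between
#' every population of `group_a` and every population of `group_b`
#' (or within one group when `group_b` is missing).
#'
#' @param fm an `fst_matrix`.
#' @param pops_a,pops_b character vectors of population labels.
#' @return Mean of the selected entries (NA entries dropped).
#' @export
mean_fst_between <- function(fm, pops_a, pops_b = NULL) {
  if (is.null(pops_b)) {
    sub <- fm$fst[pops_a, pops_a, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  } else {
    mean(fm$fst[pops_a, pops_b], na.rm = TRUE)
  }
}
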