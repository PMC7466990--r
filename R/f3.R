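#' Three-population admixture test f3(C; A, B)
#'
#' Tests whether target population C descends from a mixture of sources
#' related to A and B. The per-locus term is
#' \deqn{(\hat c - \hat a)(\hat c - \hat b) - \frac{\hat c(1-\hat c)}{n_C - 1}}
#' where the hats are sample alternate-allele frequencies and \eqn{n_C}
#' is the allele count (twice the genotyped diploids) in C; the second
#' term removes the finite-sample bias contributed by the target's
#' sampling variance (no outgroup is needed). f3 is the plain mean over
#' usable loci; a clearly negative value indicates admixture. Standard
#' errors come from a delete-one block jackknife over contiguous blocks
#' of `block_size` loci in genome order (the reproducible analogue of
#' map-distance blocks when no genetic map exists), using the weighted
#' delete-m jackknife so a short final block is handled exactly.
#'
#' Loci with no genotyped individual in any of the three populations, or
#' monomorphic across all three, are dropped before blocking.
#'
#' @param gm a [genotype_matrix].
#' @param target,source_a,source_b distinct population labels.
#' @param popmap a [population_map].
#' @param block_size loci per jackknife block (default 500).
#' @return An `f3_result`: `f3`, `se`, `z`, `n_blocks`, `n_loci`.
#' @export
f3_test <- function(gm, target, source_a, source_b, popmap, block_size = 500) {
  popmap <- population_map(as.data.frame(popmap))
  if (length(unique(c(target, source_a, source_b))) != 3) {
    stop("target and the two sources must be three distinct populations")
  }
  ind <- lapply(c(target, source_a, source_b), function(p)
    intersect(.pop_individuals(popmap, p), gm$individuals))
  if (length(Reduce(intersect, ind)) > 0) {
    stop("populations share individuals; assignments must not overlap")
  }
  fc <- lapply(ind, function(x) .freq_counts(gm, x))
  cc <- fc[[1]]$freq; aa <- fc[[2]]$freq; bb <- fc[[3]]$freq
  n_c <- fc[[1]]$n
  use <- !is.na(cc) & !is.na(aa) & !is.na(bb) & n_c >= 2
  # drop loci monomorphic across all three populations
  mono <- (cc == 0 & aa == 0 & bb == 0) | (cc == 1 & aa == 1 & bb == 1)
  use <- use & !ifelse(is.na(mono), TRUE, mono)
  term <- (cc - aa) * (cc - bb) - cc * (1 - cc) / (n_c - 1)
  .f3_from_terms(term[use], block_size, n_loci_supplied = n_loci(gm))
}

#' f3 from population allele frequencies (frequency mode)
#'
#' Evaluates `mean((c - a) * (c - b))` over loci with a block-jackknife
#' standard error. Because the inputs are population frequencies rather
#' than finite samples, no sampling-bias correction is applied; this mode
#' exists for exact hand-checkable computations and simulation oracles.
#'
#' @param freq_c,freq_a,freq_b numeric vectors of per-locus allele
#'   frequencies for the target and the two sources.
#' @param block_size loci per jackknife block.
#' @return An `f3_result`.
#' @export
f3_from_freq <- function(freq_c, freq_a, freq_b, block_size = 500) {
  stopifnot(length(freq_c) == length(freq_a), length(freq_c) == length(freq_b))
  use <- !is.na(freq_c) & !is.na(freq_a) & !is.na(freq_b)
  mono <- (freq_c == 0 & freq_a == 0 & freq_b == 0) |
          (freq_c == 1 & freq_a == 1 & freq_b == 1)
  use <- use & !ifelse(is.na(mono), TRUE, mono)
  term <- (freq_c - freq_a) * (freq_c - freq_b)
  .f3_from_terms(term[use], block_size, n_loci_supplied = length(freq_c))
}

.f3_from_terms <- function(term, block_size, n_loci_supplied) {
  n <- length(term)
  if (n < 2) stop("fewer than two usable loci")
  block <- (seq_len(n) - 1L) %/% block_size + 1L
  B <- max(block)
  if (B < 2) {
    stop("fewer than 2 jackknife blocks; reduce block_size (",
         n, " usable loci)")
  }
  theta <- mean(term)
  m_j <- tabulate(block, B)
  sum_j <- rowsum(term, block)[, 1]
  theta_j <- (sum(term) - sum_j) / (n - m_j)  # delete-block estimates
  h_j <- n / m_j
  theta_J <- B * theta - sum((1 - m_j / n) * theta_j)
  tau <- h_j * theta - (h_j - 1) * theta_j
  var_j <- mean((tau - theta_J)^2 / (h_j - 1))
  se <- sqrt(var_j)
  structure(list(f3 = theta, se = se,
                 z = if (se > 0) theta / se else NA_real_,
                 n_blocks = B, n_loci = n,
                 n_loci_supplied = n_loci_supplied),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.6f  SE = %.6f  Z = %.3f  (%d loci, %d blocks)\n",
              x$f3, x$se, x$z, x$n_loci, x$n_blocks))
  invisible(x)
}

#' Batch f3 tests over a table of population triples
#'
#' @param gm a [genotype_matrix].
#' @param triples data frame with columns `target`, `source_a`,
#'   `source_b`.
#' @param popmap a [population_map].
#' @param block_size loci per jackknife block.
#' @return Data frame with one row per triple: f3, SE, Z, loci, blocks.
#' @export
f3_batch <- function(gm, triples, popmap, block_size = 500) {
  rows <- lapply(seq_len(nrow(triples)), function(i) {
    r <- f3_test(gm, triples$target[i], triples$source_a[i],
                 triples$source_b[i], popmap, block_size)
    data.frame(target = triples$target[i], source_a = triples$source_a[i],
               source_b = triples$source_b[i],
               f3 = r$f3, se = r$se, z = r$z,
               n_loci = r$n_loci, n_blocks = r$n_blocks)
  })
  do.call(rbind, rows)
}
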