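#' Locus-by-locus hierarchical AMOVA
#'
#' Partitions allele-level variance into three strata - among groups,
#' among populations within groups, and within populations - from
#' unphased SNP dosages. Each diploid genotype contributes two allele
#' copies scored 0/1 for the alternate allele; squared allele-count
#' differences make this equivalent to F-statistics on allele
#' frequencies. Sums of squares, unequal-sample-size coefficients and
#' variance components are computed per locus (over populations with at
#' least one called copy at that locus) and summed across loci; fixation
#' indices derive from the summed components:
#' \deqn{F_{CT} = \sigma^2_a/\sigma^2_T,\quad
#'       F_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c),\quad
#'       F_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T.}
#'
#' Significance uses three permutation schemes: whole populations among
#' groups (F_CT), individuals among populations within groups (F_SC),
#' and individuals among all populations (F_ST), with the +1-corrected
#' p-value `(hits + 1)/(n_perm + 1)`. The conventional full-scale setting
#' is 16,000 permutations; pass a smaller `n_perm` for quick runs.
#'
#' @param gm a [genotype_matrix].
#' @param popmap a [population_map] (its `group` column defines the top
#'   stratum).
#' @param n_perm number of permutations per scheme (default 16000).
#' @param seed RNG seed for the permutations.
#' @return An `amova_result`: `table` (data frame mirroring the classic
#'   AMOVA layout), `indices`, `p_values`, `n_perm`, `n_loci_used`.
#' @export
amova <- function(gm, popmap, n_perm = 16000, seed = NULL) {
  popmap <- population_map(as.data.frame(popmap))
  .check_popmap_covers(gm, popmap)
  if (!is.null(seed)) set.seed(seed)

  ord <- match(gm$individuals, popmap$individual)
  ind_pop <- popmap$population[ord]
  pops <- unique(ind_pop)
  group_of_pop <- popmap$group[match(pops, popmap$population)]
  names(group_of_pop) <- pops
  n_groups <- length(unique(group_of_pop))
  if (length(pops) < 2) stop("need at least two populations")

  td <- t(gm$dosages)              # individuals x loci
  tc <- (!is.na(td)) * 1L

  obs <- .amova_components(td, tc, factor(ind_pop, levels = pops), group_of_pop)
  tot <- obs$sa + obs$sb + obs$sc
  indices <- list(
    F_CT = if (n_groups >= 2) obs$sa / tot else NA_real_,
    F_SC = obs$sb / (obs$sb + obs$sc),
    F_ST = if (n_groups >= 2) (obs$sa + obs$sb) / tot
           else obs$sb / (obs$sb + obs$sc))

  p_values <- c(F_CT = NA_real_, F_SC = NA_real_, F_ST = NA_real_)
  if (n_perm > 0) {
    hits <- c(F_CT = 0L, F_SC = 0L, F_ST = 0L)
    pop_lv <- factor(ind_pop, levels = pops)
    for (b in seq_len(n_perm)) {
      # individuals among all populations -> F_ST
      perm <- sample(ind_pop)
      r <- .amova_components(td, tc, factor(perm, levels = pops), group_of_pop)
      f <- (r$sa + r$sb) / (r$sa + r$sb + r$sc)
      if (!is.na(f) && f >= indices$F_ST) hits["F_ST"] <- hits["F_ST"] + 1L
      # individuals among populations within groups -> F_SC
      perm2 <- ind_pop
      for (g in unique(group_of_pop)) {
        in_g <- ind_pop %in% pops[group_of_pop == g]
        perm2[in_g] <- sample(ind_pop[in_g])
      }
      r <- .amova_components(td, tc, factor(perm2, levels = pops), group_of_pop)
      f <- r$sb / (r$sb + r$sc)
      if (!is.na(f) && f >= indices$F_SC) hits["F_SC"] <- hits["F_SC"] + 1L
      # whole populations among groups -> F_CT
      if (n_groups >= 2) {
        gperm <- setNames(sample(group_of_pop), pops)
        r <- .amova_components(td, tc, pop_lv, gperm)
        f <- r$sa / (r$sa + r$sb + r$sc)
        if (!is.na(f) && f >= indices$F_CT) hits["F_CT"] <- hits["F_CT"] + 1L
      }
    }
    p_values <- (hits + 1) / (n_perm + 1)
    if (n_groups < 2) p_values["F_CT"] <- NA_real_
  }

  comp <- c(obs$sa, obs$sb, obs$sc)
  table <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(obs$df_a, obs$df_b, obs$df_c, obs$df_a + obs$df_b + obs$df_c),
    sum_sq = c(obs$ssa, obs$ssb, obs$ssc, obs$ssa + obs$ssb + obs$ssc),
    variance = c(comp, sum(comp)),
    percent = c(100 * comp / sum(comp), 100))
  structure(list(table = table, indices = indices, p_values = p_values,
                 n_perm = n_perm, n_loci_used = obs$n_loci),
            class = "amova_result")
}

# Variance components summed over loci for one assignment of individuals
# to populations (pop_f) and populations to groups (group_of_pop).
# td: individuals x loci dosages; tc: 1/0 called indicator.
.amova_components <- function(td, tc, pop_f, group_of_pop) {
  sp <- rowsum(ifelse(is.na(td), 0L, td), pop_f)   # alt copies per pop x locus
  np <- 2 * rowsum(tc, pop_f)                      # called copies per pop x locus
  pops <- rownames(sp)
  grp <- factor(group_of_pop[pops])
  G <- nlevels(grp)
  P <- length(pops)

  ok <- colSums(np == 0) == 0                      # every pop informative
  if (!any(ok)) {
    return(list(sa = NA_real_, sb = NA_real_, sc = NA_real_,
                ssa = NA_real_, ssb = NA_real_, ssc = NA_real_,
                df_a = 0, df_b = 0, df_c = 0, n_loci = 0L))
  }
  sp <- sp[, ok, drop = FALSE]; np <- np[, ok, drop = FALSE]
  S <- colSums(sp); N <- colSums(np)
  sg <- rowsum(sp, grp); ng <- rowsum(np, grp)

  ss_within <- colSums(sp - sp^2 / np)
  ss_groups <- colSums(sg^2 / ng) - S^2 / N
  ss_pops <- colSums(sp^2 / np) - colSums(sg^2 / ng)

  df_a <- G - 1
  df_b <- P - G
  df_c <- N - P
  sum_pg <- colSums(rowsum(np^2, grp) / ng)
  n1 <- (N - sum_pg) / df_b
  n2 <- if (df_a > 0) (sum_pg - colSums(np^2) / N) / df_a else rep(NA_real_, length(N))
  n3 <- if (df_a > 0) (N - colSums(ng^2) / N) / df_a else rep(NA_real_, length(N))

  msc <- ss_within / df_c
  msb <- ss_pops / df_b
  sigma_c <- msc
  sigma_b <- (msb - sigma_c) / n1
  if (df_a > 0) {
    msa <- ss_groups / df_a
    sigma_a <- (msa - sigma_c - n2 * sigma_b) / n3
  } else {
    sigma_a <- rep(0, length(N))
  }
  list(sa = sum(sigma_a), sb = sum(sigma_b), sc = sum(sigma_c),
       ssa = sum(ss_groups), ssb = sum(ss_pops), ssc = sum(ss_within),
       df_a = df_a * sum(ok), df_b = df_b * sum(ok), df_c = sum(df_c),
       n_loci = sum(ok))
}

#' @export
print.amova_result <- function(x, ...) {
  tbl <- x$table
  tbl$sum_sq <- round(tbl$sum_sq, 3)
  tbl$variance <- round(tbl$variance, 5)
  tbl$percent <- round(tbl$percent, 1)
  print(tbl, row.names = FALSE)
  cat(sprintf("F_CT = %.3f (p = %.4g), F_SC = %.3f (p = %.4g), F_ST = %.3f (p = %.4g)\n",
              x$indices$F_CT, x$p_values["F_CT"],
              x$indices$F_SC, x$p_values["F_SC"],
              x$indices$F_ST, x$p_values["F_ST"]))
  invisible(x)
}
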