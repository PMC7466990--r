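test_that("samples from one pool give F_ST near zero, fixed difference gives one", {
  set.seed(8)
  p <- runif(1000, 0.1, 0.9)
  d1 <- matrix(rbinom(1000 * 8, 2, p), ncol = 8)
  d2 <- matrix(rbinom(1000 * 8, 2, p), ncol = 8)
  two <- make_two_pop(d1, d2)
  f <- pairwise_fst(two$gm, two$popmap)
  expect_lt(abs(f$fst["popA", "popB"]), 0.02)
  fixed <- make_two_pop(matrix(0L, 1, 4), matrix(2L, 1, 4))
  ff <- pairwise_fst(fixed$gm, fixed$popmap)
  expect_equal(ff$fst["popA", "popB"], 1)
})

test_that("the multi-locus estimator equals the exhaustive small-case oracle", {
  # all 2-population dosage tables with n = 2 diploids each, 2 loci
  combos <- expand.grid(a1 = 0:2, a2 = 0:2, b1 = 0:2, b2 = 0:2)
  set.seed(101)
  pick <- combos[sample(nrow(combos), 40), ]
  for (k in seq_len(nrow(pick))) {
    d1 <- rbind(c(pick$a1[k], pick$a2[k]), c(pick$b1[k], pick$b2[k]))
    d2 <- rbind(c(pick$b1[k], pick$a1[k]), c(pick$a2[k], pick$b2[k]))
    two <- make_two_pop(d1, d2)
    f <- suppressWarnings(pairwise_fst(two$gm, two$popmap))
    # oracle: per-locus a, b, c from the published formulas, ratio of sums
    comp <- lapply(1:2, function(l) {
      p1 <- mean(d1[l, ]) / 2; p2 <- mean(d2[l, ]) / 2
      h1 <- mean(d1[l, ] == 1); h2 <- mean(d2[l, ] == 1)
      if (((p1 + p2) / 2) %in% c(0, 1)) return(c(a = 0, b = 0, c = 0))
      wc84_oracle_locus(2, p1, h1, 2, p2, h2)
    })
    num <- sum(vapply(comp, `[[`, numeric(1), "a"))
    den <- sum(vapply(comp, function(x) sum(x), numeric(1)))
    expected <- if (den == 0) NA_real_ else num / den
    expect_equal(f$fst["popA", "popB"], expected, tolerance = 1e-12)
  }
})

test_that("F_ST increases with divergence time on coalescent-simulated pairs", {
  fst_at <- function(t1, seed) {
    par <- demographic_params(ancsize = 1000, t1 = t1, n_wild = 1000,
                              n_dom = 1000)
    cfg <- synth_config(
      populations = data.frame(population = c("w", "d"),
                               group = c("wild", "domestic_european"),
                               n = c(12, 12), stringsAsFactors = FALSE),
      n_loci = 1500, missing_rate = 0, method = "coalescent",
      scenario = demographic_params(ancsize = 1000, t1 = t1, n_wild = 1000,
                                    n_dom = 1000, m1_wd = 0, m1_dw = 0,
                                    m2_wd = 0, m2_dw = 0),
      f_cluster = c(wild = 0.02, domestic_european = 0.02),
      f_pop = c(wild = 0.01, domestic_european = 0.01),
      seed = seed)
    ds <- generate_dataset(cfg)
    pairwise_fst(ds$gm, ds$popmap)$fst["w", "d"]
  }
  short <- vapply(1:5, function(s) fst_at(200, s), numeric(1))
  long <- vapply(1:5, function(s) fst_at(2000, s + 100), numeric(1))
  expect_gt(mean(long), mean(short))
})

test_that("AMOVA reproduces the hand-computed two-group toy", {
  # 2 groups x 2 populations x 2 diploids, one locus: group 1 all ref,
  # group 2 all alt. Between-population-within-group variance is zero and
  # F_CT = F_ST = 1 (all variation among groups).
  d <- matrix(c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L), nrow = 1)
  gm <- make_gm(d)
  pm <- population_map(data.frame(
    individual = gm$individuals,
    population = rep(c("p1", "p2", "p3", "p4"), each = 2),
    group = rep(c("wild", "domestic_european"), each = 4)))
  res <- amova(gm, pm, n_perm = 0)
  expect_equal(res$indices$F_CT, 1)
  expect_equal(res$indices$F_ST, 1)
  expect_equal(res$table$variance[2], 0) # among pops within groups
  # brute-force check of the sums of squares on the 16 allele copies
  x <- rep(c(0, 1), each = 8)
  sst <- sum((x - mean(x))^2)
  expect_equal(res$table$sum_sq[4], sst)
  expect_equal(res$table$sum_sq[1], sst) # all SS between groups
})

test_that("AMOVA components are invariant to relabeling within populations", {
  set.seed(9)
  d <- matrix(sample(c(0:2, NA), 30 * 12, replace = TRUE,
                     prob = c(.45, .2, .3, .05)), nrow = 30)
  gm <- make_gm(d)
  pops <- rep(c("p1", "p2", "p3"), each = 4)
  groups <- setNames(c("wild", "wild", "domestic_european"), c("p1", "p2", "p3"))
  pm <- make_popmap(gm$individuals, pops, groups[pops])
  res1 <- amova(gm, pm, n_perm = 0)
  # shuffle individuals within each population (labels follow individuals)
  perm <- unlist(lapply(split(seq_len(12), pops), sample))
  gm2 <- gm_subset(gm, individuals = perm)
  pm2 <- make_popmap(gm2$individuals, pops[perm], groups[pops[perm]])
  res2 <- amova(gm2, pm2, n_perm = 0)
  expect_equal(res1$table$variance, res2$table$variance)
  # components sum to the reported total
  expect_equal(sum(res1$table$variance[1:3]), res1$table$variance[4])
  expect_equal(sum(res1$table$percent[1:3]), 100)
})

test_that("permutation p-values are large for random group structure", {
  set.seed(10)
  d <- matrix(rbinom(50 * 16, 2, 0.3), nrow = 50)
  gm <- make_gm(d)
  pops <- rep(paste0("p", 1:4), each = 4)
  groups <- setNames(c("wild", "wild", "domestic_european",
                       "domestic_european"), paste0("p", 1:4))
  pm <- make_popmap(gm$individuals, pops, groups[pops])
  res <- amova(gm, pm, n_perm = 99, seed = 5)
  expect_gt(res$p_values[["F_ST"]], 0.05)
  expect_true(all(res$p_values > 0 & res$p_values <= 1, na.rm = TRUE))
})
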