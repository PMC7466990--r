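test_that("frequency-mode f3 reproduces hand computations", {
  # c identical to a: the (c - a) factor vanishes locus-wise
  a <- c(0.1, 0.4, 0.9, 0.3, 0.6, 0.2, 0.8, 0.5)
  b <- c(0.9, 0.1, 0.2, 0.8, 0.3, 0.7, 0.1, 0.4)
  r0 <- f3_from_freq(a, a, b, block_size = 2)
  expect_equal(r0$f3, 0)
  # 4-locus toy: every term is (0.5-1)(0.5-0) or (0.5-0)(0.5-1) = -0.25
  fa <- c(1, 1, 0, 0); fb <- c(0, 0, 1, 1); fc <- rep(0.5, 4)
  r1 <- f3_from_freq(fc, fa, fb, block_size = 2)
  expect_equal(r1$f3, -0.25)
  expect_equal(r1$n_blocks, 2L)
})

test_that("f3 is symmetric in the two sources and drops monomorphic loci", {
  set.seed(21)
  d <- matrix(sample(0:2, 200 * 12, replace = TRUE), nrow = 200)
  d[1:10, ] <- 0L # monomorphic everywhere: must be dropped
  gm <- make_gm(d)
  pm <- make_popmap(gm$individuals, rep(c("C", "A", "B"), each = 4),
                    setNames(c("wild", "wild", "wild"), c("C", "A", "B")))
  r_ab <- f3_test(gm, "C", "A", "B", pm, block_size = 50)
  r_ba <- f3_test(gm, "C", "B", "A", pm, block_size = 50)
  expect_equal(r_ab$f3, r_ba$f3)
  expect_equal(r_ab$se, r_ba$se)
  expect_equal(r_ab$n_loci, 190L)
  expect_equal(r_ab$z, r_ab$f3 / r_ab$se)
  expect_error(f3_test(gm, "C", "C", "B", pm), "distinct")
})

test_that("the target bias correction removes the sampling-variance offset", {
  # with C drawn from the same pool as A and B, uncorrected
  # (c-a)(c-b) is inflated by Var(c-hat); the corrected statistic is ~0
  set.seed(22)
  L <- 4000
  p <- runif(L, 0.1, 0.9)
  draw <- function(n) matrix(rbinom(L * n, 2, p), nrow = L)
  gm <- make_gm(cbind(draw(4), draw(6), draw(6)))
  pm <- make_popmap(gm$individuals,
                    rep(c("C", "A", "B"), c(4, 6, 6)),
                    rep("wild", 16))
  r <- f3_test(gm, "C", "A", "B", pm, block_size = 400)
  expect_lt(abs(r$z), 3)
  # the raw product is clearly positive on the same data
  fc <- allele_frequency(gm, "C", pm)$freq
  fa <- allele_frequency(gm, "A", pm)$freq
  fb <- allele_frequency(gm, "B", pm)$freq
  raw <- mean((fc - fa) * (fc - fb), na.rm = TRUE)
  expect_gt(raw, abs(r$f3))
})

test_that("admixed targets give Z < -3, unadmixed targets do not", {
  z_for <- function(alpha, seed) {
    pops <- data.frame(
      population = c("src_e", "src_c", "tgt"),
      group = c("domestic_european", "domestic_chinese", "domestic_european"),
      n = c(10, 10, 10),
      alpha = c(NA, NA, alpha),
      src1 = c(NA, NA, "src_e"), src2 = c(NA, NA, "src_c"),
      stringsAsFactors = FALSE)
    cfg <- synth_config(populations = pops, n_loci = 8000, missing_rate = 0,
                        f_pop = c(domestic_european = 0.02,
                                  domestic_chinese = 0.02), seed = seed)
    ds <- generate_dataset(cfg)
    f3_test(ds$gm, "tgt", "src_e", "src_c", ds$popmap, block_size = 500)$z
  }
  z_adm <- vapply(1:6, function(s) z_for(0.5, s), numeric(1))
  expect_true(all(z_adm < -3))
  z_pure <- vapply(1:6, function(s) z_for(0, s + 50), numeric(1))
  expect_true(mean(z_pure >= -3) >= 5 / 6)
})

test_that("jackknife SE tracks the replicate-to-replicate SD of f3", {
  # frequency-mode replicates of a fixed mixture scenario
  one <- function(seed) {
    set.seed(seed)
    L <- 5000
    pa <- runif(L, 0.05, 0.95)
    pb <- runif(L, 0.05, 0.95)
    pc <- 0.5 * pa + 0.5 * pb
    # finite sampling of the three population frequencies (n = 20 copies)
    f3_from_freq(rbinom(L, 20, pc) / 20, rbinom(L, 20, pa) / 20,
                 rbinom(L, 20, pb) / 20, block_size = 250)
  }
  runs <- lapply(1:40, one)
  f3s <- vapply(runs, `[[`, numeric(1), "f3")
  ses <- vapply(runs, `[[`, numeric(1), "se")
  expect_lt(abs(mean(ses) / sd(f3s) - 1), 0.25)
})

test_that("too few blocks is an error", {
  expect_error(f3_from_freq(c(.5, .5), c(.1, .2), c(.9, .8), block_size = 10),
               "blocks")
})
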