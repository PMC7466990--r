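make_sfs <- function(entries, n = c(22, 30), mono = 100) {
  m <- matrix(0, n[1] + 1, n[2] + 1)
  for (e in entries) m[e[1] + 1, e[2] + 1] <- e[3]
  sfs2d(m, mono, n)
}

test_that("folding merges complementary orientations and conserves sites", {
  s <- make_sfs(list(c(1, 0, 5), c(21, 30, 3)))
  f <- fold(s)
  expect_equal(f$counts["1", "0"], 8)
  expect_equal(total_sites(f), total_sites(s))
  expect_true(f$folded)
  expect_error(fold(f), "already folded")
  # tie cell (11,15) is self-complementary and keeps its mass
  s2 <- make_sfs(list(c(11, 15, 4)))
  expect_equal(fold(s2)$counts["11", "15"], 4)
  # non-self-complementary tie pair splits between the two orientations
  s3 <- make_sfs(list(c(10, 16, 6), c(12, 14, 2)))
  f3 <- fold(s3)
  expect_equal(f3$counts["10", "16"], 4) # (6 + 2) / 2
  expect_equal(f3$counts["12", "14"], 4)
  expect_equal(total_sites(f3), total_sites(s3))
})

test_that("a symmetric spectrum folds to half support with sites conserved", {
  set.seed(41)
  m <- matrix(runif(23 * 31), 23, 31)
  m <- m + m[rev(1:23), rev(1:31)]  # symmetrise
  m[1, 1] <- m[23, 31] <- 0
  s <- sfs2d(m, 50, c(22, 30))
  f <- fold(s)
  expect_equal(total_sites(f), total_sites(s))
  pooled <- outer(0:22, 0:30, "+")
  expect_true(all(f$counts[pooled > 26] == 0))
})

test_that("composite log-likelihood follows the multinomial identity", {
  # toy 2-cell case: O = (3, 1), p = (0.75, 0.25)
  o <- make_sfs(list(c(1, 0, 3), c(2, 0, 1)), mono = 0)
  e <- make_sfs(list(c(1, 0, 75), c(2, 0, 25)), mono = 0)
  ll <- composite_log_likelihood(o, e)
  expect_equal(as.numeric(ll), 3 * log(0.75) + log(0.25))
  # observed proportions equal to expected probabilities are maximal
  e2 <- make_sfs(list(c(1, 0, 3), c(2, 0, 2)), mono = 0)
  expect_gt(as.numeric(ll), as.numeric(composite_log_likelihood(o, e2)))
  # single cell holding all sites with p = 1
  o3 <- make_sfs(list(c(5, 5, 10)), mono = 0)
  expect_equal(as.numeric(composite_log_likelihood(o3, o3)), 0)
  # zero-probability cells with observations are floored and flagged
  e4 <- make_sfs(list(c(1, 0, 1)), mono = 0)
  ll4 <- composite_log_likelihood(o3, e4)
  expect_equal(attr(ll4, "n_floored"), 1L)
  expect_equal(as.numeric(ll4), 10 * log(1e-10))
  expect_error(composite_log_likelihood(o, fold(e)), "folding")
})

test_that("the observed SFS from genotypes uses complete loci and accounts sites", {
  # 2 wild + 3 domestic diploids, 4 loci (one with missing data)
  dw <- rbind(c(1L, 0L), c(2L, 2L), c(0L, 0L), c(NA, 1L))
  dd <- rbind(c(0L, 0L, 1L), c(2L, 2L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L))
  gm <- make_gm(cbind(dw, dd))
  s <- sfs_from_genotypes(gm, c("ind1", "ind2"), c("ind3", "ind4", "ind5"),
                          total_sites = 1000, fold = FALSE)
  expect_equal(s$n, c(4L, 6L))
  expect_equal(s$counts["1", "1"], 1)  # locus 1
  expect_equal(s$counts["4", "5"], 1)  # locus 2
  # locus 3 is sample-monomorphic, locus 4 incomplete: 998 monomorphic
  expect_equal(s$monomorphic, 998)
  expect_equal(total_sites(s), 1000)
  folded <- sfs_from_genotypes(gm, c("ind1", "ind2"),
                               c("ind3", "ind4", "ind5"), 1000)
  expect_true(folded$folded)
  expect_equal(folded$counts["1", "1"], 1)        # pooled count 2: stays
  expect_equal(folded$counts["0", "1"], 1)        # (4,5) folds to (0,1)
})

test_that("SFS serialization round-trips in both dialects", {
  set.seed(42)
  m <- matrix(rpois(23 * 31, 2), 23, 31)
  m[1, 1] <- m[23, 31] <- 0
  s <- fold(sfs2d(m, 12345, c(22, 30)))
  p1 <- tempfile(fileext = ".json")
  write_sfs_json(s, p1)
  back <- read_sfs_json(p1)
  expect_equal(back$counts, s$counts, ignore_attr = TRUE)
  expect_equal(back$monomorphic, s$monomorphic)
  expect_equal(back$folded, s$folded)
  p2 <- tempfile(fileext = ".obs")
  write_sfs_obs(s, p2)
  back2 <- read_sfs_obs(p2, folded = TRUE)
  expect_equal(back2$counts, s$counts, ignore_attr = TRUE)
  expect_equal(back2$monomorphic, s$monomorphic)
  expect_equal(readLines(p2)[1], "1 observations")
})

test_that("sfs2d rejects inconsistent construction", {
  m <- matrix(0, 23, 31); m[1, 1] <- 5
  expect_error(sfs2d(m, 0, c(22, 30)), "corner")
  m2 <- matrix(0, 23, 31); m2[23, 30] <- 1  # pooled count 51 > 26
  expect_error(sfs2d(m2, 0, c(22, 30), folded = TRUE), "boundary")
})
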