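test_that("zero mutation rate yields an all-monomorphic spectrum", {
  m <- build_model("i", demographic_params(500, 1000, 500, 500))
  s <- simulate_sfs(m, 10, 10, n_sites = 1e5, mu = 0, n_reps = 50, seed = 1)
  expect_equal(sum(s$counts), 0)
  expect_equal(s$monomorphic, 1e5)
})

test_that("a zero split time reproduces Watterson's expected segregating sites", {
  N <- 1000; mu <- 1.38e-7; n <- 52
  m <- build_model("panmictic", demographic_params(N, 0, N, N))
  reps <- 4000
  s <- simulate_sfs(m, 22, 30, n_sites = 1e6, mu = mu, n_reps = reps,
                    seed = 2, mode = "expected", fold = FALSE)
  expected <- 4 * N * mu * sum(1 / seq_len(n - 1)) * 1e6
  # Monte-Carlo SE of total tree length is well under 2% at this effort
  expect_equal(sum(s$counts), expected, tolerance = 0.06)
})

test_that("deeply split demes share no polymorphism", {
  p <- demographic_params(100, 19999, 300, 300)
  s <- simulate_sfs(build_model("i", p), 10, 10, n_sites = 1e6,
                    n_reps = 400, seed = 3, mode = "expected", fold = FALSE)
  shared <- s$counts[2:10, 2:10]   # segregating in both demes
  private <- sum(s$counts) - sum(shared) -
    sum(s$counts[11, 2:10]) - sum(s$counts[2:10, 11])
  # fixed-different and private classes dominate; truly shared mass is tiny
  expect_lt(sum(shared) / sum(s$counts), 0.02)
  expect_gt(private, 0)
})

test_that("total sites are conserved through simulate, fold and likelihood", {
  m <- build_model("iii", goose_mle_params())
  s <- simulate_sfs(m, 22, 30, n_sites = 1681316, n_reps = 500, seed = 4,
                    fold = FALSE)
  expect_equal(total_sites(s), 1681316)
  f <- fold(s)
  expect_equal(total_sites(f), 1681316)
  samp <- simulate_sfs(m, 22, 30, n_sites = 1681316, n_reps = 500, seed = 5,
                       mode = "sampled", fold = FALSE)
  expect_equal(total_sites(samp), 1681316)
  expect_true(all(samp$counts == round(samp$counts)))
  # folding may split boundary-tie cells in half, but conserves sites
  expect_equal(total_sites(fold(samp)), 1681316)
})

test_that("model nesting gives bit-identical spectra under shared seeds", {
  base <- demographic_params(800, 2000, 1000, 400, m1_wd = 5e-4, m1_dw = 3e-4,
                             m2_wd = 5e-4, m2_dw = 3e-4, t2 = 300)
  m_ii <- build_model("ii", base)
  m_iii <- build_model("iii", base)  # same rates in both epochs
  s_ii <- simulate_sfs(m_ii, 12, 12, n_sites = 1e5, n_reps = 300, seed = 7)
  s_iii <- simulate_sfs(m_iii, 12, 12, n_sites = 1e5, n_reps = 300, seed = 7)
  expect_identical(s_ii$counts, s_iii$counts)
  nomig <- demographic_params(800, 2000, 1000, 400)
  s_i <- simulate_sfs(build_model("i", nomig), 12, 12, n_sites = 1e5,
                      n_reps = 300, seed = 8)
  s_ii0 <- simulate_sfs(build_model("ii", nomig), 12, 12, n_sites = 1e5,
                        n_reps = 300, seed = 8)
  expect_identical(s_i$counts, s_ii0$counts)
  # and the likelihoods of any observed data follow suit
  obs <- simulate_sfs(m_iii, 12, 12, n_sites = 1e5, n_reps = 200, seed = 9,
                      mode = "sampled")
  expect_identical(composite_log_likelihood(obs, s_ii),
                   composite_log_likelihood(obs, s_iii))
})

test_that("expected-mode spectra converge as replicates grow", {
  m <- build_model("iii", goose_mle_params())
  lo <- simulate_sfs(m, 22, 30, n_sites = 1, n_reps = 500, seed = 10)
  hi1 <- simulate_sfs(m, 22, 30, n_sites = 1, n_reps = 8000, seed = 11)
  hi2 <- simulate_sfs(m, 22, 30, n_sites = 1, n_reps = 8000, seed = 12)
  d_lo <- sum(abs(lo$counts - hi2$counts))
  d_hi <- sum(abs(hi1$counts - hi2$counts))
  expect_lt(d_hi, d_lo)
})

test_that("simulation rejects impossible inputs", {
  m <- build_model("i", demographic_params(100, 100, 100, 100))
  expect_error(simulate_sfs(m, 10, 10, n_sites = 0, n_reps = 10), "n_sites")
  expect_error(simulate_sfs(m, 10, 10, n_sites = 10, n_reps = 0), "n_reps")
})
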