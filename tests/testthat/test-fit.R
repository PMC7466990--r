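# Small-scale fitting checks. Full-scale recovery of the goose history is
# exercised in test-acceptance.R; here the one-parameter panmictic model
# keeps the composite-likelihood machinery honest at desk cost.

small <- fit_settings("desk", n_reps = 1500, n_cycles = 3, n_restarts = 3,
                      n_select = 2, n_refine = 1, refine_factor = 2,
                      n_polish = 1, polish_factor = 4)

test_that("a panmictic size is recovered within ten percent", {
  truth <- build_model("panmictic", demographic_params(1000, 0, 1000, 1000))
  obs <- simulate_sfs(truth, 22, 30, n_sites = 1e6, n_reps = 15000, seed = 42,
                      mode = "sampled")
  f <- fit_sfs(obs, "panmictic", settings = small, seed = 7)
  expect_lt(abs(f$estimates[["ancsize"]] / 1000 - 1), 0.10)
  expect_equal(f$k, 1L)
  expect_equal(f$AIC, 2 * 1 - 2 * f$lnCL)
})

test_that("the optimiser matches a brute-force grid oracle", {
  truth <- build_model("panmictic", demographic_params(1500, 0, 1500, 1500))
  obs <- simulate_sfs(truth, 22, 30, n_sites = 1e6, n_reps = 15000, seed = 43,
                      mode = "sampled")
  # oracle: likelihood profile on a fixed grid with one shared seed
  grid <- round(10^seq(log10(300), log10(6000), length.out = 25))
  ll <- vapply(grid, function(N) {
    e <- simulate_sfs(build_model("panmictic",
                                  demographic_params(N, 0, N, N)),
                      22, 30, n_sites = 1e6, n_reps = 4000, seed = 99)
    as.numeric(composite_log_likelihood(obs, e))
  }, numeric(1))
  n_grid <- grid[which.max(ll)]
  f <- fit_sfs(obs, "panmictic", settings = small, seed = 8)
  # the continuous optimiser must land within one grid step of the oracle
  expect_lt(abs(log10(f$estimates[["ancsize"]]) - log10(n_grid)), 0.15)
})

test_that("akaike weights follow the AIC identity and reject mismatched data", {
  truth <- build_model("i", demographic_params(900, 1200, 900, 400))
  obs <- simulate_sfs(truth, 12, 12, n_sites = 2e5, n_reps = 10000, seed = 44,
                      mode = "sampled")
  fake <- function(model_id, lnCL, k) {
    structure(list(model_id = model_id, lnCL = lnCL, k = k,
                   AIC = 2 * k - 2 * lnCL, observed = obs),
              class = "fit_result")
  }
  aw <- akaike_weights(list(fake("a", -1000, 4), fake("b", -1000, 4)))
  expect_equal(aw$weight, c(0.5, 0.5))
  aw2 <- akaike_weights(list(fake("a", -1000, 4), fake("b", -1000, 5)))
  expect_equal(aw2$weight[1] / aw2$weight[2], exp(1), tolerance = 1e-10)
  aw3 <- akaike_weights(list(fake("a", -1000, 4), fake("b", -1025, 4)))
  expect_lt(aw3$weight[2], 1e-10)
  other <- simulate_sfs(truth, 12, 12, n_sites = 1e5, n_reps = 100, seed = 4,
                        mode = "sampled")
  bad <- fake("c", -900, 4); bad$observed <- other
  expect_error(akaike_weights(list(fake("a", -1000, 4), bad)), "different")
})

test_that("parametric bootstrap enforces its guard and covers a panmictic fit", {
  truth <- build_model("panmictic", demographic_params(1000, 0, 1000, 1000))
  obs <- simulate_sfs(truth, 22, 30, n_sites = 1e6, n_reps = 15000, seed = 45,
                      mode = "sampled")
  f <- fit_sfs(obs, "panmictic", settings = small, seed = 9)
  expect_error(parametric_bootstrap(f, B = 2), "at least 20")
  tiny <- fit_settings("desk", n_reps = 800, n_cycles = 2, n_restarts = 1,
                       n_select = 1, n_refine = 1, refine_factor = 2,
                       n_polish = 0)
  bs <- parametric_bootstrap(f, B = 20, settings = tiny, seed = 10)
  ci <- bs$bootstrap_ci
  expect_equal(ci$parameter, "ancsize")
  expect_lt(ci$lower, f$estimates[["ancsize"]])
  expect_gt(ci$upper, f$estimates[["ancsize"]])
  expect_lt(ci$lower, 1000 * 1.2)
  expect_gt(ci$upper, 1000 * 0.8)
})

test_that("fit metadata and input guards behave", {
  truth <- build_model("panmictic", demographic_params(500, 0, 500, 500))
  obs <- simulate_sfs(truth, 10, 10, n_sites = 1e5, n_reps = 3000, seed = 46,
                      mode = "sampled")
  expect_error(fit_sfs(obs, "panmictic", bounds = list(ancsize = c(-1, 10))),
               "bounds")
  f <- fit_sfs(obs, "panmictic", settings = small, seed = 11,
               init = c(ancsize = 500))
  expect_s3_class(f$params, "demographic_params")
  expect_true(is.finite(f$lnCL))
})
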