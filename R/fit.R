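#' Fitting settings profiles
#'
#' Bundles the Monte-Carlo and optimisation effort knobs for
#' [fit_sfs]. The search is staged: `n_restarts` starts are explored
#' for `n_cycles` ECM cycles at `n_reps` coalescent replicates per
#' likelihood evaluation; the best `n_select` candidates are refined for
#' `n_refine` further cycles at `refine_factor` times the replicates;
#' the winner is ridge-scanned and finished by a Nelder-Mead simplex
#' (`nm_maxit` iterations at `nm_factor` times the replicates), followed
#' for two-population models by a split-time profile with joint
#' re-optimisation (`profile_t1`, `profile_maxit`); candidates from
#' different stages are compared at `rank_factor` times the replicates.
#' `n_polish`/`polish_factor` add optional extra coordinate cycles.
#' The `"desk"` profile is sized for interactive use and testing; the
#' `"paper"` profile carries the full-scale effort used for the
#' published goose analysis (100,000 simulations, 40 conditional-
#' maximisation cycles, 100 independent runs).
#'
#' @param profile `"desk"` or `"paper"`.
#' @param ... overrides for any setting listed above.
#' @return A list of settings.
#' @export
fit_settings <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  s <- switch(profile,
              desk = list(n_reps = 2000, n_cycles = 6, n_restarts = 10,
                          n_select = 3, n_refine = 1, refine_factor = 4,
                          n_polish = 0, polish_factor = 12, rank_factor = 50,
                          nm_maxit = 100, nm_factor = 25,
                          profile_t1 = TRUE, profile_maxit = 70),
              paper = list(n_reps = 100000, n_cycles = 40, n_restarts = 100,
                           n_select = 5, n_refine = 8, refine_factor = 1,
                           n_polish = 2, polish_factor = 1, rank_factor = 2,
                           nm_maxit = 300, nm_factor = 1,
                           profile_t1 = TRUE, profile_maxit = 120))
  over <- list(...)
  s[names(over)] <- over
  s$profile <- profile
  s
}

#' Default parameter bounds for model fitting
#'
#' Finite positive search bounds per free parameter: diploid sizes and
#' times span 100 to 20,000 (individuals / generations), migration rates
#' 1e-8 to 0.01 (above one percent per generation two demes are
#' effectively panmictic), and the switch time from 5 generations
#' (clipped to stay below the current split time during optimisation).
#'
#' @param model_id model identifier (see [build_model]).
#' @return Named list of `c(lower, upper)` per free parameter.
#' @export
default_bounds <- function(model_id) {
  all <- list(ancsize = c(100, 20000), t1 = c(100, 20000),
              n_wild = c(100, 20000), n_dom = c(100, 20000),
              m1_wd = c(1e-8, 0.01), m1_dw = c(1e-8, 0.01),
              t2 = c(5, 20000), m2_wd = c(1e-8, 0.01), m2_dw = c(1e-8, 0.01))
  all[free_params(model_id)]
}

# Build a full demographic_params from a named free-parameter vector.
.vec_to_params <- function(model_id, v, mu, generation_time = 3) {
  g <- function(nm, default = 0) if (nm %in% names(v)) unname(v[[nm]]) else default
  model_id <- .canon_model(model_id)
  if (model_id == "panmictic") {
    return(demographic_params(ancsize = g("ancsize", 1000), t1 = 0,
                              n_wild = g("ancsize", 1000), n_dom = g("ancsize", 1000),
                              mu = mu, generation_time = generation_time))
  }
  m1_wd <- g("m1_wd"); m1_dw <- g("m1_dw")
  if (model_id == "constant_migration") {
    m2_wd <- m1_wd; m2_dw <- m1_dw; t2 <- 0
  } else if (model_id == "no_migration") {
    m2_wd <- 0; m2_dw <- 0; t2 <- 0
  } else {
    m2_wd <- g("m2_wd"); m2_dw <- g("m2_dw"); t2 <- min(g("t2"), g("t1"))
  }
  demographic_params(ancsize = g("ancsize"), t1 = g("t1"),
                     n_wild = g("n_wild"), n_dom = g("n_dom"),
                     m1_wd = m1_wd, m1_dw = m1_dw,
                     m2_wd = m2_wd, m2_dw = m2_dw, t2 = t2,
                     mu = mu, generation_time = generation_time)
}

#' Fit a demographic model to an observed SFS
#'
#' Maximises the composite log-likelihood of `observed` under the chosen
#' model by ECM-style block-coordinate ascent: each cycle sweeps the
#' parameter blocks (sizes, times, migration rates), maximising the
#' likelihood over one parameter at a time by golden-section search on a
#' log scale within its bounds. All likelihood evaluations within a
#' cycle reuse the same coalescent random seed (common random numbers),
#' without which Monte-Carlo noise defeats the one-dimensional
#' maximisations. `n_restarts` independent starting points are drawn
#' log-uniformly within the bounds; finishers are re-evaluated under one
#' shared seed, and the best candidate receives `n_polish` further
#' cycles at `polish_factor` times the Monte-Carlo effort to sharpen the
#' optimum before it is returned.
#'
#' @param observed an `sfs2d` (folded or unfolded).
#' @param model_id model identifier (see [build_model]).
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   defaults to [default_bounds].
#' @param settings a list from [fit_settings].
#' @param seed master seed; every random draw of the fit derives from
#'   it.
#' @param mu fixed mutation rate per site per generation.
#' @param init optional named vector of free parameters used as the
#'   starting point of the first restart (the remaining restarts stay
#'   random); the usual warm start for bootstrap refits.
#' @return A `fit_result`: `model_id`, `params` (the MLE as a
#'   [demographic_params]), `estimates` (free-parameter vector), `lnCL`,
#'   `k`, `AIC`, plus the observed spectrum and fitting metadata.
#' @export
fit_sfs <- function(observed, model_id, bounds = NULL,
                    settings = fit_settings("desk"), seed = 1,
                    mu = 1.38e-7, init = NULL) {
  stopifnot(inherits(observed, "sfs2d"))
  if (total_sites(observed) <= 0) stop("observed spectrum has no sites")
  model_id <- .canon_model(model_id)
  fp <- free_params(model_id)
  if (is.null(bounds)) bounds <- default_bounds(model_id)
  if (!all(fp %in% names(bounds))) stop("bounds missing for: ",
                                        paste(setdiff(fp, names(bounds)), collapse = ", "))
  for (b in bounds) {
    if (any(!is.finite(b)) || any(b <= 0) || b[1] > b[2]) {
      stop("bounds must be finite, positive and ordered")
    }
  }
  ns <- total_sites(observed)
  n1 <- observed$n[1]; n2 <- observed$n[2]

  objective <- function(v, eval_seed, n_reps) {
    par <- .vec_to_params(model_id, v, mu)
    mod <- build_model(model_id, par)
    exp_sfs <- simulate_sfs(mod, n1, n2, n_sites = ns, mu = mu,
                            n_reps = n_reps, seed = eval_seed,
                            mode = "expected", fold = observed$folded)
    as.numeric(composite_log_likelihood(observed, exp_sfs))
  }

  blocks <- list(sizes = intersect(c("ancsize", "n_wild", "n_dom"), fp),
                 times = intersect(c("t1", "t2"), fp),
                 rates = intersect(c("m1_wd", "m1_dw", "m2_wd", "m2_dw"), fp))
  blocks <- blocks[lengths(blocks) > 0]

  set.seed(seed)
  n_rs <- settings$n_restarts
  n_cy <- settings$n_cycles
  eval_seed_final <- sample.int(.Machine$integer.max - 1, 1)
  screen_seed <- sample.int(.Machine$integer.max - 1, 1)
  g <- function(nm, default) if (is.null(settings[[nm]])) default else settings[[nm]]

  draw_start <- function() {
    v <- vapply(bounds[fp], function(b) 10^runif(1, log10(b[1]), log10(b[2])),
                numeric(1))
    names(v) <- fp
    if ("t2" %in% fp) v["t2"] <- min(v["t2"], v["t1"] * 0.9)
    v
  }

  explore_cycles <- n_cy
  if (model_id == "changing_migration" && isTRUE(g("hierarchical", TRUE))) {
    # Hierarchical start construction: the epoch-switch model nests the
    # constant-migration model, whose fit pins the backbone (sizes, split
    # time, average rates) far more reliably than random starts pin all
    # nine parameters at once. A short nested prefit is run, and starts
    # for the full model are laid out on a grid over the weakly
    # identified epoch subspace: switch time as a fraction of the split
    # time, recent rates as multiples of the old rates.
    pre_settings <- settings
    pre_settings$hierarchical <- FALSE
    pre_settings$n_restarts <- min(n_rs, 6)
    pre_settings$n_cycles <- min(n_cy, 4)
    pre_settings$n_select <- 2
    pre_settings$n_refine <- 1
    pre_settings$n_polish <- 0
    pre_settings$nm_maxit <- 0  # the backbone prefit stays cheap
    pre_seed <- sample.int(.Machine$integer.max - 1, 1)
    pre <- fit_sfs(observed, "constant_migration",
                   bounds = bounds[free_params("constant_migration")],
                   settings = pre_settings, seed = pre_seed, mu = mu)
    bb <- pre$estimates
    clip <- function(x, nm) min(max(x, bounds[[nm]][1]), bounds[[nm]][2])
    starts <- list()
    for (tf in c(0.7, 1)) {
      t1_cell <- clip(tf * bb[["t1"]], "t1")
      anc_cell <- clip(bb[["ancsize"]] + (bb[["t1"]] - t1_cell) / 2, "ancsize")
      for (fr in c(0.02, 0.06)) {
        for (ra in c(1, 3)) {
          v <- c(ancsize = anc_cell, t1 = t1_cell,
                 n_wild = bb[["n_wild"]], n_dom = bb[["n_dom"]],
                 m1_wd = bb[["m1_wd"]], m1_dw = bb[["m1_dw"]],
                 t2 = clip(fr * t1_cell, "t2"),
                 m2_wd = clip(ra * bb[["m1_wd"]], "m2_wd"),
                 m2_dw = clip(ra * bb[["m1_dw"]], "m2_dw"))
          starts <- c(starts, list(v[fp]))
        }
      }
    }
    explore_cycles <- min(n_cy, g("n_cycles_structured", 2))
    # profile-likelihood exploration: each grid cell's split time and
    # epoch parameters stay frozen while sizes and old-epoch rates adapt
    # to them, so cells are compared as distinct history hypotheses at
    # ranking precision instead of all sliding along the flat ridges
    # during the cheap cycles
    explore_skip <- c("t1", "t2", "m2_wd", "m2_dw")
  } else {
    # screen a wider pool of random points and start the ascent from the
    # most promising ones (one cheap likelihood evaluation each)
    n_screen <- 10 * n_rs
    pool <- replicate(n_screen, draw_start(), simplify = FALSE)
    pool_scores <- vapply(pool, function(v)
      tryCatch(objective(v, screen_seed, settings$n_reps),
               error = function(e) -Inf), numeric(1))
    starts <- pool[order(pool_scores, decreasing = TRUE)[seq_len(n_rs)]]
  }
  if (!is.null(init)) {
    if (!all(fp %in% names(init))) stop("init must name every free parameter")
    starts[[1]] <- init[fp]
  }
  stream <- matrix(sample.int(.Machine$integer.max - 1,
                              length(starts) * (explore_cycles + 1)),
                   nrow = length(starts))

  # Two parameter pairs are nearly unidentified pointwise and act as
  # ridges: the recent-epoch dose t2 * m2 (shorter epochs with stronger
  # flow mimic longer, weaker ones) and the deep coalescence depth
  # t1 + 2 * ANCSIZE (later splits with smaller ancestors mimic earlier
  # ones). Searches over t2 and t1 therefore move along those ridges -
  # rescaling the recent rates, or co-adjusting the ancestral size - so
  # each step compares history shapes instead of sliding along a flat
  # direction.
  coupled <- function(v, pm, lx) {
    w <- v; w[pm] <- 10^lx
    if (pm == "t2" && all(c("m2_wd", "m2_dw") %in% fp) && v[["t2"]] > 0) {
      sc <- v[["t2"]] / w[["t2"]]
      for (mm in c("m2_wd", "m2_dw")) {
        w[mm] <- min(max(v[[mm]] * sc, bounds[[mm]][1]), bounds[[mm]][2])
      }
    }
    if (pm == "t1" && "ancsize" %in% fp) {
      anc <- v[["ancsize"]] + (v[["t1"]] - w[["t1"]]) / 2
      w["ancsize"] <- min(max(anc, bounds[["ancsize"]][1]),
                          bounds[["ancsize"]][2])
    }
    w
  }
  param_range <- function(v, pm) {
    b <- bounds[[pm]]
    lo <- b[1]; hi <- b[2]
    if (pm == "t2") hi <- min(hi, unname(v["t1"]) * 0.99)
    if (pm == "t1" && "t2" %in% fp) lo <- max(lo, unname(v["t2"]) / 0.99)
    c(lo, hi)
  }

  sweep_cycle <- function(v, cyc_seed, n_reps, skip = character(0)) {
    for (blk in blocks) {
      for (pm in setdiff(blk, skip)) {
        r <- param_range(v, pm)
        if (r[2] <= r[1]) next
        f1 <- function(lx) objective(coupled(v, pm, lx), cyc_seed, n_reps)
        opt <- optimize(f1, lower = log10(r[1]), upper = log10(r[2]),
                        maximum = TRUE, tol = 0.04)
        cur <- objective(v, cyc_seed, n_reps)
        if (opt$objective > cur) v <- coupled(v, pm, opt$maximum)
      }
    }
    # epoch-swap proposal: the two migration epochs can trade roles and
    # trap coordinate ascent in the mirrored mode; offer the exchange
    if (all(c("t2", "m1_wd", "m2_wd") %in% fp) && !("t2" %in% skip)) {
      w <- v
      w[c("m1_wd", "m1_dw")] <- v[c("m2_wd", "m2_dw")]
      w[c("m2_wd", "m2_dw")] <- v[c("m1_wd", "m1_dw")]
      if (objective(w, cyc_seed, n_reps) > objective(v, cyc_seed, n_reps)) v <- w
    }
    v
  }

  n_select <- min(g("n_select", 3), length(starts))
  n_refine <- g("n_refine", 3)
  rf <- g("refine_factor", 4)
  n_polish <- g("n_polish", 2)
  pf <- g("polish_factor", 12)

  if (!exists("explore_skip", inherits = FALSE)) explore_skip <- character(0)

  # stage 1: explore all starts at base Monte-Carlo effort
  finishers <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    v <- starts[[r]]
    for (cy in seq_len(explore_cycles)) {
      v <- sweep_cycle(v, stream[r, cy], settings$n_reps, skip = explore_skip)
    }
    finishers[[r]] <- v
  }
  rank_reps <- round(g("rank_factor", 50) * settings$n_reps)
  scores <- vapply(finishers, objective, numeric(1),
                   eval_seed = eval_seed_final,
                   n_reps = max(2 * settings$n_reps, round(rank_reps / 2)))
  if (all(!is.finite(scores))) {
    stop("optimization failure: no finite composite likelihood found; ",
         "check bounds and the observed spectrum")
  }

  # stage 2: refine the leading candidates at higher precision. The
  # split time stays frozen here as well when the candidates came from
  # the structured grid: it is the flattest direction, and releasing it
  # at refine precision would re-collapse the distinct hypotheses; the
  # simplex and profile stages below move it under far more replicates.
  refine_seeds <- sample.int(.Machine$integer.max - 1, max(n_refine, 1))
  top <- order(scores, decreasing = TRUE)[seq_len(n_select)]
  refine_skip <- intersect(explore_skip, "t1")
  refined <- lapply(finishers[top], function(v) {
    for (cy in seq_len(n_refine)) {
      v <- sweep_cycle(v, refine_seeds[cy], round(rf * settings$n_reps),
                       skip = refine_skip)
    }
    v
  })
  rescores <- vapply(refined, objective, numeric(1),
                     eval_seed = eval_seed_final, n_reps = rank_reps)
  v <- refined[[which.max(rescores)]]

  # stage 3: ridge scans at ranking precision. Along the two ridges the
  # curvature is a few tens of log-units across the plausible range -
  # real structure at this Monte-Carlo effort, pure noise at search
  # effort - so the winner's t1 and t2 get one dedicated
  # golden-section pass each at rank_reps before the final polish.
  scan_one <- function(v, pm, reps) {
    r <- param_range(v, pm)
    if (r[2] <= r[1]) return(v)
    opt <- optimize(function(lx) objective(coupled(v, pm, lx),
                                           eval_seed_final, reps),
                    lower = log10(r[1]), upper = log10(r[2]),
                    maximum = TRUE, tol = 0.02)
    cur <- objective(v, eval_seed_final, reps)
    if (opt$objective > cur) coupled(v, pm, opt$maximum) else v
  }
  if (isTRUE(g("ridge_scan", TRUE))) {
    if (all(c("t1", "ancsize") %in% fp)) v <- scan_one(v, "t1", rank_reps)
    if (all(c("t2", "m2_wd", "m2_dw") %in% fp)) v <- scan_one(v, "t2", rank_reps)
  }

  # stage 4: joint finishing search. The likelihood valley is curved in
  # several parameters at once (split time, ancestral size and the old
  # migration rates trade off jointly), which one-parameter-at-a-time
  # ascent cannot follow; a derivative-free simplex search on the log
  # scale under one fixed coalescent seed (so the surrogate surface is
  # smooth) walks the valley. Box constraints enter as a finite penalty.
  nm_maxit <- g("nm_maxit", 250)
  nm_reps <- round(g("nm_factor", 25) * settings$n_reps)
  nm_seed <- sample.int(.Machine$integer.max - 1, 1)
  llo <- vapply(bounds[fp], function(b) log10(b[1]), numeric(1))
  lhi <- vapply(bounds[fp], function(b) log10(b[2]), numeric(1))
  run_nm <- function(v, fixed, maxit, reps) {
    free <- setdiff(fp, fixed)
    if (length(free) < 2 || maxit <= 0) return(v)
    nm_obj <- function(lx) {
      if (any(lx < llo[free]) || any(lx > lhi[free])) return(1e10)
      w <- v; w[free] <- 10^lx
      if ("t2" %in% fp && w[["t2"]] >= w[["t1"]]) return(1e10)
      -objective(w, nm_seed, reps)
    }
    nm <- optim(log10(v[free]), nm_obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-10))
    w <- v; w[free] <- 10^nm$par
    if ("t2" %in% fp && w[["t2"]] >= w[["t1"]]) return(v)
    if (any(w[fp] < vapply(bounds[fp], `[`, numeric(1), 1)) ||
        any(w[fp] > vapply(bounds[fp], `[`, numeric(1), 2))) return(v)
    w
  }
  if (nm_maxit > 0 && length(fp) > 1) {
    v <- run_nm(v, character(0), nm_maxit, nm_reps)
  }

  # t1 profile with joint re-optimisation: the split time is the
  # flattest direction of the surface once everything else re-adapts,
  # so candidate split times are laid out around both the simplex
  # winner and the best refined candidate, each re-optimised with the
  # split time held fixed. Every candidate goes into one final ranking.
  prof_cand <- list()
  if (isTRUE(g("profile_t1", TRUE)) && nm_maxit > 0 &&
      all(c("t1", "ancsize") %in% fp)) {
    pm_iters <- g("profile_maxit", 70)
    for (fct in c(0.72, 0.85, 1, 1.18)) {
      w <- v
      t1_new <- min(max(w[["t1"]] * fct, bounds[["t1"]][1]),
                    bounds[["t1"]][2])
      if ("t2" %in% fp) t1_new <- max(t1_new, w[["t2"]] / 0.99)
      anc <- w[["ancsize"]] + (w[["t1"]] - t1_new) / 2  # keep tree depth
      w["ancsize"] <- min(max(anc, bounds[["ancsize"]][1]),
                          bounds[["ancsize"]][2])
      w["t1"] <- t1_new
      prof_cand <- c(prof_cand,
                     list(run_nm(w, fixed = "t1", pm_iters,
                                 round(nm_reps / 2))))
    }
  }

  # stage 5: optional extra coordinate polish, then rank every finishing
  # candidate at high precision - modes a handful of log-units apart are
  # real at that scale; deciding between them at search precision would
  # hand the choice to noise
  if (n_polish > 0) {
    polish_seeds <- sample.int(.Machine$integer.max - 1, n_polish)
    for (cy in seq_len(n_polish)) {
      v <- sweep_cycle(v, polish_seeds[cy], round(pf * settings$n_reps))
    }
  }
  final_pool <- c(refined, list(v), prof_cand)
  final_scores <- c(rescores,
                    vapply(c(list(v), prof_cand), objective, numeric(1),
                           eval_seed = eval_seed_final, n_reps = rank_reps))
  v <- final_pool[[which.max(final_scores)]]
  par <- .vec_to_params(model_id, v, mu)
  k <- length(fp)
  lnCL <- objective(v, eval_seed_final, rank_reps)
  structure(list(model_id = model_id, params = par, estimates = v,
                 lnCL = lnCL, k = k, AIC = 2 * k - 2 * lnCL,
                 akaike_weight = NA_real_, bootstrap_ci = NULL,
                 observed = observed, bounds = bounds,
                 settings = settings, seed = seed, mu = mu),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: model %s, lnCL = %.2f, k = %d, AIC = %.2f\n",
              x$model_id, x$lnCL, x$k, x$AIC))
  print(round(x$estimates, 6))
  if (!is.null(x$bootstrap_ci)) {
    cat("bootstrap 95% CIs:\n"); print(x$bootstrap_ci)
  }
  invisible(x)
}

.observed_digest <- function(sfs) {
  c(sfs$n, sfs$folded, round(total_sites(sfs), 6), round(sum(sfs$counts), 6))
}

#' Akaike weights across fitted models
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}. All fits must target the same
#' observed spectrum.
#'
#' @param fits list of `fit_result` objects (>= 2).
#' @return Data frame with model, lnCL, k, AIC, delta and weight, sorted
#'   by weight.
#' @export
akaike_weights <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  digests <- lapply(fits, function(f) .observed_digest(f$observed))
  if (!all(vapply(digests[-1], identical, logical(1), digests[[1]]))) {
    stop("fits target different observed spectra")
  }
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = vapply(fits, function(f) f$model_id, character(1)),
                    lnCL = vapply(fits, function(f) f$lnCL, numeric(1)),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    AIC = aic, delta = delta, weight = w)
  out[order(-out$weight), ]
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `B` spectra at the fitted MLE (multinomial "sampled" mode,
#' same sample sizes and total sites as the observed spectrum), refits
#' the model to each, and reports 2.5th-97.5th percentile intervals per
#' free parameter. Replicates whose refit fails are dropped and counted;
#' more than 20% failures aborts. The full-scale convention is B = 100
#' replicates with 50 independent runs per refit; scaled-down refit
#' settings may be passed for desk use. A minimum of 20 replicates is
#' enforced so the percentiles are estimable.
#'
#' @param fit a `fit_result` from [fit_sfs].
#' @param B number of bootstrap replicates (>= 20).
#' @param settings refit settings ([fit_settings]); defaults to the
#'   settings stored in `fit`.
#' @param seed master seed.
#' @return The `fit` with `bootstrap_ci` filled in (data frame of
#'   parameter, lower, upper) and an `estimates_boot` matrix attached.
#' @export
parametric_bootstrap <- function(fit, B = 100, settings = NULL, seed = 1) {
  stopifnot(inherits(fit, "fit_result"))
  if (B < 20) stop("B must be at least 20 for percentile intervals")
  if (is.null(settings)) settings <- fit$settings
  obs <- fit$observed
  mod <- build_model(fit$model_id, fit$params)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1, B)
  fit_seeds <- sample.int(.Machine$integer.max - 1, B)
  est <- matrix(NA_real_, B, fit$k, dimnames = list(NULL, names(fit$estimates)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    boot_sfs <- simulate_sfs(mod, obs$n[1], obs$n[2],
                             n_sites = total_sites(obs), mu = fit$mu,
                             n_reps = settings$n_reps, seed = sim_seeds[b],
                             mode = "sampled", fold = obs$folded)
    rf <- tryCatch(
      fit_sfs(boot_sfs, fit$model_id, bounds = fit$bounds,
              settings = settings, seed = fit_seeds[b], mu = fit$mu),
      error = function(e) NULL)
    if (is.null(rf)) n_failed <- n_failed + 1L else est[b, ] <- rf$estimates
  }
  if (n_failed > 0.2 * B) {
    stop("parametric bootstrap failed: ", n_failed, " of ", B,
         " replicates could not be refitted")
  }
  ok <- complete.cases(est)
  ci <- data.frame(
    parameter = colnames(est),
    lower = apply(est[ok, , drop = FALSE], 2, quantile, 0.025),
    upper = apply(est[ok, , drop = FALSE], 2, quantile, 0.975),
    row.names = NULL)
  fit$bootstrap_ci <- ci
  fit$estimates_boot <- est[ok, , drop = FALSE]
  fit$bootstrap_failed <- n_failed
  fit
}
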