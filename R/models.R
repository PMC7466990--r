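#' Demographic parameters for the two-population divergence models
#'
#' Parameter container for the wild/domestic divergence histories. Time
#' is in generations backward from the present; population sizes are
#' diploid; migration rates are per-generation fractions, with the
#' convention that `m_xy` is the fraction of population *y* replaced by
#' migrants from *x* each generation, so the expected migrant count into
#' *y* is `N_y * m_xy`. The `1` rates apply between the split (`t1`) and
#' the migration-change time (`t2`); the `2` rates apply from `t2` to
#' the present.
#'
#' @param ancsize diploid effective size of the ancestral population.
#' @param t1 split time, generations before present.
#' @param n_wild,n_dom diploid effective sizes after the split.
#' @param m1_wd,m1_dw migration rates in the old epoch `[t2, t1)`.
#' @param m2_wd,m2_dw migration rates in the recent epoch `[0, t2)`.
#' @param t2 migration-change time, generations (`t2 <= t1`).
#' @param mu per-site per-generation mutation rate (default 1.38e-7, the
#'   pink-footed goose pedigree estimate used for geese).
#' @param generation_time generation time in years (default 3).
#' @return A `demographic_params` list.
#' @export
demographic_params <- function(ancsize, t1, n_wild, n_dom,
                               m1_wd = 0, m1_dw = 0,
                               m2_wd = m1_wd, m2_dw = m1_dw,
                               t2 = 0, mu = 1.38e-7, generation_time = 3) {
  p <- list(ancsize = ancsize, t1 = t1, n_wild = n_wild, n_dom = n_dom,
            m1_wd = m1_wd, m1_dw = m1_dw, m2_wd = m2_wd, m2_dw = m2_dw,
            t2 = t2, mu = mu, generation_time = generation_time)
  sizes <- c(p$ancsize, p$n_wild, p$n_dom)
  rates <- c(p$m1_wd, p$m1_dw, p$m2_wd, p$m2_dw)
  if (any(sizes < 1)) stop("population sizes must be >= 1")
  if (p$t1 < 0 || p$t2 < 0) stop("times must be >= 0")
  if (p$t2 > p$t1) stop("t2 must not exceed t1")
  if (any(rates < 0 | rates >= 1)) stop("migration rates must lie in [0, 1)")
  if (p$mu <= 0) stop("mu must be positive")
  class(p) <- "demographic_params"
  p
}

#' Table-of-record parameter set for the preferred goose model
#'
#' The maximum-likelihood estimates of the divergence-with-changing-gene-
#' flow history for graylag and European domestic geese: ancestral size
#' 1112, split 5319 generations ago, wild and domestic sizes 2504 and
#' 959, old-epoch migration 4.25e-4 (wild to domestic) and 5.35e-4
#' (domestic to wild), switching 159 generations ago to 1.72e-3 and
#' 6.69e-4.
#'
#' @return A `demographic_params`.
#' @export
goose_mle_params <- function() {
  demographic_params(ancsize = 1112, t1 = 5319, n_wild = 2504, n_dom = 959,
                     m1_wd = 4.25e-4, m1_dw = 5.35e-4,
                     m2_wd = 1.72e-3, m2_dw = 6.69e-4, t2 = 159)
}

.model_ids <- c(no_migration = "no_migration",
                constant_migration = "constant_migration",
                changing_migration = "changing_migration",
                panmictic = "panmictic",
                i = "no_migration", ii = "constant_migration",
                iii = "changing_migration")

#' Free parameters per model
#' @param model_id one of `"no_migration"` (i), `"constant_migration"`
#'   (ii), `"changing_migration"` (iii) or `"panmictic"`.
#' @return Character vector of free parameter names.
#' @export
free_params <- function(model_id) {
  model_id <- .canon_model(model_id)
  switch(model_id,
         panmictic = "ancsize",
         no_migration = c("ancsize", "t1", "n_wild", "n_dom"),
         constant_migration = c("ancsize", "t1", "n_wild", "n_dom",
                                "m1_wd", "m1_dw"),
         changing_migration = c("ancsize", "t1", "n_wild", "n_dom",
                                "m1_wd", "m1_dw", "t2", "m2_wd", "m2_dw"))
}

.canon_model <- function(model_id) {
  if (!model_id %in% names(.model_ids)) {
    stop("unknown model: ", model_id,
         " (use no_migration/i, constant_migration/ii, changing_migration/iii, panmictic)")
  }
  unname(.model_ids[[model_id]])
}

#' Build and validate a demographic model
#'
#' The three candidate histories of goose domestication: (i) simple
#' divergence with no gene flow, (ii) divergence with continuous gene
#' flow, and (iii) divergence with an epoch switch in the migration
#' rates at `t2`. A fourth convenience model, `"panmictic"`, is a single
#' population of size `ancsize` (used for calibration and oracle
#' checks). The canonical event list runs backward in time: present,
#' rate switch at `t2` (model iii), merge of the two demes into the
#' ancestor of size `ancsize` at `t1`.
#'
#' @param model_id `"no_migration"`/`"i"`, `"constant_migration"`/`"ii"`,
#'   `"changing_migration"`/`"iii"`, or `"panmictic"`.
#' @param params a [demographic_params]. For model i all migration rates
#'   must be zero; for model ii both epochs must carry the same rates
#'   (`t2` is unused and forced to 0); for `"panmictic"` `t1` must be 0.
#' @return A `demographic_model`.
#' @export
build_model <- function(model_id, params) {
  stopifnot(inherits(params, "demographic_params"))
  model_id <- .canon_model(model_id)
  p <- params
  rates <- c(p$m1_wd, p$m1_dw, p$m2_wd, p$m2_dw)
  if (model_id == "no_migration" && any(rates != 0)) {
    stop("model i (no_migration) requires all migration rates to be zero")
  }
  if (model_id == "constant_migration") {
    if (p$m2_wd != p$m1_wd || p$m2_dw != p$m1_dw) {
      stop("model ii (constant_migration) requires identical rates in both epochs")
    }
    p$t2 <- 0 # the switch time is meaningless when the rates are equal
  }
  if (model_id == "changing_migration" &&
      p$m2_wd == p$m1_wd && p$m2_dw == p$m1_dw) {
    # a switch between identical rate matrices is vacuous; dropping it
    # makes the nesting with the constant-migration model exact, down to
    # identical event lists and random-number streams
    p$t2 <- 0
  }
  if (model_id == "panmictic") {
    if (any(rates != 0)) stop("panmictic model has no migration")
    p$t1 <- 0; p$t2 <- 0
  }
  events <- list(
    list(time = 0, what = "sampling: wild and domestic demes",
         rates = c(wd = p$m2_wd, dw = p$m2_dw)),
    if (model_id == "changing_migration")
      list(time = p$t2, what = "migration-rate switch",
           rates = c(wd = p$m1_wd, dw = p$m1_dw)),
    list(time = p$t1, what = sprintf("demes merge into ancestor (2N = %g)",
                                     2 * p$ancsize)))
  events <- events[!vapply(events, is.null, logical(1))]
  structure(list(model_id = model_id, params = p,
                 k_free = length(free_params(model_id)), events = events),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model '%s' (%d free parameters)\n",
              x$model_id, x$k_free))
  p <- x$params
  cat(sprintf("  ANCSIZE %g, T1 %g, N_WILD %g, N_DOM %g, T2 %g\n",
              p$ancsize, p$t1, p$n_wild, p$n_dom, p$t2))
  cat(sprintf("  M1 (wd, dw) = (%g, %g); M2 = (%g, %g)\n",
              p$m1_wd, p$m1_dw, p$m2_wd, p$m2_dw))
  invisible(x)
}
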