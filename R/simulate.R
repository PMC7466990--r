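#' Simulate the joint SFS under a demographic model
#'
#' Runs the structured coalescent for the two-deme history (migration as
#' a per-lineage, per-generation deme switch backward in time; demes
#' merge into the ancestor at `t1`), accumulating expected branch lengths
#' per sample configuration, and converts them to a site-frequency
#' spectrum under the infinite-sites approximation: the expected density
#' of sites with configuration (i, j) is `mu` times the mean branch
#' length subtending i wild and j domestic copies.
#'
#' `mode = "expected"` returns the normalised expected spectrum scaled by
#' `n_sites` (real-valued cells); `mode = "sampled"` draws the site
#' counts multinomially around it, emulating a finite dataset.
#'
#' @param model a `demographic_model` from [build_model].
#' @param n_wild_chroms,n_dom_chroms sampled allele copies per deme
#'   (defaults 22 and 30, the goose analysis panel).
#' @param n_sites total callable sites represented by the spectrum.
#' @param mu per-site per-generation mutation rate; defaults to the rate
#'   stored in the model parameters.
#' @param n_reps number of coalescent genealogies (Monte-Carlo
#'   replicates).
#' @param seed RNG seed (optional; any R RNG state is used as-is when
#'   `NULL`).
#' @param mode `"expected"` or `"sampled"`.
#' @param fold fold the spectrum by pooled minor allele (default `TRUE`).
#' @return An `sfs2d`.
#' @export
simulate_sfs <- function(model, n_wild_chroms = 22, n_dom_chroms = 30,
                         n_sites, mu = model$params$mu, n_reps = 5000,
                         seed = NULL, mode = c("expected", "sampled"),
                         fold = TRUE) {
  stopifnot(inherits(model, "demographic_model"))
  mode <- match.arg(mode)
  if (n_sites <= 0) stop("n_sites must be positive")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- model$params
  L <- .coal_branch_config(as.integer(n_wild_chroms), as.integer(n_dom_chroms),
                           p$ancsize, p$t1, p$t2, p$n_wild, p$n_dom,
                           p$m1_wd, p$m1_dw, p$m2_wd, p$m2_dw,
                           as.integer(n_reps))
  p_poly <- mu * L
  tot <- sum(p_poly)
  if (tot >= 1) {
    stop("polymorphism probability per site exceeds 1; mu or the tree length is too large")
  }
  if (mode == "expected") {
    counts <- n_sites * p_poly
    mono <- n_sites * (1 - tot)
  } else {
    probs <- c(as.vector(p_poly), 1 - tot)
    draw <- rmultinom(1, size = n_sites, prob = probs)[, 1]
    mono <- draw[length(draw)]
    counts <- matrix(draw[-length(draw)], nrow = n_wild_chroms + 1L)
  }
  out <- sfs2d(counts, mono, c(n_wild_chroms, n_dom_chroms), folded = FALSE)
  if (fold) fold(out) else out
}
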