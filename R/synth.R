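#' Configuration for the synthetic genotype generator
#'
#' Describes a study-like dataset: three diverged source gene pools
#' (wild graylag, European domestic, Chinese domestic), populations of
#' 5-15 diploids drawn from them with population-level drift, optional
#' admixed populations formed as locus-wise frequency mixtures of two
#' source populations, i.i.d. per-genotype missingness, and roughly
#' 10^4 polymorphic loci over 10^6 callable sites. Cluster frequencies
#' come either from a Balding-Nichols hierarchy (fast; the default) or
#' from the two-deme structured coalescent (`method = "coalescent"`,
#' wild and European pools only, with the Chinese pool layered on by
#' Balding-Nichols drift).
#'
#' The defaults emulate the goose study design: four wild populations
#' and four European breeds of about ten diploids each, one Chinese
#' population, and one admixed European breed (a 50:50
#' European-Chinese mixture); cluster drift is mild for wild geese
#' (F = 0.08), stronger for European domestics (F = 0.18, the
#' domestication bottleneck) and strongest for the Chinese pool
#' (F = 0.55, a different source species), with extra breed-formation
#' drift within European breeds.
#'
#' @param populations data frame with columns `population`, `group`,
#'   `n` (diploids), and optionally `alpha`, `src1`, `src2` describing
#'   admixture (`alpha` in `[0,1]`, `NA` for unadmixed populations).
#' @param n_loci number of candidate polymorphic loci.
#' @param total_sites callable sites represented by the dataset.
#' @param missing_rate i.i.d. per-genotype missing probability
#'   (in `[0, 0.5]`).
#' @param method `"balding_nichols"` or `"coalescent"`.
#' @param scenario a [demographic_params] for the coalescent method.
#' @param f_cluster named drift coefficients per group.
#' @param f_pop named within-cluster drift per group.
#' @param seed RNG seed; all generation is seed-deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(populations = NULL,
                         n_loci = 10000, total_sites = 1e6,
                         missing_rate = 0.05,
                         method = c("balding_nichols", "coalescent"),
                         scenario = NULL,
                         f_cluster = c(wild = 0.08, domestic_european = 0.18,
                                       domestic_chinese = 0.55),
                         f_pop = c(wild = 0.03, domestic_european = 0.12,
                                   domestic_chinese = 0.05),
                         seed = 1) {
  method <- match.arg(method)
  if (is.null(populations)) {
    populations <- data.frame(
      population = c("wild_finland", "wild_norway", "wild_netherlands",
                     "wild_kazakhstan", "dom_embden", "dom_toulouse",
                     "dom_landes", "dom_turkey", "dom_chinese", "dom_african"),
      group = c(rep("wild", 4), rep("domestic_european", 4),
                "domestic_chinese", "domestic_european"),
      n = c(10, 10, 10, 10, 9, 9, 9, 9, 8, 8),
      alpha = c(rep(NA, 9), 0.5),
      src1 = c(rep(NA, 9), "dom_landes"),
      src2 = c(rep(NA, 9), "dom_chinese"),
      stringsAsFactors = FALSE)
  }
  if (is.null(populations$alpha)) populations$alpha <- NA_real_
  if (is.null(populations$src1)) populations$src1 <- NA_character_
  if (is.null(populations$src2)) populations$src2 <- NA_character_
  if (any(populations$n < 1)) stop("sample sizes must be >= 1")
  if (missing_rate < 0 || missing_rate > 0.5) stop("missing_rate must be in [0, 0.5]")
  adm <- !is.na(populations$alpha)
  if (any(populations$alpha[adm] < 0 | populations$alpha[adm] > 1)) {
    stop("admixture proportions must lie in [0, 1]")
  }
  bad_src <- adm & (!(populations$src1 %in% populations$population) |
                    !(populations$src2 %in% populations$population))
  if (any(bad_src)) stop("admixture sources must name other configured populations")
  if (method == "coalescent" && is.null(scenario)) scenario <- goose_mle_params()
  structure(list(populations = populations, n_loci = n_loci,
                 total_sites = total_sites, missing_rate = missing_rate,
                 method = method, scenario = scenario,
                 f_cluster = f_cluster, f_pop = f_pop, seed = seed),
            class = "synth_config")
}

# Balding-Nichols draw: frequency around p with drift coefficient F
.bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), a, b)
}

#' Generate a synthetic genotype dataset with known ground truth
#'
#' Draws cluster pool frequencies, per-population frequencies (admixed
#' populations as `alpha * p_src1 + (1 - alpha) * p_src2` locus-wise),
#' genotypes as `Binomial(2, p)`, and i.i.d. missingness. Outputs are
#' deterministic given the config seed. When `dir` is given, a VCF, a
#' population-map TSV and a ground-truth JSON are written there.
#'
#' @param config a [synth_config].
#' @param dir optional output directory.
#' @return List with `gm` ([genotype_matrix]), `popmap`
#'   ([population_map]), `truth` (cluster and population frequencies,
#'   admixture proportions, config echo) and, when written, `paths`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  pops <- config$populations
  L <- config$n_loci
  groups <- unique(pops$group)

  if (config$method == "balding_nichols") {
    p_anc <- runif(L, 0.05, 0.95)
    pool <- sapply(groups, function(g)
      .bn_draw(p_anc, config$f_cluster[[g]]))
  } else {
    sc <- config$scenario
    mod <- build_model("changing_migration", sc)
    n_pool <- 100L
    Lmat <- .coal_branch_config(n_pool, n_pool, sc$ancsize, sc$t1, sc$t2,
                                sc$n_wild, sc$n_dom,
                                sc$m1_wd, sc$m1_dw, sc$m2_wd, sc$m2_dw, 2000L)
    pr <- as.vector(Lmat); pr[1] <- 0
    cells <- sample.int(length(pr), L, replace = TRUE, prob = pr)
    ci <- (cells - 1) %% (n_pool + 1)
    cj <- (cells - 1) %/% (n_pool + 1)
    p_anc <- (ci + cj) / (2 * n_pool)
    pool <- cbind(ci / n_pool, cj / n_pool)
    colnames(pool) <- c("wild", "domestic_european")
    extra <- setdiff(groups, colnames(pool))
    for (g in extra) {
      pool <- cbind(pool, .bn_draw(pmin(pmax(p_anc, 0.01), 0.99),
                                   config$f_cluster[[g]]))
      colnames(pool)[ncol(pool)] <- g
    }
    pool <- pool[, groups, drop = FALSE]
  }
  colnames(pool) <- groups

  adm <- !is.na(pops$alpha)
  p_pop <- matrix(NA_real_, L, nrow(pops), dimnames = list(NULL, pops$population))
  for (k in which(!adm)) {
    p_pop[, k] <- .bn_draw(pool[, pops$group[k]], config$f_pop[[pops$group[k]]])
  }
  for (k in which(adm)) {
    p_pop[, k] <- pops$alpha[k] * p_pop[, pops$src1[k]] +
      (1 - pops$alpha[k]) * p_pop[, pops$src2[k]]
  }

  n_ind <- sum(pops$n)
  ind_pop <- rep(pops$population, pops$n)
  individuals <- paste0(ind_pop, "_", unlist(lapply(pops$n, seq_len)))
  dos <- matrix(NA_integer_, L, n_ind)
  for (k in seq_len(nrow(pops))) {
    cols <- which(ind_pop == pops$population[k])
    dos[, cols] <- rbinom(L * length(cols), 2, p_pop[, k])
  }
  if (config$missing_rate > 0) {
    dos[runif(length(dos)) < config$missing_rate] <- NA_integer_
  }

  loci <- data.frame(chrom = "1", pos = seq_len(L) * 100L,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, loci, individuals)
  popmap <- population_map(data.frame(
    individual = individuals,
    population = ind_pop,
    group = pops$group[match(ind_pop, pops$population)],
    purity = !ind_pop %in% pops$population[adm],
    stringsAsFactors = FALSE))
  truth <- list(seed = config$seed, method = config$method,
                n_loci = L, total_sites = config$total_sites,
                missing_rate = config$missing_rate,
                pool_frequencies = pool, population_frequencies = p_pop,
                admixture = pops[adm, c("population", "alpha", "src1", "src2")])

  out <- list(gm = gm, popmap = popmap, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "synthetic.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_vcf(gm, paths$vcf)
    write_popmap(popmap, paths$popmap)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Deterministic miniature dataset with planted expectations
#'
#' A 12-individual, 60-locus dataset over four populations (one wild,
#' one European domestic, one Chinese domestic, and one admixed
#' 50:50 European-Chinese breed) built under a fixed internal seed.
#' Four defective loci are planted for exercising the site filters: one
#' indel, one triallelic locus, one invariant locus, and one locus with
#' nearly all individuals heterozygous (observed heterozygosity 11/12).
#' The returned `expected` list records the planted truths every
#' pipeline stage should recover.
#'
#' @param dir optional output directory (VCF + popmap + truth JSON).
#' @return As [generate_dataset], plus `expected`.
#' @export
generate_worked_toy <- function(dir = NULL) {
  pops <- data.frame(
    population = c("wild_a", "euro_b", "chinese_c", "admixed_d"),
    group = c("wild", "domestic_european", "domestic_chinese",
              "domestic_european"),
    n = c(3, 3, 3, 3),
    alpha = c(NA, NA, NA, 0.5),
    src1 = c(NA, NA, NA, "euro_b"),
    src2 = c(NA, NA, NA, "chinese_c"),
    stringsAsFactors = FALSE)
  cfg <- synth_config(populations = pops, n_loci = 160, total_sites = 5000,
                      missing_rate = 0, seed = 20200701)
  base <- generate_dataset(cfg)
  # keep the first 56 candidate loci that are clean in the realised sample
  # (polymorphic, observed heterozygosity within bounds), so the planted
  # defects below are the only loci the site filters may remove
  d <- base$gm$dosages
  freq <- rowMeans(d) / 2
  het <- rowMeans(d == 1L)
  clean <- which(freq > 0 & freq < 1 & het <= 0.75)[1:56]
  gm <- gm_subset(base$gm, loci = clean)
  gm$loci$pos <- seq_len(56) * 100L
  base$truth$population_frequencies <-
    base$truth$population_frequencies[clean, , drop = FALSE]
  base$truth$pool_frequencies <- base$truth$pool_frequencies[clean, , drop = FALSE]
  base$truth$n_loci <- 56L

  # planted defective loci appended at the end, positions continuing on
  planted <- data.frame(
    chrom = "1", pos = c(6001L, 6002L, 6003L, 6004L),
    ref = c("AT", "A", "A", "A"),
    alt = c("A", "C,G", "C", "C"),
    stringsAsFactors = FALSE)
  dos_planted <- rbind(
    rep(1L, 12),                     # indel: dosages irrelevant
    rep(1L, 12),                     # triallelic
    rep(0L, 12),                     # invariant (all reference)
    c(rep(1L, 11), 0L))              # heterozygosity 11/12 > 0.75
  dosages <- rbind(gm$dosages, dos_planted)
  loci <- rbind(gm$loci[, c("chrom", "pos", "ref", "alt")], planted)
  gm <- genotype_matrix(dosages, loci, gm$individuals)

  expected <- list(
    n_loci = 60L, n_individuals = 12L,
    filter_removed = c(indel = 1L, multiallelic = 1L, invariant = 1L,
                       heterozygosity = 1L),
    admixed_population = "admixed_d",
    admixed_sources = c("euro_b", "chinese_c"),
    alpha = 0.5)

  out <- list(gm = gm, popmap = base$popmap, truth = base$truth,
              expected = expected)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "worked_toy.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_vcf(gm, paths$vcf)
    write_popmap(out$popmap, paths$popmap)
    jsonlite::write_json(out$truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
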