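#' Run the analysis pipeline end-to-end
#'
#' Orchestrates the stages over one genotype dataset with a single
#' configuration and one master seed: site and individual filtering,
#' diversity (expected heterozygosity and the wild-vs-domestic Welch
#' test), pairwise F_ST, AMOVA, PCA, the neighbor-joining tree, f3
#' tests, observed-SFS construction, and optionally demographic model
#' fitting, model selection and parametric bootstrap. Each stage writes
#' its output under `out_dir`; a manifest records package version,
#' seeds, parameters, input checksums and per-stage output checksums,
#' so a rerun with the same config and seed reproduces identical
#' checksums. Any stage failure stops the run with prior outputs (and
#' the manifest up to that stage) preserved on disk.
#'
#' @param config a list, or path to a JSON file, with fields:
#'   `vcf` (input path), `popmap` (input path), `out_dir`, `seed`,
#'   optional `stages` (subset of filter, diversity, fst, amova, pca,
#'   njtree, f3, sfs, fit, model_select, bootstrap; default runs
#'   everything up to `sfs`), `profile` (`"desk"`/`"paper"`),
#'   `overrides` (per-stage parameter lists, e.g.
#'   `list(amova = list(n_perm = 200))`), `f3_triples` (data frame or
#'   TSV path of target/source_a/source_b), and for the `sfs`/`fit`
#'   stages `sfs_wild`, `sfs_dom` (individual identifiers) and
#'   `total_sites`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (f in c("vcf", "popmap", "out_dir", "seed")) {
    if (is.null(config[[f]])) stop("pipeline config is missing field: ", f)
  }
  if (!file.exists(config$vcf)) stop("input VCF does not exist: ", config$vcf)
  if (!file.exists(config$popmap)) stop("population map does not exist: ", config$popmap)
  all_stages <- c("filter", "diversity", "fst", "amova", "pca", "njtree",
                  "f3", "sfs", "fit", "model_select", "bootstrap")
  stages <- if (is.null(config$stages)) {
    c("filter", "diversity", "fst", "amova", "pca", "njtree", "f3", "sfs")
  } else unlist(config$stages)
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  ov <- function(stage, name, default) {
    v <- config$overrides[[stage]][[name]]
    if (is.null(v)) default else v
  }
  profile <- if (is.null(config$profile)) "desk" else config$profile

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # one master seed, one named substream per stage
  set.seed(config$seed)
  sub_seed <- setNames(sample.int(.Machine$integer.max - 1, length(all_stages)),
                       all_stages)

  manifest <- list(package = "goosepop",
                   version = as.character(utils::packageVersion("goosepop")),
                   seed = config$seed, profile = profile, stages = stages,
                   inputs = list(vcf = unname(tools::md5sum(config$vcf)),
                                 popmap = unname(tools::md5sum(config$popmap))),
                   completed = character(0), outputs = list())
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  record <- function(stage, paths) {
    manifest$completed <<- c(manifest$completed, stage)
    manifest$outputs[[stage]] <<- lapply(paths, function(p) unname(tools::md5sum(p)))
    save_manifest()
  }
  outp <- function(...) file.path(config$out_dir, ...)

  gm <- read_vcf(config$vcf)
  popmap <- read_popmap(config$popmap)
  fits <- list()
  obs_sfs <- NULL

  for (stage in all_stages) {
    if (!stage %in% stages) next
    t0 <- Sys.time()
    switch(stage,
      filter = {
        fs <- apply_site_filters(gm,
                keep_cross_species_divergent = ov("filter", "keep_divergent_invariant", FALSE),
                max_het = ov("filter", "max_het", 0.75))
        fi <- apply_individual_filter(fs$gm,
                max_missing = ov("filter", "max_missing", 0.20))
        gm <- fi$gm
        write_vcf(gm, outp("filtered.vcf"))
        jsonlite::write_json(
          list(site = list(removed = as.list(fs$report$removed),
                           input_loci = fs$report$input_loci,
                           output_loci = fs$report$output_loci),
               individual = fi$report[c("input_individuals", "output_individuals",
                                        "removed_individuals")]),
          outp("filter_report.json"), auto_unbox = TRUE, digits = NA)
        record(stage, list(outp("filtered.vcf"), outp("filter_report.json")))
      },
      diversity = {
        het <- expected_heterozygosity(gm, popmap)
        write.csv(data.frame(population = names(het$means),
                             mean_HE = het$means, n_loci = het$n_defined,
                             row.names = NULL),
                  outp("diversity.csv"), row.names = FALSE)
        grp <- popmap$group[match(names(het$means), popmap$population)]
        welch <- NULL
        if (sum(grp == "wild") >= 2 && sum(grp == "domestic_european") >= 2) {
          welch <- welch_t_test(het$means[grp == "wild"],
                                het$means[grp == "domestic_european"])
          jsonlite::write_json(unclass(welch), outp("welch.json"),
                               auto_unbox = TRUE, digits = NA)
        }
        record(stage, c(list(outp("diversity.csv")),
                        if (!is.null(welch)) list(outp("welch.json"))))
      },
      fst = {
        fm <- pairwise_fst(gm, popmap)
        write.csv(fm$fst, outp("fst.csv"))
        record(stage, list(outp("fst.csv")))
      },
      amova = {
        am <- amova(gm, popmap, n_perm = ov("amova", "n_perm", 16000),
                    seed = sub_seed[["amova"]])
        jsonlite::write_json(list(table = am$table, indices = am$indices,
                                  p_values = as.list(am$p_values),
                                  n_perm = am$n_perm),
                             outp("amova.json"), auto_unbox = TRUE, digits = NA)
        record(stage, list(outp("amova.json")))
      },
      pca = {
        pc <- pca(gm, alpha = ov("pca", "alpha", 0.05))
        write.csv(data.frame(individual = rownames(pc$scores),
                             pc$scores[, seq_len(min(10, ncol(pc$scores)))],
                             row.names = NULL),
                  outp("pca_scores.csv"), row.names = FALSE)
        jsonlite::write_json(list(n_significant = pc$n_significant,
                                  eigenvalues = pc$eigenvalues,
                                  p_values = pc$p_values),
                             outp("pca.json"), auto_unbox = TRUE, digits = NA)
        record(stage, list(outp("pca_scores.csv"), outp("pca.json")))
      },
      njtree = {
        dm <- pairwise_distance(gm)
        write_phylip(dm, outp("distances.phy"))
        as_newick(nj_tree(dm), outp("tree.nwk"))
        record(stage, list(outp("distances.phy"), outp("tree.nwk")))
      },
      f3 = {
        triples <- config$f3_triples
        if (is.character(triples)) {
          triples <- utils::read.table(triples, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
        }
        if (is.null(triples)) {
          # default: test every admixture-flagged or non-pure population
          # is skipped; without triples the stage only writes an empty table
          triples <- data.frame(target = character(0), source_a = character(0),
                                source_b = character(0))
        }
        res <- if (nrow(triples) > 0) {
          f3_batch(gm, triples, popmap,
                   block_size = ov("f3", "block_size", 500))
        } else {
          data.frame(target = character(0), source_a = character(0),
                     source_b = character(0), f3 = numeric(0), se = numeric(0),
                     z = numeric(0), n_loci = integer(0), n_blocks = integer(0))
        }
        write.csv(res, outp("f3.csv"), row.names = FALSE)
        record(stage, list(outp("f3.csv")))
      },
      sfs = {
        if (is.null(config$sfs_wild) || is.null(config$sfs_dom) ||
            is.null(config$total_sites)) {
          stop("sfs stage needs config fields sfs_wild, sfs_dom, total_sites")
        }
        obs_sfs <- sfs_from_genotypes(gm, unlist(config$sfs_wild),
                                      unlist(config$sfs_dom),
                                      config$total_sites)
        write_sfs_json(obs_sfs, outp("observed_sfs.json"))
        write_sfs_obs(obs_sfs, outp("observed_sfs.obs"))
        record(stage, list(outp("observed_sfs.json"), outp("observed_sfs.obs")))
      },
      fit = {
        if (is.null(obs_sfs)) obs_sfs <- read_sfs_json(outp("observed_sfs.json"))
        st <- fit_settings(profile,
                           n_reps = ov("fit", "n_reps", fit_settings(profile)$n_reps),
                           n_cycles = ov("fit", "n_cycles", fit_settings(profile)$n_cycles),
                           n_restarts = ov("fit", "n_restarts", fit_settings(profile)$n_restarts))
        models <- ov("fit", "models", c("no_migration", "constant_migration",
                                        "changing_migration"))
        fits <- lapply(models, function(m)
          fit_sfs(obs_sfs, m, settings = st, seed = sub_seed[["fit"]]))
        names(fits) <- models
        jsonlite::write_json(
          lapply(fits, function(f) list(model = f$model_id,
                                        estimates = as.list(f$estimates),
                                        lnCL = f$lnCL, AIC = f$AIC, k = f$k)),
          outp("fits.json"), auto_unbox = TRUE, digits = NA)
        record(stage, list(outp("fits.json")))
      },
      model_select = {
        if (length(fits) < 2) stop("model_select needs at least two fitted models")
        aw <- akaike_weights(fits)
        write.csv(aw, outp("model_select.csv"), row.names = FALSE)
        record(stage, list(outp("model_select.csv")))
      },
      bootstrap = {
        if (length(fits) == 0) stop("bootstrap needs a fitted model")
        aw <- akaike_weights(fits)
        best <- fits[[aw$model[1]]]
        bs <- parametric_bootstrap(best, B = ov("bootstrap", "B", 100),
                                   settings = fit_settings(profile,
                                     n_restarts = ov("bootstrap", "n_restarts", 5)),
                                   seed = sub_seed[["bootstrap"]])
        jsonlite::write_json(list(model = bs$model_id, ci = bs$bootstrap_ci,
                                  n_failed = bs$bootstrap_failed),
                             outp("bootstrap.json"), auto_unbox = TRUE, digits = NA)
        record(stage, list(outp("bootstrap.json")))
      })
    message(sprintf("[goosepop] stage %-12s done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  save_manifest()
  invisible(manifest)
}
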