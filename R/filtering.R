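#' Site-level variant filters
#'
#' Reproduces the post-calling locus filters used for GBS goose data, in a
#' fixed order so that per-rule removal counts are deterministic:
#' indels first, then loci with more than two alleles, then loci invariant
#' within the dataset, then loci whose observed heterozygosity (fraction
#' of heterozygous calls among non-missing genotypes) exceeds `max_het`
#' (potential paralogs). Each removed locus is attributed to exactly one
#' rule. Thresholds are strict: a locus is removed only when its observed
#' heterozygosity is strictly greater than `max_het`.
#'
#' "Invariant" means no allele-level variation among non-missing
#' genotypes: the alternate-allele frequency is 0 or 1 (loci with no
#' non-missing call at all count as invariant). With
#' `keep_cross_species_divergent = TRUE`, invariant loci fixed for the
#' alternate allele (i.e. divergent from the mapping reference) are
#' retained, as done for datasets feeding cross-species phylogenetics.
#'
#' @param gm a [genotype_matrix].
#' @param keep_cross_species_divergent keep within-dataset-invariant loci
#'   whose fixed allele differs from the reference.
#' @param max_het observed-heterozygosity ceiling (default 0.75).
#' @return A list with elements `gm` (the filtered matrix) and `report`
#'   (a `filter_report`).
#' @export
apply_site_filters <- function(gm, keep_cross_species_divergent = FALSE,
                               max_het = 0.75) {
  d <- gm$dosages
  n_in <- n_loci(gm)
  rule <- rep(NA_character_, n_in)

  is_indel <- gm$loci$is_indel
  rule[is_indel] <- "indel"

  n_alt <- lengths(strsplit(gm$loci$alt, ",", fixed = TRUE))
  multi <- is.na(rule) & n_alt > 1L
  rule[multi] <- "multiallelic"

  called <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  freq <- ifelse(called > 0, alt / (2 * called), NA_real_)
  invariant <- is.na(freq) | freq == 0 | freq == 1
  keep_div <- if (keep_cross_species_divergent) {
    !is.na(freq) & freq == 1
  } else rep(FALSE, n_in)
  inv_rm <- is.na(rule) & invariant & !keep_div
  rule[inv_rm] <- "invariant"

  het <- ifelse(called > 0, rowSums(d == 1L, na.rm = TRUE) / called, 0)
  het_rm <- is.na(rule) & !invariant & het > max_het
  rule[het_rm] <- "heterozygosity"

  keep <- is.na(rule)
  report <- filter_report(
    removed = c(indel = sum(rule == "indel", na.rm = TRUE),
                multiallelic = sum(rule == "multiallelic", na.rm = TRUE),
                invariant = sum(rule == "invariant", na.rm = TRUE),
                heterozygosity = sum(rule == "heterozygosity", na.rm = TRUE),
                individual_missingness = 0L),
    input_loci = n_in, output_loci = sum(keep),
    input_individuals = n_individuals(gm),
    output_individuals = n_individuals(gm))
  list(gm = gm_subset(gm, loci = keep), report = report)
}

#' Individual-level missingness filter
#'
#' Drops individuals whose fraction of missing genotypes strictly exceeds
#' `max_missing`; loci are untouched.
#'
#' @param gm a [genotype_matrix].
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @return A list with elements `gm` and `report` (a `filter_report`
#'   whose `removed_individuals` names the dropped samples).
#' @export
apply_individual_filter <- function(gm, max_missing = 0.20) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(gm$dosages))
  if (n_loci(gm) == 0) frac <- rep(0, n_individuals(gm))
  drop <- frac > max_missing
  report <- filter_report(
    removed = c(indel = 0L, multiallelic = 0L, invariant = 0L,
                heterozygosity = 0L, individual_missingness = 0L),
    input_loci = n_loci(gm), output_loci = n_loci(gm),
    input_individuals = n_individuals(gm),
    output_individuals = sum(!drop))
  report$removed_individuals <- gm$individuals[drop]
  list(gm = gm_subset(gm, individuals = !drop), report = report)
}

filter_report <- function(removed, input_loci, output_loci,
                          input_individuals, output_individuals) {
  if (input_loci - sum(removed) != output_loci) {
    stop("filter accounting error: input - removed != output")
  }
  structure(list(removed = removed,
                 input_loci = input_loci, output_loci = output_loci,
                 input_individuals = input_individuals,
                 output_individuals = output_individuals),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d -> %d loci, %d -> %d individuals\n",
              x$input_loci, x$output_loci,
              x$input_individuals, x$output_individuals))
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Monomorphic-site accounting for the SFS denominator
#'
#' Derives the total number of callable sites backing a site-frequency
#' spectrum from the number of base pairs covered by GBS tags, mimicking
#' the accounting used with the goose data: sites removed as indels,
#' multi-allelic or heterozygosity-excess loci are subtracted as absolute
#' counts, and the remainder is scaled down by the same proportion as
#' SNPs lost to the complete-data requirement of the SFS
#' (`kept_snps / report$output_loci`). The polymorphic class is
#' `kept_snps`; the monomorphic class is the rest.
#'
#' @param report a `filter_report` from [apply_site_filters].
#' @param covered_bp total base pairs covered by sequencing tags.
#' @param kept_snps number of SNPs actually entering the SFS (complete
#'   data over the analysis individuals).
#' @return A `site_accounts` object with fields `total`, `monomorphic`,
#'   `polymorphic`.
#' @export
site_accounting <- function(report, covered_bp, kept_snps) {
  stopifnot(inherits(report, "filter_report"))
  if (covered_bp < report$input_loci) {
    stop("covered_bp must be at least the number of input loci")
  }
  absolute <- sum(report$removed[c("indel", "multiallelic", "heterozygosity")])
  remaining <- covered_bp - absolute
  if (remaining < 0) stop("accounting error: negative site count after absolute removals")
  if (report$output_loci <= 0) stop("accounting error: no loci left after filtering")
  prop <- kept_snps / report$output_loci
  if (prop < 0 || prop > 1) stop("kept_snps must be between 0 and output_loci")
  total <- round(remaining * prop)
  if (total < kept_snps) stop("accounting error: fewer total sites than SNPs")
  structure(list(total = total, monomorphic = total - kept_snps,
                 polymorphic = kept_snps),
            class = "site_accounts")
}

#' @export
print.site_accounts <- function(x, ...) {
  cat(sprintf("site_accounts: %d sites = %d monomorphic + %d polymorphic\n",
              x$total, x$monomorphic, x$polymorphic))
  invisible(x)
}
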