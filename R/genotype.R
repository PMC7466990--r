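#' Construct a genotype matrix
#'
#' The central genotype container: a loci x individuals matrix of diploid
#' alternate-allele dosages (0, 1, 2, or `NA` for missing) plus per-locus
#' metadata. Positions are 1-based, as in VCF; phase is never tracked and
#' alleles are taken as written (never strand-complemented).
#'
#' @param dosages integer matrix, loci in rows, individuals in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param loci data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated string for multi-allelic records) and optionally
#'   `is_indel`; one row per row of `dosages`.
#' @param individuals character vector of unique sample identifiers, one
#'   per column of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, loci, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!all(is.na(dosages) | dosages %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(individuals)) stop("individual identifiers must be unique")
  if (length(individuals) != ncol(dosages)) {
    stop("length(individuals) must equal ncol(dosages)")
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns chrom, pos, ref, alt")
  }
  if (nrow(loci) != nrow(dosages)) stop("nrow(loci) must equal nrow(dosages)")
  if (is.null(loci$is_indel)) {
    loci$is_indel <- .locus_is_indel(loci$ref, loci$alt)
  }
  if (anyDuplicated(paste(loci$chrom, loci$pos))) {
    stop("locus positions must be unique per (chromosome, position)")
  }
  colnames(dosages) <- individuals
  rownames(dosages) <- NULL
  structure(
    list(dosages = dosages, loci = loci, individuals = as.character(individuals),
         ploidy = 2L),
    class = "genotype_matrix"
  )
}

.locus_is_indel <- function(ref, alt) {
  snp_allele <- function(a) nchar(a) == 1L & a %in% c("A", "C", "G", "T")
  alt_ok <- vapply(strsplit(alt, ",", fixed = TRUE), function(v) {
    length(v) > 0 && all(snp_allele(v))
  }, logical(1))
  !(snp_allele(ref) & alt_ok)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals (%.1f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Number of loci / individuals in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count.
#' @export
n_loci <- function(gm) nrow(gm$dosages)

#' @rdname n_loci
#' @export
n_individuals <- function(gm) ncol(gm$dosages)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param loci logical or integer index over loci (rows); `NULL` keeps all.
#' @param individuals logical/integer index or character names over
#'   individuals; `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, loci = NULL, individuals = NULL) {
  if (is.null(loci)) loci <- seq_len(n_loci(gm))
  if (is.null(individuals)) individuals <- seq_len(n_individuals(gm))
  if (is.character(individuals)) {
    individuals <- match(individuals, gm$individuals)
    if (anyNA(individuals)) stop("unknown individual identifier")
  }
  genotype_matrix(gm$dosages[loci, individuals, drop = FALSE],
                  gm$loci[loci, , drop = FALSE],
                  gm$individuals[individuals])
}

#' Read a population map
#'
#' A population map assigns each individual to a population and each
#' population to one of the three study groups: `wild`,
#' `domestic_european` or `domestic_chinese`. The file format is
#' tab-separated with a header and columns
#' `individual`, `population`, `group`, optionally followed by `purity`
#' (logical; `TRUE` for populations regarded as pure, i.e. with < 10%
#' admixture from the other gene pool).
#'
#' @param path path to the TSV file.
#' @return A data frame of class `population_map`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  population_map(df)
}

#' Construct / validate a population map
#'
#' @param df data frame with columns `individual`, `population`, `group`
#'   and optionally `purity`.
#' @return The validated data frame with class `population_map`.
#' @export
population_map <- function(df) {
  need <- c("individual", "population", "group")
  if (!all(need %in% names(df))) {
    stop("population map needs columns individual, population, group")
  }
  if (anyDuplicated(df$individual)) stop("duplicated individual in population map")
  ok_groups <- c("wild", "domestic_european", "domestic_chinese")
  if (!all(df$group %in% ok_groups)) {
    stop("group must be one of: ", paste(ok_groups, collapse = ", "))
  }
  # groups must partition populations
  gp <- unique(df[, c("population", "group")])
  if (anyDuplicated(gp$population)) {
    stop("a population is assigned to more than one group")
  }
  if (is.null(df$purity)) df$purity <- NA
  class(df) <- c("population_map", "data.frame")
  df
}

#' Write a population map to TSV
#' @param popmap a `population_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(as.data.frame(popmap)[, c("individual", "population", "group")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pop_individuals <- function(popmap, pop) {
  ind <- popmap$individual[popmap$population == pop]
  if (length(ind) == 0) stop("unknown population: ", pop)
  ind
}

.check_popmap_covers <- function(gm, popmap) {
  missing <- setdiff(gm$individuals, popmap$individual)
  if (length(missing) > 0) {
    stop("individuals without a population assignment: ",
         paste(head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Per-locus alternate-allele frequency within one population
#'
#' Frequencies are computed over non-missing genotypes only; the allele
#' count reported is twice the number of non-missing diploid genotypes.
#' Loci with no non-missing call in the population are flagged
#' (`no_calls = TRUE`) and get `NA` frequency.
#'
#' @param gm a `genotype_matrix`.
#' @param pop population label present in `popmap`.
#' @param popmap a `population_map` covering the individuals of `gm`.
#' @return Data frame with columns `chrom`, `pos`, `freq`, `n_alleles`,
#'   `no_calls`.
#' @export
allele_frequency <- function(gm, pop, popmap) {
  popmap <- population_map(as.data.frame(popmap))
  ind <- intersect(.pop_individuals(popmap, pop), gm$individuals)
  if (length(ind) == 0) stop("population ", pop, " has no individuals in the matrix")
  d <- gm$dosages[, ind, drop = FALSE]
  called <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
             freq = ifelse(called > 0, alt / (2 * called), NA_real_),
             n_alleles = 2L * called,
             no_calls = called == 0L)
}

# internal: frequency and allele-count vectors for a set of individuals
.freq_counts <- function(gm, ind) {
  d <- gm$dosages[, ind, drop = FALSE]
  called <- rowSums(!is.na(d))
  list(freq = ifelse(called > 0, rowSums(d, na.rm = TRUE) / (2 * called), NA_real_),
       n = 2L * called)
}
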