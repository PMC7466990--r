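#' Read genotypes from a VCF file
#'
#' Parses a VCF (4.x) with GT fields into a [genotype_matrix]. Only the
#' genotype call is used; phase is ignored (`0/1` and `0|1` are the same
#' dosage) and half-calls such as `./1` are treated as missing.
#' Multi-allelic records are retained with all alternate alleles listed;
#' their dosage is the count of non-reference alleles. Filtering to
#' biallelic SNPs is a separate, downstream step ([apply_site_filters]).
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)
  samples <- samples[samples != "FORMAT"]
  n_rec <- nrow(vcf@gt)
  if (is.null(n_rec) || n_rec == 0) {
    return(genotype_matrix(
      matrix(integer(0), nrow = 0, ncol = length(samples)),
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      samples))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec)
  n_header <- length(vcf@meta) + 1L # meta lines plus the #CHROM line
  dos <- .gt_to_dosage(gt, n_header)
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, loci, samples)
}

# Convert a matrix of GT strings to dosages. `n_header` lets error
# messages name the 1-based file line of the offending record.
.gt_to_dosage <- function(gt, n_header = 0L) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L) return(NA_integer_) # haploid or malformed arity
    if (any(al == ".")) return(NA_integer_)   # half-calls are missing
    if (!all(grepl("^[0-9]+$", al))) return(-1L) # malformed token
    sum(al != "0")
  }, integer(1))
  first_record <- function(values) {
    hit <- matrix(as.vector(gt) %in% values, nrow = nrow(gt))
    which(hit, arr.ind = TRUE)[1, 1]
  }
  bad <- u[!is.na(map) & map == -1L]
  if (length(bad) > 0) {
    stop(sprintf("malformed GT field '%s' at line %d", bad[[1]],
                 n_header + first_record(bad)), call. = FALSE)
  }
  malformed_arity <- u[is.na(map) & !grepl("\\.", u)]
  if (length(malformed_arity) > 0) {
    stop(sprintf("expected diploid GT, got '%s' at line %d",
                 malformed_arity[[1]], n_header + first_record(malformed_arity)),
         call. = FALSE)
  }
  dos <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dos[dos > 2L] <- 2L # cannot happen for diploids, kept as a guard
  dos
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits a GT-only VCF: missing dosages become `./.`, dosage 1 is written
#' `0/1` and dosage 2 `1/1` (for multi-allelic loci the first alternate
#' allele is used, so writing is lossless only for the dosage encoding,
#' which is all the package stores).
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=goosepop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t")
  ), con)
  if (n_loci(gm) > 0) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix(code[gm$dosages + 1L], nrow = n_loci(gm))
    gt[is.na(gm$dosages)] <- "./."
    lines <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                   ".", ".", ".", "GT", sep = "\t")
    body <- apply(gt, 1L, paste, collapse = "\t")
    writeLines(paste(lines, body, sep = "\t"), con)
  }
  invisible(path)
}
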