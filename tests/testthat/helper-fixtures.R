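# Shared fixture builders: tiny genotype matrices and population maps
# constructed in code, never stored on disk.

make_gm <- function(dosages, chrom = "1", pos = NULL, ref = "A", alt = "C",
                    individuals = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(pos)) pos <- seq_len(nrow(dosages))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(dosages)))
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE),
                  individuals)
}

make_popmap <- function(individuals, populations, groups = NULL) {
  if (is.null(groups)) {
    groups <- rep("wild", length(unique(populations)))
    names(groups) <- unique(populations)
    groups <- groups[populations]
  }
  population_map(data.frame(individual = unname(individuals),
                            population = unname(populations),
                            group = unname(groups), stringsAsFactors = FALSE))
}

# two-population fixture: n1 + n2 individuals, dosage matrix by columns
make_two_pop <- function(d1, d2, groups = c("wild", "domestic_european")) {
  d <- cbind(d1, d2)
  gm <- make_gm(d)
  pops <- c(rep("popA", ncol(as.matrix(d1))), rep("popB", ncol(as.matrix(d2))))
  pm <- make_popmap(gm$individuals, pops,
                    setNames(groups, c("popA", "popB"))[pops])
  list(gm = gm, popmap = pm)
}

# write a small VCF text fixture to a temp file
write_toy_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

toy_vcf_3sites <- function() {
  write_toy_vcf(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", ".", "A", "C", ".", ".", ".", "GT", "0/0", "0/0", sep = "\t"),
    paste("1", "200", ".", "G", "T", ".", ".", ".", "GT", "0/1", "0/1", sep = "\t"),
    paste("1", "300", ".", "T", "A", ".", ".", ".", "GT", "1/1", "1/1", sep = "\t")))
}

# independent Weir & Cockerham (1984) oracle: direct transcription of the
# published two-population, single-locus formulas, scalar arithmetic only
wc84_oracle_locus <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}
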