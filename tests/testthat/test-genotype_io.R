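test_that("a VCF with records maps GT calls to dosages by hand transcription", {
  gm <- read_vcf(toy_vcf_3sites())
  expect_equal(n_loci(gm), 3L)
  expect_equal(gm$individuals, c("s1", "s2"))
  expect_equal(unname(gm$dosages[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosages[, 2]), c(0L, 1L, 2L))
  expect_equal(gm$loci$pos, c(100L, 200L, 300L))
  expect_equal(gm$loci$ref, c("A", "G", "T"))
})

test_that("an empty VCF yields a 0-locus matrix with its samples", {
  path <- write_toy_vcf(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t")))
  gm <- read_vcf(path)
  expect_equal(n_loci(gm), 0L)
  expect_equal(n_individuals(gm), 2L)
})

test_that("missing, half-calls and phase are handled; malformed GT is a parse error", {
  path <- write_toy_vcf(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("1", "100", ".", "A", "C", ".", ".", ".", "GT", "./.", "./1", sep = "\t"),
    paste("1", "200", ".", "G", "T", ".", ".", ".", "GT", "0|1", "1|1", sep = "\t")))
  gm <- read_vcf(path)
  expect_true(all(is.na(gm$dosages[1, ])))      # missing and half-call
  expect_equal(unname(gm$dosages[2, ]), c(1L, 2L)) # phased == unphased
  bad <- write_toy_vcf(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", ".", "A", "C", ".", ".", ".", "GT", "0/x", sep = "\t")))
  expect_error(read_vcf(bad), "line")
})

test_that("write_vcf encodes dosages and read(write(x)) is the identity", {
  gm <- make_gm(rbind(c(0L, 2L), c(1L, NA)), ref = c("A", "G"), alt = c("C", "T"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  body <- strsplit(lines[length(lines) - 1], "\t")[[1]]
  expect_equal(body[10:11], c("0/0", "1/1"))
  back <- read_vcf(path)
  expect_equal(back$dosages, gm$dosages)
  expect_equal(back$loci$pos, gm$loci$pos)
  expect_equal(back$individuals, gm$individuals)
  # empty matrix round-trips as a header-only VCF
  empty <- gm_subset(gm, loci = integer(0))
  write_vcf(empty, path)
  expect_equal(n_loci(read_vcf(path)), 0L)
})

test_that("allele_frequency counts non-missing copies and flags empty cells", {
  gm <- make_gm(rbind(rep(1L, 4), c(0L, 2L, NA, NA), rep(NA_integer_, 4)))
  pm <- make_popmap(gm$individuals, rep("p1", 4))
  af <- allele_frequency(gm, "p1", pm)
  expect_equal(af$freq[1], 0.5)
  expect_equal(af$n_alleles[1], 8L)
  expect_equal(af$freq[2], 0.5)     # (0 + 2) / 4
  expect_equal(af$n_alleles[2], 4L)
  expect_true(af$no_calls[3])
  expect_true(is.na(af$freq[3]))
  expect_error(allele_frequency(gm, "nope", pm), "population")
})

test_that("allele frequency is invariant to individual order and merges by counts", {
  set.seed(1)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 10)
  gm <- make_gm(d)
  pm <- make_popmap(gm$individuals, rep(c("a", "b"), each = 3))
  shuffled <- gm_subset(gm, individuals = sample(ncol(d)))
  af1 <- allele_frequency(gm, "a", pm)
  af2 <- allele_frequency(shuffled, "a", pm)
  expect_equal(af1$freq, af2$freq)
  # merged population frequency equals the count-weighted mean of parts
  pm_merged <- make_popmap(gm$individuals, rep("all", 6))
  afa <- allele_frequency(gm, "a", pm)
  afb <- allele_frequency(gm, "b", pm)
  afm <- allele_frequency(gm, "all", pm_merged)
  both <- !is.na(afa$freq) & !is.na(afb$freq)
  w <- (afa$freq * afa$n_alleles + afb$freq * afb$n_alleles) /
    (afa$n_alleles + afb$n_alleles)
  expect_equal(afm$freq[both], w[both])
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(make_gm(rbind(c(0L, 3L))), "dosages")
  expect_error(genotype_matrix(matrix(0L, 1, 2),
                               data.frame(chrom = "1", pos = 1, ref = "A", alt = "C"),
                               c("x", "x")), "unique")
  expect_error(make_gm(rbind(0L, 1L), pos = c(5L, 5L)), "unique")
})

test_that("population map validation catches bad groups and split populations", {
  expect_error(population_map(data.frame(individual = "i1", population = "p",
                                         group = "zoo")), "group")
  expect_error(population_map(data.frame(individual = c("i1", "i2"),
                                         population = c("p", "p"),
                                         group = c("wild", "domestic_european"))),
               "more than one group")
  pm <- make_popmap(c("i1"), "p")
  path <- tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(read_popmap(path)$population, "p")
})
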