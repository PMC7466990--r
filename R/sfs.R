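#' Joint two-population site-frequency spectrum
#'
#' Container for a joint SFS over a wild sample of `n[1]` and a domestic
#' sample of `n[2]` allele copies, with an explicit monomorphic-site
#' class so that the total number of callable sites is conserved through
#' every operation (`sum(counts) + monomorphic == total_sites`). The
#' corner cells (0,0) and (n1,n2) are always empty: sites invariant in
#' the sample belong to the monomorphic class.
#'
#' @param counts numeric matrix with `n[1]+1` rows and `n[2]+1` columns;
#'   entry `[i+1, j+1]` is the number (or expected number) of sites with
#'   `i` alternate/derived copies in the wild sample and `j` in the
#'   domestic sample.
#' @param monomorphic count of sites invariant in the pooled sample.
#' @param n integer vector `c(n_wild, n_dom)` of sample sizes in allele
#'   copies.
#' @param folded is the spectrum folded by pooled minor allele?
#' @return An `sfs2d` object.
#' @export
sfs2d <- function(counts, monomorphic, n, folded = FALSE) {
  counts <- as.matrix(counts)
  n <- as.integer(n)
  if (!all(dim(counts) == n + 1L)) stop("counts must be (n1+1) x (n2+1)")
  if (any(counts < 0) || monomorphic < 0) stop("negative site counts")
  if (counts[1, 1] != 0 || counts[n[1] + 1L, n[2] + 1L] != 0) {
    stop("corner cells must be empty; monomorphic sites go in the monomorphic class")
  }
  if (folded) {
    pooled <- outer(0:n[1], 0:n[2], "+")
    if (any(counts[pooled > sum(n) / 2] != 0)) {
      stop("folded spectrum has mass above the pooled minor-allele boundary")
    }
  }
  dimnames(counts) <- list(0:n[1], 0:n[2])
  structure(list(counts = counts, monomorphic = monomorphic, n = n,
                 folded = folded),
            class = "sfs2d")
}

#' @export
print.sfs2d <- function(x, ...) {
  cat(sprintf("sfs2d (%s): samples %d + %d copies, %s sites (%s polymorphic)\n",
              if (x$folded) "folded" else "unfolded",
              x$n[1], x$n[2],
              format(total_sites(x), big.mark = ","),
              format(round(sum(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Total callable sites behind a spectrum
#' @param sfs an `sfs2d`.
#' @return `sum(counts) + monomorphic`.
#' @export
total_sites <- function(sfs) sum(sfs$counts) + sfs$monomorphic

#' Fold a joint SFS by pooled minor allele
#'
#' Merges each cell (i, j) with its complement (n1-i, n2-j), keeping the
#' orientation whose pooled derived count is at most half the pooled
#' sample size. Cells exactly on the boundary (pooled count equal to
#' half) receive half the mass from each orientation, so total sites are
#' conserved exactly.
#'
#' @param sfs an unfolded `sfs2d`.
#' @return The folded `sfs2d`.
#' @export
fold <- function(sfs) {
  stopifnot(inherits(sfs, "sfs2d"))
  if (sfs$folded) stop("spectrum is already folded")
  n1 <- sfs$n[1]; n2 <- sfs$n[2]
  x <- sfs$counts
  rev_x <- x[rev(seq_len(n1 + 1L)), rev(seq_len(n2 + 1L))]
  pooled <- outer(0:n1, 0:n2, "+")
  half <- (n1 + n2) / 2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  out[pooled < half] <- x[pooled < half] + rev_x[pooled < half]
  out[pooled == half] <- (x[pooled == half] + rev_x[pooled == half]) / 2
  sfs2d(out, sfs$monomorphic, sfs$n, folded = TRUE)
}

#' Composite log-likelihood of an observed SFS
#'
#' Multinomial-style composite log-likelihood
#' \eqn{\ln CL = \sum_{cells} O \ln p} over all cells with observed
#' sites, including the monomorphic class. Expected cells with zero
#' probability but observed sites are floored at `p_min` and counted in
#' the `n_floored` attribute (finite simulation can miss rare cells).
#'
#' @param observed,expected `sfs2d` objects with matching sample sizes
#'   and folding; `expected` is normalised internally to probabilities.
#' @param p_min floor for zero expected probabilities (default 1e-10).
#' @return The log composite likelihood (numeric scalar) with attribute
#'   `n_floored`.
#' @export
composite_log_likelihood <- function(observed, expected, p_min = 1e-10) {
  stopifnot(inherits(observed, "sfs2d"), inherits(expected, "sfs2d"))
  if (!all(observed$n == expected$n)) stop("sample-size (dimension) mismatch")
  if (observed$folded != expected$folded) stop("folding mismatch")
  o <- c(as.vector(observed$counts), observed$monomorphic)
  e <- c(as.vector(expected$counts), expected$monomorphic)
  p <- e / sum(e)
  floored <- o > 0 & p <= 0
  p[floored] <- p_min
  ll <- sum(o[o > 0] * log(p[o > 0]))
  attr(ll, "n_floored") <- sum(floored)
  ll
}

#' Observed joint SFS from genotype data
#'
#' Builds the folded (default) joint SFS over two fixed sets of
#' individuals. Only loci with complete data over the selected
#' individuals are used (matching the complete-data requirement of
#' SFS-based inference); loci monomorphic within the selected subsample
#' fall into the monomorphic class together with the
#' `total_sites - (loci used)` invariant sites.
#'
#' @param gm a [genotype_matrix].
#' @param wild_individuals,dom_individuals character vectors of sample
#'   identifiers; sample sizes in allele copies are twice their lengths.
#' @param total_sites total callable sites (e.g. from
#'   [site_accounting]).
#' @param fold return the folded spectrum (default `TRUE`).
#' @return An `sfs2d`.
#' @export
sfs_from_genotypes <- function(gm, wild_individuals, dom_individuals,
                               total_sites, fold = TRUE) {
  iw <- match(wild_individuals, gm$individuals)
  id <- match(dom_individuals, gm$individuals)
  if (anyNA(iw) || anyNA(id)) stop("unknown individual identifier")
  n1 <- 2L * length(iw); n2 <- 2L * length(id)
  dw <- gm$dosages[, iw, drop = FALSE]
  dd <- gm$dosages[, id, drop = FALSE]
  complete <- rowSums(is.na(dw)) == 0 & rowSums(is.na(dd)) == 0
  i <- rowSums(dw[complete, , drop = FALSE])
  j <- rowSums(dd[complete, , drop = FALSE])
  poly <- (i + j) > 0 & (i + j) < (n1 + n2)
  if (total_sites < sum(poly)) stop("total_sites smaller than polymorphic loci")
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  if (any(poly)) {
    tab <- table(factor(i[poly], levels = 0:n1), factor(j[poly], levels = 0:n2))
    counts <- counts + unclass(tab)
  }
  out <- sfs2d(counts, total_sites - sum(poly), c(n1, n2), folded = FALSE)
  if (fold) fold(out) else out
}

#' Write / read an SFS as JSON
#'
#' Native serialization: dimensions, folded flag, monomorphic count and
#' the cell matrix.
#'
#' @param sfs an `sfs2d`.
#' @param path file path.
#' @return `path` invisibly (writer); an `sfs2d` (reader).
#' @export
write_sfs_json <- function(sfs, path) {
  jsonlite::write_json(list(n = sfs$n, folded = sfs$folded,
                            monomorphic = sfs$monomorphic,
                            counts = sfs$counts),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sfs_json
#' @export
read_sfs_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sfs2d(x$counts, x$monomorphic, x$n, x$folded)
}

#' Write / read the fastsimcoal-style joint SFS text dialect
#'
#' The `.obs`-style layout: a "1 observations" header, a tab-separated
#' column-label line, then one labelled row per wild-sample frequency
#' class. The monomorphic class is carried in the (0,0) cell, as that
#' dialect does; reading splits it back out.
#'
#' @param sfs an `sfs2d`.
#' @param path file path.
#' @param folded folding flag to assign on read.
#' @return `path` invisibly (writer); an `sfs2d` (reader).
#' @export
write_sfs_obs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("1 observations", con)
  writeLines(paste(c("", paste0("d1_", 0:sfs$n[2])), collapse = "\t"), con)
  m <- sfs$counts
  m[1, 1] <- m[1, 1] + sfs$monomorphic
  for (i in 0:sfs$n[1]) {
    writeLines(paste(c(paste0("d0_", i), format(m[i + 1L, ], scientific = FALSE,
                                                trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_sfs_obs
#' @export
read_sfs_obs <- function(path, folded = TRUE) {
  lines <- readLines(path)
  if (!grepl("observations", lines[1])) stop("not an .obs-style SFS file")
  body <- lines[-(1:2)]
  rows <- lapply(strsplit(body, "\t"), function(v) as.numeric(v[-1]))
  m <- do.call(rbind, rows)
  n <- c(nrow(m) - 1L, ncol(m) - 1L)
  mono <- m[1, 1]
  m[1, 1] <- 0
  sfs2d(m, mono, n, folded = folded)
}
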