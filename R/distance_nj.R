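#' Allele-sharing distance between individuals
#'
#' For each pair of individuals, the mean absolute dosage difference over
#' co-called loci, divided by the ploidy so distances lie in [0, 1]:
#' identical genotypes give 0, opposite homozygotes at every shared locus
#' give 1. The number of co-called loci per pair is reported.
#'
#' @param gm a [genotype_matrix].
#' @return A `pairwise_dist`: `d` (symmetric matrix, zero diagonal) and
#'   `n_shared` (co-called loci per pair).
#' @export
pairwise_distance <- function(gm) {
  d <- gm$dosages
  n <- n_individuals(gm)
  dist <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
  shared <- matrix(n_loci(gm), n, n,
                   dimnames = list(gm$individuals, gm$individuals))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      m <- sum(ok)
      if (m == 0) {
        stop("individuals ", gm$individuals[i], " and ", gm$individuals[j],
             " share no co-called locus")
      }
      dist[i, j] <- dist[j, i] <- mean(abs(d[ok, i] - d[ok, j])) / 2
      shared[i, j] <- shared[j, i] <- m
    }
  }
  structure(list(d = dist, n_shared = shared), class = "pairwise_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric
#' distance matrix, returning an unrooted tree. Negative branch lengths,
#' which the NJ update can produce, are clamped to zero with the deficit
#' transferred to the sister edge so path lengths through the parent node
#' are preserved.
#'
#' @param dm a `pairwise_dist` from [pairwise_distance], or a symmetric
#'   numeric matrix with zero diagonal.
#' @return An \pkg{ape} `phylo` object.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "pairwise_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("need at least 3 individuals")
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("undefined distance between ", rownames(d)[idx[1]], " and ",
         colnames(d)[idx[2]])
  }
  tree <- ape::nj(stats::as.dist(d))
  .clamp_negative_edges(tree)
}

.clamp_negative_edges <- function(tree, eps = 1e-12) {
  for (it in seq_len(length(tree$edge.length) + 1L)) {
    neg <- which(tree$edge.length < -eps)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Newick serialization of a tree
#'
#' @param tree an \pkg{ape} `phylo`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to a file).
#' @export
as_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write distances as a PHYLIP square matrix
#'
#' @param dm a `pairwise_dist` or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  d <- if (inherits(dm, "pairwise_dist")) dm$d else as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " "), con)
  }
  invisible(path)
}
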