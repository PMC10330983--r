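#' Allele-sharing distance matrix
#'
#' For a pair of diploid genotypes at one site the shared-allele score is
#' 1 (identical genotypes), 0.5 (one shared allele) or 0 (opposite
#' homozygotes); the distance is one minus the score averaged over sites
#' typed in both samples. Robust to missingness and standard input for SNP
#' neighbor-joining trees. The result is symmetric with a zero diagonal;
#' the triangle inequality is not guaranteed.
#'
#' @param table a \code{variant_table}.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_distance <- function(table) {
  g <- table$geno
  n <- ncol(g)
  check(n >= 2, "need at least two samples")
  ids <- table$samples$id
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    if (!any(ok))
      stop("samples ", ids[i], " and ", ids[j], " share no typed sites",
           call. = FALSE)
    # |dosage difference| of 0/1/2 maps to scores 1/0.5/0
    d[i, j] <- d[j, i] <- mean(abs(g[ok, i] - g[ok, j])) / 2
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining on an allele-sharing (or any) distance
#' matrix. Taxa are ordered lexicographically before agglomeration so the
#' result is invariant to input order (ties broken by id), and negative
#' branch lengths are clamped to zero. For additive matrices the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param dm symmetric numeric distance matrix with taxon dimnames.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(dm) {
  check(is.matrix(dm) && nrow(dm) == ncol(dm), "dm must be square")
  check(nrow(dm) >= 3, "need at least 3 taxa")
  check(isTRUE(all.equal(dm, t(dm))), "distance matrix must be symmetric")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tree <- ape::nj(stats::as.dist(dm))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples sites with replacement, rebuilds the distance matrix and NJ
#' tree per replicate, and reports the proportion of replicates supporting
#' each internal edge of the point-estimate tree.
#'
#' @param table a \code{variant_table}.
#' @param n_boot replicate count (default 100, suited to desk-scale data).
#' @param seed RNG seed.
#' @return list with \code{tree} (the point estimate) and \code{support}
#'   (proportion in [0,1] per internal node).
#' @export
nj_bootstrap <- function(table, n_boot = 100, seed = 1) {
  tree <- nj_tree(pairwise_distance(table))
  n_sites <- nrow(table$sites)
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_sites, n_sites, replace = TRUE)
      bt <- table
      bt$sites <- bt$sites[idx, , drop = FALSE]
      # duplicate positions are fine for distances; bypass the constructor
      bt$geno <- bt$geno[idx, , drop = FALSE]
      nj_tree(pairwise_distance(bt))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  list(tree = tree, support = counts / n_boot)
}

#' Principal component analysis of genotypes
#'
#' MAF-filters the table, codes genotypes 0/1/2, centres each site at twice
#' its allele frequency and scales by \eqn{\sqrt{2p(1-p)}} (the
#' variance-standardized GRM convention of GCTA-style tools), sets missing
#' standardized entries to zero, and eigendecomposes the sample-by-sample
#' covariance. Components are ordered by eigenvalue and signs fixed so each
#' component's largest-magnitude loading is positive.
#'
#' @param table a \code{variant_table}.
#' @param maf_threshold MAF filter applied first (default 0.05).
#' @param k number of components to return.
#' @return object of class \code{genotype_pca}: list with \code{scores}
#'   (samples x k, eigenvector scaled by sqrt(eigenvalue)), \code{vectors},
#'   \code{values} and \code{varexp}.
#' @export
pca_genotypes <- function(table, maf_threshold = 0.05, k = 10) {
  tab <- maf_filter(table, maf_threshold)
  g <- tab$geno
  check(nrow(g) >= 1, "no sites left after MAF filtering")
  check(ncol(g) >= 2, "need at least two samples")
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  sd <- sqrt(2 * p * (1 - p))
  keep <- sd > 0
  check(any(keep), "zero-variance input")
  x <- (g[keep, , drop = FALSE] - 2 * p[keep]) / sd[keep]
  x[is.na(x)] <- 0
  m <- nrow(x)
  K <- crossprod(x) / m                 # samples x samples
  e <- eigen(K, symmetric = TRUE)
  k <- min(k, ncol(K))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  val <- pmax(e$values[seq_len(k)], 0)
  for (j in seq_len(k)) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(val), `*`)
  dimnames(scores) <- list(tab$samples$id, paste0("PC", seq_len(k)))
  structure(list(scores = scores, vectors = vec, values = val,
                 varexp = e$values[seq_len(k)] / sum(pmax(e$values, 0)),
                 pops = tab$samples$pop),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$varexp, 5)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.genotype_pca <- function(x, ...) {
  pops <- factor(x$pops %||% rep("sample", nrow(x$scores)))
  graphics::plot(x$scores[, 1], x$scores[, 2], col = as.integer(pops),
                 pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$varexp[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$varexp[2]), ...)
  graphics::legend("topright", legend = levels(pops), col = seq_along(levels(pops)),
                   pch = 16, bty = "n")
  invisible(x)
}
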