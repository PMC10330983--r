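#' Read a GMT gene-set file
#'
#' Tab-separated: set id, description, then member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  check(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1L))
}

#' Hypergeometric over-representation analysis
#'
#' One-sided enrichment of a candidate gene list against pathway gene sets:
#' for a universe of N genes, a pathway of K, and n candidates of which k
#' hit the pathway, \eqn{p = P(X \ge k)} for hypergeometric X. P-values
#' are BH-adjusted across pathways and sets with \eqn{q \le} \code{alpha}
#' flagged significant (inclusive threshold). Candidates outside the
#' universe are dropped with a warning; only over-representation is tested
#' (no depletion).
#'
#' @param candidates character vector of candidate gene ids.
#' @param gene_sets named list of pathway gene id vectors (e.g. from
#'   [read_gmt()]); genes outside the universe are ignored.
#' @param universe character vector of background gene ids.
#' @param alpha FDR threshold, default 0.05.
#' @return data.frame per pathway: K, n, k, expected overlap, p, q,
#'   significant; sorted by p.
#' @export
ora <- function(candidates, gene_sets, universe, alpha = 0.05) {
  check(length(candidates) > 0, "empty candidate set")
  candidates <- unique(candidates)
  outside <- setdiff(candidates, universe)
  if (length(outside)) {
    warning(length(outside), " candidate gene(s) outside the universe dropped")
    candidates <- intersect(candidates, universe)
    check(length(candidates) > 0, "no candidates left inside the universe")
  }
  n_u <- length(unique(universe))
  n <- length(candidates)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], universe)
    big_k <- length(set)
    if (big_k == 0) return(NULL)
    k <- length(intersect(candidates, set))
    p <- stats::phyper(k - 1, big_k, n_u - big_k, n, lower.tail = FALSE)
    data.frame(pathway = id, K = big_k, n = n, k = k,
               expected = n * big_k / n_u, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  check(!is.null(out), "no pathway overlaps the universe")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
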