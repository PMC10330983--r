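#' Build a sliding-window grid
#'
#' Windows of fixed size at starts 0, step, 2*step, ... (0-based half-open),
#' keeping only windows fully inside the chromosome; trailing partial
#' windows are dropped. Defaults follow the 20-kb window / 5-kb step scheme
#' standard for genome-wide sweep scans.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step between window starts in bp; must satisfy
#'   \code{size >= step > 0}.
#' @return data.frame with columns chrom, start, end (class
#'   \code{window_grid}).
#' @export
make_windows <- function(chrom_lengths, size = 20000, step = 5000) {
  check(is.numeric(size) && is.numeric(step) && step > 0 && size >= step,
        "need size >= step > 0")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < size) {
      warning("chromosome ", ch, " (", len, " bp) is shorter than the window size")
      return(NULL)
    }
    starts <- seq(0, len - size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  if (is.null(grid))
    grid <- data.frame(chrom = character(), start = numeric(), end = numeric())
  class(grid) <- c("window_grid", "data.frame")
  grid
}

# Per-site pi from ALT allele count and total allele number: the fraction
# of unordered haplotype pairs that differ, 2*ac*(an-ac) / (an*(an-1)).
# an < 2 yields NA (site skipped for that subset).
site_pi_counts <- function(ac, an) {
  ifelse(an >= 2, 2 * ac * (an - ac) / (an * (an - 1)), NA_real_)
}

#' Per-site nucleotide diversity
#'
#' The pair-counting form of pi at one site: the fraction of all unordered
#' pairs of non-missing haploid alleles that differ. Genotypes are treated
#' as unphased; dosage counts are equivalent to pair counting for a
#' biallelic site.
#'
#' @param geno integer dosage vector (0/1/2, NA missing) for one site.
#' @param subset optional index/logical vector selecting samples.
#' @return pi in [0,1], or NA when fewer than 2 alleles are available.
#' @export
site_pi <- function(geno, subset = NULL) {
  if (!is.null(subset)) geno <- geno[subset]
  ac <- sum(geno, na.rm = TRUE)
  an <- 2 * sum(!is.na(geno))
  site_pi_counts(ac, an)
}

# Sum a per-site quantity over every window of a grid using cumulative sums
# (sites sorted by position within chromosome, grid half-open on 0-based
# coordinates; VCF positions are 1-based so site pos p occupies [p-1, p)).
window_sums <- function(grid, chrom, pos, ...) {
  vals <- list(...)
  res <- matrix(0, nrow(grid), length(vals) + 1L,
                dimnames = list(NULL, c("n_sites", names(vals))))
  for (ch in unique(grid$chrom)) {
    wi <- which(grid$chrom == ch)
    si <- which(chrom == ch)
    if (length(si) == 0L) next
    p0 <- pos[si] - 1                   # 0-based site coordinate
    o <- order(p0); si <- si[o]; p0 <- p0[o]
    lo <- findInterval(grid$start[wi] - 0.5, p0) + 1L
    hi <- findInterval(grid$end[wi] - 0.5, p0)
    css <- function(x) c(0, cumsum(ifelse(is.na(x), 0, x)))
    cnt <- c(0, cumsum(rep(1, length(si))))
    res[wi, "n_sites"] <- cnt[hi + 1L] - cnt[lo]
    for (k in seq_along(vals)) {
      cv <- css(vals[[k]][si])
      res[wi, k + 1L] <- cv[hi + 1L] - cv[lo]
    }
  }
  res
}

#' Windowed nucleotide diversity for one population
#'
#' Sums per-site pi over the SNPs in each window and divides by the window
#' length in bp (invariant positions contribute zero). A site at a position
#' covered by several overlapping sliding windows contributes to each.
#'
#' @param table a \code{variant_table}.
#' @param grid a window grid from [make_windows()].
#' @param pop population label (column of the sample table).
#' @return the grid with columns n_sites and pi (per-bp) appended.
#' @export
window_pi <- function(table, grid, pop) {
  g <- pop_geno(table, pop)
  ac <- rowSums(g, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(g))
  pi_site <- site_pi_counts(ac, an)
  ws <- window_sums(grid, table$sites$chrom, table$sites$pos, pi = pi_site)
  out <- as.data.frame(grid)
  out$n_sites <- ws[, "n_sites"]
  out$pi <- ws[, "pi"] / (grid$end - grid$start)
  out
}

#' Hudson-style weighted Fst
#'
#' Estimates \eqn{F_{st} = (\pi_{between} - \pi_{within}) / \pi_{between}}
#' where \eqn{\pi_{within}} is the unweighted mean of the two
#' within-population average pairwise differences and \eqn{\pi_{between}}
#' the average difference across all inter-population haplotype pairs.
#' Components are summed over sites and the ratio taken last (ratio of
#' sums, the "weighted" estimator), both per window and genome-wide.
#' No sample-size correction is applied: the plug-in frequency form is used
#' throughout so pair-counting oracles match exactly.
#'
#' @param table a \code{variant_table}.
#' @param pop_a,pop_b population labels.
#' @param grid optional window grid; when supplied the per-window Fst table
#'   is returned with the genome-wide value as attribute
#'   \code{"genomewide"}, otherwise the genome-wide scalar.
#' @return scalar Fst, or a data.frame of per-window values.
#' @export
hudson_fst <- function(table, pop_a, pop_b, grid = NULL) {
  ga <- pop_geno(table, pop_a); gb <- pop_geno(table, pop_b)
  ac_a <- rowSums(ga, na.rm = TRUE); an_a <- 2 * rowSums(!is.na(ga))
  ac_b <- rowSums(gb, na.rm = TRUE); an_b <- 2 * rowSums(!is.na(gb))
  ok <- an_a >= 2 & an_b >= 2
  pi_a <- site_pi_counts(ac_a, an_a)
  pi_b <- site_pi_counts(ac_b, an_b)
  pa <- ac_a / an_a; pb <- ac_b / an_b
  between <- pa * (1 - pb) + pb * (1 - pa)
  within <- (pi_a + pi_b) / 2
  between[!ok] <- NA; within[!ok] <- NA

  genomewide <- {
    sb <- sum(between, na.rm = TRUE); sw <- sum(within, na.rm = TRUE)
    if (sb > 0) (sb - sw) / sb else NA_real_
  }
  if (is.null(grid)) return(genomewide)
  ws <- window_sums(grid, table$sites$chrom[ok], table$sites$pos[ok],
                    between = between[ok], within = within[ok])
  out <- as.data.frame(grid)
  out$n_sites <- ws[, "n_sites"]
  out$fst <- ifelse(ws[, "between"] > 0,
                    (ws[, "between"] - ws[, "within"]) / ws[, "between"],
                    NA_real_)
  attr(out, "genomewide") <- genomewide
  out
}

#' Windowed theta-pi ratio
#'
#' Elementwise ratio \eqn{\theta_{\pi,A} / \theta_{\pi,B}} on a shared
#' window grid. Windows with \eqn{\pi_B = 0} (including both-zero windows)
#' are flagged undefined (NA), not infinite, and are excluded from any
#' downstream quantile computation. By convention A is the
#' reference/control group and B the target/case group, so a sweep in B
#' inflates the ratio.
#'
#' @param pi_a,pi_b numeric vectors of per-window pi on the same grid.
#' @return numeric vector of ratios with NA where undefined.
#' @export
theta_pi_ratio <- function(pi_a, pi_b) {
  check(length(pi_a) == length(pi_b), "pi vectors must share a grid")
  ifelse(is.na(pi_b) | pi_b == 0, NA_real_, pi_a / pi_b)
}

#' Per-window scan statistics for one comparison
#'
#' Convenience wrapper computing, on one grid: per-population windowed pi,
#' the Hudson Fst (ratio of sums per window), and the theta-pi ratio
#' (A = control/reference, B = target/case).
#'
#' @param table a \code{variant_table}.
#' @param grid a window grid.
#' @param pop_a,pop_b control (numerator) and target (denominator)
#'   population labels.
#' @return data.frame chrom/start/end/n_sites/pi_a/pi_b/fst/ratio with the
#'   genome-wide Fst as attribute \code{"genomewide_fst"}.
#' @export
window_stats <- function(table, grid, pop_a, pop_b) {
  wa <- window_pi(table, grid, pop_a)
  wb <- window_pi(table, grid, pop_b)
  wf <- hudson_fst(table, pop_a, pop_b, grid = grid)
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    n_sites = wf$n_sites, pi_a = wa$pi, pi_b = wb$pi,
                    fst = wf$fst, stringsAsFactors = FALSE)
  out$ratio <- theta_pi_ratio(out$pi_a, out$pi_b)
  attr(out, "genomewide_fst") <- attr(wf, "genomewide")
  attr(out, "comparison") <- c(a = pop_a, b = pop_b)
  out
}
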