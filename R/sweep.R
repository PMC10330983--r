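#' Empirical-tail threshold (nearest rank)
#'
#' For the right tail the top \code{ceiling(fraction * N)} finite values are
#' selected and the threshold reported is the smallest selected value (an
#' attained data value, no interpolation); the left tail is symmetric.
#'
#' @param values numeric vector; non-finite entries are ignored.
#' @param fraction tail fraction, default 0.05.
#' @param side \code{"right"} or \code{"left"}.
#' @return the threshold, with the number of selected values as attribute
#'   \code{"n_selected"}.
#' @export
tail_threshold <- function(values, fraction = 0.05, side = c("right", "left")) {
  side <- match.arg(side)
  v <- values[is.finite(values)]
  n <- length(v)
  check(n >= 1 / fraction,
        paste0("need at least ", ceiling(1 / fraction),
               " finite values for a ", fraction, " tail"))
  k <- ceiling(fraction * n)
  check(k < n, "tail would cover the whole set")
  s <- sort(v, decreasing = (side == "right"))
  structure(s[k], n_selected = k)
}

#' Select candidate sweep windows by joint empirical tails
#'
#' A window is selected iff its Fst lies in the right \code{fraction} tail
#' of the empirical Fst distribution AND its theta-pi ratio lies in the
#' requested ratio tail. \code{mode = "left"} targets sweeps in the ratio
#' denominator (B) population, \code{"right"} in the numerator, and
#' \code{"both"} takes the union of the two joint selections. Thresholds
#' are recomputed from the supplied windows — attained cutoffs are
#' properties of each dataset, never constants of the method. Windows with
#' an undefined Fst or ratio are excluded from the empirical distributions
#' and can never be selected.
#'
#' @param stats per-window statistics from [window_stats()] (needs columns
#'   fst and ratio).
#' @param fraction tail fraction, default 0.05.
#' @param mode which ratio tail must fire: left, right or both.
#' @return the selected rows of \code{stats} plus a \code{tail} column
#'   recording the ratio tail that fired; thresholds in attribute
#'   \code{"thresholds"}.
#' @export
select_windows <- function(stats, fraction = 0.05,
                           mode = c("right", "left", "both")) {
  mode <- match.arg(mode)
  ok <- is.finite(stats$fst) & is.finite(stats$ratio)
  fst_thr <- tail_threshold(stats$fst[ok], fraction, "right")
  thr <- list(fst = as.numeric(fst_thr), ratio_left = NA_real_,
              ratio_right = NA_real_, fraction = fraction, mode = mode)
  sel_r <- sel_l <- rep(FALSE, nrow(stats))
  if (mode %in% c("right", "both")) {
    thr$ratio_right <- as.numeric(tail_threshold(stats$ratio[ok], fraction, "right"))
    sel_r <- ok & stats$fst >= thr$fst & stats$ratio >= thr$ratio_right
  }
  if (mode %in% c("left", "both")) {
    thr$ratio_left <- as.numeric(tail_threshold(stats$ratio[ok], fraction, "left"))
    sel_l <- ok & stats$fst >= thr$fst & stats$ratio <= thr$ratio_left
  }
  out <- stats[sel_r | sel_l, , drop = FALSE]
  out$tail <- ifelse(sel_r[sel_r | sel_l], "right", "left")
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  out
}

#' Merge selected windows into candidate regions
#'
#' Overlapping or bookended (touching) windows are merged into maximal
#' half-open intervals; sliding windows that share sequence therefore
#' collapse into one region per sweep signal.
#'
#' @param windows data.frame with chrom/start/end and optionally fst/ratio.
#' @return data.frame of regions with n_windows, peak_fst, peak_ratio and
#'   mean_ratio where available.
#' @export
merge_regions <- function(windows) {
  base_cols <- c("chrom", "start", "end", "n_windows",
                 "peak_fst", "peak_ratio", "mean_ratio")
  if (nrow(windows) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), peak_fst = numeric(),
                      peak_ratio = numeric(), mean_ratio = numeric())
    return(out)
  }
  merged <- merge_intervals(windows)
  stat <- function(reg, f, col) {
    if (is.null(windows[[col]])) return(NA_real_)
    inside <- windows$chrom == reg$chrom &
      windows$start < reg$end & windows$end > reg$start
    f(windows[[col]][inside], na.rm = TRUE)
  }
  merged$n_windows <- vapply(seq_len(nrow(merged)), function(i)
    sum(windows$chrom == merged$chrom[i] & windows$start < merged$end[i] &
          windows$end > merged$start[i]), 0)
  merged$peak_fst <- vapply(seq_len(nrow(merged)), function(i)
    stat(merged[i, ], max, "fst"), 0)
  merged$peak_ratio <- vapply(seq_len(nrow(merged)), function(i)
    stat(merged[i, ], max, "ratio"), 0)
  merged$mean_ratio <- vapply(seq_len(nrow(merged)), function(i)
    stat(merged[i, ], mean, "ratio"), 0)
  merged
}

#' Intersect candidate regions with gene annotation
#'
#' A gene is a candidate when it overlaps a region by at least 1 bp.
#' Regions are 0-based half-open; gene intervals (1-based closed) are
#' converted at the boundary.
#'
#' @param regions data.frame of merged regions.
#' @param genes a \code{gene_model}.
#' @return list with \code{regions} (a \code{genes} column added, comma
#'   separated) and \code{genes} (deduplicated candidate gene ids).
#' @export
regions_to_genes <- function(regions, genes) {
  g <- genes$genes
  g0 <- g$start - 1            # to 0-based half-open [start-1, end)
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- g$chrom == regions$chrom[i] & g0 < regions$end[i] &
      g$end > regions$start[i]
    g$gene_id[hit]
  })
  regions$genes <- vapply(per_region, paste, "", collapse = ",")
  list(regions = regions, genes = unique(unlist(per_region)))
}

#' Shared regions and genes across comparisons
#'
#' Computes the genomic intervals covered by candidate regions of every
#' comparison (maximal common intervals of the intersection), the
#' intersection of candidate gene sets, and the full Venn partition of
#' both: for regions, counts of maximal intervals covered by exactly each
#' non-empty subset of comparisons; for genes, membership counts per
#' subset. Commutative and associative in the comparisons.
#'
#' @param region_list named list (>= 2) of region data.frames.
#' @param gene_sets optional named list of candidate gene id vectors,
#'   same names.
#' @return list with \code{shared} (intervals in every comparison),
#'   \code{venn_regions}, \code{shared_genes} and \code{venn_genes}.
#' @export
shared_regions <- function(region_list, gene_sets = NULL) {
  check(is.list(region_list) && length(region_list) >= 2,
        "need at least two comparisons")
  if (is.null(names(region_list)))
    names(region_list) <- paste0("cmp", seq_along(region_list))
  sets <- lapply(region_list, function(r)
    merge_intervals(r[, c("chrom", "start", "end")]))
  shared <- Reduce(intersect_intervals, sets)

  # Venn partition of the covered genome: split at all boundaries, label
  # each segment with its membership pattern, merge adjacent same-pattern
  # segments, count them.
  labs <- names(region_list)
  venn <- list()
  chroms <- unique(unlist(lapply(sets, function(s) s$chrom)))
  for (ch in chroms) {
    cuts <- sort(unique(unlist(lapply(sets, function(s) {
      d <- s[s$chrom == ch, ]; c(d$start, d$end)
    }))))
    if (length(cuts) < 2) next
    seg_s <- cuts[-length(cuts)]; seg_e <- cuts[-1]
    mid <- (seg_s + seg_e) / 2
    memb <- sapply(sets, function(s) {
      d <- s[s$chrom == ch, ]
      vapply(mid, function(m) any(d$start <= m & m < d$end), TRUE)
    })
    if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1)
    pat <- apply(memb, 1, function(r) paste(labs[r], collapse = "&"))
    covered <- pat != ""
    # count maximal runs of identical pattern over contiguous segments
    i <- 1
    while (i <= length(pat)) {
      if (!covered[i]) { i <- i + 1; next }
      j <- i
      while (j + 1 <= length(pat) && pat[j + 1] == pat[i] &&
             seg_s[j + 1] == seg_e[j]) j <- j + 1
      venn[[pat[i]]] <- (venn[[pat[i]]] %||% 0L) + 1L
      i <- j + 1
    }
  }
  venn_regions <- data.frame(
    members = if (length(venn)) names(venn) else character(),
    n_intervals = if (length(venn)) unlist(venn, use.names = FALSE)
                  else integer(),
    stringsAsFactors = FALSE)

  shared_genes <- NULL; venn_genes <- NULL
  if (!is.null(gene_sets)) {
    shared_genes <- Reduce(intersect, gene_sets)
    all_genes <- unique(unlist(gene_sets))
    pat <- vapply(all_genes, function(g)
      paste(labs[vapply(gene_sets, function(s) g %in% s, TRUE)],
            collapse = "&"), "")
    tb <- base::table(pat)
    venn_genes <- data.frame(members = names(tb),
                             n_genes = as.integer(tb),
                             stringsAsFactors = FALSE)
  }
  list(shared = shared, venn_regions = venn_regions,
       shared_genes = shared_genes, venn_genes = venn_genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan one comparison for selective sweeps
#'
#' The central fit: joint empirical-tail selection of windows (high Fst
#' plus extreme theta-pi ratio), merging into candidate regions and
#' optional candidate-gene calling, returned as a classed object with
#' print, summary and plot methods.
#'
#' @param stats per-window statistics from [window_stats()].
#' @param genes optional \code{gene_model} for candidate-gene calling.
#' @param fraction tail fraction (default 0.05).
#' @param mode ratio tail: "right", "left" or "both".
#' @param label optional comparison label.
#' @return an object of class \code{sweep_scan} with elements stats,
#'   selected, thresholds, regions, genes, label.
#' @export
sweep_scan <- function(stats, genes = NULL, fraction = 0.05,
                       mode = c("right", "left", "both"), label = NULL) {
  mode <- match.arg(mode)
  selected <- select_windows(stats, fraction, mode)
  thresholds <- attr(selected, "thresholds")
  regions <- merge_regions(selected)
  gene_ids <- NULL
  if (!is.null(genes)) {
    rg <- regions_to_genes(regions, genes)
    regions <- rg$regions
    gene_ids <- rg$genes
  }
  structure(list(stats = stats, selected = selected, thresholds = thresholds,
                 regions = regions, genes = gene_ids,
                 fraction = fraction, mode = mode,
                 label = label %||% paste(attr(stats, "comparison"),
                                          collapse = "_vs_")),
            class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  t <- x$thresholds
  cat("Selective-sweep scan [", x$label, "]\n", sep = "")
  cat("  windows: ", nrow(x$stats), " scanned, ", nrow(x$selected),
      " selected (joint ", 100 * x$fraction, "% tails, ratio tail: ",
      x$mode, ")\n", sep = "")
  cat(sprintf("  thresholds: Fst > %.4g", t$fst))
  if (is.finite(t$ratio_right)) cat(sprintf(", ratio > %.4g", t$ratio_right))
  if (is.finite(t$ratio_left)) cat(sprintf(", ratio < %.4g", t$ratio_left))
  cat("\n  regions:", nrow(x$regions))
  if (!is.null(x$genes)) cat("  candidate genes:", length(x$genes))
  cat("\n")
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  out <- list(label = object$label, n_windows = nrow(object$stats),
              n_selected = nrow(object$selected),
              thresholds = object$thresholds,
              n_regions = nrow(object$regions),
              n_genes = length(object$genes),
              regions = object$regions)
  class(out) <- "summary.sweep_scan"
  out
}

#' @export
print.summary.sweep_scan <- function(x, ...) {
  cat("Sweep scan summary [", x$label, "]: ", x$n_selected, "/", x$n_windows,
      " windows -> ", x$n_regions, " regions, ", x$n_genes, " genes\n",
      sep = "")
  if (nrow(x$regions)) {
    print(utils::head(x$regions[order(-x$regions$peak_fst), ], 10))
  }
  invisible(x)
}

#' Plot a sweep scan
#'
#' Two panels along the genome: windowed Fst and the theta-pi ratio (log
#' scale), with the attained tail thresholds as dashed lines and selected
#' windows highlighted.
#'
#' @param x a \code{sweep_scan}.
#' @param ... passed to \code{plot}.
#' @export
plot.sweep_scan <- function(x, ...) {
  s <- x$stats
  mid <- (s$start + s$end) / 2
  # lay chromosomes end to end
  offs <- c(0, cumsum(tapply(s$end, s$chrom, max)))
  names(offs) <- c(unique(s$chrom), "")
  gx <- mid + offs[s$chrom]
  sel <- paste(s$chrom, s$start) %in% paste(x$selected$chrom, x$selected$start)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(gx, s$fst, pch = 16, cex = 0.4,
                 col = ifelse(sel, "firebrick", "grey50"),
                 xlab = "", ylab = "Fst", main = x$label, ...)
  graphics::abline(h = x$thresholds$fst, lty = 2)
  graphics::plot(gx, s$ratio, pch = 16, cex = 0.4, log = "y",
                 col = ifelse(sel, "firebrick", "grey50"),
                 xlab = "genome position", ylab = expression(theta[pi] ~ ratio))
  if (is.finite(x$thresholds$ratio_right))
    graphics::abline(h = x$thresholds$ratio_right, lty = 2)
  if (is.finite(x$thresholds$ratio_left))
    graphics::abline(h = x$thresholds$ratio_left, lty = 2)
  invisible(x)
}
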