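#' Per-SNP case--control association
#'
#' Allelic 2x2 test per SNP: ALT/REF allele counts in cases vs controls,
#' Pearson chi-square with 1 df (no continuity correction), replaced by
#' Fisher's exact test whenever any expected cell count is below 5.
#' P-values are Benjamini--Hochberg adjusted across tested SNPs.
#' Monomorphic SNPs are skipped with a note; genotype (0/1/2) count
#' columns per group are emitted alongside for transparency.
#'
#' @param table a \code{variant_table}.
#' @param phenotypes data.frame with columns sample_id and status
#'   (\code{"case"}/\code{"control"}), or a case/control vector named by
#'   sample id.
#' @return data.frame per tested SNP: position, allele and genotype counts,
#'   statistic, test used, p and BH-adjusted q; skipped monomorphic count
#'   in attribute \code{"n_skipped"}.
#' @export
snp_association <- function(table, phenotypes) {
  if (is.data.frame(phenotypes)) {
    check(all(c("sample_id", "status") %in% names(phenotypes)),
          "phenotypes needs sample_id and status columns")
    ph <- stats::setNames(phenotypes$status, phenotypes$sample_id)
  } else ph <- phenotypes
  idx <- match(table$samples$id, names(ph))
  check(!anyNA(idx), "every sample needs a phenotype")
  status <- unname(ph[idx])
  check(all(status %in% c("case", "control")), "status must be case/control")
  case <- status == "case"
  check(sum(case) >= 2 && sum(!case) >= 2,
        "need at least 2 cases and 2 controls")

  g <- table$geno
  alt_case <- rowSums(g[, case, drop = FALSE], na.rm = TRUE)
  n_case <- 2 * rowSums(!is.na(g[, case, drop = FALSE]))
  alt_ctrl <- rowSums(g[, !case, drop = FALSE], na.rm = TRUE)
  n_ctrl <- 2 * rowSums(!is.na(g[, !case, drop = FALSE]))
  a <- alt_case; b <- n_case - alt_case       # case ALT / REF
  c_ <- alt_ctrl; d <- n_ctrl - alt_ctrl      # control ALT / REF

  poly <- (a + c_) > 0 & (b + d) > 0 & n_case > 0 & n_ctrl > 0
  n_tot <- a + b + c_ + d
  stat <- n_tot * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  # exact test where the chi-square approximation is unsafe
  e_min <- pmin((a + b) * (a + c_), (a + b) * (b + d),
                (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n_tot
  use_exact <- poly & e_min < 5
  test <- ifelse(use_exact, "exact", "chisq")
  for (i in which(use_exact)) {
    p[i] <- stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2,
                                      byrow = TRUE))$p.value
    stat[i] <- NA_real_
  }

  gcnt <- function(sel, val) rowSums(g[, sel, drop = FALSE] == val, na.rm = TRUE)
  out <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                    ref = table$sites$ref, alt = table$sites$alt,
                    alt_case = a, ref_case = b, alt_ctrl = c_, ref_ctrl = d,
                    rr_case = gcnt(case, 0L), ra_case = gcnt(case, 1L),
                    aa_case = gcnt(case, 2L), rr_ctrl = gcnt(!case, 0L),
                    ra_ctrl = gcnt(!case, 1L), aa_ctrl = gcnt(!case, 2L),
                    test = test, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  out <- out[poly, , drop = FALSE]
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  attr(out, "n_skipped") <- sum(!poly)
  out
}

# Enumerate the 2^k haplotypes over k biallelic SNPs as a 0/1 matrix.
enumerate_haplotypes <- function(k) {
  h <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  dimnames(h) <- list(apply(h, 1, paste, collapse = ""), NULL)
  h
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies over k SNPs (k <= 8, so the
#' 2^k haplotype space is enumerable) under the multinomial haplotype-pair
#' likelihood with Hardy--Weinberg pairing. The E-step distributes each
#' multi-heterozygous genotype over its compatible phase resolutions in
#' proportion to current frequency products; the M-step re-estimates
#' frequencies from expected haplotype counts. The log-likelihood is
#' asserted non-decreasing at every iteration. Multiple restarts (one
#' uniform, the rest random) guard against local optima; the best
#' likelihood is kept. When no multi-site heterozygotes are present the
#' fixed point equals direct gamete counting.
#'
#' @param geno matrix of dosages (samples x k SNPs). SNPs missing in every
#'   sample are dropped; samples with a remaining missing genotype are
#'   excluded from the fit.
#' @param n_restarts number of EM starts (default 5).
#' @param tol convergence threshold on the log-likelihood gain.
#' @param max_iter iteration cap per start.
#' @param min_freq haplotypes at or above this frequency are reported as
#'   present/identified (default 1e-3).
#' @param seed RNG seed for the random restarts.
#' @return object of class \code{em_haplotypes}: frequencies (named by 0/1
#'   haplotype string), log-likelihood, iteration count, \code{present}
#'   flags, and each sample's most probable haplotype pair.
#' @export
em_haplotypes <- function(geno, n_restarts = 5, tol = 1e-8, max_iter = 1000,
                          min_freq = 1e-3, seed = 1) {
  geno <- as.matrix(geno)
  all_missing <- colSums(!is.na(geno)) == 0
  if (any(all_missing)) geno <- geno[, !all_missing, drop = FALSE]
  k <- ncol(geno)
  check(k >= 1 && k <= 8, "need 1-8 SNPs with data")
  complete <- stats::complete.cases(geno)
  geno <- geno[complete, , drop = FALSE]
  n <- nrow(geno)
  check(n >= 1, "no complete genotypes")

  H <- enumerate_haplotypes(k)
  nh <- nrow(H)
  key <- apply(geno, 1, paste, collapse = "/")
  uniq <- !duplicated(key)
  ug <- geno[uniq, , drop = FALSE]
  cnt <- as.numeric(base::table(key)[key[uniq]])

  # compatible ordered haplotype pairs per unique genotype
  pairs <- lapply(seq_len(nrow(ug)), function(r) {
    g <- ug[r, ]
    het <- which(g == 1)
    fixed <- ifelse(g == 2, 1L, 0L)
    if (length(het) == 0) {
      i <- 1L + sum(fixed * 2^((k - 1):0))
      return(cbind(i, i))
    }
    m <- length(het)
    combos <- as.matrix(expand.grid(rep(list(0:1), m)))
    h1 <- matrix(rep(fixed, each = nrow(combos)), nrow(combos), k)
    h1[, het] <- combos
    h2 <- matrix(rep(ifelse(g >= 1, 1L, 0L), each = nrow(combos)),
                 nrow(combos), k)
    h2[, het] <- 1L - combos
    idx <- function(hm) 1L + hm %*% 2^((k - 1):0)
    cbind(idx(h1), idx(h2))
  })

  run_em <- function(freq) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      counts <- numeric(nh)
      ll <- 0
      for (r in seq_along(pairs)) {
        pr <- pairs[[r]]
        w <- freq[pr[, 1]] * freq[pr[, 2]]
        tot <- sum(w)
        if (tot <= 0) { w <- rep(1 / nrow(pr), nrow(pr)); tot <- 1e-300 }
        else w <- w / tot
        ll <- ll + cnt[r] * log(tot)
        add <- cnt[r] * w
        for (q in seq_len(nrow(pr))) {
          counts[pr[q, 1]] <- counts[pr[q, 1]] + add[q]
          counts[pr[q, 2]] <- counts[pr[q, 2]] + add[q]
        }
      }
      if (ll < ll_old - 1e-9)
        stop("EM log-likelihood decreased; this is a bug", call. = FALSE)
      freq <- counts / (2 * n)
      if (is.finite(ll_old) && ll - ll_old < tol) return(list(freq = freq, ll = ll, iter = it))
      ll_old <- ll
    }
    list(freq = freq, ll = ll_old, iter = max_iter)
  }

  best <- with_seed(seed, {
    starts <- c(list(rep(1 / nh, nh)),
                lapply(seq_len(max(0, n_restarts - 1)), function(s) {
                  x <- stats::rexp(nh); x / sum(x)
                }))
    fits <- lapply(starts, run_em)
    fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  })

  freq <- stats::setNames(best$freq, rownames(H))
  # most probable phase per unique genotype, mapped back to samples
  mp <- vapply(seq_along(pairs), function(r) {
    pr <- pairs[[r]]
    w <- freq[pr[, 1]] * freq[pr[, 2]]
    b <- which.max(w)
    paste(rownames(H)[sort(pr[b, ])], collapse = "|")
  }, "")
  sample_pairs <- mp[match(key, key[uniq])]

  structure(list(freq = freq, loglik = best$ll, n_iter = best$iter,
                 present = freq >= min_freq, n_samples = n, k = k,
                 sample_pairs = sample_pairs, min_freq = min_freq),
            class = "em_haplotypes")
}

#' @export
print.em_haplotypes <- function(x, ...) {
  cat("EM haplotype frequencies (", x$k, " SNPs, ", x$n_samples,
      " samples, logLik ", sprintf("%.3f", x$loglik), "):\n", sep = "")
  f <- sort(x$freq[x$present], decreasing = TRUE)
  for (h in names(f)) cat(sprintf("  %s  %.4f\n", h, f[h]))
  cat("  (", sum(x$present), " haplotypes at frequency >= ", x$min_freq,
      ")\n", sep = "")
  invisible(x)
}

#' Linkage disequilibrium statistics for one SNP pair
#'
#' From the four haplotype frequencies of a biallelic SNP pair:
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{D' = |D| / D_{max}} with
#' \eqn{D_{max}} the tightest frequency bound, and
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))}.
#'
#' @param freq numeric vector of length 4 in the order (AB, Ab, aB, ab)
#'   where A/B denote the first allele at each SNP; must sum to 1.
#' @return list with D, Dprime and r2. A SNP fixed for one allele makes LD
#'   undefined and is an error.
#' @export
ld_stats <- function(freq) {
  check(length(freq) == 4, "need 4 haplotype frequencies (AB, Ab, aB, ab)")
  check(abs(sum(freq) - 1) < 1e-6, "frequencies must sum to 1")
  p_a <- freq[1] + freq[2]
  p_b <- freq[1] + freq[3]
  check(p_a > 0 && p_a < 1 && p_b > 0 && p_b < 1,
        "LD undefined: a SNP is fixed")
  d <- freq[1] - p_a * p_b
  d_max <- if (d >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  list(D = unname(d),
       Dprime = unname(if (d == 0) 0 else abs(d) / d_max),
       r2 = unname(d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))))
}

#' Pairwise LD matrices from unphased genotypes
#'
#' Estimates the four haplotype frequencies for every SNP pair by a 2-SNP
#' EM fit and evaluates D' and r-squared.
#'
#' @param geno dosage matrix, samples x SNPs.
#' @param seed RNG seed forwarded to the per-pair EM.
#' @return list with symmetric matrices \code{Dprime} and \code{r2}
#'   (NA where undefined).
#' @export
ld_matrix <- function(geno, seed = 1) {
  geno <- as.matrix(geno)
  k <- ncol(geno)
  dp <- r2 <- matrix(NA_real_, k, k, dimnames = list(colnames(geno),
                                                     colnames(geno)))
  diag(dp) <- diag(r2) <- 1
  if (k < 2) return(list(Dprime = dp, r2 = r2))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fit <- tryCatch(em_haplotypes(geno[, c(i, j)], seed = seed),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$freq) != 4) next
    # em order over (SNPi, SNPj) bits: 00,01,10,11 -> (ab, aB, Ab, AB)
    st <- tryCatch(ld_stats(unname(fit$freq[c("11", "10", "01", "00")])),
                   error = function(e) NULL)
    if (is.null(st)) next
    dp[i, j] <- dp[j, i] <- st$Dprime
    r2[i, j] <- r2[j, i] <- st$r2
  }
  list(Dprime = dp, r2 = r2)
}

#' Delimit an LD block
#'
#' The block is the maximal run of consecutive (position-ordered) SNPs in
#' which every pairwise r-squared is at least \code{min_r2}; ties are
#' broken leftmost. The block interval spans the first to the last SNP
#' position.
#'
#' @param positions SNP positions, ascending.
#' @param r2 symmetric pairwise r-squared matrix.
#' @param min_r2 threshold (default 0.5).
#' @return list with \code{idx} (SNP indices), \code{start}, \code{end};
#'   or NULL (with a message) when no pair passes.
#' @export
define_block <- function(positions, r2, min_r2 = 0.5) {
  k <- length(positions)
  check(k == nrow(r2), "positions and r2 must match")
  check(!is.unsorted(positions), "SNPs must be ordered by position")
  extends <- function(i, j) {
    # can SNP j+1 join the run i..j? needs r2 >= min_r2 against all of them
    vals <- r2[i:j, j + 1]
    !anyNA(vals) && all(vals >= min_r2)
  }
  best <- NULL
  for (i in seq_len(k)) {
    j <- i
    while (j + 1 <= k && extends(i, j)) j <- j + 1
    if (j > i && (is.null(best) || (j - i) > (best[2] - best[1])))
      best <- c(i, j)
  }
  if (is.null(best)) {
    message("no SNP pair reaches r2 >= ", min_r2, "; no block defined")
    return(NULL)
  }
  list(idx = best[1]:best[2], start = positions[best[1]],
       end = positions[best[2]])
}

#' Haplotype block analysis of a candidate locus
#'
#' Combines pairwise LD estimation, block delimitation and EM haplotype
#' frequencies over the block SNPs — the follow-up analysis applied to a
#' candidate locus such as a horn-phenotype gene: which haplotypes exist,
#' at what frequency, and how they divide between cases and controls.
#'
#' @param table a \code{variant_table} restricted (or subsettable) to the
#'   candidate SNPs.
#' @param sites indices of candidate SNPs in \code{table} (default: all).
#' @param min_r2 block threshold.
#' @param phenotypes optional phenotype table; adds per-group haplotype
#'   frequencies.
#' @param seed RNG seed.
#' @return object of class \code{haplotype_block} or NULL when no block
#'   forms.
#' @export
haplotype_block <- function(table, sites = seq_len(nrow(table$sites)),
                            min_r2 = 0.5, phenotypes = NULL, seed = 1) {
  pos <- table$sites$pos[sites]
  geno <- t(table$geno[sites, , drop = FALSE])
  ld <- ld_matrix(geno, seed = seed)
  blk <- define_block(pos, ld$r2, min_r2)
  if (is.null(blk)) return(NULL)
  bidx <- sites[blk$idx]
  bg <- t(table$geno[bidx, , drop = FALSE])
  em <- em_haplotypes(bg, seed = seed)
  group_freq <- NULL
  if (!is.null(phenotypes)) {
    ph <- stats::setNames(phenotypes$status, phenotypes$sample_id)
    st <- ph[table$samples$id]
    group_freq <- lapply(stats::setNames(nm = c("case", "control")), function(s) {
      rows <- which(st == s)
      if (length(rows) < 2) return(NULL)
      em_haplotypes(bg[rows, , drop = FALSE], seed = seed)$freq
    })
  }
  structure(list(snp_idx = bidx, positions = table$sites$pos[bidx],
                 chrom = table$sites$chrom[bidx][1],
                 interval = c(blk$start, blk$end), ld = ld, em = em,
                 freq = em$freq[em$present], group_freq = group_freq,
                 min_r2 = min_r2),
            class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("Haplotype block ", x$chrom, ":", x$interval[1], "-", x$interval[2],
      " (", length(x$snp_idx), " SNPs, ",
      round((x$interval[2] - x$interval[1]) / 1000, 1), " kb, r2 >= ",
      x$min_r2, ")\n", sep = "")
  cat(" ", length(x$freq), "haplotypes identified:\n")
  f <- sort(x$freq, decreasing = TRUE)
  for (h in names(f)) cat(sprintf("    %s  %.4f\n", h, f[h]))
  invisible(x)
}
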