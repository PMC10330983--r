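#' Construct a variant table
#'
#' The central container for biallelic SNP data: per-site metadata
#' (chromosome, 1-based position, REF/ALT alleles, the QD/FS/MQ hard-filter
#' annotations), an ALT-dosage genotype matrix (0/1/2, \code{NA} = missing)
#' of sites by samples, an optional genotype-quality matrix, and a sample
#' table with population labels. Positions are kept strictly increasing
#' within each chromosome.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt and optionally
#'   qd, fs, mq.
#' @param geno integer matrix, sites x samples, ALT allele dosage.
#' @param gq optional numeric matrix of genotype qualities, same shape.
#' @param samples data.frame with columns id and pop.
#' @param log named list of bookkeeping counts (skipped records etc.).
#' @return an object of class \code{variant_table}.
#' @export
variant_table <- function(sites, geno, gq = NULL,
                          samples = data.frame(id = colnames(geno),
                                               pop = NA_character_),
                          log = list()) {
  check(is.data.frame(sites) && all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
        "sites needs columns chrom, pos, ref, alt")
  check(is.matrix(geno) && nrow(geno) == nrow(sites),
        "geno must be a sites x samples matrix")
  check(nrow(samples) == ncol(geno), "samples must match geno columns")
  for (k in c("qd", "fs", "mq"))
    if (is.null(sites[[k]])) sites[[k]] <- rep(NA_real_, nrow(sites))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[ord, , drop = FALSE]
  dup <- stats::ave(sites$pos, sites$chrom, FUN = function(p) c(1, diff(p))) <= 0
  check(!any(dup), "positions must be strictly increasing within chromosome")
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, gq = gq, samples = samples,
                 log = log),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", nrow(x$samples), "samples")
  pops <- unique(x$samples$pop)
  if (!all(is.na(pops))) cat(" (", length(pops), " populations)", sep = "")
  cat("\n")
  if (length(x$log)) {
    for (k in names(x$log)) cat("  ", k, ": ", x$log[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), nrow(x$samples))

# Row-subset a variant table, keeping matrices aligned.
subset_sites <- function(table, keep) {
  table$sites <- table$sites[keep, , drop = FALSE]
  rownames(table$sites) <- NULL
  table$geno <- table$geno[keep, , drop = FALSE]
  if (!is.null(table$gq)) table$gq <- table$gq[keep, , drop = FALSE]
  table
}

# Dosage submatrix for one population.
pop_geno <- function(table, pop) {
  cols <- which(table$samples$pop == pop)
  check(length(cols) > 0, paste0("population '", pop, "' not found"))
  table$geno[, cols, drop = FALSE]
}

#' Read a multi-sample VCF into a variant table
#'
#' Loads biallelic SNP records. Multi-allelic records and non-SNP records
#' (indels, symbolic alleles) are excluded and counted in the skip log —
#' downstream statistics assume biallelic sites. INFO keys QD, FS and MQ and
#' the FORMAT key GQ are carried along when present.
#'
#' @param path VCF file (v4.x, plain or bgzipped).
#' @param pop_map optional population assignment: a named character vector
#'   (names = sample ids) or a data.frame with columns id/sample and pop.
#'   Every mapped sample must be present in the VCF.
#' @return a \code{variant_table}.
#' @export
read_vcf <- function(path, pop_map = NULL) {
  check(file.exists(path), paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)        # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character()

  if (nrow(fix) == 0L) {
    tab <- variant_table(
      sites = data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         stringsAsFactors = FALSE),
      geno = matrix(integer(), 0L, length(samples),
                    dimnames = list(NULL, samples)),
      samples = data.frame(id = samples, pop = NA_character_,
                           stringsAsFactors = FALSE))
    return(attach_pops(tab, pop_map))
  }

  snv <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_snp <- !multi & fix$REF %in% snv & fix$ALT %in% snv
  log <- list(multiallelic_skipped = sum(multi),
              non_snp_skipped = sum(!multi & !is_snp))
  keep <- which(is_snp)

  info_num <- function(key) {
    x <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
    if (length(x) == 0L) rep(NA_real_, nrow(fix)) else x
  }
  qd <- info_num("QD")[keep]; fs <- info_num("FS")[keep]; mq <- info_num("MQ")[keep]

  as_site_matrix <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = nrow(fix),
                                dimnames = list(NULL, names(x)))
    else x
  }
  gt <- as_site_matrix(vcfR::extract.gt(v, element = "GT"))[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, length(keep), length(samples),
                 dimnames = list(NULL, samples))
  dose[gt == "0/0"] <- 0L
  dose[gt == "0/1" | gt == "1/0"] <- 1L
  dose[gt == "1/1"] <- 2L

  gq <- tryCatch(
    suppressWarnings(as_site_matrix(
      vcfR::extract.gt(v, element = "GQ",
                       as.numeric = TRUE))[keep, , drop = FALSE]),
    error = function(e) NULL)

  tab <- variant_table(
    sites = data.frame(chrom = fix$CHROM[keep],
                       pos = as.integer(fix$POS[keep]),
                       ref = fix$REF[keep], alt = fix$ALT[keep],
                       qd = qd, fs = fs, mq = mq, stringsAsFactors = FALSE),
    geno = dose, gq = gq,
    samples = data.frame(id = samples, pop = NA_character_,
                         stringsAsFactors = FALSE),
    log = log)
  attach_pops(tab, pop_map)
}

attach_pops <- function(table, pop_map) {
  if (is.null(pop_map)) return(table)
  if (is.data.frame(pop_map)) {
    idc <- intersect(c("id", "sample", "sample_id"), names(pop_map))[1]
    check(!is.na(idc) && "pop" %in% names(pop_map),
          "pop_map data.frame needs an id/sample column and a pop column")
    map <- stats::setNames(as.character(pop_map$pop), pop_map[[idc]])
  } else map <- pop_map
  missing <- setdiff(names(map), table$samples$id)
  check(length(missing) == 0,
        paste0("pop_map samples absent from VCF: ", paste(missing, collapse = ", ")))
  table$samples$pop <- unname(map[table$samples$id])
  table
}

#' Apply GATK-style hard filters
#'
#' Removes sites failing \code{QD < 2.0 || FS > 60.0 || MQ < 40.0} and masks
#' genotypes with \code{GQ < 20} as missing. All inequalities are strict, so
#' boundary values (QD = 2.0, FS = 60.0, MQ = 40.0, GQ = 20) pass. Sites
#' with a missing QD/FS/MQ annotation fail closed (removed). The operation
#' is idempotent. The SNP-cluster clause of the upstream caller (window-based
#' clustering) has no published semantics and is recorded as not applied.
#'
#' @param table a \code{variant_table} with INFO annotations.
#' @param qd_min,fs_max,mq_min,gq_min filter thresholds.
#' @return the filtered \code{variant_table}; removal counts in \code{$log}.
#' @export
hard_filter <- function(table, qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                        gq_min = 20) {
  s <- table$sites
  fail <- is.na(s$qd) | is.na(s$fs) | is.na(s$mq) |
    s$qd < qd_min | s$fs > fs_max | s$mq < mq_min
  out <- subset_sites(table, !fail)
  masked <- 0L
  if (!is.null(out$gq)) {
    mask <- !is.na(out$gq) & out$gq < gq_min & !is.na(out$geno)
    masked <- sum(mask)
    out$geno[mask] <- NA_integer_
  }
  out$log$hard_filter_sites_removed <- sum(fail)
  out$log$hard_filter_genotypes_masked <- masked
  out$log$snp_cluster_filter <- "not applied (window clause unimplemented)"
  out
}

#' Remove low minor-allele-frequency sites
#'
#' Minor allele frequency is computed over non-missing alleles with all
#' samples pooled; sites with MAF strictly below the threshold are removed
#' (a site at exactly the threshold is retained). Sites where every
#' genotype is missing are removed and logged.
#'
#' @param table a \code{variant_table}.
#' @param threshold MAF cutoff, default 0.05.
#' @return the filtered \code{variant_table}.
#' @export
maf_filter <- function(table, threshold = 0.05) {
  ac <- rowSums(table$geno, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(table$geno))
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= threshold
  out <- subset_sites(table, keep)
  out$log$maf_removed <- sum(!is.na(maf) & maf < threshold)
  out$log$all_missing_removed <- sum(is.na(maf))
  out
}

#' Transition/transversion ratio
#'
#' Transitions are the purine--purine and pyrimidine--pyrimidine changes
#' (A<->G, C<->T); transversions are all other REF/ALT substitutions.
#'
#' @param table a \code{variant_table}.
#' @return the ts/tv ratio. With zero transversions the ratio is undefined
#'   and an error of class \code{sweepscan_no_transversions} is signalled.
#' @export
tstv_ratio <- function(table) {
  pair <- paste0(table$sites$ref, table$sites$alt)
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  n_tv <- sum(!ts)
  if (n_tv == 0)
    stop(errorCondition("ts/tv undefined: zero transversions",
                        class = c("sweepscan_no_transversions", "error",
                                  "condition")))
  sum(ts) / n_tv
}

#' Ratio of nonsynonymous to synonymous substitution counts
#'
#' @param n_nonsynonymous,n_synonymous substitution counts.
#' @return \code{n_nonsynonymous / n_synonymous}.
#' @export
substitution_ratio <- function(n_nonsynonymous, n_synonymous) {
  check(n_synonymous > 0, "synonymous count must be positive")
  n_nonsynonymous / n_synonymous
}
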