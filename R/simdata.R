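#' Configure a synthetic multi-population cohort
#'
#' Builds a validated configuration for [simulate_cohort()]. The generator
#' draws ancestral allele frequencies from a neutral-SFS-like law
#' (probability proportional to 1/i over ancestral allele counts), diverges
#' populations under the Balding--Nichols model
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} with divergence parameter
#' \code{background_fst}, and implants selective sweeps by displacing the
#' target population's allele frequencies toward fixation so that expected
#' heterozygosity inside the sweep interval is multiplied by
#' \code{1 - diversity_reduction}.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop diploid samples per population.
#' @param chrom_lengths numeric vector of chromosome lengths in bp;
#'   names are used as chromosome ids (defaults \code{chr1, chr2, ...}).
#' @param n_sites total number of polymorphic sites to place.
#' @param background_fst Balding--Nichols divergence parameter F, in (0,1).
#' @param sweeps \code{NULL} or a data.frame with columns \code{pop}
#'   (population id, 1-based), \code{chrom}, \code{start}, \code{end}
#'   (1-based inclusive bp) and \code{diversity_reduction} in [0,1).
#' @param causal \code{NULL} or a list with \code{sweep} (row index into
#'   \code{sweeps}), \code{n_causal} and \code{penetrance} in [0.5,1].
#' @param qc_fail_rate fraction of sites/genotypes drawn to fail each VCF
#'   hard-filter annotation (QD, FS, MQ, GQ), exercising the filter stage.
#' @param seed integer seed; fully determines every draw.
#' @return an object of class \code{sim_config}.
#' @seealso [simulate_cohort()], [simulate_phenotypes()], [write_cohort()]
#' @export
sim_config <- function(n_pops = 2, samples_per_pop = 20,
                       chrom_lengths = 5e6, n_sites = 5000,
                       background_fst = 0.05, sweeps = NULL, causal = NULL,
                       qc_fail_rate = 0.02, seed = 1) {
  check(is_count(n_pops) && n_pops >= 1, "n_pops must be a positive integer")
  check(is_count(samples_per_pop), "samples_per_pop must be a positive integer")
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  check(is.numeric(chrom_lengths) && all(chrom_lengths >= 1),
        "chrom_lengths must be positive")
  if (is.list(sweeps) && !is.data.frame(sweeps))
    sweeps <- as.data.frame(lapply(sweeps, unlist), stringsAsFactors = FALSE)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  check(is_count(n_sites), "n_sites must be a positive integer")
  check(is.numeric(background_fst) && background_fst > 0 && background_fst < 1,
        "background_fst must lie in (0,1)")
  check(is.numeric(qc_fail_rate) && qc_fail_rate >= 0 && qc_fail_rate < 1,
        "qc_fail_rate must lie in [0,1)")
  if (!is.null(sweeps)) {
    check(is.data.frame(sweeps) &&
            all(c("pop", "chrom", "start", "end", "diversity_reduction") %in%
                  names(sweeps)),
          "sweeps needs columns pop, chrom, start, end, diversity_reduction")
    check(all(sweeps$pop %in% seq_len(n_pops)), "sweep pop out of range")
    check(all(sweeps$chrom %in% names(chrom_lengths)),
          "sweep chrom not in chrom_lengths")
    check(all(sweeps$start >= 1 & sweeps$end <= chrom_lengths[sweeps$chrom] &
                sweeps$start < sweeps$end),
          "sweep intervals must lie within their chromosome")
    check(all(sweeps$diversity_reduction >= 0 & sweeps$diversity_reduction < 1),
          "diversity_reduction must lie in [0,1)")
  }
  if (!is.null(causal)) {
    check(!is.null(sweeps), "causal spec requires sweeps")
    check(is.list(causal) && all(c("sweep", "n_causal", "penetrance") %in% names(causal)),
          "causal needs fields sweep, n_causal, penetrance")
    check(causal$sweep %in% seq_len(nrow(sweeps)), "causal$sweep out of range")
    check(is_count(causal$n_causal), "n_causal must be a positive integer")
    check(causal$penetrance >= 0.5 && causal$penetrance <= 1,
          "penetrance must lie in [0.5,1]")
  }
  check(is_count(abs(seed) + 1), "seed must be an integer")
  structure(list(n_pops = as.integer(n_pops),
                 samples_per_pop = as.integer(samples_per_pop),
                 chrom_lengths = chrom_lengths, n_sites = as.integer(n_sites),
                 background_fst = background_fst, sweeps = sweeps,
                 causal = causal, qc_fail_rate = qc_fail_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Displace an allele frequency toward the nearer boundary of {0,1} so that
# expected heterozygosity 2q(1-q) is multiplied by (1 - reduction).
# Exact closed form: q' = (1 +- sqrt(1 - 4(1-r)q(1-q))) / 2.
squeeze_het <- function(q, reduction) {
  disc <- sqrt(pmax(0, 1 - 4 * (1 - reduction) * q * (1 - q)))
  ifelse(q <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
}

#' Simulate a diverged multi-population diploid cohort
#'
#' Draws site positions uniformly along chromosomes, ancestral frequencies
#' from the 1/i neutral-spectrum law over a pool of all sampled chromosomes,
#' per-population frequencies from the Balding--Nichols Beta, applies any
#' configured sweeps, and samples diploid genotypes binomially. VCF-style
#' quality annotations (QD, FS, MQ per site; GQ per genotype) are drawn so a
#' configurable fraction fails each hard filter.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements \code{table} (a \code{variant_table}) and
#'   \code{truth} (a \code{sim_truth} carrying ancestral and per-population
#'   frequencies, sweep coordinates and causal site ids).
#' @export
simulate_cohort <- function(config) {
  check(inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, {
    cl <- config$chrom_lengths
    # allocate site counts proportional to chromosome length (largest remainder)
    raw <- config$n_sites * cl / sum(cl)
    n_per <- floor(raw)
    left <- config$n_sites - sum(n_per)
    if (left > 0) {
      ord <- order(raw - n_per, decreasing = TRUE)
      n_per[ord[seq_len(left)]] <- n_per[ord[seq_len(left)]] + 1L
    }
    chrom <- rep(names(cl), n_per)
    pos <- unlist(lapply(seq_along(cl), function(i) {
      if (n_per[i] == 0L) return(integer())
      sort(sample.int(cl[i], n_per[i]))
    }), use.names = FALSE)
    n_sites <- length(pos)

    n_hap <- 2L * config$n_pops * config$samples_per_pop
    # neutral-SFS-like ancestral counts: P(i) proportional to 1/i, i in 1..n_hap-1
    i <- sample.int(n_hap - 1L, n_sites, replace = TRUE,
                    prob = 1 / seq_len(n_hap - 1L))
    p_anc <- i / n_hap

    f <- config$background_fst
    scale <- (1 - f) / f
    pop_freq <- matrix(0, n_sites, config$n_pops)
    for (k in seq_len(config$n_pops))
      pop_freq[, k] <- stats::rbeta(n_sites, p_anc * scale, (1 - p_anc) * scale)

    sweep_sites <- vector("list", if (is.null(config$sweeps)) 0L else nrow(config$sweeps))
    if (!is.null(config$sweeps)) {
      for (s in seq_len(nrow(config$sweeps))) {
        sw <- config$sweeps[s, ]
        idx <- which(chrom == sw$chrom & pos >= sw$start & pos <= sw$end)
        if (length(idx) == 0L)
          stop("sweep interval ", sw$chrom, ":", sw$start, "-", sw$end,
               " contains zero sites", call. = FALSE)
        pop_freq[idx, sw$pop] <- squeeze_het(pop_freq[idx, sw$pop],
                                             sw$diversity_reduction)
        sweep_sites[[s]] <- idx
      }
    }

    n_samp <- config$n_pops * config$samples_per_pop
    geno <- matrix(0L, n_sites, n_samp)
    for (k in seq_len(config$n_pops)) {
      cols <- (k - 1L) * config$samples_per_pop + seq_len(config$samples_per_pop)
      g <- stats::rbinom(n_sites * config$samples_per_pop, 2L,
                         rep(pop_freq[, k], config$samples_per_pop))
      geno[, cols] <- matrix(g, n_sites, config$samples_per_pop)
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

    # quality annotations: a qc_fail_rate slice fails each filter clause
    fr <- config$qc_fail_rate
    bad_qd <- stats::runif(n_sites) < fr
    qd <- ifelse(bad_qd, stats::runif(n_sites, 0, 1.99), stats::runif(n_sites, 5, 35))
    bad_fs <- stats::runif(n_sites) < fr
    fs <- ifelse(bad_fs, stats::runif(n_sites, 60.01, 120), stats::runif(n_sites, 0, 30))
    bad_mq <- stats::runif(n_sites) < fr
    mq <- ifelse(bad_mq, stats::runif(n_sites, 10, 39.9), stats::runif(n_sites, 40, 60))
    bad_gq <- stats::runif(n_sites * n_samp) < fr
    gq <- matrix(ifelse(bad_gq, sample(0:19, n_sites * n_samp, replace = TRUE),
                        sample(20:99, n_sites * n_samp, replace = TRUE)),
                 n_sites, n_samp)

    pops <- rep(paste0("pop", seq_len(config$n_pops)), each = config$samples_per_pop)
    ids <- paste0(pops, "_", rep(seq_len(config$samples_per_pop), config$n_pops))
    colnames(geno) <- ids
    colnames(gq) <- ids

    site_id <- paste0(chrom, ":", pos)
    table <- variant_table(
      sites = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = alt, qd = round(qd, 2), fs = round(fs, 2),
                         mq = round(mq, 2), stringsAsFactors = FALSE),
      geno = geno, gq = gq,
      samples = data.frame(id = ids, pop = pops, stringsAsFactors = FALSE))

    causal_sites <- integer()
    if (!is.null(config$causal)) {
      cs <- config$causal
      idx <- sweep_sites[[cs$sweep]]
      ac <- rowSums(geno[idx, , drop = FALSE])
      an <- 2L * n_samp
      maf <- pmin(ac / an, 1 - ac / an)
      seg <- idx[maf > 0]
      check(length(seg) >= cs$n_causal,
            "not enough segregating sites in the causal sweep interval")
      # most informative segregating sites: pooled MAF nearest 0.5
      causal_sites <- seg[order(abs(maf[maf > 0] - 0.5))][seq_len(cs$n_causal)]
    }

    truth <- structure(list(p_anc = p_anc, pop_freq = pop_freq,
                            site_chrom = chrom, site_pos = as.integer(pos),
                            site_id = site_id, sweeps = config$sweeps,
                            sweep_sites = sweep_sites,
                            causal_sites = causal_sites, config = config),
                       class = "sim_truth")
    list(table = table, truth = truth)
  })
}

#' Simulate a genotype-driven binary phenotype
#'
#' Labels each sample \code{case} with probability equal to the penetrance if
#' it carries at least one derived (ALT) allele at any causal site, and with
#' probability \code{1 - penetrance} otherwise. With penetrance 1 the labels
#' equal carrier status exactly; with penetrance 0.5 they are independent of
#' genotype.
#'
#' @param table the \code{variant_table} from [simulate_cohort()].
#' @param truth the matching \code{sim_truth} (supplies the causal sites).
#' @param penetrance overrides the configured penetrance; in [0.5,1].
#' @param seed RNG seed; defaults to the cohort seed + 1 so cohort and
#'   phenotype draws are distinct but jointly determined by the config.
#' @return data.frame with columns \code{sample_id} and \code{status}
#'   (\code{"case"}/\code{"control"}), plus a \code{carrier} logical column.
#' @export
simulate_phenotypes <- function(table, truth, penetrance = NULL, seed = NULL) {
  check(inherits(truth, "sim_truth"), "truth must come from simulate_cohort()")
  check(length(truth$causal_sites) > 0, "no causal sites in truth")
  if (is.null(penetrance)) penetrance <- truth$config$causal$penetrance
  check(penetrance >= 0.5 && penetrance <= 1, "penetrance must lie in [0.5,1]")
  if (is.null(seed)) seed <- truth$config$seed + 1L
  idx <- match(truth$site_id[truth$causal_sites],
               paste0(table$sites$chrom, ":", table$sites$pos))
  idx <- idx[!is.na(idx)]
  check(length(idx) > 0, "causal sites absent from the supplied table")
  g <- table$geno[idx, , drop = FALSE]
  carrier <- apply(g, 2, function(x) any(!is.na(x) & x > 0))
  with_seed(seed, {
    p_case <- ifelse(carrier, penetrance, 1 - penetrance)
    status <- ifelse(stats::runif(length(carrier)) < p_case, "case", "control")
    data.frame(sample_id = table$samples$id, status = status,
               carrier = unname(carrier), stringsAsFactors = FALSE)
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulation config:", x$n_pops, "populations x",
      x$samples_per_pop, "diploids,", x$n_sites, "sites on",
      length(x$chrom_lengths), "chromosome(s)\n")
  cat("  background Fst:", x$background_fst, " seed:", x$seed, "\n")
  if (!is.null(x$sweeps)) cat("  sweeps:", nrow(x$sweeps), "\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$p_anc), "sites,",
      ncol(x$pop_freq), "populations")
  if (!is.null(x$sweeps)) cat(",", nrow(x$sweeps), "sweep(s)")
  if (length(x$causal_sites)) cat(",", length(x$causal_sites), "causal site(s)")
  cat("\n")
  invisible(x)
}
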