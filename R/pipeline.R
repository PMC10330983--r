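#' Run the full sweep-discovery pipeline
#'
#' Orchestrates simulate (or load) -> hard filter -> MAF filter ->
#' annotation summary -> per-comparison window statistics and sweep scans
#' -> shared regions -> structure summaries (NJ tree, PCA) -> optional
#' association and haplotype-block follow-up -> optional gene-set
#' enrichment, writing every stage's output plus a machine-readable
#' summary and a log into one run directory. A fixed seed makes the whole
#' run, including the summary JSON, byte-reproducible.
#'
#' @param config a list, or path to a YAML/JSON file, with elements:
#'   \describe{
#'     \item{simulate}{arguments for [sim_config()] (exclusive with
#'       \code{inputs}).}
#'     \item{inputs}{paths: vcf, pop_map (TSV id/pop), gff, fasta, pheno,
#'       gmt — vcf and pop_map required, the rest optional.}
#'     \item{comparisons}{list of lists with \code{control} (ratio
#'       numerator A), \code{case} (denominator B), optional \code{mode}
#'       (ratio tail, default "right") and \code{label}.}
#'     \item{window, step, tail_fraction, maf, flank, fdr}{scan settings;
#'       defaults 20000, 5000, 0.05, 0.05, 1000, 0.05.}
#'   }
#' @param out_dir run directory (created); default a fresh temp directory.
#' @return object of class \code{sweepscan_run}: the summary list with the
#'   run directory and per-stage objects attached.
#' @export
run_pipeline <- function(config, out_dir = tempfile("sweepscan_run_")) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
              else yaml::read_yaml(config)
  }
  check(xor(is.null(config$simulate), is.null(config$inputs)),
        "config needs exactly one of 'simulate' or 'inputs'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logfile <- file.path(out_dir, "log.txt")
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  def <- function(x, d) if (is.null(x)) d else x
  window <- def(config$window, 20000); step <- def(config$step, 5000)
  tail_fraction <- def(config$tail_fraction, 0.05)
  maf <- def(config$maf, 0.05); flank <- def(config$flank, 1000)
  fdr <- def(config$fdr, 0.05)
  summary <- list(settings = list(window = window, step = step,
                                  tail_fraction = tail_fraction, maf = maf,
                                  flank = flank, fdr = fdr))

  # ---- inputs ------------------------------------------------------------
  truth <- NULL; genes <- NULL; fasta <- NULL; pheno <- NULL; gmt <- NULL
  if (!is.null(config$simulate)) {
    sc <- stage("simulate", do.call(sim_config, config$simulate))
    sim <- stage("simulate", simulate_cohort(sc))
    table <- sim$table; truth <- sim$truth
    chrom_lengths <- sc$chrom_lengths
    if (!is.null(sc$causal))
      pheno <- stage("simulate", simulate_phenotypes(table, truth))
    files <- stage("simulate",
                   write_cohort(table, truth, file.path(out_dir, "data"),
                                phenotypes = pheno))
    genes <- read_gene_model(files["gff"], flank = flank)
    fasta <- Biostrings::readDNAStringSet(files["fasta"])
    names(fasta) <- sub("\\s.*$", "", names(fasta))
    log("simulated cohort: ", nrow(table$sites), " sites, ",
        nrow(table$samples), " samples, seed ", sc$seed)
  } else {
    inp <- config$inputs
    pm <- utils::read.delim(inp$pop_map, stringsAsFactors = FALSE)
    table <- stage("read_vcf", read_vcf(inp$vcf, pop_map = pm))
    chrom_lengths <- tapply(table$sites$pos, table$sites$chrom, max) + window
    if (!is.null(inp$gff)) genes <- read_gene_model(inp$gff, flank = flank)
    if (!is.null(inp$fasta)) fasta <- Biostrings::readDNAStringSet(inp$fasta)
    if (!is.null(inp$pheno))
      pheno <- utils::read.delim(inp$pheno, stringsAsFactors = FALSE)
    if (!is.null(inp$gmt)) gmt <- read_gmt(inp$gmt)
    log("loaded VCF: ", nrow(table$sites), " sites, ", nrow(table$samples),
        " samples")
  }
  if (!is.null(config$simulate) && !is.null(config$gmt_file))
    gmt <- read_gmt(config$gmt_file)
  summary$n_sites_raw <- nrow(table$sites)

  # ---- filtering ---------------------------------------------------------
  table <- stage("hard_filter", hard_filter(table))
  summary$hard_filter <- table$log[c("hard_filter_sites_removed",
                                     "hard_filter_genotypes_masked")]
  table <- stage("maf_filter", maf_filter(table, maf))
  summary$maf_removed <- table$log$maf_removed
  summary$n_sites_filtered <- nrow(table$sites)
  log("filtered: ", nrow(table$sites), " sites retained")
  write_vcf(table, file.path(out_dir, "filtered.vcf"),
            chrom_lengths = chrom_lengths)

  # ---- annotation summary ------------------------------------------------
  summary$tstv <- tryCatch(tstv_ratio(table), error = function(e) NA_real_)
  if (!is.null(genes)) {
    cls <- stage("classify", classify_sites(table, genes))
    summary$site_classes <- as.list(cls$counts)
    if (!is.null(fasta)) {
      cons <- stage("consequence", consequence(table, genes, fasta))
      summary$consequence <- list(nonsynonymous = cons$n_nonsynonymous,
                                  synonymous = cons$n_synonymous,
                                  ratio = cons$ratio)
    }
  }

  # ---- per-comparison scans ----------------------------------------------
  grid <- make_windows(chrom_lengths, window, step)
  scans <- list()
  if (!is.null(config$comparisons)) {
    for (cmp in config$comparisons) {
      lab <- def(cmp$label, paste0(cmp$control, "_vs_", cmp$case))
      st <- stage(paste0("scan:", lab),
                  window_stats(table, grid, cmp$control, cmp$case))
      scan <- stage(paste0("scan:", lab),
                    sweep_scan(st, genes = genes, fraction = tail_fraction,
                               mode = def(cmp$mode, "right"), label = lab))
      scans[[lab]] <- scan
      utils::write.table(st, file.path(out_dir, paste0("windows_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bed <- scan$regions
      if (nrow(bed))
        utils::write.table(
          data.frame(bed$chrom, format(bed$start, scientific = FALSE, trim = TRUE),
                     format(bed$end, scientific = FALSE, trim = TRUE)),
          file.path(out_dir, paste0("regions_", lab, ".bed")),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      if (!is.null(scan$genes))
        writeLines(scan$genes, file.path(out_dir, paste0("genes_", lab, ".txt")))
      summary$comparisons[[lab]] <- list(
        thresholds = scan$thresholds[c("fst", "ratio_left", "ratio_right")],
        n_windows = nrow(st), n_selected = nrow(scan$selected),
        n_regions = nrow(scan$regions), n_genes = length(scan$genes),
        genomewide_fst = attr(st, "genomewide_fst"))
      log("scan ", lab, ": ", nrow(scan$selected), " windows -> ",
          nrow(scan$regions), " regions")
    }
    if (length(scans) >= 2) {
      sh <- stage("shared_regions",
                  shared_regions(lapply(scans, `[[`, "regions"),
                                 gene_sets = if (!is.null(genes))
                                   lapply(scans, `[[`, "genes")))
      summary$shared <- list(n_shared_regions = nrow(sh$shared),
                             n_shared_genes = length(sh$shared_genes),
                             venn_regions = sh$venn_regions,
                             venn_genes = sh$venn_genes)
      if (nrow(sh$shared))
        utils::write.table(
          data.frame(sh$shared$chrom,
                     format(sh$shared$start, scientific = FALSE, trim = TRUE),
                     format(sh$shared$end, scientific = FALSE, trim = TRUE)),
          file.path(out_dir, "shared_regions.bed"),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }

  # ---- population structure ----------------------------------------------
  if (nrow(table$samples) >= 3) {
    tree <- stage("nj", nj_tree(pairwise_distance(table)))
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  }
  pca <- tryCatch(pca_genotypes(table, maf_threshold = maf),
                  error = function(e) NULL)
  if (!is.null(pca)) {
    utils::write.table(
      data.frame(sample = rownames(pca$scores), pop = pca$pops,
                 pca$scores[, 1:min(4, ncol(pca$scores))]),
      file.path(out_dir, "pca.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    summary$pca_varexp <- pca$varexp[1:min(4, length(pca$varexp))]
  }

  # ---- association follow-up ---------------------------------------------
  if (!is.null(pheno)) {
    assoc <- stage("association", snp_association(table, pheno))
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- assoc[which.min(assoc$p), ]
    summary$association <- list(n_tested = nrow(assoc),
                                top_snp = paste0(top$chrom, ":", top$pos),
                                top_p = top$p, top_q = top$q)
    # haplotype block around the top hit: nearest neighbours by position
    chrom_idx <- which(table$sites$chrom == top$chrom)
    ord <- chrom_idx[order(abs(table$sites$pos[chrom_idx] - top$pos))]
    cand <- sort(utils::head(ord, 5))
    blk <- tryCatch(haplotype_block(table, cand, phenotypes = pheno),
                    error = function(e) NULL)
    if (!is.null(blk)) {
      summary$haplotype_block <- list(
        chrom = blk$chrom, start = blk$interval[1], end = blk$interval[2],
        n_snps = length(blk$snp_idx), n_haplotypes = length(blk$freq),
        freq = as.list(blk$freq))
      log("haplotype block: ", length(blk$freq), " haplotypes over ",
          length(blk$snp_idx), " SNPs")
    }
  }

  # ---- enrichment --------------------------------------------------------
  if (!is.null(gmt) && length(scans) && !is.null(genes)) {
    cand_genes <- unique(unlist(lapply(scans, `[[`, "genes")))
    if (length(cand_genes)) {
      enr <- stage("enrichment",
                   ora(cand_genes, gmt, universe = genes$genes$gene_id,
                       alpha = fdr))
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$enrichment <- list(n_pathways = nrow(enr),
                                 n_significant = sum(enr$significant))
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  log("done")
  structure(list(summary = summary, dir = out_dir, table = table,
                 truth = truth, scans = scans, pheno = pheno),
            class = "sweepscan_run")
}

#' @export
print.sweepscan_run <- function(x, ...) {
  cat("sweepscan pipeline run in", x$dir, "\n")
  cat("  sites:", x$summary$n_sites_raw, "raw ->",
      x$summary$n_sites_filtered, "filtered\n")
  for (lab in names(x$summary$comparisons)) {
    cm <- x$summary$comparisons[[lab]]
    cat("  ", lab, ": ", cm$n_selected, " windows, ", cm$n_regions,
        " regions, ", cm$n_genes, " genes\n", sep = "")
  }
  if (!is.null(x$summary$shared))
    cat("  shared regions:", x$summary$shared$n_shared_regions,
        " shared genes:", x$summary$shared$n_shared_genes, "\n")
  invisible(x)
}
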