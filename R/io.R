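# Plain-text writers for the formats the simulator and pipeline emit.
# Reading always goes through the established parsers (vcfR, rtracklayer,
# Biostrings); these writers exist because the generator must control
# every byte of its fixtures.

#' Write a variant table as VCF v4.2
#'
#' Emits contig headers, the QD/FS/MQ INFO keys and GT:GQ genotypes.
#'
#' @param table a \code{variant_table}.
#' @param path output file.
#' @param chrom_lengths optional named lengths for contig header lines.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(table, path, chrom_lengths = NULL) {
  s <- table$sites
  hdr <- c("##fileformat=VCFv4.2", "##source=sweepscan")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                          as.integer(chrom_lengths)))
  hdr <- c(hdr,
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", table$samples$id), collapse = "\t"))
  info <- sprintf("QD=%.2f;FS=%.2f;MQ=%.2f", s$qd, s$fs, s$mq)
  info[is.na(s$qd) & is.na(s$fs) & is.na(s$mq)] <- "."
  gt_str <- matrix(".:.", nrow(s), ncol(table$geno))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gq <- table$gq
  for (j in seq_len(ncol(table$geno))) {
    g <- table$geno[, j]
    q <- if (is.null(gq)) rep(99L, length(g)) else gq[, j]
    gt_str[, j] <- ifelse(is.na(g), "./.:.",
                          paste0(code[as.character(g)], ":",
                                 ifelse(is.na(q), ".", as.integer(q))))
  }
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, "100", "PASS", info,
                "GT:GQ", apply(gt_str, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a gene model as GFF3
#'
#' @param genes a \code{gene_model}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  g <- genes$genes; cc <- genes$cds
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    lines <- c(lines,
               paste(g$chrom[i], "sweepscan", "gene", g$start[i], g$end[i],
                     ".", g$strand[i], ".", paste0("ID=", g$gene_id[i]),
                     sep = "\t"))
    d <- cc[cc$gene_id == g$gene_id[i], , drop = FALSE]
    for (r in seq_len(nrow(d)))
      lines <- c(lines,
                 paste(d$chrom[r], "sweepscan", "CDS", d$start[r], d$end[r],
                       ".", d$strand[r], d$phase[r],
                       paste0("ID=", g$gene_id[i], ".cds", r, ";Parent=",
                              g$gene_id[i]),
                       sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Tile a simple gene model along the simulated chromosomes: one gene every
# `every` bp, two CDS segments per gene with summed length divisible by 3
# and correct phases, strands alternating to exercise reverse-complement
# consequence calls.
tile_genes <- function(chrom_lengths, every = 10000, gene_len = 3000,
                       flank = 1000) {
  genes <- list(); cds <- list()
  gi <- 0L
  for (ch in names(chrom_lengths)) {
    starts <- seq(1, max(1, chrom_lengths[[ch]] - gene_len), by = every)
    for (s in starts) {
      gi <- gi + 1L
      id <- paste0("gene", gi)
      strand <- if (gi %% 2 == 0) "-" else "+"
      e <- s + gene_len - 1
      genes[[gi]] <- data.frame(gene_id = id, chrom = ch, start = s, end = e,
                                strand = strand, stringsAsFactors = FALSE)
      # two CDS segments, 301 + 302 = 603 bp (divisible by 3)
      c1 <- c(s + 200, s + 500)      # length 301
      c2 <- c(s + 1000, s + 1301)    # length 302
      segs <- list(c1, c2)
      if (strand == "-") segs <- rev(segs)   # transcription order
      ph <- c(0L, (3L - (segs[[1]][2] - segs[[1]][1] + 1L) %% 3L) %% 3L)
      if (strand == "-") { segs <- rev(segs); ph <- rev(ph) }  # back to genomic order
      cds[[gi]] <- data.frame(gene_id = id, chrom = ch,
                              start = c(segs[[1]][1], segs[[2]][1]),
                              end = c(segs[[1]][2], segs[[2]][2]),
                              strand = strand, phase = ph,
                              stringsAsFactors = FALSE)
    }
  }
  gene_model(do.call(rbind, genes), do.call(rbind, cds), flank = flank)
}

#' Write a simulated cohort as standard files
#'
#' Emits, into \code{dir}: \code{cohort.vcf} (QD/FS/MQ INFO and GT:GQ
#' genotypes), \code{genes.gff3} (genes tiled over the chromosomes with
#' frame-consistent CDS), \code{reference.fa} (random sequence overwritten
#' with the VCF REF allele at every site, so REF always matches),
#' \code{populations.tsv}, \code{phenotypes.tsv} when phenotypes are given,
#' and \code{truth.json}.
#'
#' @param table a \code{variant_table} from [simulate_cohort()].
#' @param truth the matching \code{sim_truth}.
#' @param dir output directory (created if needed).
#' @param phenotypes optional phenotype table from [simulate_phenotypes()].
#' @param gene_every,gene_len gene tiling parameters for the GFF3.
#' @return named character vector of the files written.
#' @export
write_cohort <- function(table, truth, dir, phenotypes = NULL,
                         gene_every = 10000, gene_len = 3000) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  check(file.access(dir, 2) == 0, paste0("directory not writable: ", dir))
  cl <- truth$config$chrom_lengths
  files <- c(vcf = file.path(dir, "cohort.vcf"),
             gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "reference.fa"),
             pops = file.path(dir, "populations.tsv"),
             truth = file.path(dir, "truth.json"))

  write_vcf(table, files["vcf"], chrom_lengths = cl)

  genes <- tile_genes(cl, every = gene_every, gene_len = gene_len)
  write_gff3(genes, files["gff"])

  # reference consistent with REF alleles, deterministic given the config seed
  seqs <- with_seed(truth$config$seed + 2L, {
    lapply(stats::setNames(nm = names(cl)), function(ch) {
      x <- sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE)
      idx <- table$sites$chrom == ch
      x[table$sites$pos[idx]] <- table$sites$ref[idx]
      paste(x, collapse = "")
    })
  })
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)),
                              files["fasta"], width = 80)

  utils::write.table(table$samples, files["pops"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(phenotypes)) {
    files["pheno"] <- file.path(dir, "phenotypes.tsv")
    utils::write.table(phenotypes[, c("sample_id", "status")], files["pheno"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth_json <- list(
    n_sites = length(truth$p_anc),
    sweeps = truth$sweeps,
    causal_sites = truth$site_id[truth$causal_sites],
    p_anc = truth$p_anc, pop_freq = truth$pop_freq,
    seed = truth$config$seed)
  jsonlite::write_json(truth_json, files["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  files
}
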