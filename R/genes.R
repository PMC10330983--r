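#' Construct a gene model
#'
#' Holds gene intervals and their CDS segments on a shared reference
#' coordinate system (1-based, closed, as in GFF3). Used for site
#' classification, codon-level consequence calls and candidate-gene
#' intersection. Per-gene summed CDS length must be divisible by 3.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param cds data.frame with columns gene_id, chrom, start, end, strand,
#'   phase; may be empty for annotation-free intervals.
#' @param flank upstream/downstream flank size in bp used by
#'   [classify_sites()]; default 1,000 (the conventional annotator default).
#' @return an object of class \code{gene_model}.
#' @export
gene_model <- function(genes, cds = NULL, flank = 1000) {
  check(is.data.frame(genes) &&
          all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
        "genes needs columns gene_id, chrom, start, end, strand")
  if (is.null(cds))
    cds <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      phase = integer(), stringsAsFactors = FALSE)
  check(all(cds$gene_id %in% genes$gene_id), "CDS references unknown gene")
  if (nrow(cds)) {
    gi <- match(cds$gene_id, genes$gene_id)
    check(all(cds$start >= genes$start[gi] & cds$end <= genes$end[gi]),
          "CDS segments must lie within gene bounds")
    len <- tapply(cds$end - cds$start + 1, cds$gene_id, sum)
    check(all(len %% 3 == 0), "per-gene summed CDS length must be divisible by 3")
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, cds = cds, flank = flank), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,", nrow(x$cds),
      "CDS segments, flank", x$flank, "bp\n")
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Imports \code{gene} and \code{CDS} features; CDS segments are linked to
#' genes through their \code{Parent} attribute (directly, or via an
#' intermediate mRNA feature).
#'
#' @param path GFF3 file.
#' @inheritParams gene_model
#' @return a \code{gene_model}.
#' @export
read_gene_model <- function(path, flank = 1000) {
  check(file.exists(path), paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  first_chr <- function(x) vapply(x, function(v) if (length(v)) v[1] else NA_character_, "")

  g <- gr[typ == "gene"]
  genes <- data.frame(gene_id = as.character(g$ID),
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      start = GenomicRanges::start(g),
                      end = GenomicRanges::end(g),
                      strand = as.character(GenomicRanges::strand(g)),
                      stringsAsFactors = FALSE)

  # map transcript ids to gene ids so CDS with mRNA parents resolve
  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx_parent <- if (length(tx)) stats::setNames(first_chr(tx$Parent),
                                               as.character(tx$ID)) else character()
  cc <- gr[typ == "CDS"]
  parent <- first_chr(cc$Parent)
  parent <- ifelse(parent %in% names(tx_parent), tx_parent[parent], parent)
  ph <- if (!is.null(cc$phase)) suppressWarnings(as.integer(as.character(cc$phase)))
        else rep(NA_integer_, length(cc))
  cds <- data.frame(gene_id = parent,
                    chrom = as.character(GenomicRanges::seqnames(cc)),
                    start = GenomicRanges::start(cc),
                    end = GenomicRanges::end(cc),
                    strand = as.character(GenomicRanges::strand(cc)),
                    phase = ph, stringsAsFactors = FALSE)
  gene_model(genes, cds, flank = flank)
}

#' Classify SNP sites by genic context
#'
#' Each site gets exactly one label from \{exonic, UTR, intronic, upstream,
#' downstream, intergenic\} with precedence exonic > UTR > intronic >
#' upstream > downstream > intergenic. Exonic means inside a CDS segment;
#' UTR means inside the gene body but outside the span of its CDS; intronic
#' is the remainder of the gene body; upstream/downstream are within
#' \code{flank} bp of the transcription start/end, respecting strand. Sites
#' on chromosomes absent from the model are intergenic.
#'
#' @param table a \code{variant_table}.
#' @param genes a \code{gene_model}.
#' @return a list with \code{class} (factor per site), \code{counts} and
#'   \code{proportions} over the six labels.
#' @export
classify_sites <- function(table, genes) {
  lv <- c("exonic", "UTR", "intronic", "upstream", "downstream", "intergenic")
  n <- nrow(table$sites)
  site_gr <- GenomicRanges::GRanges(table$sites$chrom,
                                    IRanges::IRanges(table$sites$pos, width = 1))
  hit <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(rep(FALSE, n))
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
    suppressWarnings(
      GenomicRanges::countOverlaps(site_gr, gr, ignore.strand = TRUE) > 0)
  }

  g <- genes$genes; cc <- genes$cds; fl <- genes$flank
  # UTR intervals: gene body outside the CDS span, for genes that have CDS
  utr <- NULL
  if (nrow(cc)) {
    span <- do.call(rbind, lapply(split(cc, cc$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1], lo = min(d$start), hi = max(d$end))))
    gi <- match(span$gene_id, g$gene_id)
    left <- data.frame(chrom = g$chrom[gi], start = g$start[gi], end = span$lo - 1)
    right <- data.frame(chrom = g$chrom[gi], start = span$hi + 1, end = g$end[gi])
    utr <- rbind(left[left$start <= left$end, ], right[right$start <= right$end, ])
  }
  up_start <- ifelse(g$strand == "-", g$end + 1, pmax(1, g$start - fl))
  up_end   <- ifelse(g$strand == "-", g$end + fl, g$start - 1)
  dn_start <- ifelse(g$strand == "-", pmax(1, g$start - fl), g$end + 1)
  dn_end   <- ifelse(g$strand == "-", g$start - 1, g$end + fl)

  cls <- rep("intergenic", n)
  ok <- function(s, e) data.frame(chrom = g$chrom, start = s, end = e)[s <= e, ]
  cls[hit(ok(dn_start, dn_end))] <- "downstream"
  cls[hit(ok(up_start, up_end))] <- "upstream"
  cls[hit(g[, c("chrom", "start", "end")])] <- "intronic"
  cls[hit(utr)] <- "UTR"
  cls[hit(cc[, c("chrom", "start", "end")])] <- "exonic"

  cls <- factor(cls, levels = lv)
  counts <- base::table(cls)
  list(class = cls, counts = counts, proportions = counts / max(1, n))
}

# Per-gene spliced CDS in transcription order plus the genomic position of
# each spliced base, from a DNAStringSet reference.
splice_cds <- function(gene_cds, strand, ref_seq) {
  gene_cds <- gene_cds[order(gene_cds$start), , drop = FALSE]
  segs <- lapply(seq_len(nrow(gene_cds)), function(i)
    seq.int(gene_cds$start[i], gene_cds$end[i]))
  pos <- unlist(segs)
  chars <- strsplit(as.character(ref_seq), "")[[1]][pos]
  if (strand == "-") {
    pos <- rev(pos)
    chars <- rev(chartr("ACGT", "TGCA", chars))
  }
  list(pos = pos, seq = chars)
}

#' Call coding consequences of SNPs
#'
#' For every site inside a CDS the surrounding codon is rebuilt from the
#' reference (reverse-complemented for minus-strand genes), the ALT allele
#' substituted, and both codons translated with the standard genetic code.
#' Sites outside CDS are \code{noncoding}. Every site's REF allele is
#' checked against the reference sequence; a mismatch is a hard error
#' naming the site.
#'
#' @param table a \code{variant_table}.
#' @param genes a \code{gene_model} with CDS segments.
#' @param reference a FASTA path or a \code{Biostrings::DNAStringSet}.
#' @return list with \code{class} (factor synonymous/nonsynonymous/noncoding
#'   per site), counts, and the nonsynonymous/synonymous \code{ratio}.
#' @export
consequence <- function(table, genes, reference) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  s <- table$sites
  check(all(s$chrom %in% names(reference)),
        "reference is missing chromosomes present in the table")

  ref_chars <- lapply(stats::setNames(nm = unique(s$chrom)), function(ch)
    strsplit(as.character(reference[[ch]]), "")[[1]])
  fasta_base <- vapply(seq_len(nrow(s)), function(i)
    ref_chars[[s$chrom[i]]][s$pos[i]], "")
  bad <- which(fasta_base != s$ref)
  if (length(bad))
    stop("REF/FASTA mismatch at ", s$chrom[bad[1]], ":", s$pos[bad[1]],
         " (REF ", s$ref[bad[1]], ", FASTA ", fasta_base[bad[1]], ")",
         call. = FALSE)

  code <- Biostrings::GENETIC_CODE
  cls <- rep("noncoding", nrow(s))
  cc <- genes$cds
  if (nrow(cc)) {
    for (gid in unique(cc$gene_id)) {
      d <- cc[cc$gene_id == gid, , drop = FALSE]
      strand <- d$strand[1]
      sp <- splice_cds(d, strand, reference[[d$chrom[1]]])
      idx <- which(s$chrom == d$chrom[1] & s$pos %in% sp$pos)
      for (i in idx) {
        cp <- match(s$pos[i], sp$pos)           # 1-based spliced coordinate
        c0 <- ((cp - 1) %/% 3) * 3
        codon <- sp$seq[(c0 + 1):(c0 + 3)]
        within <- cp - c0
        alt <- s$alt[i]
        if (strand == "-") alt <- chartr("ACGT", "TGCA", alt)
        mutated <- codon
        mutated[within] <- alt
        aa_ref <- code[[paste(codon, collapse = "")]]
        aa_alt <- code[[paste(mutated, collapse = "")]]
        cls[i] <- if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
      }
    }
  }
  cls <- factor(cls, levels = c("synonymous", "nonsynonymous", "noncoding"))
  n_syn <- sum(cls == "synonymous"); n_non <- sum(cls == "nonsynonymous")
  list(class = cls, n_synonymous = n_syn, n_nonsynonymous = n_non,
       ratio = if (n_syn > 0) substitution_ratio(n_non, n_syn) else NA_real_)
}
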