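# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately share no code with the package internals.

# Quick variant_table from a dosage matrix (sites x samples).
toy_table <- function(geno, pops = NULL, chrom = "chr1",
                      pos = seq_len(nrow(geno)) * 100L,
                      ref = rep("A", nrow(geno)), alt = rep("G", nrow(geno)),
                      qd = rep(30, nrow(geno)), fs = rep(1, nrow(geno)),
                      mq = rep(50, nrow(geno)), gq = NULL) {
  n <- ncol(geno)
  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  colnames(geno) <- ids
  if (is.null(pops)) pops <- rep("popA", n)
  variant_table(
    sites = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = alt, qd = qd, fs = fs, mq = mq,
                       stringsAsFactors = FALSE),
    geno = geno, gq = gq,
    samples = data.frame(id = ids, pop = pops, stringsAsFactors = FALSE))
}

# Expand a dosage vector into haploid alleles (0/1), dropping missing.
dosage_to_alleles <- function(g) {
  g <- g[!is.na(g)]
  unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
}

# Brute-force per-site pi: fraction of unordered allele pairs differing.
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + (alleles[i] != alleles[j])
  diffs / choose(n, 2)
}

# Brute-force Hudson Fst components at one site from two allele vectors.
oracle_fst_site <- function(a, b) {
  between <- mean(outer(a, b, `!=`))
  within <- (oracle_site_pi(a) + oracle_site_pi(b)) / 2
  c(between = between, within = within)
}

# Brute-force multi-site Fst (ratio of summed components).
oracle_fst <- function(geno_a, geno_b) {
  bt <- wt <- 0
  for (s in seq_len(nrow(geno_a))) {
    a <- dosage_to_alleles(geno_a[s, ]); b <- dosage_to_alleles(geno_b[s, ])
    if (length(a) < 2 || length(b) < 2) next
    comp <- oracle_fst_site(a, b)
    bt <- bt + comp["between"]; wt <- wt + comp["within"]
  }
  unname((bt - wt) / bt)
}

# Exhaustive 2-SNP haplotype-frequency ML by grid search over the simplex.
# Pairs compatible with each distinct genotype are enumerated once.
oracle_em2_grid <- function(geno, grid_n = 30) {
  hs <- as.matrix(expand.grid(0:1, 0:1))        # 4 haplotypes over 2 SNPs
  key <- apply(geno, 1, paste, collapse = "/")
  ug <- geno[!duplicated(key), , drop = FALSE]
  cnt <- as.numeric(table(key)[apply(ug, 1, paste, collapse = "/")])
  pairs <- lapply(seq_len(nrow(ug)), function(r) {
    g <- ug[r, ]
    keep <- which(outer(1:4, 1:4, Vectorize(function(i, j)
      all(hs[i, ] + hs[j, ] == g))), arr.ind = TRUE)
    matrix(keep, ncol = 2)
  })
  best <- -Inf; bf <- NULL
  for (i in 0:grid_n) for (j in 0:(grid_n - i)) for (k in 0:(grid_n - i - j)) {
    f <- c(i, j, k, grid_n - i - j - k) / grid_n
    ll <- 0; bad <- FALSE
    for (r in seq_along(pairs)) {
      pr <- sum(f[pairs[[r]][, 1]] * f[pairs[[r]][, 2]])
      if (pr <= 0) { bad <- TRUE; break }
      ll <- ll + cnt[r] * log(pr)
    }
    if (!bad && ll > best) { best <- ll; bf <- f }
  }
  list(freq = bf, loglik = best)
}

# Small in-memory VCF text for parser tests.
write_toy_vcf <- function(path, records,
                          samples = c("s1", "s2"),
                          format = "GT:GQ") {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="x">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="x">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Random additive distance matrix from a random topology (oracle for NJ):
# path distances on a random tree are additive by construction.
random_additive <- function(n_taxa, seed) {
  tr <- withr::with_seed(seed, ape::rtree(n_taxa, rooted = FALSE,
                                          br = function(n) runif(n, 0.5, 2)))
  tr$tip.label <- sort(tr$tip.label)
  list(tree = tr, dm = cophenetic(tr))
}

# Consequence oracle: translate the whole spliced CDS with Biostrings for
# REF and ALT sequences and compare proteins.
oracle_consequence <- function(cds_df, strand, chrom_seq, pos, alt) {
  cds_df <- cds_df[order(cds_df$start), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(cds_df)), function(i)
    cds_df$start[i]:cds_df$end[i]))
  chars <- strsplit(chrom_seq, "")[[1]]
  ref_cds <- chars[gpos]
  alt_chars <- chars
  alt_chars[pos] <- alt
  alt_cds <- alt_chars[gpos]
  tr <- function(x) {
    d <- Biostrings::DNAString(paste(x, collapse = ""))
    if (strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, no.init.codon = TRUE))
  }
  if (!(pos %in% gpos)) return("noncoding")
  if (tr(ref_cds) == tr(alt_cds)) "synonymous" else "nonsynonymous"
}
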