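test_that("allelic chi-square matches the closed-form worked example", {
  # cases 15 samples: ALT 30 / REF 70 alleles... construct via dosages:
  # 50 case samples with 30 ALT alleles; 50 controls with 50 ALT alleles
  case_g <- c(rep(1L, 30), rep(0L, 20))     # 30/100 ALT
  ctrl_g <- c(rep(1L, 50))                  # 50/100 ALT
  # second site to keep the table polymorphic everywhere
  g <- rbind(c(case_g, ctrl_g), rep(c(0L, 1L), 50))
  tab <- toy_table(g, pos = c(100L, 200L))
  ph <- data.frame(sample_id = tab$samples$id,
                   status = rep(c("case", "control"), each = 50))
  res <- snp_association(tab, ph)
  i <- which(res$pos == 100)
  expect_equal(res$alt_case[i], 30); expect_equal(res$alt_ctrl[i], 50)
  expect_equal(res$stat[i],
               200 * (30 * 50 - 70 * 50)^2 / (100 * 100 * 80 * 120),
               tolerance = 1e-12)
  expect_equal(res$stat[i], 8.333, tolerance = 1e-3)
  expect_equal(res$p[i], pchisq(res$stat[i], 1, lower.tail = FALSE))
  expect_equal(res$p[i], 0.0039, tolerance = 0.01)
})

test_that("identical allele counts give statistic 0 and p 1", {
  g <- rbind(rep(c(0L, 1L, 2L, 1L), 5), rep(1L, 20))
  tab <- toy_table(g, pos = c(100L, 200L))
  ph <- data.frame(sample_id = tab$samples$id,
                   status = rep(c("case", "control"), 10))
  res <- snp_association(tab, ph)
  # site 2: every sample heterozygous, so case/control counts coincide
  i <- which(res$pos == 200)
  expect_equal(unname(res$stat[i]), 0)
  expect_equal(unname(res$p[i]), 1)
})

test_that("a fully penetrant split yields an extreme exact p", {
  g <- matrix(c(rep(2L, 50), rep(0L, 50)), 1, 100)
  tab <- toy_table(g, pos = 100L)
  ph <- data.frame(sample_id = tab$samples$id,
                   status = rep(c("case", "control"), each = 50))
  res <- snp_association(tab, ph)
  expect_lt(res$p[1], 1e-20)
})

test_that("monomorphic SNPs are skipped and BH adjustment is applied", {
  g <- rbind(rep(0L, 20), rep(c(0L, 1L), 10), rep(c(1L, 2L), 10))
  tab <- toy_table(g, pos = c(100L, 200L, 300L))
  ph <- data.frame(sample_id = tab$samples$id,
                   status = rep(c("case", "control"), each = 10))
  res <- snp_association(tab, ph)
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("EM with only unambiguous genotypes equals direct gamete counting", {
  # single-het and homozygous genotypes phase uniquely
  geno <- rbind(c(2, 0), c(2, 0), c(0, 2), c(1, 0), c(0, 0))
  em <- em_haplotypes(geno, seed = 1)
  # gametes: 10,10 /10,10 /01,01 /10,00 /00,00 -> 10:5, 01:2, 00:3 of 10
  expect_equal(unname(em$freq[c("10", "01", "00", "11")]),
               c(0.5, 0.2, 0.3, 0), tolerance = 1e-6)
})

test_that("EM resolves the classic coupling mixture", {
  geno <- rbind(matrix(rep(c(2, 2), 40), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 0), 40), ncol = 2, byrow = TRUE),
                matrix(rep(c(1, 1), 20), ncol = 2, byrow = TRUE))
  em <- em_haplotypes(geno, seed = 1)
  expect_equal(unname(em$freq["11"]), 0.5, tolerance = 0.01)
  expect_equal(unname(em$freq["00"]), 0.5, tolerance = 0.01)
  expect_lt(unname(em$freq["10"]), 0.01)
  expect_lt(unname(em$freq["01"]), 0.01)
})

test_that("EM matches exhaustive grid-search ML on random 2-SNP fixtures", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      f_true <- c(rexp(4)); f_true <- f_true / sum(f_true)
      n <- 40
      hap <- function() sample(1:4, 1, prob = f_true)
      hs <- expand.grid(0:1, 0:1)   # rows: (0,0),(1,0),(0,1),(1,1)
      geno <- t(replicate(n, as.numeric(hs[hap(), ] + hs[hap(), ])))
      em <- em_haplotypes(geno, seed = rep)
      grid <- oracle_em2_grid(geno, grid_n = 40)
      expect_gte(em$loglik, grid$loglik - 1e-3)
    }
  })
})

test_that("EM recovers known haplotype frequencies from simulated blocks", {
  withr::with_seed(62, {
    ok <- replicate(20, {
      k <- 3
      haps <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 0, 1), c(0, 1, 0))
      f_true <- c(0.4, 0.3, 0.2, 0.1)
      n <- 200
      pick <- sample(1:4, 2 * n, replace = TRUE, prob = f_true)
      h <- haps[pick, ]
      geno <- h[seq(1, 2 * n, 2), ] + h[seq(2, 2 * n, 2), ]
      em <- em_haplotypes(geno, seed = 3)
      est <- em$freq[apply(haps, 1, paste, collapse = "")]
      # recovery target: the realized gamete composition of the sample
      realized <- tabulate(pick, 4) / (2 * n)
      all(abs(est - realized) <= 0.03)
    })
    expect_gte(mean(ok), 0.9)
  })
})

test_that("LD statistics follow the textbook formulas", {
  # complete coupling LD
  st <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(st$Dprime, 1); expect_equal(st$r2, 1)

  # exact equilibrium
  st2 <- ld_stats(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(st2$D, 0); expect_equal(st2$r2, 0)

  # worked example
  st3 <- ld_stats(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(st3$D, 0.15)
  expect_equal(st3$Dprime, 0.6)
  expect_equal(st3$r2, 0.36)

  expect_error(ld_stats(c(0.5, 0.5, 0, 0)), "fixed")
})

test_that("blocks are maximal all-pairs r2 runs with leftmost ties", {
  pos <- c(100, 200, 300)
  r2 <- matrix(1, 3, 3)
  blk <- define_block(pos, r2, 0.5)
  expect_equal(blk$idx, 1:3)
  expect_equal(c(blk$start, blk$end), c(100, 300))

  r2b <- diag(3); r2b[1, 2] <- r2b[2, 1] <- 0.9; r2b[2, 3] <- r2b[3, 2] <- 0.1
  r2b[1, 3] <- r2b[3, 1] <- 0.1; diag(r2b) <- 1
  blk2 <- define_block(pos, r2b, 0.5)
  expect_equal(blk2$idx, 1:2)

  # interior weak pair breaks the 4-run; leftmost maximal run wins
  pos4 <- c(100, 200, 300, 400)
  r2c <- matrix(1, 4, 4); r2c[2, 3] <- r2c[3, 2] <- 0.4
  blk3 <- define_block(pos4, r2c, 0.5)
  expect_equal(blk3$idx, 1:2)

  r2d <- matrix(0.1, 3, 3); diag(r2d) <- 1
  expect_message(blk4 <- define_block(pos, r2d, 0.5), "no block")
  expect_null(blk4)
})

test_that("haplotype_block ties LD, block and EM together on a clean locus", {
  withr::with_seed(63, {
    haps <- rbind(c(0, 0, 0), c(1, 1, 1))
    n <- 60
    pick <- sample(1:2, 2 * n, replace = TRUE)
    h <- haps[pick, ]
    geno <- t(h[seq(1, 2 * n, 2), ] + h[seq(2, 2 * n, 2), ])
    tab <- toy_table(geno, pos = c(1000L, 3000L, 8000L))
    blk <- haplotype_block(tab)
    expect_equal(length(blk$snp_idx), 3)
    expect_equal(unname(blk$interval), c(1000, 8000))
    expect_equal(length(blk$freq), 2)   # two haplotypes identified
    expect_equal(sum(blk$em$freq), 1, tolerance = 1e-9)
  })
})

test_that("the causal SNP tops a genome-wide association under full penetrance", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 50,
                    chrom_lengths = c(chr1 = 1e6), n_sites = 1000,
                    background_fst = 0.05,
                    sweeps = data.frame(pop = 2, chrom = "chr1", start = 4e5,
                                        end = 6e5, diversity_reduction = 0.5),
                    causal = list(sweep = 1, n_causal = 1, penetrance = 1),
                    seed = 71)
  sim <- simulate_cohort(cfg)
  ph <- simulate_phenotypes(sim$table, sim$truth)
  res <- snp_association(sim$table, ph)
  ci <- sim$truth$causal_sites[1]
  expect_equal(min(res$p), res$p[res$pos == sim$truth$site_pos[ci]])
})
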