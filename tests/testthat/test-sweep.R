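test_that("nearest-rank tail thresholds are attained data values", {
  expect_equal(as.numeric(tail_threshold(1:100, 0.05, "right")), 96)
  expect_equal(as.numeric(tail_threshold(1:100, 0.05, "left")), 5)
  thr <- tail_threshold(1:20, 0.05, "right")
  expect_equal(as.numeric(thr), 20)                 # ceil(0.05*20)=1: the max
  expect_equal(attr(thr, "n_selected"), 1)
  expect_error(tail_threshold(1:10, 0.05, "right"), "at least")
})

test_that("joint tail selection intersects the Fst and ratio tails", {
  withr::with_seed(41, {
    stats <- data.frame(chrom = "chr1", start = seq(0, 95000, 5000),
                        end = seq(20000, 115000, 5000),
                        fst = runif(20), ratio = runif(20, 0.5, 2))
  })
  # force the max-Fst window to also carry the max ratio
  i <- which.max(stats$fst)
  stats$ratio[i] <- max(stats$ratio) + 1
  sel <- select_windows(stats, 0.05, "right")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$start, stats$start[i])
  expect_equal(sel$tail, "right")

  # disjoint tails -> empty selection
  stats2 <- stats
  stats2$ratio <- rev(sort(stats2$ratio))[rank(stats2$fst)]  # anti-aligned
  sel2 <- select_windows(stats2, 0.05, "right")
  expect_equal(nrow(sel2), 0)

  # mode both = union of left and right joint selections
  sl <- select_windows(stats, 0.05, "left")
  sr <- select_windows(stats, 0.05, "right")
  sb <- select_windows(stats, 0.05, "both")
  expect_setequal(sb$start, union(sl$start, sr$start))
})

test_that("selection thresholds equal the recomputed empirical quantiles", {
  withr::with_seed(42, {
    stats <- data.frame(chrom = "chr1", start = seq(0, 495000, 5000),
                        end = seq(20000, 515000, 5000),
                        fst = runif(100), ratio = rlnorm(100))
  })
  sel <- select_windows(stats, 0.05, "both")
  thr <- attr(sel, "thresholds")
  expect_equal(thr$fst, as.numeric(tail_threshold(stats$fst, 0.05, "right")))
  expect_equal(thr$ratio_right,
               as.numeric(tail_threshold(stats$ratio, 0.05, "right")))
  expect_equal(thr$ratio_left,
               as.numeric(tail_threshold(stats$ratio, 0.05, "left")))
  # joint condition can only shrink the set
  expect_lte(nrow(sel), 2 * ceiling(0.05 * 100))
  expect_lte(nrow(select_windows(stats, 0.05, "right")), ceiling(0.05 * 100))
})

test_that("windows merge transitively, including bookended ones", {
  w <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(20000, 25000))
  expect_equal(merge_regions(w)[, c("start", "end")],
               data.frame(start = 0, end = 25000))

  w2 <- data.frame(chrom = "chr1", start = c(0, 40000), end = c(20000, 60000))
  expect_equal(nrow(merge_regions(w2)), 2)

  w3 <- data.frame(chrom = "chr1", start = c(0, 5000, 10000),
                   end = c(20000, 25000, 30000))
  m3 <- merge_regions(w3)
  expect_equal(m3$start, 0); expect_equal(m3$end, 30000)
  expect_equal(m3$n_windows, 3)

  w4 <- data.frame(chrom = "chr1", start = c(0, 20000), end = c(20000, 40000))
  expect_equal(nrow(merge_regions(w4)), 1)   # bookended -> merged
})

test_that("genes overlap regions by >= 1 bp under half-open coordinates", {
  gm <- gene_model(data.frame(
    gene_id = c("inside", "beyond", "spanning"),
    chrom = "chr1", start = c(10001L, 25001L, 24001L),
    end = c(12000L, 26000L, 26000L), strand = "+"))
  regions <- data.frame(chrom = "chr1", start = 0, end = 25000)
  rg <- regions_to_genes(regions, gm)
  expect_setequal(rg$genes, c("inside", "spanning"))
  expect_false("beyond" %in% rg$genes)   # [25000,26000) touches but no overlap
})

test_that("shared regions across comparisons form the right intersections", {
  a <- data.frame(chrom = "chr1", start = 0, end = 20000)
  b <- data.frame(chrom = "chr1", start = 10000, end = 30000)
  sh <- shared_regions(list(A = a, B = b))
  expect_equal(sh$shared, data.frame(chrom = "chr1", start = 10000, end = 20000))

  # identical single region
  sh2 <- shared_regions(list(A = a, B = a))
  expect_equal(sh2$shared, a)

  # disjoint -> none
  c_ <- data.frame(chrom = "chr1", start = 30000, end = 50000)
  expect_equal(nrow(shared_regions(list(A = a, B = c_))$shared), 0)
})

test_that("shared_regions is commutative and associative and emits Venn counts", {
  a <- data.frame(chrom = "chr1", start = c(0, 50000), end = c(20000, 70000))
  b <- data.frame(chrom = "chr1", start = 10000, end = 60000)
  c_ <- data.frame(chrom = "chr1", start = c(15000, 55000),
                   end = c(30000, 65000))
  perms <- list(list(A = a, B = b, C = c_), list(C = c_, A = a, B = b),
                list(B = b, C = c_, A = a))
  shared <- lapply(perms, function(p) shared_regions(p)$shared)
  expect_equal(shared[[1]], shared[[2]])
  expect_equal(shared[[1]], shared[[3]])
  # A&B&C coverage: [15000,20000) and [55000,60000)
  expect_equal(shared[[1]]$start, c(15000, 55000))
  expect_equal(shared[[1]]$end, c(20000, 60000))

  gs <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
             C = c("g3", "g5"))
  sh <- shared_regions(list(A = a, B = b, C = c_), gene_sets = gs)
  expect_equal(sh$shared_genes, "g3")
  vg <- setNames(sh$venn_genes$n_genes, sh$venn_genes$members)
  expect_equal(vg[["A&B&C"]], 1L)   # g3
  expect_equal(vg[["A&B"]], 1L)     # g2
  expect_equal(vg[["A"]], 1L)       # g1
})

test_that("sweep_scan recovers an implanted sweep and controls the null", {
  hits <- logical(20)
  for (s in 1:20) {
    cfg <- sim_config(n_pops = 2, samples_per_pop = 20,
                      chrom_lengths = c(chr1 = 5e6), n_sites = 5000,
                      background_fst = 0.05,
                      sweeps = data.frame(pop = 2, chrom = "chr1", start = 2e6,
                                          end = 2.2e6,
                                          diversity_reduction = 0.8),
                      seed = 200 + s)
    sim <- simulate_cohort(cfg)
    grid <- make_windows(c(chr1 = 5e6))
    st <- window_stats(sim$table, grid, "pop1", "pop2")
    sc <- sweep_scan(st)
    hits[s] <- nrow(sc$regions) > 0 &&
      any(sc$regions$start < 2.2e6 & sc$regions$end > 2e6)
  }
  expect_gte(sum(hits), 18)

  # null: no sweep -> selected fraction bounded by the tail fraction
  for (s in 1:5) {
    cfg0 <- sim_config(n_pops = 2, samples_per_pop = 20,
                       chrom_lengths = c(chr1 = 5e6), n_sites = 5000,
                       background_fst = 0.05, seed = 300 + s)
    sim0 <- simulate_cohort(cfg0)
    grid <- make_windows(c(chr1 = 5e6))
    st0 <- window_stats(sim0$table, grid, "pop1", "pop2")
    sel0 <- select_windows(st0, 0.05, "right")
    expect_lte(nrow(sel0) / nrow(st0), 0.05)
  }
})

test_that("sweep_scan objects print, summarise and plot", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 10,
                    chrom_lengths = c(chr1 = 1e6), n_sites = 1500,
                    background_fst = 0.05,
                    sweeps = data.frame(pop = 2, chrom = "chr1", start = 4e5,
                                        end = 5e5, diversity_reduction = 0.8),
                    seed = 17)
  sim <- simulate_cohort(cfg)
  grid <- make_windows(c(chr1 = 1e6))
  sc <- sweep_scan(window_stats(sim$table, grid, "pop1", "pop2"),
                   label = "demo")
  expect_output(print(sc), "Selective-sweep scan")
  expect_output(print(summary(sc)), "regions")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sc))
})
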