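# Shuffled nulls, the two-proportion Z-test and overlap reporting.

test_that("the Z statistic matches the closed form and the chi-square identity", {
  zt <- two_proportion_ztest(40, 100, 20, 100)
  expect_equal(round(zt$z, 3), 3.086)
  expect_equal(round(zt$p_value, 3), 0.002)

  expect_equal(two_proportion_ztest(15, 50, 30, 100)$z, 0)
  expect_equal(two_proportion_ztest(15, 50, 30, 100)$p_value, 1)
  expect_equal(two_proportion_ztest(0, 50, 0, 80)$z, 0)  # degenerate pool

  extreme <- two_proportion_ztest(50, 50, 0, 50)
  expect_gt(extreme$z, 0)
  expect_lt(extreme$p_value, 1e-10)

  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    zt <- two_proportion_ztest(k1, n1, k2, n2)
    chi <- suppressWarnings(stats::chisq.test(
      matrix(c(k1, n1 - k1, k2, n2 - k2), 2), correct = FALSE))
    expect_equal(zt$z^2, unname(chi$statistic), tolerance = 1e-10)
  }
  expect_error(two_proportion_ztest(1, 0, 1, 2), "positive")
})

test_that("shuffling preserves lengths, avoids masks and is seeded", {
  set.seed(1)
  lens <- c(c1 = 500000, c2 = 500000)
  starts <- sample(0:400000, 40)
  regions <- data.frame(chrom = sample(names(lens), 40, TRUE),
                        start = starts,
                        end = starts + sample(200:5000, 40, TRUE))
  mask <- data.frame(chrom = "c1", start = 0, end = 250000)
  cfg <- shuffle_config(seed = 1000, mask = mask)
  out <- shuffle_regions(regions, lens, cfg)
  expect_equal(sort(out$end - out$start), sort(regions$end - regions$start))
  # mask avoidance
  in_mask <- out$chrom == "c1" & out$start < 250000 & out$end > 0
  expect_false(any(in_mask))
  # mutual disjointness
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start + 1, out$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0)
  # determinism and seed sensitivity
  expect_identical(shuffle_regions(regions, lens, cfg), out)
  out2 <- shuffle_regions(regions, lens, shuffle_config(seed = 2, mask = mask))
  expect_false(identical(out2, out))
})

test_that("a forced placement lands in the only unmasked window", {
  lens <- c(c1 = 100000)
  region <- data.frame(chrom = "c1", start = 0, end = 1000)
  mask <- data.frame(chrom = "c1", start = c(0, 51000), end = c(50000, 100000))
  out <- shuffle_regions(region, lens, shuffle_config(seed = 3, mask = mask))
  expect_equal(out$start, 50000)
  expect_equal(out$end, 51000)
  # no space at all: the error names the region
  full <- data.frame(chrom = "c1", start = 0, end = 100000)
  expect_error(shuffle_regions(region, lens,
                               shuffle_config(mask = full, max_retries = 50)),
               "region 1")
})

test_that("overlap fractions count query regions region-wise", {
  q <- data.frame(chrom = "c", start = seq(0, 900, 100),
                  end = seq(50, 950, 100))
  hit4 <- data.frame(chrom = "c", start = c(0, 110, 210, 310),
                     end = c(10, 120, 220, 320))
  o <- overlap_fraction(q, hit4)
  expect_equal(o$k, 4); expect_equal(o$n, 10); expect_equal(o$fraction, 0.4)
  everywhere <- data.frame(chrom = "c", start = 0, end = 1000)
  expect_equal(overlap_fraction(q, everywhere)$fraction, 1)
  nowhere <- data.frame(chrom = "other", start = 0, end = 1000)
  expect_equal(overlap_fraction(q, nowhere)$fraction, 0)
})

test_that("expression threshold is inclusive on the replicate mean", {
  gm <- gene_models(c("g1", "g2", "g3"), "c", c("+", "+", "-"),
                    c(0, 5000, 9000), c(3000, 8000, 12000))
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "gX"),
                     fpkm_1 = c(0.5, 0.4, 3, 9), fpkm_2 = c(1.5, 0.5, 4, 9))
  expect_warning(out <- expressed_gene_bodies(expr, gm), "not in the gene")
  expect_setequal(out$gene_id, c("g1", "g3"))  # mean 1.0 is expressed
  expect_equal(out$start[out$gene_id == "g1"], 0)
  expect_equal(out$end[out$gene_id == "g1"], 3000)
})

test_that("enrichment reporting stars thresholds and flags untestable rows", {
  feats <- list(f = data.frame(chrom = "c", start = 0, end = 500))
  dmrs <- list(hypo = data.frame(chrom = "c", start = seq(0, 490, 10),
                                 end = seq(5, 495, 10)),
               hyper = data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  nulls <- list(hypo = data.frame(chrom = "c", start = seq(1000, 1490, 10),
                                  end = seq(1005, 1495, 10)),
                hyper = dmrs$hyper)
  rep <- enrichment_report(dmrs, feats, nulls)
  hypo <- rep[rep$direction == "hypo", ]
  expect_equal(hypo$k1, 50); expect_equal(hypo$k2, 0)
  expect_equal(hypo$stars, "**")
  expect_equal(rep$stars[rep$direction == "hyper"], "untestable")

  # identical observed and null sets give z = 0 and no stars
  same <- enrichment_report(dmrs["hypo"], feats, dmrs["hypo"])
  expect_equal(same$z, 0)
  expect_equal(same$stars, "")
})

test_that("star cutoffs sit at 0.05 and 0.001", {
  # choose counts whose p-values straddle the cutoffs
  p_of <- function(k1, n1, k2, n2) two_proportion_ztest(k1, n1, k2, n2)$p_value
  p_star <- p_of(33, 100, 20, 100)   # ~0.036
  expect_true(p_star < 0.05 && p_star > 0.001)
  p_2star <- p_of(45, 100, 20, 100)  # ~1e-4
  expect_lt(p_2star, 0.001)
})

test_that("the Z-test holds its size under a shuffled-overlap null", {
  # pool of uniformly relocated regions classified against a feature set,
  # resampled into many null-vs-null comparisons
  set.seed(2024)
  lens <- c(g = 1e6)
  gm <- place <- NULL
  feature <- data.frame(chrom = "g", start = seq(0, 9.5e5, 5e4),
                        end = seq(0, 9.5e5, 5e4) + 15000)  # 30% coverage
  pool_n <- 20000
  width <- 500
  starts <- sample(0:(1e6 - width), pool_n, replace = TRUE)
  gr <- GenomicRanges::GRanges("g", IRanges::IRanges(starts + 1,
                                                     starts + width))
  fgr <- GenomicRanges::GRanges(feature$chrom,
                                IRanges::IRanges(feature$start + 1,
                                                 feature$end))
  hit <- GenomicRanges::countOverlaps(gr, fgr) > 0
  n <- 100
  rej <- 0
  for (i in 1:1000) {
    k1 <- sum(sample(hit, n, replace = TRUE))
    k2 <- sum(sample(hit, n, replace = TRUE))
    if (two_proportion_ztest(k1, n, k2, n)$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / 1000 - 0.05), 0.02)
})
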