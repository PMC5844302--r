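# Synthetic WGBS generator: determinism, mixture recovery, planted effects,
# polymorphisms and pileup artifacts.

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_wgbs(cfg), d1)
  write_simulation(simulate_wgbs(cfg), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_true(length(f1) > 5)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("CpG counts follow the configured density and the spike-in exists", {
  cfg <- sim_config(chrom_lengths = c(chrX = 100000), cpg_rate = 0.02,
                    island_frac_genes = 0, n_genes = 2,
                    spike_in_length = 30000, seed = 5)
  ref <- build_reference(cfg)
  n_chr <- sum(ref$cpg$chrom == "chrX")
  expect_lt(abs(n_chr - 2000), 5 * sqrt(2000))
  expect_true("lambda" %in% ref$cpg$chrom)
  expect_true(all(ref$cpg$start[ref$cpg$chrom == "lambda"] <
                    cfg$spike_in_length))
  # every chromosome carries at least one gene
  expect_true(all(names(cfg$chrom_lengths) %in% ref$gene_models$chrom))
})

test_that("methylome mixture matches its weights and zeroes the spike-in", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2.5e6, chr2 = 2.5e6),
                    cpg_rate = 0.02, n_genes = 40, seed = 2)
  ref <- build_reference(cfg)
  truth <- draw_methylome(cfg, ref)
  genomic <- truth$cpg[truth$cpg$chrom != "lambda", ]
  expect_gt(nrow(genomic), 90000)
  expect_lt(abs(mean(genomic$level_wt > 0.75) - 0.82), 0.01)
  expect_lt(abs(mean(genomic$level_wt < 0.25) - 0.07), 0.01)
  spike <- truth$cpg[truth$cpg$chrom == "lambda", ]
  expect_true(all(spike$level_wt == 0))

  # degenerate mixture: all mass in the high component
  cfg1 <- tiny_config(high_frac = 1, low_frac = 0, mid_frac = 0)
  t1 <- draw_methylome(cfg1, build_reference(cfg1))
  g1 <- t1$cpg[t1$cpg$chrom != "lambda", ]
  expect_true(all(g1$level_wt > 0.75))
})

test_that("planted effects have exact bookkeeping, direction and delta", {
  cfg <- tiny_config(n_hypo = 0, n_hyper = 0)
  t0 <- plant_effects(draw_methylome(cfg, build_reference(cfg)), cfg)
  expect_equal(t0$cpg$level_ko, t0$cpg$level_wt)
  expect_equal(nrow(t0$dmr_truth), 0)

  cfg2 <- sim_config(chrom_lengths = c(chr1 = 5e5), n_genes = 15,
                     n_hypo = 6, n_hyper = 3, seed = 21)
  tr <- plant_effects(draw_methylome(cfg2, build_reference(cfg2)), cfg2)
  expect_equal(sum(tr$dmr_truth$direction == "hypo"), 6)
  expect_equal(sum(tr$dmr_truth$direction == "hyper"), 3)
  for (i in seq_len(nrow(tr$dmr_truth))) {
    d <- tr$dmr_truth[i, ]
    m <- tr$cpg$chrom == d$chrom & tr$cpg$start >= d$start &
      tr$cpg$start < d$end
    expect_gte(sum(m), cfg2$dmr_n_cpgs)
    dif <- tr$cpg$level_ko[m] - tr$cpg$level_wt[m]
    if (d$direction == "hypo") {
      expect_true(all(abs(dif + cfg2$dmr_delta) < 1e-12))
    } else {
      expect_true(all(abs(dif - cfg2$dmr_delta) < 1e-12))
    }
  }
  # outside planted regions the two methylomes agree
  outside <- rep(TRUE, nrow(tr$cpg))
  for (i in seq_len(nrow(tr$dmr_truth))) {
    d <- tr$dmr_truth[i, ]
    outside <- outside & !(tr$cpg$chrom == d$chrom & tr$cpg$start >= d$start &
                             tr$cpg$start < d$end)
  }
  expect_equal(tr$cpg$level_ko[outside], tr$cpg$level_wt[outside])
})

test_that("without baseline redraw, shifted levels are clipped into [0,1]", {
  cfg <- tiny_config(dmr_redraw_wt = FALSE, dmr_delta = 0.9,
                     n_hypo = 2, n_hyper = 2)
  tr <- plant_effects(draw_methylome(cfg, build_reference(cfg)), cfg)
  expect_true(all(tr$cpg$level_ko >= 0 & tr$cpg$level_ko <= 1))
  hypo <- tr$dmr_truth[tr$dmr_truth$direction == "hypo", ]
  m <- tr$cpg$chrom == hypo$chrom[1] & tr$cpg$start >= hypo$start[1] &
    tr$cpg$start < hypo$end[1]
  expect_true(any(tr$cpg$level_ko[m] == 0))  # clipping visibly binds
})

test_that("polymorphism planting is binomial and avoids planted regions", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), n_genes = 10,
                    snp_rate = 0.05, n_hypo = 0, n_hyper = 0, seed = 9)
  tr <- plant_cpg_snps(plant_effects(draw_methylome(cfg, build_reference(cfg)),
                                     cfg), cfg)
  n_cpg <- sum(tr$cpg$chrom != "lambda")
  expect_lt(abs(nrow(tr$snp_sites) - 0.05 * n_cpg),
            3 * sqrt(n_cpg * 0.05 * 0.95))
  expect_false(any(tr$snp_sites$chrom == "lambda"))

  cfg0 <- tiny_config(snp_rate = 0)
  tr0 <- plant_cpg_snps(draw_methylome(cfg0, build_reference(cfg0)), cfg0)
  expect_equal(nrow(tr0$snp_sites), 0)

  cfg1 <- tiny_config(snp_rate = 0.2, snp_exclude_dmrs = TRUE,
                      n_hypo = 2, n_hyper = 1)
  tr1 <- plant_cpg_snps(plant_effects(draw_methylome(cfg1,
                                                     build_reference(cfg1)),
                                      cfg1), cfg1)
  for (i in seq_len(nrow(tr1$dmr_truth))) {
    d <- tr1$dmr_truth[i, ]
    expect_false(any(tr1$snp_sites$chrom == d$chrom &
                       tr1$snp_sites$start >= d$start &
                       tr1$snp_sites$start < d$end))
  }
})

test_that("pileups hit deterministic limits and mark SNP sites", {
  cfg <- tiny_config(conversion_failure = 0, base_miscall = 0,
                     snp_rate = 0.1, n_hypo = 0, n_hyper = 0)
  truth <- plant_cpg_snps(draw_methylome(cfg, build_reference(cfg)), cfg)
  # force fully methylated genomic levels to probe the deterministic limit
  truth$cpg$level_wt <- ifelse(truth$cpg$chrom == "lambda", 0, 1)
  sim <- simulate_pileups(truth, cfg)
  pu <- sim$pileups$wt[[1]]
  genomic <- truth$cpg[truth$cpg$chrom != "lambda", ]
  # level 1 and no conversion failure: every genomic call is methylated
  crow <- pu[pu$strand == "+" & paste(pu$chrom, pu$pos) %in%
               paste(genomic$chrom, genomic$start), ]
  expect_true(all(crow$nUnmeth == 0))
  expect_true(all(crow$nMeth == crow$nC))
  # SNP sites show zero G on the plus strand at N+1
  snp <- truth$snp_sites
  grow <- pu[pu$strand == "+" & paste(pu$chrom, pu$pos) %in%
               paste(snp$chrom, snp$start + 1), ]
  expect_gt(nrow(grow), 0)
  expect_true(all(grow$nG == 0))
  # spike-in is fully unmethylated when conversion is perfect
  lam <- sim$gbed$wt[[1]]
  lam <- lam[lam$chrom == "lambda", ]
  expect_true(all(lam$meth == 0))
})

test_that("simulated ratios converge to true levels at high depth", {
  cfg <- tiny_config(depth_mean = 500, n_replicates = 1,
                     snp_rate = 0, n_hypo = 0, n_hyper = 0)
  sim <- simulate_wgbs(cfg)
  gb <- sim$gbed$wt[[1]]
  key <- paste(gb$chrom, gb$start)
  lvl <- sim$truth$cpg$level_wt[match(key, paste(sim$truth$cpg$chrom,
                                                 sim$truth$cpg$start))]
  err <- abs(gb$ratio - lvl)
  expect_lt(mean(err, na.rm = TRUE), 0.02)
  expect_gt(stats::cor(gb$ratio, lvl, use = "complete.obs"), 0.99)
})
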