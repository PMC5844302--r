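# Feature construction, overlap annotation and TSS distances.

toy_models <- function() {
  gene_models(
    gene_id = c("gA", "gB"), chrom = c("t", "t"), strand = c("+", "-"),
    tx_start = c(10000, 40000), tx_end = c(20000, 50000),
    exon_starts = list(c(10000, 15000), c(40000, 46000)),
    exon_ends = list(c(12000, 20000), c(44000, 50000))
  )
}

test_that("promoter and 3'-end windows follow the strand-aware arithmetic", {
  f <- build_features(toy_models(), data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0)))
  pA <- f$promoters[f$promoters$strand == "+", ]
  expect_equal(c(pA$start, pA$end), c(9000, 10500))
  # minus-strand gene: TSS at 49999, window mirrored
  pB <- f$promoters[f$promoters$strand == "-", ]
  expect_equal(c(pB$start, pB$end), c(49500, 51000))
  # 3' ends are 1000 bp each side of the TES
  eA <- f$three_prime_ends[f$three_prime_ends$strand == "+", ]
  expect_equal(c(eA$start, eA$end), c(18999, 21000))
  # introns are the body minus the exons
  expect_equal(f$introns$start, c(12000, 44000))
  expect_equal(f$introns$end, c(15000, 46000))
})

test_that("island shores and shelves match hand-derived coordinates", {
  isl <- data.frame(chrom = "t", start = 20000, end = 21000)
  f <- build_features(toy_models(), isl)
  expect_equal(f$cpg_shores$start, c(18000, 21000))
  expect_equal(f$cpg_shores$end, c(20000, 23000))
  expect_equal(f$cpg_shelves$start, c(16000, 23000))
  expect_equal(f$cpg_shelves$end, c(18000, 25000))

  # two islands 1 kb apart: no shore base inside any island
  isl2 <- rbind(isl, data.frame(chrom = "t", start = 22000, end = 22500))
  f2 <- build_features(toy_models(), isl2)
  sh <- bed_gr <- f2$cpg_shores
  for (i in seq_len(nrow(sh))) {
    for (j in seq_len(nrow(isl2))) {
      expect_true(sh$end[i] <= isl2$start[j] || sh$start[i] >= isl2$end[j])
    }
  }
})

test_that("island, shore and shelf classes never share a base", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    s <- sort(sample(seq(0, 80000, by = 100), n))
    isl <- data.frame(chrom = "t", start = s, end = s + sample(200:3000, n,
                                                               replace = TRUE))
    f <- build_features(toy_models(), isl,
                        chrom_lengths = c(t = 100000))
    gr <- function(df) GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1, df$end))
    expect_equal(sum(IRanges::width(GenomicRanges::intersect(
      gr(f$cpg_islands), gr(f$cpg_shores)))), 0)
    expect_equal(sum(IRanges::width(GenomicRanges::intersect(
      gr(f$cpg_islands), gr(f$cpg_shelves)))), 0)
    expect_equal(sum(IRanges::width(GenomicRanges::intersect(
      gr(f$cpg_shores), gr(f$cpg_shelves)))), 0)
  }
})

test_that("overlap flags agree with a per-base oracle on a toy genome", {
  isl <- data.frame(chrom = "t", start = c(5000, 30000), end = c(6000, 32000))
  f <- build_features(toy_models(), isl, chrom_lengths = c(t = 100000))
  set.seed(3)
  starts <- sample(0:99000, 60)
  dmrs <- data.frame(chrom = "t", start = starts,
                     end = starts + sample(100:900, 60, replace = TRUE))
  ann <- annotate_dmrs(dmrs, f)
  for (cat in list(c("promoter", "promoters"), c("exon", "exons"),
                   c("intron", "introns"), c("three_prime", "three_prime_ends"),
                   c("island", "cpg_islands"), c("shore", "cpg_shores"),
                   c("shelf", "cpg_shelves"))) {
    expect_equal(ann[[cat[1]]], oracle_overlaps(dmrs, f[[cat[2]]], 100000),
                 info = cat[1])
  }
  genic <- ann$promoter | ann$exon | ann$intron | ann$three_prime
  expect_equal(ann$intergenic, !genic)

  # fully exonic region: exon only; junction region: both
  inside <- annotate_dmrs(data.frame(chrom = "t", start = 10100, end = 10200), f)
  expect_true(inside$exon); expect_false(inside$intron)
  expect_false(inside$intergenic)
  junction <- annotate_dmrs(data.frame(chrom = "t", start = 11900, end = 12100), f)
  expect_true(junction$exon); expect_true(junction$intron)
  nowhere <- annotate_dmrs(data.frame(chrom = "t", start = 98000, end = 98100), f)
  expect_true(nowhere$intergenic)
})

test_that("TSS distances are signed by the TSS strand", {
  tss <- data.frame(chrom = "t", pos = c(1000, 5000),
                    strand = c("+", "-"), gene_id = c("g1", "g2"))
  # region downstream of the plus-strand TSS
  d1 <- tss_distance(data.frame(chrom = "t", start = 3000, end = 3200),
                     tss[1, ])
  expect_equal(d1$distance, 2000)
  expect_equal(d1$bin, "0bp-5kb_downstream")
  # region to the right of a minus-strand TSS is upstream
  d2 <- tss_distance(data.frame(chrom = "t", start = 5500, end = 5600),
                     tss[2, ])
  expect_equal(d2$distance, -500)
  expect_equal(d2$bin, "0bp-5kb_upstream")
  # containment gives zero
  d3 <- tss_distance(data.frame(chrom = "t", start = 900, end = 1100), tss)
  expect_equal(d3$distance, 0)
  expect_equal(d3$bin, "overlaps_tss")
  # nearest TSS by absolute distance
  d4 <- tss_distance(data.frame(chrom = "t", start = 4000, end = 4100), tss)
  expect_equal(d4$distance, 901)  # minus-strand TSS at 5000, downstream
  expect_error(tss_distance(data.frame(chrom = "t", start = 0, end = 1),
                            tss[0, ]), "empty")
})

test_that("promoter construction is strand-mirror symmetric", {
  L <- 100000
  fwd <- gene_models("g", "t", "+", 30000, 40000)
  # reflect the genome: x -> L - x; the gene becomes minus-strand
  rev <- gene_models("g", "t", "-", L - 40000, L - 30000)
  e <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  pf <- build_features(fwd, e)$promoters
  pr <- build_features(rev, e)$promoters
  expect_equal(pr$start, L - pf$end)
  expect_equal(pr$end, L - pf$start)
})
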