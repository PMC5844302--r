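# Length-matched shuffled null regions and overlap-enrichment testing.

#' Shuffle configuration
#'
#' @param seed RNG seed for placement (the conventional default 1000)
#' @param no_overlap forbid overlap among output regions
#' @param mask BED-style data.frame of intervals excluded from placement
#' @param max_retries placement attempts per region before failing
#' @return a list of class `shuffle_config`
#' @export
shuffle_config <- function(seed = 1000, no_overlap = TRUE, mask = NULL,
                           max_retries = 10000) {
  structure(list(seed = as.integer(seed), no_overlap = no_overlap,
                 mask = mask, max_retries = max_retries),
            class = "shuffle_config")
}

#' Generate length-matched random control regions
#'
#' Each input region is relocated to a start drawn uniformly over all
#' placements of its exact length that fit entirely in unmasked space (the
#' same distribution an accept/reject sampler over the unmasked genome
#' converges to, computed exactly). With `no_overlap`, placed regions are
#' added to the mask as placement proceeds. Deterministic given the seed.
#'
#' @param regions BED-style data.frame of query regions
#' @param chrom_lengths named vector of chromosome lengths
#' @param config a [shuffle_config()]
#' @return BED-style data.frame of null regions, one per input, in input
#'   order
#' @export
shuffle_regions <- function(regions, chrom_lengths,
                            config = shuffle_config()) {
  n <- nrow(regions)
  if (n == 0) return(regions)
  chroms <- names(chrom_lengths)
  genome_gr <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(1L, as.integer(chrom_lengths)))
  free_gr <- if (!is.null(config$mask) && nrow(config$mask) > 0) {
    GenomicRanges::setdiff(genome_gr,
                           GenomicRanges::reduce(bed_to_gr(config$mask),
                                                 ignore.strand = TRUE),
                           ignore.strand = TRUE)
  } else genome_gr
  out <- data.frame(chrom = character(n), start = integer(n),
                    end = integer(n), strand = ".", stringsAsFactors = FALSE)
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      w <- regions$end[i] - regions$start[i]
      # gaps wide enough for this region; starts per gap = width - w + 1
      gw <- IRanges::width(free_gr)
      fit <- which(gw >= w)
      slots <- gw[fit] - w + 1
      if (length(fit) == 0 || sum(slots) < 1) {
        stop("cannot place region ", i, " (", w,
             " bp): no unmasked window is wide enough")
      }
      t <- sample.int(sum(slots), 1)
      cs <- cumsum(slots)
      j <- which(t <= cs)[1]
      off <- t - c(0, cs)[j] - 1
      gi <- fit[j]
      s <- GenomicRanges::start(free_gr)[gi] - 1L + as.integer(off)
      ch <- as.character(GenomicRanges::seqnames(free_gr))[gi]
      out$chrom[i] <- ch
      out$start[i] <- s
      out$end[i] <- s + w
      if (config$no_overlap) {
        free_gr <- GenomicRanges::setdiff(
          free_gr,
          GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1L, s + w)),
          ignore.strand = TRUE
        )
      }
    }
  })
  out
}

#' Two-proportion Z-test
#'
#' Pooled-variance Z statistic for the difference p1 - p2 with a two-sided
#' normal p-value; z is defined as 0 when the pooled proportion is 0 or 1.
#'
#' @param k1,n1 successes and size of set 1
#' @param k2,n2 successes and size of set 2
#' @return list with k1, n1, k2, n2, p1, p2, z, p_value
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("set sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must satisfy 0 <= k <= n")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  }
  list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Region-wise overlap of a query set with a subject set
#'
#' @param query_regions,subject_regions BED-style data.frames
#' @return list with k (queries overlapping at least one subject base),
#'   n (query count) and fraction k/n
#' @export
overlap_fraction <- function(query_regions, subject_regions) {
  n <- nrow(query_regions)
  if (n == 0) return(list(k = 0L, n = 0L, fraction = NA_real_))
  k <- sum(overlaps_any(query_regions, subject_regions))
  list(k = as.integer(k), n = as.integer(n), fraction = k / n)
}

#' Gene bodies of expressed genes
#'
#' A gene is expressed when its mean FPKM over replicates is at least
#' `min_fpkm` (inclusive); its body spans TSS to TES.
#'
#' @param expression data.frame with gene_id plus numeric per-replicate
#'   FPKM columns
#' @param gene_models data.frame from [gene_models()]
#' @param min_fpkm expression threshold
#' @return BED-style data.frame of expressed gene bodies (with gene_id)
#' @export
expressed_gene_bodies <- function(expression, gene_models, min_fpkm = 1) {
  fpkm_cols <- setdiff(names(expression), "gene_id")
  mean_fpkm <- rowMeans(as.matrix(expression[, fpkm_cols, drop = FALSE]))
  expressed <- expression$gene_id[mean_fpkm >= min_fpkm]
  unknown <- setdiff(expressed, gene_models$gene_id)
  if (length(unknown) > 0) {
    warning(length(unknown), " expressed gene ids not in the gene models; ",
            "skipped")
    expressed <- setdiff(expressed, unknown)
  }
  gm <- gene_models[gene_models$gene_id %in% expressed, , drop = FALSE]
  out <- data.frame(
    chrom = gm$chrom, start = pmin(gm$tss, gm$tes),
    end = pmax(gm$tss, gm$tes) + 1L, strand = gm$strand,
    gene_id = gm$gene_id, stringsAsFactors = FALSE
  )
  sort_bed(out)
}

#' Overlap-enrichment report against length-matched nulls
#'
#' For each direction and feature category, tests whether the proportion of
#' regions overlapping the category differs between the observed set and
#' its length-matched null set with the two-proportion Z-test. Raw p-values
#' are starred at 0.05 (*) and 0.001 (**).
#'
#' @param dmrs_by_direction named list (e.g. hypo, hyper) of BED-style
#'   region data.frames
#' @param features named list mapping category names to BED-style feature
#'   data.frames
#' @param null_regions named list parallel to `dmrs_by_direction` of
#'   length-matched null sets
#' @return data.frame with direction, category, k1, n1, k2, n2, p1, p2, z,
#'   p_value, stars; rows with n1 = 0 are flagged untestable (NA z)
#' @export
enrichment_report <- function(dmrs_by_direction, features, null_regions) {
  rows <- list()
  for (dir in names(dmrs_by_direction)) {
    dmrs <- dmrs_by_direction[[dir]]
    nulls <- null_regions[[dir]]
    for (cat in names(features)) {
      feat <- features[[cat]]
      o1 <- overlap_fraction(dmrs, feat)
      o2 <- overlap_fraction(nulls, feat)
      if (o1$n == 0 || o2$n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          direction = dir, category = cat, k1 = o1$k, n1 = o1$n,
          k2 = o2$k, n2 = o2$n, p1 = NA_real_, p2 = NA_real_,
          z = NA_real_, p_value = NA_real_, stars = "untestable",
          stringsAsFactors = FALSE
        )
        next
      }
      zt <- two_proportion_ztest(o1$k, o1$n, o2$k, o2$n)
      stars <- if (zt$p_value < 0.001) "**" else if (zt$p_value < 0.05) "*" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, category = cat, k1 = zt$k1, n1 = zt$n1,
        k2 = zt$k2, n2 = zt$n2, p1 = zt$p1, p2 = zt$p2, z = zt$z,
        p_value = zt$p_value, stars = stars, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
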