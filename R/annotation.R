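# Gene-model and CpG-island context annotation of genomic regions.
#
# Feature windows (0-based, half-open):
#   promoter      1000 bp upstream to 500 bp downstream of the TSS,
#                 strand-mirrored: + strand [tss-1000, tss+500),
#                 - strand [tss-499, tss+1001)
#   3' end        1000 bp either side of the TES: [tes-1000, tes+1001)
#   gene body     TSS to TES
#   introns       gene body minus exons
#   CpG shores    up to 2 kb flanking island edges, minus island bases
#   CpG shelves   up to 2 kb flanking shores, minus shore/island bases

#' Build derived feature sets from gene models and CpG islands
#'
#' @param gene_models data.frame from [gene_models()]
#' @param cpg_islands BED-style data.frame of island intervals
#' @param chrom_lengths optional named vector for clipping at chromosome
#'   ends (intervals are always clipped at 0)
#' @param promoter_up,promoter_down promoter window in bp around the TSS
#' @param tes_flank 3'-end window half-width in bp
#' @param shore_width,shelf_width flank widths in bp
#' @return list of class `feature_set` with BED-style data.frames:
#'   promoters, gene_bodies, exons, introns, three_prime_ends, cpg_islands,
#'   cpg_shores, cpg_shelves, and `tss_points` (chrom, pos, strand, gene_id)
#' @export
build_features <- function(gene_models, cpg_islands, chrom_lengths = NULL,
                           promoter_up = 1000, promoter_down = 500,
                           tes_flank = 1000,
                           shore_width = 2000, shelf_width = 2000) {
  gm <- gene_models
  clip <- function(df) {
    if (nrow(df) == 0) return(df)
    df$start <- pmax(0L, as.integer(df$start))
    if (!is.null(chrom_lengths)) {
      lim <- chrom_lengths[df$chrom]
      over <- !is.na(lim) & df$end > lim
      if (any(over)) df$end[over] <- as.integer(lim[over])
    }
    df <- df[df$end > df$start, , drop = FALSE]
    sort_bed(df)
  }
  plus <- gm$strand == "+"
  promoters <- data.frame(
    chrom = gm$chrom,
    start = ifelse(plus, gm$tss - promoter_up, gm$tss - promoter_down + 1L),
    end = ifelse(plus, gm$tss + promoter_down, gm$tss + promoter_up + 1L),
    strand = gm$strand, stringsAsFactors = FALSE
  )
  three_prime <- data.frame(
    chrom = gm$chrom, start = gm$tes - tes_flank, end = gm$tes + tes_flank + 1L,
    strand = gm$strand, stringsAsFactors = FALSE
  )
  bodies <- data.frame(
    chrom = gm$chrom, start = pmin(gm$tss, gm$tes),
    end = pmax(gm$tss, gm$tes) + 1L, strand = gm$strand,
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    chrom = rep(gm$chrom, lengths(gm$exon_starts)),
    start = unlist(gm$exon_starts),
    end = unlist(gm$exon_ends),
    strand = rep(gm$strand, lengths(gm$exon_starts)),
    stringsAsFactors = FALSE
  )
  # introns: per-gene body minus that gene's exons
  introns_gr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(bed_to_gr(bodies), ignore.strand = TRUE),
    GenomicRanges::reduce(bed_to_gr(exons), ignore.strand = TRUE),
    ignore.strand = TRUE
  )
  introns <- gr_to_bed(introns_gr)

  isl <- clip(cpg_islands)
  isl_gr <- GenomicRanges::reduce(bed_to_gr(isl), ignore.strand = TRUE)
  flank1 <- expand_bed(isl, shore_width)
  shores_gr <- GenomicRanges::setdiff(
    GenomicRanges::reduce(bed_to_gr(clip(flank1)), ignore.strand = TRUE),
    isl_gr, ignore.strand = TRUE
  )
  flank2 <- expand_bed(isl, shore_width + shelf_width)
  shelves_gr <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(
      GenomicRanges::reduce(bed_to_gr(clip(flank2)), ignore.strand = TRUE),
      shores_gr, ignore.strand = TRUE
    ),
    isl_gr, ignore.strand = TRUE
  )

  structure(list(
    promoters = clip(promoters),
    gene_bodies = clip(bodies),
    exons = clip(exons),
    introns = clip(introns),
    three_prime_ends = clip(three_prime),
    cpg_islands = isl,
    cpg_shores = clip(gr_to_bed(shores_gr)),
    cpg_shelves = clip(gr_to_bed(shelves_gr)),
    tss_points = data.frame(chrom = gm$chrom, pos = gm$tss,
                            strand = gm$strand, gene_id = gm$gene_id,
                            stringsAsFactors = FALSE)
  ), class = "feature_set")
}

expand_bed <- function(df, by) {
  if (nrow(df) == 0) return(df)
  out <- df
  out$start <- df$start - as.integer(by)
  out$end <- df$end + as.integer(by)
  out
}

#' Annotate regions with feature overlap flags and TSS distances
#'
#' A flag is TRUE when the region shares at least one base with the
#' feature; flags are non-exclusive (a region spanning an exon/intron
#' junction sets both) and intergenic means no overlap with promoter, exon,
#' intron or 3' end. Regions on chromosomes absent from the feature set are
#' flagged unannotatable.
#'
#' @param dmrs BED-style data.frame of regions
#' @param features a [build_features()] result
#' @param bin_edges TSS-distance bin edges in bp (see [tss_distance()])
#' @return data.frame with one row per region: chrom, start, end, overlap
#'   flags (promoter, exon, intron, three_prime, intergenic, island, shore,
#'   shelf), tss_distance, tss_bin
#' @export
annotate_dmrs <- function(dmrs, features, bin_edges = c(5e3, 5e4, 5e5)) {
  if (nrow(dmrs) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  flag <- function(subject) overlaps_any(dmrs, subject)
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    stringsAsFactors = FALSE)
  out$promoter <- flag(features$promoters)
  out$exon <- flag(features$exons)
  out$intron <- flag(features$introns)
  out$three_prime <- flag(features$three_prime_ends)
  out$intergenic <- !(out$promoter | out$exon | out$intron | out$three_prime)
  out$island <- flag(features$cpg_islands)
  out$shore <- flag(features$cpg_shores)
  out$shelf <- flag(features$cpg_shelves)
  known <- dmrs$chrom %in% unique(features$tss_points$chrom)
  if (any(!known)) {
    warning(sum(!known), " regions on chromosomes without gene models; ",
            "TSS distance unannotatable")
  }
  td <- tss_distance(dmrs, features$tss_points, bin_edges)
  out$tss_distance <- td$distance
  out$tss_bin <- td$bin
  out
}

#' Signed distance from regions to the nearest TSS
#'
#' Distance is 0 when the region contains the TSS; otherwise it is the gap
#' between the nearest region edge and the TSS, signed positive when the
#' region lies downstream of the TSS in the TSS's strand orientation. The
#' nearest TSS is chosen by absolute distance with ties broken toward
#' downstream, then toward the lower TSS coordinate.
#'
#' @param dmrs BED-style data.frame of regions
#' @param tss_points data.frame with chrom, pos, strand (one row per TSS)
#' @param bin_edges increasing positive bin edges in bp
#' @return data.frame with columns distance (NA when the chromosome has no
#'   TSS) and bin
#' @export
tss_distance <- function(dmrs, tss_points, bin_edges = c(5e3, 5e4, 5e5)) {
  if (nrow(tss_points) == 0) stop("empty TSS set")
  n <- nrow(dmrs)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tss <- tss_points[tss_points$chrom == dmrs$chrom[i], , drop = FALSE]
    if (nrow(tss) == 0) next
    s <- dmrs$start[i]; e <- dmrs$end[i]
    inside <- tss$pos >= s & tss$pos < e
    raw <- ifelse(inside, 0,
                  ifelse(tss$pos < s, s - tss$pos, tss$pos - e + 1L))
    # signed: + when the region is downstream in the TSS's orientation
    downstream <- ifelse(tss$pos < s, tss$strand == "+", tss$strand == "-")
    signed <- ifelse(raw == 0, 0, ifelse(downstream, raw, -raw))
    ord <- order(raw, !downstream, tss$pos)
    dist[i] <- signed[ord[1]]
  }
  data.frame(distance = dist, bin = tss_bin_label(dist, bin_edges),
             stringsAsFactors = FALSE)
}

tss_bin_label <- function(d, edges) {
  edges <- sort(edges)
  lab_mag <- function(x) {
    k <- findInterval(x, edges, left.open = TRUE)
    lo <- c(0, edges)[k + 1]
    if (k == length(edges)) {
      sprintf(">%s", fmt_kb(edges[k]))
    } else {
      sprintf("%s-%s", fmt_kb(lo), fmt_kb(edges[k + 1]))
    }
  }
  vapply(d, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x == 0) return("overlaps_tss")
    side <- if (x > 0) "downstream" else "upstream"
    paste(lab_mag(abs(x)), side, sep = "_")
  }, character(1))
}

fmt_kb <- function(x) {
  if (x >= 1000 && x %% 1000 == 0) paste0(x / 1000, "kb") else paste0(x, "bp")
}

#' Non-exclusive per-category overlap percentages of a region set
#'
#' @param annotation data.frame from [annotate_dmrs()]
#' @return named numeric vector of percentages over the region set (may sum
#'   to more than 100)
#' @export
category_percentages <- function(annotation) {
  cats <- c("promoter", "exon", "intron", "three_prime", "intergenic",
            "island", "shore", "shelf")
  n <- nrow(annotation)
  if (n == 0) return(stats::setNames(rep(NA_real_, length(cats)), cats))
  vapply(cats, function(c) 100 * sum(annotation[[c]]) / n, numeric(1))
}
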