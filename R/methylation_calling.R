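# Per-CpG methylation calling, replicate merging, distribution summaries
# and bisulfite-conversion estimation from unmethylated controls.

#' Depth-filtered methylation calls
#'
#' Keeps context-validated CpG records with at least `min_depth` reads
#' (inclusive) and recomputes the mCG/CG ratio from the counts. Strand
#' evidence is expected to be pooled into one record per CpG.
#'
#' @param records G.bed-style data.frame (chrom, start, end, ratio, total,
#'   meth)
#' @param min_depth minimal read depth (inclusive)
#' @return the filtered records with `ratio = meth / total`
#' @export
call_methylation <- function(records, min_depth = 10) {
  validate_methyl_records(records, "methylation records")
  out <- records[records$total >= min_depth, , drop = FALSE]
  out$ratio <- ifelse(out$total > 0, out$meth / out$total, NA_real_)
  rownames(out) <- NULL
  out
}

#' Merge biological replicates into group-level counts
#'
#' Counts are summed per site over replicates (mirroring merged alignments),
#' so the group ratio is the depth-weighted mean of replicate ratios.
#'
#' @param replicates list of G.bed-style data.frames
#' @return one G.bed-style data.frame with per-site summed counts
#' @export
merge_replicates <- function(replicates) {
  if (length(replicates) == 0) stop("no replicates to merge")
  for (r in replicates) validate_methyl_records(r, "replicate records")
  dt <- data.table::rbindlist(lapply(replicates, function(r) {
    data.table::as.data.table(r[, c("chrom", "start", "end", "total", "meth")])
  }))
  bad <- dt[, list(n = data.table::uniqueN(end)), by = c("chrom", "start")]
  if (any(bad$n > 1)) {
    stop("conflicting coordinates across replicates at ",
         bad$chrom[bad$n > 1][1], ":", bad$start[bad$n > 1][1])
  }
  out <- dt[, list(total = sum(total), meth = sum(meth)),
            by = c("chrom", "start", "end")]
  out[, ratio := ifelse(total > 0, meth / total, NA_real_)]
  data.table::setorder(out, chrom, start)
  as.data.frame(out[, c("chrom", "start", "end", "ratio", "total", "meth"),
                    with = FALSE])
}

#' Summarize the global methylation distribution
#'
#' Classes follow strict outer inequalities: methylated means ratio > `hi`,
#' unmethylated means ratio < `lo`; ratios equal to a boundary count as
#' intermediate.
#'
#' @param calls depth-filtered methylation calls with a `ratio` column
#' @param lo,hi class boundaries
#' @return list with n_sites, frac_methylated, frac_unmethylated,
#'   frac_intermediate (summing to 1)
#' @export
summarize_distribution <- function(calls, lo = 0.25, hi = 0.75) {
  r <- calls$ratio[!is.na(calls$ratio)]
  if (length(r) == 0) stop("no callable sites to summarize")
  n <- length(r)
  fm <- sum(r > hi) / n
  fu <- sum(r < lo) / n
  list(n_sites = n, frac_methylated = fm, frac_unmethylated = fu,
       frac_intermediate = 1 - fm - fu, lo = lo, hi = hi)
}

#' Estimate the bisulfite conversion rate from unmethylated controls
#'
#' Every methylated call on a control known to be unmethylated (phage
#' lambda spike-in, mitochondrial DNA) is a conversion failure, so the
#' conversion rate is `1 - methylated calls / total calls`, reported per
#' source and as a composite pooling all sources.
#'
#' @param controls named list mapping a source name to a G.bed-style
#'   data.frame of calls on that control contig
#' @return data.frame with columns source, n_calls, n_meth_calls,
#'   conversion_rate; the final row is the composite
#' @export
estimate_conversion <- function(controls) {
  if (length(controls) == 0) stop("no control call sets supplied")
  rows <- lapply(names(controls), function(s) {
    df <- controls[[s]]
    data.frame(source = s, n_calls = sum(df$total),
               n_meth_calls = sum(df$meth), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(source = "composite",
                               n_calls = sum(out$n_calls),
                               n_meth_calls = sum(out$n_meth_calls)))
  if (any(out$n_calls == 0)) {
    stop("control source with zero calls: ",
         out$source[out$n_calls == 0][1])
  }
  out$conversion_rate <- 1 - out$n_meth_calls / out$n_calls
  out
}

#' Joint table of per-site methylation in two groups
#'
#' Inner join on (chrom, start) of sites with depth at least `min_depth` in
#' both groups; the (ratio1, ratio2) pairs feed scatter/density export.
#'
#' @param group1,group2 G.bed-style data.frames of group-level calls
#' @param min_depth minimal depth required in each group (inclusive)
#' @return data.frame with chrom, start, meth1, total1, ratio1, meth2,
#'   total2, ratio2
#' @export
paired_site_table <- function(group1, group2, min_depth = 10) {
  g1 <- data.table::as.data.table(
    call_methylation(group1, min_depth)[, c("chrom", "start", "meth", "total",
                                            "ratio")])
  g2 <- data.table::as.data.table(
    call_methylation(group2, min_depth)[, c("chrom", "start", "meth", "total",
                                            "ratio")])
  data.table::setnames(g1, c("meth", "total", "ratio"),
                       c("meth1", "total1", "ratio1"))
  data.table::setnames(g2, c("meth", "total", "ratio"),
                       c("meth2", "total2", "ratio2"))
  out <- g1[g2, on = c("chrom", "start"), nomatch = NULL]
  data.table::setorder(out, chrom, start)
  as.data.frame(out)
}
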