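# Polymorphism-aware genomic-context validation of CpG sites.
#
# A reference CpG keyed by its plus-strand C at coordinate N is retained
# only when the combined evidence over all samples shows the dinucleotide
# intact in every genotype: at least `min_frac` of mapped bases must be G
# both at N+1 on the plus strand and at N on the minus strand, and the G
# read depth at both coordinates must reach `min_g_depth`. All four
# thresholds are inclusive.

#' Combine strand-split pileups over samples
#'
#' Sums base and methylation-call counts over a list of pileup data frames
#' keyed by (chrom, pos, strand).
#'
#' @param pileups list of pileup data.frames (see [read_pileup()])
#' @return a single combined pileup data.frame
#' @export
combine_pileups <- function(pileups) {
  dt <- data.table::rbindlist(lapply(pileups, data.table::as.data.table))
  out <- dt[, list(nA = sum(nA), nC = sum(nC), nG = sum(nG), nT = sum(nT),
                   nMeth = sum(nMeth), nUnmeth = sum(nUnmeth)),
            by = c("chrom", "pos", "strand")]
  data.table::setorder(out, chrom, pos, strand)
  as.data.frame(out)
}

#' Validate reference CpG sites against opposite-strand G evidence
#'
#' @param pileup combined pileup over all samples (see [combine_pileups()])
#' @param reference_cpgs data.frame with columns chrom, start (plus-strand C
#'   coordinate of each reference CpG)
#' @param min_frac minimal G fraction among mapped bases (inclusive)
#' @param min_g_depth minimal G read depth (inclusive)
#' @return data.frame with one row per reference CpG: chrom, cpg_start,
#'   plus_g_frac, minus_g_frac, plus_g_depth, minus_g_depth, passed,
#'   fail_reasons (comma-separated subset of plus_frac, minus_frac,
#'   plus_depth, minus_depth). Coordinates without pileup coverage fail on
#'   depth; their G fraction is NA and does not add a fraction reason.
#' @export
validate_cpg_sites <- function(pileup, reference_cpgs,
                               min_frac = 0.95, min_g_depth = 5) {
  pu <- data.table::as.data.table(pileup)
  pu[, total_bases := nA + nC + nG + nT]
  ref <- data.table::data.table(chrom = reference_cpgs$chrom,
                                cpg_start = as.integer(reference_cpgs$start))

  plus <- pu[strand == "+", c("chrom", "pos", "nG", "total_bases")]
  minus <- pu[strand == "-", c("chrom", "pos", "nG", "total_bases")]
  data.table::setnames(plus, c("nG", "total_bases"),
                       c("plus_g_depth", "plus_bases"))
  data.table::setnames(minus, c("nG", "total_bases"),
                       c("minus_g_depth", "minus_bases"))

  ref[, pos := cpg_start + 1L]
  res <- plus[ref, on = c("chrom", "pos")]
  res[, pos := cpg_start]
  res <- minus[res, on = c("chrom", "pos")]

  res[is.na(plus_bases), `:=`(plus_bases = 0L, plus_g_depth = 0L)]
  res[is.na(minus_bases), `:=`(minus_bases = 0L, minus_g_depth = 0L)]
  res[, plus_g_frac := ifelse(plus_bases > 0, plus_g_depth / plus_bases,
                              NA_real_)]
  res[, minus_g_frac := ifelse(minus_bases > 0, minus_g_depth / minus_bases,
                               NA_real_)]

  fail_pf <- !is.na(res$plus_g_frac) & res$plus_g_frac < min_frac
  fail_mf <- !is.na(res$minus_g_frac) & res$minus_g_frac < min_frac
  fail_pd <- res$plus_g_depth < min_g_depth
  fail_md <- res$minus_g_depth < min_g_depth

  reasons <- character(nrow(res))
  for (i in seq_len(4)) {
    f <- list(fail_pf, fail_mf, fail_pd, fail_md)[[i]]
    lab <- c("plus_frac", "minus_frac", "plus_depth", "minus_depth")[i]
    reasons[f] <- ifelse(nzchar(reasons[f]), paste0(reasons[f], ",", lab), lab)
  }
  res[, `:=`(passed = !(fail_pf | fail_mf | fail_pd | fail_md),
             fail_reasons = reasons)]
  out <- as.data.frame(res[, c("chrom", "cpg_start", "plus_g_frac",
                               "minus_g_frac", "plus_g_depth",
                               "minus_g_depth", "passed", "fail_reasons"),
                           with = FALSE])
  out[order(out$chrom, out$cpg_start), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Restrict methylation records to context-validated sites
#'
#' @param methyl_records G.bed-style data.frame keyed by (chrom, start)
#' @param validation data.frame from [validate_cpg_sites()]
#' @return list with `records` (the retained rows, input order preserved)
#'   and `n_unvalidated` (records whose site was absent from the validation
#'   table, treated as not passed)
#' @export
apply_validation <- function(methyl_records, validation) {
  key_rec <- paste(methyl_records$chrom, methyl_records$start)
  key_val <- paste(validation$chrom, validation$cpg_start)
  idx <- match(key_rec, key_val)
  missing <- is.na(idx)
  passed <- !missing & validation$passed[idx]
  list(
    records = methyl_records[which(passed), , drop = FALSE],
    n_unvalidated = sum(missing)
  )
}
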