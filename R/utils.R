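# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed (< 2^31)
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Coordinates in user-facing tables follow the BED convention: 0-based,
# half-open [start, end). GenomicRanges is 1-based closed, so conversion
# happens at this boundary only.
bed_to_gr <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

gr_to_bed <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

# Sort a BED-style data frame: lexicographic chrom, then start, end, strand.
sort_bed <- function(df) {
  ord <- if ("strand" %in% names(df)) {
    order(df$chrom, df$start, df$end, df$strand)
  } else {
    order(df$chrom, df$start, df$end)
  }
  rownames(df) <- NULL
  df[ord, , drop = FALSE]
}

check_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(what, ": start/end must be non-missing integers")
  }
  if (any(df$start < 0)) stop(what, ": start must be >= 0")
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(what, ": end <= start at row ", bad[1])
  }
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) stop(what, ": empty chrom")
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# region-wise overlap indicator robust to disjoint chromosome namespaces
overlaps_any <- function(query_df, subject_df) {
  if (nrow(subject_df) == 0) return(rep(FALSE, nrow(query_df)))
  q <- bed_to_gr(query_df)
  s <- GenomicRanges::reduce(bed_to_gr(subject_df), ignore.strand = TRUE)
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(s))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(s) <- lv
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0
}
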