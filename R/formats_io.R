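# Readers and writers for the external formats the pipeline touches.
#
# All genomic coordinates are 0-based, half-open [start, end), matching BED.
# A CpG site is keyed by the plus-strand C coordinate N and spans [N, N+2).

#' Read a G.bed methylation table
#'
#' The G.bed dialect used throughout the pipeline has six tab-separated
#' columns: chrom, start, end, ratio, total, meth. `end` must equal
#' `start + 2` (a CpG dinucleotide keyed by its plus-strand C), `ratio` is
#' mCG/CG in \[0,1\] and is recomputed from the counts whenever `total > 0`;
#' rows with `total == 0` keep `ratio = NA`.
#'
#' @param path path to a tab-delimited G.bed file (no header)
#' @return a data.frame with columns chrom, start, end, ratio, total, meth,
#'   sorted by (chrom, start)
#' @export
read_gbed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (ncol(dt) != 6) {
    stop("malformed G.bed file ", path, ": expected 6 columns, got ", ncol(dt))
  }
  data.table::setnames(dt, c("chrom", "start", "end", "ratio", "total", "meth"))
  df <- as.data.frame(dt)
  num <- c("start", "end", "total", "meth")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) stop("parse error in ", path, " at line ", bad[1],
                          ": non-numeric ", col)
    df[[col]] <- as.integer(v)
  }
  df$ratio <- suppressWarnings(as.numeric(df$ratio))
  validate_methyl_records(df, path)
  df$ratio <- ifelse(df$total > 0, df$meth / df$total, NA_real_)
  sort_bed(df)
}

validate_methyl_records <- function(df, what = "G.bed records") {
  check_intervals(df, what)
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$end - df$start != 2L)
  if (length(bad)) stop(what, ": end - start must be 2 at line ", bad[1])
  if (any(df$total < 0) || any(df$meth < 0)) {
    stop(what, ": negative counts")
  }
  bad <- which(df$meth > df$total)
  if (length(bad)) stop(what, ": meth > total at line ", bad[1])
  invisible(df)
}

#' Write a G.bed methylation table
#'
#' @param records data.frame as returned by [read_gbed()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gbed <- function(records, path) {
  validate_methyl_records(records)
  out <- sort_bed(records)[, c("chrom", "start", "end", "ratio", "total", "meth")]
  out$ratio <- ifelse(is.na(out$ratio), "NA", format(out$ratio, digits = 15))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED3/BED6 interval file
#'
#' @param path path to a tab-delimited BED file
#' @return data.frame with columns chrom, start, end, strand (strand "." when
#'   absent from the file), sorted
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (!ncol(dt) %in% c(3L, 4L, 5L, 6L)) {
    stop("malformed BED file ", path, ": expected 3-6 columns, got ", ncol(dt))
  }
  df <- data.frame(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end = as.integer(dt[[3]]),
    strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
    stringsAsFactors = FALSE
  )
  check_intervals(df, paste0("BED file ", path))
  sort_bed(df)
}

#' Write intervals as BED
#'
#' Emits BED6 (with placeholder name/score) when any strand is set, BED3
#' otherwise. Output is sorted.
#'
#' @param intervals data.frame with chrom, start, end and optional strand
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(intervals, path) {
  check_intervals(intervals, "BED intervals")
  df <- sort_bed(as.data.frame(intervals))
  if ("strand" %in% names(df) && any(df$strand %in% c("+", "-"))) {
    out <- data.frame(df$chrom, df$start, df$end, ".", 0L, df$strand)
  } else {
    out <- data.frame(df$chrom, df$start, df$end)
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from a genePred-like table
#'
#' Expects a tab-delimited table with header columns gene_id, chrom, strand,
#' txStart, txEnd, exonStarts, exonEnds, where the exon columns are
#' comma-separated coordinate lists of equal length. The transcription start
#' site (TSS) is `txStart` for plus-strand genes and `txEnd - 1` for
#' minus-strand genes; the transcription end site (TES) is the opposite edge.
#'
#' @param path path to the gene model table
#' @return data.frame with columns gene_id, chrom, strand, tss, tes,
#'   tx_start, tx_end, exon_starts, exon_ends (the exon columns are lists of
#'   integer vectors)
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character", showProgress = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds")
  if (!all(need %in% names(dt))) {
    stop("gene model table ", path, " missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  parse_list <- function(x) {
    lapply(strsplit(x, ","), function(v) as.integer(v[nzchar(v)]))
  }
  starts <- parse_list(dt$exonStarts)
  ends <- parse_list(dt$exonEnds)
  bad <- which(lengths(starts) != lengths(ends))
  if (length(bad)) {
    stop("parse error in ", path, " at line ", bad[1] + 1L,
         ": exonStarts and exonEnds have unequal length")
  }
  gene_models(
    gene_id = dt$gene_id, chrom = dt$chrom, strand = dt$strand,
    tx_start = as.integer(dt$txStart), tx_end = as.integer(dt$txEnd),
    exon_starts = starts, exon_ends = ends
  )
}

#' Construct a gene model table from components
#'
#' @param gene_id,chrom,strand,tx_start,tx_end vectors of equal length;
#'   strand must be "+" or "-"
#' @param exon_starts,exon_ends lists of integer vectors (0-based half-open
#'   exon coordinates), defaulting to a single exon spanning the transcript
#' @return data.frame as documented in [read_gene_models()]
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (is.null(exon_starts)) exon_starts <- as.list(tx_start)
  if (is.null(exon_ends)) exon_ends <- as.list(tx_end)
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(tx_end <= tx_start)) stop("txEnd must exceed txStart")
  for (i in seq_len(n)) {
    s <- exon_starts[[i]]; e <- exon_ends[[i]]
    if (length(s) != length(e)) stop("unequal exon lists for gene ", gene_id[i])
    if (any(e <= s)) stop("empty exon in gene ", gene_id[i])
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1) {
      stop("exons not sorted for gene ", gene_id[i])
    }
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) {
      stop("overlapping exons for gene ", gene_id[i])
    }
    if (min(s) < tx_start[i] || max(e) > tx_end[i]) {
      stop("exon outside transcript for gene ", gene_id[i])
    }
  }
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand),
    tss = ifelse(strand == "+", tx_start, tx_end - 1L),
    tes = ifelse(strand == "+", tx_end - 1L, tx_start),
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  df
}

#' Write gene models as a genePred-like table
#'
#' @param models data.frame as produced by [gene_models()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_models <- function(models, path) {
  out <- data.frame(
    gene_id = models$gene_id, chrom = models$chrom, strand = models$strand,
    txStart = models$tx_start, txEnd = models$tx_end,
    exonStarts = vapply(models$exon_starts, paste, "", collapse = ","),
    exonEnds = vapply(models$exon_ends, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a strand-split base pileup table
#'
#' Tab-delimited with header: chrom, pos, strand, nA, nC, nG, nT, nMeth,
#' nUnmeth. `pos` is 0-based; `strand` is "+" or "-"; base counts are mapped
#' read bases at that strand/coordinate; nMeth/nUnmeth are methylation calls
#' at cytosine positions (0 elsewhere).
#'
#' @param path path to the pileup TSV
#' @return data.frame with the columns above
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        showProgress = FALSE))
  need <- c("chrom", "pos", "strand", "nA", "nC", "nG", "nT", "nMeth", "nUnmeth")
  if (!all(need %in% names(df))) {
    stop("pileup table ", path, " missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  counts <- as.matrix(df[, c("nA", "nC", "nG", "nT", "nMeth", "nUnmeth")])
  if (any(counts < 0)) stop("pileup table ", path, ": negative counts")
  df
}

#' @rdname read_pileup
#' @param pileup data.frame of pileup rows
#' @export
write_pileup <- function(pileup, path) {
  data.table::fwrite(pileup, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an M-bias methylation call table
#'
#' Tab-delimited with header: mate, length_class, read_pos, nMeth, nUnmeth.
#'
#' @param path path to the call table TSV
#' @return data.frame with the columns above
#' @export
read_mbias_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        showProgress = FALSE))
  need <- c("mate", "length_class", "read_pos", "nMeth", "nUnmeth")
  if (!all(need %in% names(df))) {
    stop("M-bias table ", path, " missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' @rdname read_mbias_table
#' @param calls data.frame of call rows
#' @export
write_mbias_table <- function(calls, path) {
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-delimited with header: a `gene_id` column followed by one numeric
#' FPKM column per replicate.
#'
#' @param path path to the expression TSV
#' @return data.frame with gene_id plus replicate FPKM columns
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        showProgress = FALSE))
  if (!"gene_id" %in% names(df)) stop("expression table needs a gene_id column")
  df
}

#' @rdname read_expression
#' @param expression data.frame with gene_id plus FPKM columns
#' @export
write_expression <- function(expression, path) {
  data.table::fwrite(expression, path, sep = "\t", quote = FALSE)
  invisible(path)
}
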