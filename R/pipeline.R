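# End-to-end orchestration: simulate -> M-bias QC -> context validation ->
# methylation calling -> DMR calling -> annotation -> enrichment.

#' Run the full analysis on a simulated dataset
#'
#' Generates a synthetic WGBS dataset, computes the M-bias trim report,
#' context-validates reference CpGs on the sample-combined pileup, produces
#' depth-filtered group-level methylation calls and distribution summaries,
#' estimates bisulfite conversion from the unmethylated spike-in, calls
#' DMRs between the two groups, annotates them against the generated gene
#' models and CpG islands, and tests overlap enrichment against
#' length-matched shuffled nulls.
#'
#' @param config a [sim_config()]
#' @param dmr_cfg a [dmr_config()]
#' @param min_depth per-group read depth filter for calling (inclusive)
#' @param min_frac,min_g_depth context-validation thresholds
#' @param shuffle_seed seed for the null-region shuffle
#' @param outdir optional directory; when given, simulation inputs and all
#'   stage outputs are written there
#' @return a list with elements sim, trim_report, validation, calls (per
#'   group), summaries (per group), conversion, paired, site_diffs, dmrs,
#'   features, annotation, enrichment
#' @export
run_pipeline <- function(config = sim_config(), dmr_cfg = dmr_config(),
                         min_depth = 10, min_frac = 0.95, min_g_depth = 5,
                         shuffle_seed = 1000, outdir = NULL) {
  sim <- simulate_wgbs(config)
  truth <- sim$truth

  trim_report <- mbias_trim_report(sim$mbias_table)

  combined <- combine_pileups(c(sim$pileups$wt, sim$pileups$ko))
  ref_cpgs <- truth$cpg[, c("chrom", "start")]
  validation <- validate_cpg_sites(combined, ref_cpgs,
                                   min_frac = min_frac,
                                   min_g_depth = min_g_depth)

  spike <- truth$spike_in_name
  groups <- list(wt = sim$gbed$wt, ko = sim$gbed$ko)
  calls <- list(); summaries <- list(); spike_records <- list()
  for (g in names(groups)) {
    merged <- merge_replicates(groups[[g]])
    validated <- apply_validation(merged, validation)$records
    spike_records[[g]] <- validated[validated$chrom == spike, , drop = FALSE]
    genomic <- validated[validated$chrom != spike, , drop = FALSE]
    calls[[g]] <- call_methylation(genomic, min_depth = min_depth)
    summaries[[g]] <- summarize_distribution(calls[[g]])
  }
  conversion <- estimate_conversion(list(
    spike_in = do.call(rbind, spike_records)
  ))

  paired <- paired_site_table(calls$wt, calls$ko, min_depth = min_depth)
  site_diffs <- site_cdif_table(calls$wt, calls$ko, dmr_cfg)
  dmrs <- call_dmrs(site_diffs, dmr_cfg)

  features <- build_features(truth$gene_models, truth$cpg_islands,
                             chrom_lengths = truth$chrom_lengths)
  annotation <- annotate_dmrs(dmrs, features)

  by_dir <- dmr_report(dmrs)
  sh_cfg <- shuffle_config(seed = shuffle_seed)
  nulls <- lapply(by_dir, function(d) {
    if (nrow(d) == 0) d else shuffle_regions(d, truth$chrom_lengths, sh_cfg)
  })
  expr_bodies <- expressed_gene_bodies(truth$expression, truth$gene_models)
  cats <- list(
    promoter = features$promoters, exon = features$exons,
    intron = features$introns, three_prime = features$three_prime_ends,
    gene_body = features$gene_bodies, expressed_gene_body = expr_bodies,
    island = features$cpg_islands, shore = features$cpg_shores,
    shelf = features$cpg_shelves
  )
  enrichment <- enrichment_report(by_dir, cats, nulls)

  res <- list(sim = sim, trim_report = trim_report, validation = validation,
              calls = calls, summaries = summaries, conversion = conversion,
              paired = paired, site_diffs = site_diffs, dmrs = dmrs,
              features = features, annotation = annotation,
              enrichment = enrichment)

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(res$sim, file.path(outdir, "sim"))
  data.table::fwrite(res$trim_report, file.path(outdir, "trim_report.tsv"),
                     sep = "\t")
  data.table::fwrite(res$validation, file.path(outdir, "validation.tsv"),
                     sep = "\t")
  passed <- res$validation[res$validation$passed, , drop = FALSE]
  write_bed(data.frame(chrom = passed$chrom, start = passed$cpg_start,
                       end = passed$cpg_start + 2L),
            file.path(outdir, "validated_sites.bed"))
  for (g in names(res$calls)) {
    write_gbed(res$calls[[g]], file.path(outdir, paste0(g, ".calls.G.bed")))
  }
  summaries <- lapply(res$summaries, function(s) s[c(
    "n_sites", "frac_methylated", "frac_unmethylated", "frac_intermediate")])
  jsonlite::write_json(summaries, file.path(outdir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(res$conversion, file.path(outdir, "conversion.tsv"),
                     sep = "\t")
  data.table::fwrite(res$paired, file.path(outdir, "paired_sites.tsv"),
                     sep = "\t")
  data.table::fwrite(res$site_diffs, file.path(outdir, "site_diffs.tsv"),
                     sep = "\t")
  rep <- dmr_report(res$dmrs)
  data.table::fwrite(rep$hypo, file.path(outdir, "dmrs_hypo.tsv"), sep = "\t")
  data.table::fwrite(rep$hyper, file.path(outdir, "dmrs_hyper.tsv"), sep = "\t")
  data.table::fwrite(res$annotation, file.path(outdir, "annotation.tsv"),
                     sep = "\t")
  data.table::fwrite(res$enrichment, file.path(outdir, "enrichment.tsv"),
                     sep = "\t")
  invisible(outdir)
}

#' Match called regions against truth regions by interval overlap
#'
#' A truth region counts as recovered when at least one called region
#' overlaps it by at least one base (and, when directions are supplied,
#' with the matching direction); a called region is a true positive when it
#' overlaps at least one truth region.
#'
#' @param called,truth BED-style data.frames, optionally with a `direction`
#'   column
#' @param match_direction require directions to agree
#' @return list with sensitivity, precision, n_called, n_truth
#' @export
match_dmrs <- function(called, truth, match_direction = TRUE) {
  if (nrow(truth) == 0) {
    return(list(sensitivity = NA_real_,
                precision = if (nrow(called) == 0) NA_real_ else 0,
                n_called = nrow(called), n_truth = 0L))
  }
  if (nrow(called) == 0) {
    return(list(sensitivity = 0, precision = NA_real_, n_called = 0L,
                n_truth = nrow(truth)))
  }
  cq <- bed_to_gr(called); tq <- bed_to_gr(truth)
  lv <- union(GenomeInfoDb::seqlevels(cq), GenomeInfoDb::seqlevels(tq))
  GenomeInfoDb::seqlevels(cq) <- lv
  GenomeInfoDb::seqlevels(tq) <- lv
  hits <- GenomicRanges::findOverlaps(cq, tq, ignore.strand = TRUE)
  if (match_direction && !is.null(called$direction) &&
      !is.null(truth$direction)) {
    keep <- called$direction[S4Vectors::queryHits(hits)] ==
      truth$direction[S4Vectors::subjectHits(hits)]
    hits <- hits[keep]
  }
  list(
    sensitivity = length(unique(S4Vectors::subjectHits(hits))) / nrow(truth),
    precision = length(unique(S4Vectors::queryHits(hits))) / nrow(called),
    n_called = nrow(called), n_truth = nrow(truth)
  )
}
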