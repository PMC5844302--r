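# Synthetic WGBS data generator.
#
# Simulates a toy genome (CpG coordinates, gene models, CpG islands, an
# unmethylated spike-in contig), a bimodal ground-truth methylome for two
# genotype groups with planted focal hypo-/hyper-methylation effects,
# CpG-destroying polymorphisms, and strand-split per-position pileups with
# incomplete bisulfite conversion, base miscalls and read-end M-bias
# artifacts. The simulation unit is the pileup, not the read: per-read
# positional bias is represented by a separate read-position-resolved
# methylation call table consumed by the M-bias module.

#' Simulation configuration
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param spike_in_length length of the always-unmethylated spike-in contig
#'   ("lambda"); the phage lambda genome length by default
#' @param n_genes total number of genes, distributed over chromosomes
#'   proportionally to length (at least one per chromosome)
#' @param cpg_rate expected CpGs per bp outside CpG islands
#' @param island_rate_factor CpG density multiplier inside islands
#' @param island_frac_genes fraction of genes carrying a promoter CpG island
#' @param high_frac,low_frac,mid_frac mixture weights of the
#'   highly-methylated (> 0.75), unmethylated (< 0.25) and intermediate
#'   methylome components; must sum to 1
#' @param depth_mean expected reads per CpG per strand per replicate
#'   (Poisson)
#' @param conversion_failure probability that a truly unmethylated cytosine
#'   reads as methylated (incomplete bisulfite conversion)
#' @param meth_miscall probability that a truly methylated cytosine reads as
#'   unmethylated (over-conversion)
#' @param base_miscall per-base sequencing miscall rate applied to the
#'   opposite-strand G evidence
#' @param snp_rate fraction of reference CpGs destroyed by a polymorphism in
#'   the sample genotype
#' @param snp_exclude_dmrs keep polymorphisms out of planted DMRs
#' @param n_hypo,n_hyper planted focal effect counts (hypo/hyper in group 2)
#' @param dmr_n_cpgs consecutive CpGs per planted effect
#' @param dmr_width_bp maximal genomic span of a planted effect
#' @param dmr_delta absolute methylation difference planted at every CpG of
#'   an affected region
#' @param dmr_redraw_wt redraw baseline levels inside planted regions so the
#'   full delta fits in \[0,1\] (guarantees the planted difference); when
#'   FALSE, shifted levels are clipped instead
#' @param p_genic probability a hypomethylation effect is placed inside the
#'   gene body of an expressed gene
#' @param dmr_min_separation minimal distance between planted effects in bp
#' @param mbias_spec data.frame (mate, length_class, read_pos, offset)
#'   of additive per-read-position bias artifacts
#' @param mbias_calls_per_pos methylation calls simulated per read position
#' @param n_replicates biological replicates per group
#' @param expressed_frac fraction of genes expressed (mean FPKM >= 1)
#' @param n_expr_replicates expression replicates
#' @param seed integer RNG seed; every stage derives its stream from it
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       spike_in_length = 48500,
                       n_genes = 60,
                       cpg_rate = 0.02,
                       island_rate_factor = 8,
                       island_frac_genes = 0.5,
                       high_frac = 0.82, low_frac = 0.07, mid_frac = 0.11,
                       depth_mean = 30,
                       conversion_failure = 0.0016,
                       meth_miscall = 0,
                       base_miscall = 0.005,
                       snp_rate = 0.05,
                       snp_exclude_dmrs = TRUE,
                       n_hypo = 20, n_hyper = 10,
                       dmr_n_cpgs = 10,
                       dmr_width_bp = 2000,
                       dmr_delta = 0.4,
                       dmr_redraw_wt = TRUE,
                       p_genic = 0.8,
                       dmr_min_separation = 2000,
                       mbias_spec = default_mbias_spec(),
                       mbias_calls_per_pos = 5000,
                       n_replicates = 3,
                       expressed_frac = 0.6,
                       n_expr_replicates = 2,
                       seed = 1) {
  cfg <- list(
    chrom_lengths = chrom_lengths, spike_in_length = spike_in_length,
    spike_in_name = "lambda", n_genes = n_genes, cpg_rate = cpg_rate,
    island_rate_factor = island_rate_factor,
    island_frac_genes = island_frac_genes,
    high_frac = high_frac, low_frac = low_frac, mid_frac = mid_frac,
    depth_mean = depth_mean, conversion_failure = conversion_failure,
    meth_miscall = meth_miscall, base_miscall = base_miscall,
    snp_rate = snp_rate, snp_exclude_dmrs = snp_exclude_dmrs,
    n_hypo = n_hypo, n_hyper = n_hyper, dmr_n_cpgs = dmr_n_cpgs,
    dmr_width_bp = dmr_width_bp, dmr_delta = dmr_delta,
    dmr_redraw_wt = dmr_redraw_wt, p_genic = p_genic,
    dmr_min_separation = dmr_min_separation,
    mbias_spec = mbias_spec, mbias_calls_per_pos = mbias_calls_per_pos,
    n_replicates = n_replicates, expressed_frac = expressed_frac,
    n_expr_replicates = n_expr_replicates, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default read-end bias artifacts
#'
#' An additive +0.1 apparent-methylation offset at the first five positions
#' of PE150 reads and the first three of PE75 reads, both mates.
#'
#' @return data.frame with columns mate, length_class, read_pos, offset
#' @export
default_mbias_spec <- function() {
  rbind(
    expand.grid(mate = 1:2, length_class = "PE150", read_pos = 1:5,
                offset = 0.1, stringsAsFactors = FALSE),
    expand.grid(mate = 1:2, length_class = "PE75", read_pos = 1:3,
                offset = 0.1, stringsAsFactors = FALSE)
  )
}

validate_sim_config <- function(cfg) {
  w <- cfg$high_frac + cfg$low_frac + cfg$mid_frac
  if (abs(w - 1) > 1e-9) stop("mixture weights must sum to 1, got ", w)
  if (cfg$conversion_failure < 0 || cfg$conversion_failure >= 0.05) {
    stop("conversion_failure must be in [0, 0.05)")
  }
  if (cfg$dmr_delta <= 0 || cfg$dmr_delta > 1) {
    stop("dmr_delta must be in (0, 1]")
  }
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(cfg$chrom_lengths < 20000)) {
    stop("chromosomes must be at least 20 kb to fit a minimal gene footprint")
  }
  if (cfg$snp_rate < 0 || cfg$snp_rate > 1) stop("snp_rate must be in [0, 1]")
  invisible(cfg)
}

# read-length per class
.class_lengths <- c(PE150 = 150L, PE75 = 75L)

#' Build the synthetic reference: CpG map, gene models, islands, expression
#'
#' Deterministic given `config$seed`. Gene bodies are placed without
#' overlap; a configurable fraction of genes carries a CpG island around its
#' TSS, inside which CpG density is elevated; the spike-in contig gets CpGs
#' at the background rate and carries no genes.
#'
#' @param config a [sim_config()]
#' @return a list of class `sim_reference` with elements `chrom_lengths`,
#'   `spike_in_name`, `cpg` (data.frame chrom, start of each plus-strand C),
#'   `gene_models`, `cpg_islands` (BED-style data.frame), `expression`,
#'   `expressed_gene_ids`
#' @export
build_reference <- function(config) {
  with_seed(config$seed, {
    chroms <- names(config$chrom_lengths)
    lens <- as.numeric(config$chrom_lengths)

    # distribute genes over chromosomes proportionally to length
    n_per <- pmax(1L, round(config$n_genes * lens / sum(lens)))
    gm_list <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      gm_list[[ci]] <- place_genes(chroms[ci], lens[ci], n_per[ci])
    }
    gm <- do.call(rbind, gm_list)
    gm$gene_id <- sprintf("gene%03d", seq_len(nrow(gm)))
    models <- gene_models(
      gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
      tx_start = gm$tx_start, tx_end = gm$tx_end,
      exon_starts = gm$exon_starts, exon_ends = gm$exon_ends
    )

    # CpG islands around a fraction of TSSs
    n_isl <- round(config$island_frac_genes * nrow(models))
    islands <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0))
    if (n_isl > 0) {
      idx <- sample(nrow(models), n_isl)
      w <- sample(600:1500, n_isl, replace = TRUE)
      ctr <- models$tss[idx]
      isl <- data.frame(
        chrom = models$chrom[idx],
        start = pmax(0L, as.integer(ctr - w %/% 2)),
        end = as.integer(ctr + w %/% 2),
        strand = ".", stringsAsFactors = FALSE
      )
      isl$end <- pmin(isl$end, config$chrom_lengths[isl$chrom])
      isl <- isl[isl$end > isl$start, , drop = FALSE]
      gr <- GenomicRanges::reduce(bed_to_gr(isl))
      islands <- gr_to_bed(gr)
    }

    # CpG coordinates: Bernoulli over non-overlapping 2-bp slots, with
    # elevated density inside islands
    cpg_list <- vector("list", length(chroms) + 1L)
    for (ci in seq_along(chroms)) {
      cpg_list[[ci]] <- draw_cpg_positions(
        chroms[ci], lens[ci], config$cpg_rate,
        islands[islands$chrom == chroms[ci], , drop = FALSE],
        config$island_rate_factor
      )
    }
    cpg_list[[length(chroms) + 1L]] <- draw_cpg_positions(
      config$spike_in_name, config$spike_in_length, config$cpg_rate,
      islands[0, , drop = FALSE], 1
    )
    cpg <- do.call(rbind, cpg_list)

    # expression: expressed genes have every-replicate FPKM >= 1
    n_expr <- round(config$expressed_frac * nrow(models))
    expressed <- sort(sample(nrow(models), n_expr))
    fpkm <- matrix(stats::runif(nrow(models) * config$n_expr_replicates, 0, 0.9),
                   nrow = nrow(models))
    fpkm[expressed, ] <- 1 + matrix(
      stats::rlnorm(n_expr * config$n_expr_replicates, log(4), 0.6),
      nrow = n_expr
    )
    expression <- data.frame(gene_id = models$gene_id, stringsAsFactors = FALSE)
    for (r in seq_len(config$n_expr_replicates)) {
      expression[[paste0("fpkm_", r)]] <- fpkm[, r]
    }

    structure(list(
      chrom_lengths = config$chrom_lengths,
      spike_in_name = config$spike_in_name,
      spike_in_length = config$spike_in_length,
      cpg = cpg,
      gene_models = models,
      cpg_islands = islands,
      expression = expression,
      expressed_gene_ids = models$gene_id[expressed]
    ), class = "sim_reference")
  })
}

# non-overlapping gene placement on one chromosome by rejection
place_genes <- function(chrom, len, n) {
  placed_s <- integer(0); placed_e <- integer(0)
  strand <- character(0); ex_s <- list(); ex_e <- list()
  tries <- 0L
  while (length(placed_s) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("cannot place ", n, " non-overlapping genes on ", chrom,
           " (", len, " bp)")
    }
    w <- sample(5000:15000, 1)
    if (w + 2000 >= len) stop("chromosome ", chrom, " too short for a gene")
    s <- sample.int(len - w, 1) - 1L
    e <- s + w
    if (any(s < placed_e + 1000L & e > placed_s - 1000L)) next
    placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
    strand <- c(strand, sample(c("+", "-"), 1))
    n_ex <- sample(2:5, 1)
    cuts <- sort(sample(seq(s + 200L, e - 200L, by = 50L), 2L * n_ex - 2L))
    starts <- c(s, cuts[seq(2, length(cuts), by = 2)])
    ends <- c(cuts[seq(1, length(cuts), by = 2)], e)
    ex_s <- c(ex_s, list(as.integer(starts)))
    ex_e <- c(ex_e, list(as.integer(ends)))
  }
  out <- data.frame(chrom = chrom, strand = strand,
                    tx_start = placed_s, tx_end = placed_e,
                    stringsAsFactors = FALSE)
  out$exon_starts <- ex_s
  out$exon_ends <- ex_e
  out
}

draw_cpg_positions <- function(chrom, len, rate, islands, factor) {
  slots <- seq(0L, as.integer(len) - 2L, by = 2L)
  p <- rep(min(1, 2 * rate), length(slots))
  if (nrow(islands) > 0 && factor != 1) {
    in_isl <- rep(FALSE, length(slots))
    for (i in seq_len(nrow(islands))) {
      in_isl <- in_isl | (slots >= islands$start[i] & slots < islands$end[i] - 1L)
    }
    p[in_isl] <- min(1, 2 * rate * factor)
  }
  keep <- stats::rbinom(length(slots), 1L, p) == 1L
  data.frame(chrom = chrom, start = slots[keep], stringsAsFactors = FALSE)
}

#' Draw the baseline (group 1) methylome from the three-component mixture
#'
#' Per-CpG methylation levels come from a mixture of a highly-methylated
#' component supported on (0.75, 1), an unmethylated component on (0, 0.25)
#' and an intermediate component on (0.25, 0.75); component densities vanish
#' at the class boundaries so sampling noise rarely moves sites across them.
#' Spike-in CpGs are set to exactly 0.
#'
#' @param config a [sim_config()]
#' @param reference a [build_reference()] result
#' @return a list of class `sim_truth`: the reference plus `cpg` gaining
#'   columns `level_wt` and `component`
#' @export
draw_methylome <- function(config, reference) {
  with_seed(config$seed + 1L, {
    cpg <- reference$cpg
    n <- nrow(cpg)
    comp <- sample(c("high", "low", "mid"), n, replace = TRUE,
                   prob = c(config$high_frac, config$low_frac, config$mid_frac))
    lvl <- numeric(n)
    hi <- comp == "high"; lo <- comp == "low"; mi <- comp == "mid"
    lvl[hi] <- 0.75 + 0.25 * stats::rbeta(sum(hi), 2, 1)
    lvl[lo] <- 0.25 * stats::rbeta(sum(lo), 1, 2)
    lvl[mi] <- 0.25 + 0.50 * stats::rbeta(sum(mi), 2, 2)
    spike <- cpg$chrom == reference$spike_in_name
    lvl[spike] <- 0
    comp[spike] <- "spike_in"
    cpg$level_wt <- lvl
    cpg$component <- comp
    out <- reference
    out$cpg <- cpg
    out$dmr_truth <- data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), direction = character(0),
                                stringsAsFactors = FALSE)
    out$snp_sites <- data.frame(chrom = character(0), start = integer(0),
                                alt_base = character(0), stringsAsFactors = FALSE)
    class(out) <- c("sim_truth", "sim_reference")
    out
  })
}

#' Plant focal differential-methylation effects (group 2 methylome)
#'
#' Places `n_hypo` regions where group 2 is lower by exactly `dmr_delta` and
#' `n_hyper` where it is higher, each covering `dmr_n_cpgs` consecutive CpGs
#' within a span of at most `dmr_width_bp`. Hypomethylation effects land
#' inside gene bodies of expressed genes with probability `p_genic`;
#' hypermethylated and non-genic regions are placed uniformly. Regions are
#' mutually separated by at least `dmr_min_separation` bp. With
#' `dmr_redraw_wt` (default) baseline levels inside a region are redrawn
#' uniformly from the sub-interval of \[0,1\] that accommodates the full
#' delta, so the planted difference is exact; otherwise shifted levels are
#' clipped into \[0,1\].
#'
#' @param truth a [draw_methylome()] result
#' @param config the same [sim_config()]
#' @return `truth` with `cpg$level_ko` and `dmr_truth` filled in
#' @export
plant_effects <- function(truth, config) {
  with_seed(config$seed + 2L, {
    cpg <- truth$cpg
    cpg$level_ko <- cpg$level_wt
    n_eff <- config$n_hypo + config$n_hyper
    if (n_eff == 0) {
      truth$cpg <- cpg
      return(truth)
    }
    spike <- cpg$chrom == truth$spike_in_name
    idx_by_chrom <- split(which(!spike), cpg$chrom[!spike])

    body <- truth$gene_models[truth$gene_models$gene_id %in%
                                truth$expressed_gene_ids, , drop = FALSE]
    directions <- c(rep("hypo", config$n_hypo), rep("hyper", config$n_hyper))
    placed <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), direction = character(0),
                         stringsAsFactors = FALSE)
    k <- config$dmr_n_cpgs
    for (d in directions) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        genic <- d == "hypo" && nrow(body) > 0 && stats::runif(1) < config$p_genic
        if (genic) {
          g <- body[sample.int(nrow(body), 1), ]
          cand <- idx_by_chrom[[g$chrom]]
          cand <- cand[cpg$start[cand] >= min(g$tss, g$tes) &
                         cpg$start[cand] + 2L <= max(g$tss, g$tes) + 1L]
        } else {
          ch <- sample(names(idx_by_chrom), 1,
                       prob = lengths(idx_by_chrom))
          cand <- idx_by_chrom[[ch]]
        }
        if (length(cand) < k) next
        i0 <- sample.int(length(cand) - k + 1L, 1)
        run <- cand[i0:(i0 + k - 1L)]
        # runs must be consecutive reference CpGs on the chromosome
        if (any(diff(run) != 1L)) next
        s <- cpg$start[run[1]]; e <- cpg$start[run[k]] + 2L
        if (e - s > config$dmr_width_bp) next
        ch <- cpg$chrom[run[1]]
        near <- placed$chrom == ch &
          placed$start < e + config$dmr_min_separation &
          placed$end > s - config$dmr_min_separation
        if (any(near)) next
        # plant the effect
        delta <- config$dmr_delta
        if (config$dmr_redraw_wt) {
          if (d == "hypo") {
            wt <- stats::runif(k, delta, 1)
          } else {
            wt <- stats::runif(k, 0, 1 - delta)
          }
          cpg$level_wt[run] <- wt
        }
        shift <- if (d == "hypo") -delta else delta
        cpg$level_ko[run] <- pmin(1, pmax(0, cpg$level_wt[run] + shift))
        placed <- rbind(placed, data.frame(
          chrom = ch, start = s, end = e, direction = d,
          stringsAsFactors = FALSE
        ))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not place a ", d, " effect after bounded retries; ",
             "genome too small for the requested non-overlapping regions")
      }
    }
    truth$cpg <- cpg
    truth$dmr_truth <- sort_bed(placed)
    truth
  })
}

#' Plant CpG-destroying polymorphisms
#'
#' Marks a `snp_rate` fraction of reference CpGs (never on the spike-in, and
#' never inside planted effects when `snp_exclude_dmrs` is set) as destroyed
#' in the sample genotype: the G of the dinucleotide is replaced by a random
#' alternate base, which the pileup simulator propagates to the
#' opposite-strand base evidence.
#'
#' @param truth a [plant_effects()] (or [draw_methylome()]) result
#' @param config the same [sim_config()]
#' @return `truth` with `snp_sites` filled in
#' @export
plant_cpg_snps <- function(truth, config) {
  with_seed(config$seed + 3L, {
    cpg <- truth$cpg
    eligible <- cpg$chrom != truth$spike_in_name
    if (config$snp_exclude_dmrs && nrow(truth$dmr_truth) > 0) {
      for (i in seq_len(nrow(truth$dmr_truth))) {
        d <- truth$dmr_truth[i, ]
        eligible <- eligible & !(cpg$chrom == d$chrom &
                                   cpg$start >= d$start & cpg$start < d$end)
      }
    }
    idx <- which(eligible)
    hit <- idx[stats::rbinom(length(idx), 1L, config$snp_rate) == 1L]
    truth$snp_sites <- data.frame(
      chrom = cpg$chrom[hit],
      start = cpg$start[hit],
      alt_base = sample(c("A", "C", "T"), length(hit), replace = TRUE),
      stringsAsFactors = FALSE
    )
    truth
  })
}

#' Simulate strand-split pileups, per-replicate G.bed tables and the M-bias
#' call table
#'
#' Per CpG, strand and replicate, read depth is Poisson(`depth_mean`) and
#' the methylated call count is binomial with success probability
#' `level * (1 - meth_miscall) + (1 - level) * conversion_failure`. Four
#' pileup rows are emitted per CpG keyed by the plus-strand C at N: the
#' methylation evidence at (N, +) and (N+1, -), and the base evidence at
#' (N+1, +) and (N, -) whose true base is G except at polymorphic sites.
#' Base calls are corrupted at rate `base_miscall`. The M-bias call table
#' distributes calls uniformly over read positions per (mate, length class)
#' and perturbs per-position levels by the additive offsets in
#' `mbias_spec`; pileups themselves represent post-trimming data and carry
#' no positional bias.
#'
#' @param truth a completed `sim_truth`
#' @param config the same [sim_config()]
#' @return a list of class `sim_data`: `pileups[[group]][[replicate]]`,
#'   `gbed[[group]][[replicate]]`, `mbias_table`, plus the `truth` used
#' @export
simulate_pileups <- function(truth, config) {
  with_seed(config$seed + 4L, {
    cpg <- truth$cpg
    if (is.null(cpg$level_ko)) cpg$level_ko <- cpg$level_wt
    n <- nrow(cpg)
    snp_key <- paste(truth$snp_sites$chrom, truth$snp_sites$start)
    is_snp <- paste(cpg$chrom, cpg$start) %in% snp_key
    alt <- rep(NA_character_, n)
    if (any(is_snp)) {
      alt[match(snp_key, paste(cpg$chrom, cpg$start))] <- truth$snp_sites$alt_base
    }
    comp_base <- c(A = "T", C = "G", G = "C", T = "A")

    groups <- list(wt = cpg$level_wt, ko = cpg$level_ko)
    pileups <- list(); gbed <- list()
    for (g in names(groups)) {
      lvl <- groups[[g]]
      p_eff <- lvl * (1 - config$meth_miscall) +
        (1 - lvl) * config$conversion_failure
      pileups[[g]] <- list(); gbed[[g]] <- list()
      for (r in seq_len(config$n_replicates)) {
        d_plus <- stats::rpois(n, config$depth_mean)
        d_minus <- stats::rpois(n, config$depth_mean)
        m_plus <- stats::rbinom(n, d_plus, p_eff)
        m_minus <- stats::rbinom(n, d_minus, p_eff)

        # plus-strand C row at N: methylated reads report C, converted report T
        row_c_plus <- data.frame(
          chrom = cpg$chrom, pos = cpg$start, strand = "+",
          nA = 0L, nC = m_plus, nG = 0L, nT = d_plus - m_plus,
          nMeth = m_plus, nUnmeth = d_plus - m_plus,
          stringsAsFactors = FALSE
        )
        # base evidence: G at N+1 (+) and N (-), alt base at SNP sites
        true_plus <- ifelse(is_snp, alt, "G")
        bc_plus <- draw_base_counts(d_plus, true_plus, config$base_miscall)
        row_g_plus <- data.frame(
          chrom = cpg$chrom, pos = cpg$start + 1L, strand = "+",
          nA = bc_plus[, "A"], nC = bc_plus[, "C"],
          nG = bc_plus[, "G"], nT = bc_plus[, "T"],
          nMeth = 0L, nUnmeth = 0L, stringsAsFactors = FALSE
        )
        bc_minus <- draw_base_counts(d_minus, rep("G", n), config$base_miscall)
        row_g_minus <- data.frame(
          chrom = cpg$chrom, pos = cpg$start, strand = "-",
          nA = bc_minus[, "A"], nC = bc_minus[, "C"],
          nG = bc_minus[, "G"], nT = bc_minus[, "T"],
          nMeth = 0L, nUnmeth = 0L, stringsAsFactors = FALSE
        )
        # minus-strand C row at N+1; at SNP sites the base is the
        # complement of the alternate and carries no methylation calls
        mm <- ifelse(is_snp, 0L, m_minus)
        um <- ifelse(is_snp, 0L, d_minus - m_minus)
        row_c_minus <- data.frame(
          chrom = cpg$chrom, pos = cpg$start + 1L, strand = "-",
          nA = 0L, nC = mm, nG = 0L, nT = um,
          nMeth = mm, nUnmeth = um, stringsAsFactors = FALSE
        )
        if (any(is_snp)) {
          cb <- comp_base[alt[is_snp]]
          snp_counts <- draw_base_counts(d_minus[is_snp], cb,
                                         config$base_miscall)
          row_c_minus$nA[is_snp] <- snp_counts[, "A"]
          row_c_minus$nC[is_snp] <- snp_counts[, "C"]
          row_c_minus$nG[is_snp] <- snp_counts[, "G"]
          row_c_minus$nT[is_snp] <- snp_counts[, "T"]
        }
        pu <- rbind(row_c_plus, row_g_plus, row_g_minus, row_c_minus)
        pu <- pu[order(pu$chrom, pu$pos, pu$strand), ]
        rownames(pu) <- NULL
        pileups[[g]][[r]] <- pu

        gb <- data.frame(
          chrom = cpg$chrom, start = cpg$start, end = cpg$start + 2L,
          total = d_plus + ifelse(is_snp, 0L, d_minus),
          meth = m_plus + mm, stringsAsFactors = FALSE
        )
        gb$ratio <- ifelse(gb$total > 0, gb$meth / gb$total, NA_real_)
        gbed[[g]][[r]] <- sort_bed(gb[, c("chrom", "start", "end",
                                          "ratio", "total", "meth")])
      }
    }

    mbias_table <- simulate_mbias_calls(truth, config)

    structure(list(pileups = pileups, gbed = gbed,
                   mbias_table = mbias_table, truth = truth),
              class = "sim_data")
  })
}

# multinomial base calls: true base with prob 1 - miscall, others uniform
draw_base_counts <- function(depth, true_base, miscall) {
  n <- length(depth)
  correct <- stats::rbinom(n, depth, 1 - miscall)
  wrong <- depth - correct
  w1 <- stats::rbinom(n, wrong, 1 / 3)
  w2 <- stats::rbinom(n, wrong - w1, 1 / 2)
  w3 <- wrong - w1 - w2
  out <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  bases <- c("A", "C", "G", "T")
  for (b in bases) {
    sel <- true_base == b
    if (!any(sel)) next
    others <- setdiff(bases, b)
    out[sel, b] <- correct[sel]
    out[sel, others[1]] <- w1[sel]
    out[sel, others[2]] <- w2[sel]
    out[sel, others[3]] <- w3[sel]
  }
  out
}

simulate_mbias_calls <- function(truth, config) {
  genomic <- truth$cpg$chrom != truth$spike_in_name
  mu <- mean(truth$cpg$level_wt[genomic])
  rows <- list()
  for (cls in names(.class_lengths)) {
    L <- .class_lengths[[cls]]
    for (mate in 1:2) {
      off <- rep(0, L)
      sp <- config$mbias_spec
      sp <- sp[sp$mate == mate & sp$length_class == cls, , drop = FALSE]
      if (nrow(sp) > 0) off[sp$read_pos] <- sp$offset
      lv <- pmin(1, pmax(0, mu + off))
      p <- lv * (1 - config$meth_miscall) + (1 - lv) * config$conversion_failure
      nm <- stats::rbinom(L, config$mbias_calls_per_pos, p)
      rows[[length(rows) + 1L]] <- data.frame(
        mate = mate, length_class = cls, read_pos = seq_len(L),
        nMeth = nm, nUnmeth = config$mbias_calls_per_pos - nm,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full simulation: reference, methylomes, effects, SNPs, pileups
#'
#' @param config a [sim_config()]
#' @return a `sim_data` list (see [simulate_pileups()])
#' @export
simulate_wgbs <- function(config) {
  ref <- build_reference(config)
  truth <- draw_methylome(config, ref)
  truth <- plant_effects(truth, config)
  truth <- plant_cpg_snps(truth, config)
  simulate_pileups(truth, config)
}

#' Write a simulation to disk
#'
#' Emits, under `outdir`: `pileup_<group>_rep<r>.tsv` and
#' `<group>_rep<r>.G.bed` per replicate, `mbias_calls.tsv`,
#' `gene_models.tsv`, `cpg_islands.bed`, `reference_cpgs.bed`,
#' `expression.tsv`, `dmr_truth.bed`, `snp_sites.tsv` and
#' `chrom_lengths.tsv`.
#'
#' @param sim a `sim_data` list from [simulate_wgbs()]
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- sim$truth
  for (g in names(sim$pileups)) {
    for (r in seq_along(sim$pileups[[g]])) {
      write_pileup(sim$pileups[[g]][[r]],
                   file.path(outdir, sprintf("pileup_%s_rep%d.tsv", g, r)))
      write_gbed(sim$gbed[[g]][[r]],
                 file.path(outdir, sprintf("%s_rep%d.G.bed", g, r)))
    }
  }
  write_mbias_table(sim$mbias_table, file.path(outdir, "mbias_calls.tsv"))
  write_gene_models(truth$gene_models, file.path(outdir, "gene_models.tsv"))
  write_bed(truth$cpg_islands, file.path(outdir, "cpg_islands.bed"))
  ref_cpg <- data.frame(chrom = truth$cpg$chrom, start = truth$cpg$start,
                        end = truth$cpg$start + 2L)
  write_bed(ref_cpg, file.path(outdir, "reference_cpgs.bed"))
  write_expression(truth$expression, file.path(outdir, "expression.tsv"))
  if (nrow(truth$dmr_truth) > 0) {
    data.table::fwrite(truth$dmr_truth, file.path(outdir, "dmr_truth.bed"),
                       sep = "\t", col.names = FALSE)
  } else {
    file.create(file.path(outdir, "dmr_truth.bed"))
  }
  data.table::fwrite(truth$snp_sites, file.path(outdir, "snp_sites.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.frame(chrom = names(truth$chrom_lengths),
               length = as.integer(truth$chrom_lengths)),
    file.path(outdir, "chrom_lengths.tsv"), sep = "\t"
  )
  invisible(outdir)
}
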