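# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles apply the rules literally, through code paths disjoint
# from the package implementation.

tiny_config <- function(...) {
  args <- list(
    chrom_lengths = c(chrA = 60000), spike_in_length = 20000, n_genes = 3,
    n_hypo = 1, n_hyper = 1, n_replicates = 2, seed = 11
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

random_gbed <- function(n = 100, seed = 1, chrom = "chr1") {
  set.seed(seed)
  start <- sort(sample(seq(0, 10 * n, by = 2), n))
  total <- rpois(n, 20)
  meth <- rbinom(n, total, runif(n))
  data.frame(
    chrom = chrom, start = start, end = start + 2L,
    ratio = ifelse(total > 0, meth / total, NA_real_),
    total = total, meth = meth, stringsAsFactors = FALSE
  )
}

# Literal enumeration of every candidate run [s, e] under the trim rules:
# all positions within the outer band, no two adjacent outer-only
# positions, endpoints within the inner band; best run by length, then
# containing the mid-read window midpoint, then earliest.
oracle_trim_range <- function(profile, policy, length_class) {
  win <- policy$midread_windows[[length_class]]
  lv <- profile$level[profile$pos >= win[1] & profile$pos <= win[2] &
                        profile$depth > 0]
  lv <- lv[!is.na(lv)]
  mu <- mean(lv)
  sdev <- max(stats::sd(lv), policy$sd_floor)
  dev <- abs(profile$level - mu)
  usable <- profile$depth > 0 & !is.na(profile$level)
  inner <- usable & dev <= policy$k_inner * sdev
  outer <- usable & dev <= policy$k_outer * sdev
  L <- nrow(profile)
  mid <- mean(win)
  best <- NULL
  for (s in seq_len(L)) {
    if (!inner[s]) next
    for (e in s:L) {
      if (!inner[e]) next
      seg_in <- inner[s:e]
      seg_out <- outer[s:e]
      if (!all(seg_in | seg_out)) next
      non_in <- !seg_in
      if (length(non_in) > 1 && any(non_in[-1] & non_in[-length(non_in)])) next
      cand <- c(profile$pos[s], profile$pos[e])
      if (is.null(best)) { best <- cand; next }
      len_c <- cand[2] - cand[1]; len_b <- best[2] - best[1]
      if (len_c > len_b) { best <- cand; next }
      if (len_c == len_b) {
        in_c <- cand[1] <= mid && cand[2] >= mid
        in_b <- best[1] <= mid && best[2] >= mid
        if (in_c && !in_b) { best <- cand; next }
        if (in_c == in_b && cand[1] < best[1]) best <- cand
      }
    }
  }
  best
}

random_profile <- function(seed, length_class = "PE75") {
  set.seed(seed)
  L <- if (length_class == "PE75") 75L else 150L
  level <- rnorm(L, 0.75, 0.008)
  # plant random artifacts: end bias, isolated spikes, dead positions
  if (runif(1) < 0.6) {
    k <- sample(1:6, 1)
    level[1:k] <- level[1:k] + runif(1, 0.05, 0.2)
  }
  n_spike <- rpois(1, 1.5)
  if (n_spike > 0) {
    at <- sample(L, n_spike)
    level[at] <- level[at] + sample(c(-1, 1), n_spike, TRUE) *
      runif(n_spike, 0.01, 0.08)
  }
  depth <- rep(5000L, L)
  if (runif(1) < 0.2) depth[sample(L, 1)] <- 0L
  level[depth == 0] <- NA_real_
  level <- pmin(1, pmax(0, level))
  data.frame(mate = 1L, length_class = length_class, pos = seq_len(L),
             depth = depth, level = level, stringsAsFactors = FALSE)
}

# Literal per-site application of the four context-validation criteria.
# Row lookups are resolved once up front; the criteria themselves are
# applied site by site, straight from their definitions.
oracle_validate <- function(pileup, ref_cpgs, min_frac = 0.95,
                            min_g_depth = 5) {
  key <- paste(pileup$chrom, pileup$pos, pileup$strand)
  ip_all <- match(paste(ref_cpgs$chrom, ref_cpgs$start + 1, "+"), key)
  im_all <- match(paste(ref_cpgs$chrom, ref_cpgs$start, "-"), key)
  n <- nrow(ref_cpgs)
  passed <- logical(n)
  for (i in seq_len(n)) {
    ip <- ip_all[i]
    im <- im_all[i]
    ok <- TRUE
    if (is.na(ip)) {
      ok <- FALSE
    } else {
      bases <- pileup$nA[ip] + pileup$nC[ip] + pileup$nG[ip] + pileup$nT[ip]
      if (bases == 0 || pileup$nG[ip] / bases < min_frac) ok <- FALSE
      if (pileup$nG[ip] < min_g_depth) ok <- FALSE
    }
    if (is.na(im)) {
      ok <- FALSE
    } else {
      bases <- pileup$nA[im] + pileup$nC[im] + pileup$nG[im] + pileup$nT[im]
      if (bases == 0 || pileup$nG[im] / bases < min_frac) ok <- FALSE
      if (pileup$nG[im] < min_g_depth) ok <- FALSE
    }
    passed[i] <- ok
  }
  passed
}

# Monte-Carlo credible methylation difference (independent of quadrature).
mc_cdif <- function(meth1, total1, meth2, total2, draws = 1e6, seed = 99,
                    credibility = 0.95) {
  set.seed(seed)
  d <- rbeta(draws, meth2 + 0.5, total2 - meth2 + 0.5) -
    rbeta(draws, meth1 + 0.5, total1 - meth1 + 0.5)
  alpha <- (1 - credibility) / 2
  q <- quantile(d, c(alpha, 1 - alpha), names = FALSE)
  if (q[1] > 0) q[1] else if (q[2] < 0) q[2] else 0
}

# overlap indicator for fixed-width regions at given starts vs a feature set
overlaps_any_fixture <- function(starts, width, feature) {
  gr <- GenomicRanges::GRanges(feature$chrom[1],
                               IRanges::IRanges(starts + 1, starts + width))
  fgr <- GenomicRanges::GRanges(feature$chrom,
                                IRanges::IRanges(feature$start + 1,
                                                 feature$end))
  GenomicRanges::countOverlaps(gr, fgr) > 0
}

# Per-base feature membership oracle for toy genomes.
oracle_overlaps <- function(regions, feature, genome_len) {
  cov <- logical(genome_len)
  for (i in seq_len(nrow(feature))) {
    s <- max(0L, feature$start[i]); e <- min(genome_len, feature$end[i])
    if (e > s) cov[(s + 1):e] <- TRUE
  }
  vapply(seq_len(nrow(regions)), function(i) {
    s <- max(0L, regions$start[i]); e <- min(genome_len, regions$end[i])
    e > s && any(cov[(s + 1):e])
  }, logical(1))
}
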