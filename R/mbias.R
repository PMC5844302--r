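# Per-read-position M-bias profiling and adaptive trim-range selection.
#
# Read ends in WGBS libraries show systematic distortion of apparent
# methylation (M-bias). The retained position range is chosen against the
# mid-read mean and SD of the per-position CpG methylation level:
#   (1) positions must lie within +/- k_inner * SD of the mid-read mean,
#   (2) the range must start and end with positions meeting (1),
#   (3) single, non-consecutive outliers are tolerated inside the range as
#       long as they stay within +/- k_outer * SD.

#' Trim-selection policy
#'
#' @param midread_windows named list mapping a read length class to the
#'   inclusive 1-based position window used for the mid-read statistics
#' @param k_inner SD multiplier for the retention criterion
#' @param k_outer SD multiplier for tolerated isolated outliers
#' @param sd_floor minimal SD substituted when the window SD falls below it
#'   (e.g. a constant window)
#' @return a list of class `trim_policy`
#' @export
trim_policy <- function(midread_windows = list(PE150 = c(30L, 100L),
                                               PE75 = c(20L, 50L)),
                        k_inner = 3, k_outer = 4, sd_floor = 0.002) {
  if (k_inner <= 0 || k_outer < k_inner) {
    stop("need k_outer >= k_inner > 0")
  }
  structure(list(midread_windows = midread_windows, k_inner = k_inner,
                 k_outer = k_outer, sd_floor = sd_floor),
            class = "trim_policy")
}

#' Compute per-read-position methylation profiles
#'
#' @param call_table data.frame with columns mate, length_class, read_pos,
#'   nMeth, nUnmeth (one row per position, or multiple rows summed)
#' @return data.frame with columns mate, length_class, pos, depth, level;
#'   `level` is NA where depth is 0
#' @export
compute_mbias <- function(call_table) {
  need <- c("mate", "length_class", "read_pos", "nMeth", "nUnmeth")
  if (!all(need %in% names(call_table))) {
    stop("call table missing columns: ",
         paste(setdiff(need, names(call_table)), collapse = ", "))
  }
  if (any(call_table$nMeth < 0) || any(call_table$nUnmeth < 0)) {
    stop("negative counts in M-bias call table")
  }
  dt <- data.table::as.data.table(call_table)
  prof <- dt[, list(nMeth = sum(nMeth), nUnmeth = sum(nUnmeth)),
             by = c("mate", "length_class", "read_pos")]
  prof[, `:=`(depth = nMeth + nUnmeth)]
  prof[, `:=`(level = ifelse(depth > 0, nMeth / depth, NA_real_))]
  data.table::setorder(prof, mate, length_class, read_pos)
  out <- as.data.frame(prof[, c("mate", "length_class", "read_pos",
                                "depth", "level"), with = FALSE])
  names(out)[names(out) == "read_pos"] <- "pos"
  out
}

#' Mid-read mean and SD of a positional methylation profile
#'
#' @param profile data.frame for a single (mate, length class): columns pos,
#'   depth, level
#' @param policy a [trim_policy()]
#' @param length_class which window from the policy to use
#' @return list with `mean` and `sd` (sample SD, floored at `sd_floor`)
#' @export
midread_stats <- function(profile, policy = trim_policy(),
                          length_class = profile$length_class[1]) {
  win <- policy$midread_windows[[as.character(length_class)]]
  if (is.null(win)) stop("no mid-read window for length class ", length_class)
  lv <- profile$level[profile$pos >= win[1] & profile$pos <= win[2] &
                        profile$depth > 0]
  lv <- lv[!is.na(lv)]
  if (length(lv) < 2) {
    stop("fewer than 2 usable mid-read positions for the window ",
         win[1], "-", win[2])
  }
  s <- stats::sd(lv)
  list(mean = mean(lv), sd = max(s, policy$sd_floor))
}

#' Select the retained read-position range
#'
#' Returns the longest contiguous run of positions in which every position
#' lies within `k_inner` SD of the mid-read mean except isolated (never two
#' adjacent) positions within `k_outer` SD; the run must start and end with
#' positions meeting the inner criterion. Zero-depth positions satisfy no
#' criterion and terminate runs. Ties between equal-length runs are broken
#' toward the run containing the mid-read window midpoint, then toward the
#' earlier run.
#'
#' @param profile data.frame for one (mate, length class): pos, depth, level
#' @param policy a [trim_policy()]
#' @param length_class window selector, defaulting to the profile's own
#' @return a list of class `trim_range`: mate, length_class, start_pos,
#'   end_pos, kept_outliers, mean, sd
#' @export
select_trim_range <- function(profile, policy = trim_policy(),
                              length_class = profile$length_class[1]) {
  st <- midread_stats(profile, policy, length_class)
  pos <- profile$pos
  dev <- abs(profile$level - st$mean)
  inner <- !is.na(dev) & profile$depth > 0 & dev <= policy$k_inner * st$sd
  outer <- !is.na(dev) & profile$depth > 0 & dev <= policy$k_outer * st$sd
  if (!any(inner)) stop("no position satisfies the inner criterion")

  win <- policy$midread_windows[[as.character(length_class)]]
  mid <- mean(win)

  best <- NULL
  n <- length(pos)
  i <- 1L
  while (i <= n) {
    if (!inner[i]) { i <- i + 1L; next }
    # grow a run starting at the inner position i
    j <- i
    last_ok <- i                      # last position meeting the inner rule
    prev_outlier <- FALSE
    while (j < n) {
      nxt <- j + 1L
      if (inner[nxt]) {
        j <- nxt; last_ok <- nxt; prev_outlier <- FALSE
      } else if (outer[nxt] && !prev_outlier) {
        j <- nxt; prev_outlier <- TRUE
      } else {
        break
      }
    }
    # run is [i, last_ok]: must end on an inner position
    cand <- c(i, last_ok)
    if (is.null(best) || better_run(cand, best, pos, mid)) best <- cand
    i <- last_ok + 1L
  }

  s <- best[1]; e <- best[2]
  kept <- pos[seq(s, e)][!inner[seq(s, e)]]
  structure(list(
    mate = profile$mate[1], length_class = as.character(length_class),
    start_pos = pos[s], end_pos = pos[e],
    kept_outliers = as.integer(kept), mean = st$mean, sd = st$sd
  ), class = "trim_range")
}

# is run a (index pair into pos) better than b? longest first, then the run
# containing the mid-read midpoint, then the earlier run
better_run <- function(a, b, pos, mid) {
  la <- pos[a[2]] - pos[a[1]]
  lb <- pos[b[2]] - pos[b[1]]
  if (la != lb) return(la > lb)
  ca <- pos[a[1]] <= mid && pos[a[2]] >= mid
  cb <- pos[b[1]] <= mid && pos[b[2]] >= mid
  if (ca != cb) return(ca)
  pos[a[1]] < pos[b[1]]
}

#' Trim report over all (mate, length class) profiles in a call table
#'
#' @param call_table M-bias call table (see [compute_mbias()])
#' @param policy a [trim_policy()]
#' @return data.frame with one row per (mate, length_class): start_pos,
#'   end_pos, kept_outliers (comma-separated), mean, sd
#' @export
mbias_trim_report <- function(call_table, policy = trim_policy()) {
  prof <- compute_mbias(call_table)
  keys <- unique(prof[, c("mate", "length_class")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    p <- prof[prof$mate == keys$mate[i] &
                prof$length_class == keys$length_class[i], , drop = FALSE]
    tr <- select_trim_range(p, policy, keys$length_class[i])
    data.frame(
      mate = keys$mate[i], length_class = keys$length_class[i],
      start_pos = tr$start_pos, end_pos = tr$end_pos,
      kept_outliers = paste(tr$kept_outliers, collapse = ","),
      mean = tr$mean, sd = tr$sd, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
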