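#' Peak-calling configuration
#'
#' @param ethre rER threshold; 2.0 for moderately enriched sites, 5.0 for
#'   strongly enriched sites.
#' @param ithre ChIP-intensity floor in units of the genome-mean smoothed
#'   ChIP bin count (suppresses high-ratio calls in low-coverage bins).
#' @param ipm normalized read intensity (modified RPKM) threshold for
#'   intensity-mode calling (default 7).
#' @param min_width minimum peak width in bp (default 100, one smoothing
#'   window).
#' @param merge_gap maximum sub-threshold gap bridged between runs, in bp
#'   (default 100); gaps containing masked bins are never bridged.
#' @param fdr_target swap-FDR target used by [threshold_scan()].
#' @param input_guard intensity-mode guard: ChIP intensity must exceed
#'   `input_guard` times the input intensity (eliminates pseudo-binding
#'   signals present in the input).
#' @return a list of class `peak_config`.
#' @export
peak_config <- function(ethre = 2, ithre = 2, ipm = 7, min_width = 100,
                        merge_gap = 100, fdr_target = 0.05, input_guard = 2) {
  stopifnot(ethre > 0, ithre >= 0, ipm > 0, min_width > 0,
            merge_gap >= 0, fdr_target > 0, fdr_target < 1, input_guard >= 0)
  structure(list(ethre = ethre, ithre = ithre, ipm = ipm,
                 min_width = min_width, merge_gap = merge_gap,
                 fdr_target = fdr_target, input_guard = input_guard),
            class = "peak_config")
}

# Threshold-contiguous run detection within one chromosome.
# pass/mask are logical vectors over bins; runs of pass=TRUE separated by
# at most gap_bins sub-threshold *unmasked* bins are merged (masked bins
# block merging); runs shorter than min_bins are dropped.
# Returns a matrix with columns start_bin, end_bin (1-based inclusive).
find_runs <- function(pass, mask, gap_bins, min_bins) {
  pass <- pass & !mask
  out <- NULL
  seg <- rle(mask)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  for (k in which(!seg$values)) {
    p <- pass[seg_start[k]:seg_end[k]]
    if (!any(p)) next
    r <- rle(p)
    re <- cumsum(r$lengths)
    rs <- re - r$lengths + 1L
    keep <- which(r$values)
    starts <- rs[keep]
    ends <- re[keep]
    # merge across short sub-threshold gaps
    if (length(starts) > 1) {
      ms <- starts[1]; me <- ends[1]
      merged_s <- integer(0); merged_e <- integer(0)
      for (j in 2:length(starts)) {
        if (starts[j] - me - 1L <= gap_bins) {
          me <- ends[j]
        } else {
          merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
          ms <- starts[j]; me <- ends[j]
        }
      }
      merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
      starts <- merged_s; ends <- merged_e
    }
    wide <- (ends - starts + 1L) >= min_bins
    if (any(wide))
      out <- rbind(out, cbind(starts[wide] + seg_start[k] - 1L,
                              ends[wide] + seg_start[k] - 1L))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("start_bin", "end_bin")
  out
}

runs_to_peaks <- function(runs, score, mask, chrom, bin_size, chrom_len, mode) {
  if (nrow(runs) == 0)
    return(empty_peaks())
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    b1 <- runs[i, 1]; b2 <- runs[i, 2]
    s <- score[b1:b2]
    s[mask[b1:b2]] <- NA
    peak_max <- max(s, na.rm = TRUE)
    summit_bin <- b1 + which(s == peak_max)[1] - 1L  # leftmost maximum
    data.frame(chrom = chrom,
               start = (b1 - 1) * bin_size,
               end = min(b2 * bin_size, chrom_len),
               summit = min((summit_bin - 0.5) * bin_size, chrom_len),
               max_score = peak_max,
               mean_score = mean(s, na.rm = TRUE),
               mode = mode, stringsAsFactors = FALSE)
  }))
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             summit = numeric(), max_score = numeric(),
             mean_score = numeric(), mode = character(),
             stringsAsFactors = FALSE)
}

#' Call peaks on an rER profile
#'
#' Peaks are maximal runs of unmasked bins with rER above `ethre` and
#' relative smoothed ChIP intensity (genome-mean units) above `ithre`.
#' Runs separated by at most `merge_gap` bp of sub-threshold unmasked
#' bins are merged; runs narrower than `min_width` are dropped. The
#' summit is the leftmost bin attaining the maximum rER.
#'
#' @param profile an [compute_rer()] profile.
#' @param config a [peak_config()].
#' @param chip_rel optional `binned_track` of relative ChIP intensity;
#'   defaults to the one stored in the profile.
#' @return data frame of peaks (chrom, start, end, summit, max_score,
#'   mean_score, mode), 0-based half-open, sorted and disjoint per
#'   chromosome.
#' @export
call_peaks_rer <- function(profile, config = peak_config(), chip_rel = NULL) {
  stopifnot(inherits(profile, "rer_profile"))
  track <- profile$track
  if (is.null(chip_rel)) chip_rel <- profile$chip_rel
  if (!same_binning(track, chip_rel))
    stop("rER profile and ChIP intensity track have different binning")
  bs <- track$bin_size
  gap_bins <- floor(config$merge_gap / bs)
  min_bins <- max(1L, ceiling(config$min_width / bs))
  out <- lapply(names(track$values), function(chrom) {
    rer <- track$values[[chrom]]
    m <- track$mask[[chrom]]
    pass <- !is.na(rer) & rer > config$ethre &
      chip_rel$values[[chrom]] > config$ithre
    runs <- find_runs(pass, m, gap_bins, min_bins)
    runs_to_peaks(runs, rer, m, chrom, bs, track$chrom_sizes[[chrom]], "rer")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call peaks on normalized read intensity
#'
#' Human-mode calling: runs where the ChIP \eqn{R_x} exceeds `ipm` and
#' also exceeds `input_guard` times the input \eqn{R_x} (both ChIP and
#' input are used, to eliminate pseudo-binding signals present in the
#' input sample). Merging and width rules as in [call_peaks_rer()].
#'
#' @param chip,input [normalized_intensity()] tracks on the same grid.
#' @param config a [peak_config()].
#' @return peak data frame as in [call_peaks_rer()] with `mode =
#'   "intensity"`.
#' @export
call_peaks_intensity <- function(chip, input, config = peak_config()) {
  stopifnot(inherits(chip, "intensity_track"), inherits(input, "intensity_track"))
  a <- chip$track; b <- input$track
  if (!same_binning(a, b)) stop("ChIP and input tracks have different binning")
  bs <- a$bin_size
  gap_bins <- floor(config$merge_gap / bs)
  min_bins <- max(1L, ceiling(config$min_width / bs))
  out <- lapply(names(a$values), function(chrom) {
    x <- a$values[[chrom]]
    m <- a$mask[[chrom]] | b$mask[[chrom]]
    pass <- x > config$ipm & x > config$input_guard * b$values[[chrom]]
    runs <- find_runs(pass, m, gap_bins, min_bins)
    runs_to_peaks(runs, x, m, chrom, bs, a$chrom_sizes[[chrom]], "intensity")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Swap-based false discovery rate estimate
#'
#' Exchanges the ChIP and input tracks and re-runs the identical calling
#' pipeline; the FDR estimate is the number of peaks called in the
#' swapped direction divided by the number called in the true direction
#' (with `max(1, .)` in the denominator, so no peaks in either direction
#' gives 0).
#'
#' @param chip,input `binned_track`s of raw counts.
#' @param config a [peak_config()].
#' @param mode `"rer"` or `"intensity"`.
#' @param smoothing_window,mask_fraction rER pipeline parameters
#'   (rer mode only).
#' @return list with `fdr`, `n_forward`, `n_swapped`.
#' @export
estimate_fdr_swap <- function(chip, input, config = peak_config(),
                              mode = c("rer", "intensity"),
                              smoothing_window = 100, mask_fraction = 0.20) {
  mode <- match.arg(mode)
  call_dir <- function(a, b) {
    if (mode == "rer") {
      nrow(call_peaks_rer(compute_rer(a, b, smoothing_window, mask_fraction),
                          config))
    } else {
      nrow(call_peaks_intensity(normalized_intensity(a),
                                normalized_intensity(b), config))
    }
  }
  n_fwd <- call_dir(chip, input)
  n_swp <- call_dir(input, chip)
  list(fdr = n_swp / max(1, n_fwd), n_forward = n_fwd, n_swapped = n_swp)
}

#' Choose an intensity threshold by swap-FDR scan
#'
#' Evaluates the swap FDR over an ascending grid of `ipm` thresholds and
#' returns the smallest threshold whose FDR is at or below the target; if
#' none qualifies, the largest grid value is returned with `met = FALSE`.
#'
#' @param chip,input `binned_track`s of raw counts.
#' @param grid ascending numeric vector of candidate `ipm` thresholds.
#' @param config a [peak_config()]; its `ipm` is overridden per grid point.
#' @param fdr_target FDR target (default taken from `config`).
#' @return list with `threshold`, `met` (logical), and `table` (data
#'   frame threshold/n_peaks/fdr for the full scan).
#' @export
threshold_scan <- function(chip, input, grid, config = peak_config(),
                           fdr_target = config$fdr_target) {
  stopifnot(length(grid) > 0, !is.unsorted(grid, strictly = TRUE))
  rows <- lapply(grid, function(t) {
    cfg <- config
    cfg$ipm <- t
    est <- estimate_fdr_swap(chip, input, cfg, mode = "intensity")
    data.frame(threshold = t, n_peaks = est$n_forward, fdr = est$fdr)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$fdr <= fdr_target)
  if (length(ok)) {
    list(threshold = grid[ok[1]], met = TRUE, table = tab)
  } else {
    warning("no grid threshold met the FDR target; returning the largest")
    list(threshold = grid[length(grid)], met = FALSE, table = tab)
  }
}
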