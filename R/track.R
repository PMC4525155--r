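#' Binned genome track
#'
#' The universal carrier of coverage and enrichment values: one numeric
#' vector per chromosome on a fixed-width bin grid, plus a logical mask
#' (`TRUE` = bin excluded from analysis). Bin `i` of a chromosome covers
#' the 0-based half-open interval `[(i-1)*bin_size, i*bin_size)`; the last
#' bin may be shorter when the chromosome length is not a multiple of
#' `bin_size`.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 10).
#' @param mask named list of logical vectors aligned with `values`;
#'   `NULL` means nothing masked.
#' @return an object of class `binned_track`.
#' @export
binned_track <- function(values, chrom_sizes, bin_size = 10, mask = NULL) {
  stopifnot(is.list(values), length(values) > 0)
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!setequal(names(values), names(chrom_sizes)))
    stop("chromosome names of `values` and `chrom_sizes` differ")
  values <- values[names(chrom_sizes)]
  for (chrom in names(chrom_sizes)) {
    nb <- n_bins(chrom_sizes[[chrom]], bin_size)
    if (length(values[[chrom]]) != nb)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chrom, nb, length(values[[chrom]])))
  }
  if (is.null(mask)) {
    mask <- lapply(values, function(v) rep(FALSE, length(v)))
  } else {
    mask <- mask[names(chrom_sizes)]
    stopifnot(identical(lengths(mask), lengths(values)))
    mask <- lapply(mask, function(m) { m[is.na(m)] <- TRUE; m })
  }
  bad <- vapply(names(values), function(ch) {
    v <- values[[ch]][!mask[[ch]]]
    any(!is.finite(v)) || any(v < 0)
  }, logical(1))
  if (any(bad))
    stop("non-finite or negative values at unmasked bins on: ",
         paste(names(values)[bad], collapse = ", "))
  structure(list(values = values, mask = mask,
                 chrom_sizes = chrom_sizes, bin_size = as.integer(bin_size)),
            class = "binned_track")
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    sizes <- stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else {
    stopifnot(!is.null(names(x)))
    sizes <- stats::setNames(as.numeric(x), names(x))
  }
  if (any(sizes <= 0)) stop("chromosome sizes must be positive")
  sizes
}

n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %d chromosome(s), bin_size=%d bp, %d bins (%.1f%% masked)\n",
              length(x$values), x$bin_size, total_bins(x),
              100 * masked_fraction(x)))
  invisible(x)
}

total_bins <- function(track) sum(lengths(track$values))

masked_fraction <- function(track) {
  sum(vapply(track$mask, sum, numeric(1))) / total_bins(track)
}

#' Concatenated values over unmasked bins
#' @param track a `binned_track`.
#' @return numeric vector of unmasked values, chromosome order preserved.
#' @export
unmasked_values <- function(track) {
  unlist(Map(function(v, m) v[!m], track$values, track$mask), use.names = FALSE)
}

same_binning <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$values), names(b$values)) &&
    identical(lengths(a$values), lengths(b$values))
}

#' Assign reads to bins by extended-fragment midpoint
#'
#' Each read is extended to `fragment_length` in its strand direction and
#' contributes one count to the bin containing the fragment midpoint
#' (plus strand: `start + fragment_length/2`; minus strand:
#' `end - fragment_length/2`), clipped to the chromosome.
#'
#' @param reads data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @param chrom_sizes named vector or two-column data frame of lengths.
#' @param bin_size bin width in bp.
#' @param fragment_length sequencing library fragment size in bp
#'   (default 150, the typical sonication shear size).
#' @return a `binned_track` of counts; the total over all bins equals
#'   `nrow(reads)`.
#' @export
bin_reads <- function(reads, chrom_sizes, bin_size = 10, fragment_length = 150) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  stopifnot(fragment_length > 0, bin_size > 0)
  counts <- lapply(chrom_sizes, function(len) numeric(n_bins(len, bin_size)))
  if (nrow(reads) > 0) {
    unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
    len <- chrom_sizes[reads$chrom]
    if (any(reads$start >= len))
      stop("read start beyond chromosome end")
    mid <- ifelse(reads$strand == "-",
                  reads$end - fragment_length / 2,
                  reads$start + fragment_length / 2)
    mid <- pmin(pmax(mid, 0), len - 1)
    idx <- floor(mid / bin_size) + 1L
    for (chrom in unique(reads$chrom)) {
      sel <- reads$chrom == chrom
      tab <- tabulate(idx[sel], nbins = length(counts[[chrom]]))
      counts[[chrom]] <- counts[[chrom]] + tab
    }
  }
  binned_track(counts, chrom_sizes, bin_size)
}

#' Centered moving-average smoothing
#'
#' Smooths each chromosome independently with a centered moving mean over
#' `window` bp (rounded up to an odd number of bins). Chromosome edges use
#' shrinking windows: the mean is taken over the bins that exist.
#' Smoothing ignores the mask (it operates on raw arrays); masking is
#' applied downstream.
#'
#' @param track a `binned_track`.
#' @param window smoothing window in bp (default 100); must be >= bin_size.
#' @return a smoothed `binned_track` with the same mask.
#' @export
smooth_counts <- function(track, window = 100) {
  if (window < track$bin_size) stop("smoothing window smaller than bin size")
  w <- ceiling(window / track$bin_size)
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  sm <- lapply(track$values, function(x) {
    n <- length(x)
    if (half == 0L || n == 1L) return(x)
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  out <- track
  out$values <- sm
  out
}

#' Mask bins with poor input coverage
#'
#' Bins whose smoothed input depth falls below `fraction` of the
#' genome-wide average input depth (mean over *all* bins) are flagged for
#' exclusion: low-coverage regions can show pseudo-positive enrichment
#' signals in a ratio profile.
#'
#' @param smoothed_input `binned_track` of smoothed input counts.
#' @param fraction cutoff as a proportion of the genome-average depth
#'   (default 0.20).
#' @return list with `mask` (named list of logical vectors, `TRUE` =
#'   excluded), `masked_fraction`, and `cutoff` (absolute depth).
#' @export
mask_low_input <- function(smoothed_input, fraction = 0.20) {
  stopifnot(fraction > 0, fraction < 1)
  all_vals <- unlist(smoothed_input$values, use.names = FALSE)
  if (length(all_vals) == 0) stop("empty track")
  cutoff <- fraction * mean(all_vals)
  mask <- lapply(smoothed_input$values, function(v) v < cutoff)
  list(mask = mask,
       masked_fraction = sum(vapply(mask, sum, numeric(1))) / length(all_vals),
       cutoff = cutoff)
}

#' Relative enrichment ratio (rER) profile
#'
#' Builds the normalized ChIP/input enrichment profile from bin-count
#' tracks. Pipeline order: (1) smooth ChIP and input counts with a
#' `smoothing_window` moving mean; (2) mask bins whose smoothed input
#' depth is below `mask_fraction` of the genome-average smoothed input;
#' (3) take the ratio smoothed-ChIP / smoothed-input at unmasked bins;
#' (4) divide by the mean over unmasked bins so the genome-wide average
#' rER equals 1. Masked bins carry `NA`.
#'
#' The returned profile also carries the smoothed ChIP intensity in
#' genome-mean units (`chip_rel`), used as the intensity floor in rER-mode
#' peak calling.
#'
#' @param chip,input `binned_track`s of raw bin counts on the same grid.
#' @param smoothing_window smoothing window in bp (default 100).
#' @param mask_fraction input-coverage masking threshold (default 0.20).
#' @return an object of class `rer_profile` with elements `track`
#'   (rER `binned_track`), `chip_rel`, `total_chip_reads`,
#'   `total_input_reads`, `smoothing_window`, `mask_fraction`,
#'   `normalization_constant`, `externally_scaled`.
#' @export
compute_rer <- function(chip, input, smoothing_window = 100, mask_fraction = 0.20) {
  if (!same_binning(chip, input)) stop("chip and input tracks have different binning")
  total_chip <- sum(unlist(chip$values, use.names = FALSE))
  total_input <- sum(unlist(input$values, use.names = FALSE))
  if (total_input <= 0) stop("zero total input reads")
  if (total_chip <= 0) stop("zero total ChIP reads")

  sm_chip <- smooth_counts(chip, smoothing_window)
  sm_input <- smooth_counts(input, smoothing_window)
  mk <- mask_low_input(sm_input, mask_fraction)
  if (mk$masked_fraction >= 1) stop("all bins masked by the input-coverage rule")

  ratio <- Map(function(c, i, m) {
    r <- rep(NA_real_, length(c))
    r[!m] <- c[!m] / i[!m]
    r
  }, sm_chip$values, sm_input$values, mk$mask)
  norm_const <- mean(unlist(Map(function(r, m) r[!m], ratio, mk$mask),
                            use.names = FALSE))
  rer <- lapply(ratio, function(r) r / norm_const)

  chip_mean <- mean(unlist(Map(function(v, m) v[!m], sm_chip$values, mk$mask),
                           use.names = FALSE))
  chip_rel <- lapply(sm_chip$values, function(v) v / chip_mean)

  structure(list(
    track = binned_track(rer, chip$chrom_sizes, chip$bin_size, mask = mk$mask),
    chip_rel = binned_track(chip_rel, chip$chrom_sizes, chip$bin_size, mask = mk$mask),
    total_chip_reads = total_chip,
    total_input_reads = total_input,
    smoothing_window = smoothing_window,
    mask_fraction = mask_fraction,
    normalization_constant = norm_const,
    externally_scaled = FALSE,
    rescale_constant = 1
  ), class = "rer_profile")
}

#' @export
print.rer_profile <- function(x, ...) {
  cat(sprintf(paste0("<rer_profile> %d/%d ChIP/input reads, window=%d bp, ",
                     "mask<%.0f%% input, %.1f%% bins masked%s\n"),
              x$total_chip_reads, x$total_input_reads, x$smoothing_window,
              100 * x$mask_fraction, 100 * masked_fraction(x$track),
              if (x$externally_scaled)
                sprintf(", externally scaled (x%.4g)", x$rescale_constant) else ""))
  invisible(x)
}

#' Normalized read intensity (modified RPKM)
#'
#' Converts a bin-count track to the per-kilobase, per-million-mapped-reads
#' intensity \eqn{R_x = count \times (1000/bin\_size) \times (10^6/total)}.
#' Used instead of rER where input sequencing depth is too low for a
#' stable ratio (human-mode profiling).
#'
#' @param chip `binned_track` of raw counts.
#' @param total_reads total mapped reads; defaults to the track sum.
#' @return an object of class `intensity_track` with elements `track`
#'   (the \eqn{R_x} `binned_track`) and `total_reads`.
#' @export
normalized_intensity <- function(chip, total_reads = NULL) {
  if (is.null(total_reads))
    total_reads <- sum(unlist(chip$values, use.names = FALSE))
  if (total_reads <= 0) stop("zero total mapped reads")
  scale <- (1000 / chip$bin_size) * (1e6 / total_reads)
  out <- chip
  out$values <- lapply(chip$values, function(v) v * scale)
  structure(list(track = out, total_reads = total_reads),
            class = "intensity_track")
}

#' @export
print.intensity_track <- function(x, ...) {
  cat(sprintf("<intensity_track> %g mapped reads, bin_size=%d bp\n",
              x$total_reads, x$track$bin_size))
  invisible(x)
}

# Accept rer_profile, intensity_track or binned_track wherever a plain
# score track is needed.
as_binned_track <- function(x) {
  if (inherits(x, "binned_track")) return(x)
  if (inherits(x, "rer_profile") || inherits(x, "intensity_track")) return(x$track)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a binned track")
}
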