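# Builders for toy tracks and profiles used across the suite.

toy_track <- function(values, bin_size = 10, mask = NULL, chrom = "chrT") {
  sizes <- stats::setNames(length(values) * bin_size, chrom)
  binned_track(stats::setNames(list(values), chrom), sizes, bin_size,
               mask = if (is.null(mask)) NULL
                      else stats::setNames(list(mask), chrom))
}

# rER profile wrapper around explicit values; chip_rel defaults to a
# constant 1 so only the ethre condition binds when ithre = 0.
toy_profile <- function(rer, mask = NULL, chip_rel = NULL, bin_size = 10) {
  if (is.null(mask)) mask <- rep(FALSE, length(rer))
  rer[mask] <- NA
  track <- toy_track(rer, bin_size, mask)
  if (is.null(chip_rel)) chip_rel <- rep(1, length(rer))
  structure(list(track = track,
                 chip_rel = toy_track(chip_rel, bin_size, mask),
                 total_chip_reads = 1, total_input_reads = 1,
                 smoothing_window = bin_size, mask_fraction = 0.2,
                 normalization_constant = 1, externally_scaled = FALSE,
                 rescale_constant = 1),
            class = "rer_profile")
}

toy_intensity <- function(rx, bin_size = 10, total = 1e6) {
  structure(list(track = toy_track(rx, bin_size), total_reads = total),
            class = "intensity_track")
}

small_sim <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length = 2e5, n_genes = 10,
         chip_depth = 2e5, input_depth = 2e5),
    list(...))
  do.call(sim_config, args)
}
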