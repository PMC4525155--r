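# Brute-force run enumeration: position-by-position scan, explicit merge
# loop. Deliberately independent of the rle/segment machinery in the
# package.
oracle_runs <- function(pass, mask, gap_bins, min_bins) {
  p <- pass & !mask
  runs <- list()
  s <- NA_integer_
  for (i in seq_along(p)) {
    if (p[i] && is.na(s)) s <- i
    if (!p[i] && !is.na(s)) {
      runs[[length(runs) + 1]] <- c(s, i - 1L)
      s <- NA_integer_
    }
  }
  if (!is.na(s)) runs[[length(runs) + 1]] <- c(s, length(p))
  merged <- list()
  for (r in runs) {
    if (length(merged)) {
      last <- merged[[length(merged)]]
      gap_len <- r[1] - last[2] - 1L
      gap_has_mask <- gap_len > 0 && any(mask[(last[2] + 1L):(r[1] - 1L)])
      if (gap_len <= gap_bins && !gap_has_mask) {
        merged[[length(merged)]] <- c(last[1], r[2])
        next
      }
    }
    merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) r[2] - r[1] + 1L >= min_bins, merged)
  out <- if (length(keep)) do.call(rbind, keep) else matrix(integer(0), ncol = 2)
  colnames(out) <- c("start_bin", "end_bin")
  out
}

# Exhaustive hypergeometric upper tail: enumerate every size-b subset of
# the universe and count those overlapping set_a in >= k elements.
oracle_overlap_tail <- function(N, a, b, k) {
  if (b == 0) return(as.numeric(k <= 0))
  combos <- utils::combn(N, b)
  overlaps <- colSums(combos <= a)  # set_a taken as elements 1..a
  mean(overlaps >= k)
}
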