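#' Infer TSS and TTS coordinates from CDS and UTR lengths
#'
#' Plus strand: `tss = cds_start - utr5_len`, `tts = cds_end + utr3_len`;
#' minus strand mirrored (`tss = cds_end + utr5_len` is the 5'-most
#' transcribed coordinate, `tts = cds_start - utr3_len`). Annotated UTR
#' lengths take precedence; genes without UTR information fall back to
#' the genome-wide mean UTR lengths (defaults 293 bp for the 5' UTR and
#' 430 bp for the 3' UTR). Coordinates are clipped at chromosome bounds
#' with a `clipped` flag.
#'
#' @param genes data frame with columns `id`, `chrom`, `strand`,
#'   `cds_start`, `cds_end` and optionally `utr5_len`/`utr3_len`
#'   (NA = unannotated). Coordinates 0-based half-open.
#' @param chrom_sizes optional named vector for bound clipping.
#' @param default_utr5,default_utr3 fallback UTR lengths in bp.
#' @return the gene data frame with `tss`, `tts` and `clipped` columns.
#' @export
infer_tss_tts <- function(genes, chrom_sizes = NULL,
                          default_utr5 = 293, default_utr3 = 430) {
  stopifnot(all(c("chrom", "strand", "cds_start", "cds_end") %in% names(genes)),
            default_utr5 >= 0, default_utr3 >= 0)
  if (nrow(genes) > 0 && any(genes$cds_start >= genes$cds_end))
    stop("cds_start must be < cds_end")
  utr5 <- if ("utr5_len" %in% names(genes)) genes$utr5_len else rep(NA_real_, nrow(genes))
  utr3 <- if ("utr3_len" %in% names(genes)) genes$utr3_len else rep(NA_real_, nrow(genes))
  if (any(utr5 < 0, na.rm = TRUE) || any(utr3 < 0, na.rm = TRUE))
    stop("negative UTR length")
  utr5 <- ifelse(is.na(utr5), default_utr5, utr5)
  utr3 <- ifelse(is.na(utr3), default_utr3, utr3)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$cds_start - utr5, genes$cds_end + utr5)
  tts <- ifelse(plus, genes$cds_end + utr3, genes$cds_start - utr3)
  clipped <- rep(FALSE, nrow(genes))
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_chrom_sizes(chrom_sizes)
    len <- chrom_sizes[genes$chrom]
    clipped <- tss < 0 | tts < 0 | tss > len | tts > len
    tss <- pmin(pmax(tss, 0), len)
    tts <- pmin(pmax(tts, 0), len)
  } else {
    clipped <- tss < 0 | tts < 0
    tss <- pmax(tss, 0)
    tts <- pmax(tts, 0)
  }
  genes$tss <- unname(tss)
  genes$tts <- unname(tts)
  genes$clipped <- unname(clipped)
  genes
}

# Value of the track at the bin containing each genomic position;
# NA when masked or out of range.
value_at <- function(track, chrom, pos) {
  v <- track$values[[chrom]]
  m <- track$mask[[chrom]]
  idx <- floor(pos / track$bin_size) + 1L
  out <- rep(NA_real_, length(pos))
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- ifelse(m[idx[ok]], NA_real_, v[idx[ok]])
  out
}

# Scaled per-gene signal vector: upstream flank at native bin resolution,
# body resampled to n_body_bins with fractional-overlap weighting, then
# downstream flank; minus-strand genes reversed to run TSS -> TTS.
gene_scaled_vector <- function(track, chrom, tss, tts, strand,
                               flank, n_body_bins) {
  bs <- track$bin_size
  nf <- as.integer(flank / bs)
  plus <- strand == "+"
  offsets <- (seq_len(nf) - 0.5) * bs
  if (plus) {
    up <- value_at(track, chrom, tss - flank + offsets)
    dn <- value_at(track, chrom, tts + offsets)
  } else {
    up <- value_at(track, chrom, tss + flank - offsets)
    dn <- value_at(track, chrom, tts - offsets)
  }
  lo <- min(tss, tts); hi <- max(tss, tts)
  L <- hi - lo
  v <- track$values[[chrom]]
  m <- track$mask[[chrom]]
  body <- vapply(seq_len(n_body_bins), function(j) {
    t_lo <- lo + (j - 1) * L / n_body_bins
    t_hi <- lo + j * L / n_body_bins
    b1 <- max(1L, floor(t_lo / bs) + 1L)
    b2 <- min(length(v), ceiling(t_hi / bs))
    if (b2 < b1) return(NA_real_)
    bins <- b1:b2
    w <- pmin(bins * bs, t_hi) - pmax((bins - 1) * bs, t_lo)
    w[m[bins]] <- 0
    if (sum(w) <= 0) return(NA_real_)
    sum(v[bins] * w) / sum(w)
  }, numeric(1))
  if (!plus) body <- rev(body)
  c(up, body, dn)
}

#' Metagene profile
#'
#' Averages a score track over a gene set after scaling every gene body
#' to `n_body_bins` positions, with fixed-length flanks (1 kb by default)
#' at native bin resolution upstream of the TSS and downstream of the
#' TTS. Minus-strand genes are reversed so all genes run TSS to TTS left
#' to right; masked bins are excluded from the per-gene averages, and
#' positions with no unmasked coverage in a gene are skipped for that
#' gene. The profile is the unweighted mean over genes.
#'
#' @param profile an rER profile, intensity track or `binned_track`.
#' @param genes gene data frame with `chrom`, `strand`, `tss`, `tts`.
#' @param flank flank length in bp (default 1000).
#' @param n_body_bins number of scaled gene-body positions (default 100).
#' @return object of class `metagene_profile`: `upstream`, `body`,
#'   `downstream` (mean vectors), `n_genes`, `flank`, `bin_size`, and
#'   `position` (bp-equivalent axis, body positions in scaled units).
#' @export
metagene <- function(profile, genes, flank = 1000, n_body_bins = 100) {
  mat <- metagene_matrix(profile, genes, flank, n_body_bins)
  track <- as_binned_track(profile)
  nf <- as.integer(flank / track$bin_size)
  prof <- colMeans(mat, na.rm = TRUE)
  structure(list(upstream = prof[seq_len(nf)],
                 body = prof[nf + seq_len(n_body_bins)],
                 downstream = prof[nf + n_body_bins + seq_len(nf)],
                 n_genes = nrow(mat), flank = flank,
                 n_body_bins = n_body_bins, bin_size = track$bin_size),
            class = "metagene_profile")
}

# genes x positions matrix underlying metagene() and enrichment_heatmap()
metagene_matrix <- function(profile, genes, flank = 1000, n_body_bins = 100) {
  track <- as_binned_track(profile)
  if (nrow(genes) == 0) stop("empty gene list")
  stopifnot(n_body_bins >= 1, flank %% track$bin_size == 0)
  rows <- lapply(seq_len(nrow(genes)), function(g)
    gene_scaled_vector(track, genes$chrom[g], genes$tss[g], genes$tts[g],
                       genes$strand[g], flank, n_body_bins))
  mat <- do.call(rbind, rows)
  rownames(mat) <- genes$id
  mat
}

#' Per-gene enrichment heat map matrix
#'
#' Same per-gene scaled vectors as [metagene()] without cross-gene
#' averaging; rows are ordered by descending mean score over the gene
#' body, ties broken by gene id (lexicographic), so the ordering is
#' deterministic.
#'
#' @inheritParams metagene
#' @return numeric matrix (genes x positions) with gene ids as row names,
#'   sorted by descending gene-body mean.
#' @export
enrichment_heatmap <- function(profile, genes, flank = 1000, n_body_bins = 100) {
  track <- as_binned_track(profile)
  mat <- metagene_matrix(profile, genes, flank, n_body_bins)
  nf <- as.integer(flank / track$bin_size)
  body_mean <- rowMeans(mat[, nf + seq_len(n_body_bins), drop = FALSE],
                        na.rm = TRUE)
  ord <- order(-body_mean, rownames(mat))
  mat[ord, , drop = FALSE]
}

#' Sliding-window GC fraction of a sequence
#'
#' Per-position GC content over a centered window (shrinking at sequence
#' ends), the track plotted above metagene profiles to relate enrichment
#' shape to local base composition.
#'
#' @param seq a character string, `Biostrings::DNAString`, or plain
#'   character vector of bases.
#' @param window window size in bp (default 100).
#' @return numeric vector of per-position GC fractions.
#' @export
gc_track <- function(seq, window = 100) {
  if (window < 1) stop("window must be >= 1")
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  if (length(seq) == 1 && nchar(seq[1]) > 1)
    seq <- strsplit(seq, "")[[1]]
  gc <- as.numeric(toupper(seq) %in% c("G", "C"))
  n <- length(gc)
  cs <- cumsum(c(0, gc))
  i <- seq_len(n)
  lo <- pmax(i - floor((window - 1) / 2), 1L)
  hi <- pmin(i + floor(window / 2), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Bin per-chromosome sequences into a GC-fraction track
#'
#' Convenience bridge so a GC profile can be fed through [metagene()] on
#' the same axes as a score track.
#'
#' @param seqs named list (or `DNAStringSet`) of chromosome sequences.
#' @param bin_size bin width in bp.
#' @param window sliding window passed to [gc_track()].
#' @return a `binned_track` of mean GC fraction per bin.
#' @export
gc_binned <- function(seqs, bin_size = 10, window = 100) {
  if (methods::is(seqs, "DNAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  sizes <- vapply(seqs, nchar, numeric(1))
  vals <- lapply(seqs, function(s) {
    g <- gc_track(s, window)
    nb <- n_bins(length(g), bin_size)
    idx <- rep(seq_len(nb), each = bin_size, length.out = length(g))
    as.numeric(tapply(g, idx, mean))
  })
  binned_track(vals, sizes, bin_size)
}

#' Gene-level binding amount
#'
#' Mean rER over the unmasked bins spanning each gene's transcript
#' (TSS to TTS), multiplied by `external_scale` — the qPCR-anchored
#' rescale constant when comparing samples, so gene-level amounts are on
#' a common quantitative scale across conditions.
#'
#' @param profile an rER profile or `binned_track`.
#' @param genes gene data frame with `id`, `chrom`, `tss`, `tts`.
#' @param external_scale multiplicative constant (default 1).
#' @return data frame `id`, `binding` (NA for fully masked genes).
#' @export
gene_binding_level <- function(profile, genes, external_scale = 1) {
  track <- as_binned_track(profile)
  bs <- track$bin_size
  binding <- vapply(seq_len(nrow(genes)), function(g) {
    chrom <- genes$chrom[g]
    lo <- min(genes$tss[g], genes$tts[g])
    hi <- max(genes$tss[g], genes$tts[g])
    b1 <- max(1L, floor(lo / bs) + 1L)
    b2 <- min(length(track$values[[chrom]]), ceiling(hi / bs))
    if (b2 < b1) return(NA_real_)
    ok <- !track$mask[[chrom]][b1:b2]
    if (!any(ok)) return(NA_real_)
    mean(track$values[[chrom]][b1:b2][ok]) * external_scale
  }, numeric(1))
  data.frame(id = genes$id, binding = binding, stringsAsFactors = FALSE)
}

#' Peak-to-TSS distances and TSS-proximal fraction
#'
#' Per peak: distance 0 if any TSS lies inside the peak interval,
#' otherwise the minimum over TSSs of the distance to the peak summit.
#' The report includes the fraction of peaks within `window` bp of a TSS.
#'
#' @param peaks peak data frame (chrom/start/end/summit).
#' @param genes gene data frame with `chrom` and `tss`; supply a
#'   filtered set (e.g. RNAP2-driven genes only) to restrict the TSS
#'   universe.
#' @param window proximity window in bp (default 5000).
#' @return list with `distances` (peaks with a `tss_distance` column),
#'   `fraction_within` (NA with `flagged = TRUE` when there are no
#'   peaks), `window`, `n_peaks`.
#' @export
peak_tss_association <- function(peaks, genes, window = 5000) {
  stopifnot("tss" %in% names(genes))
  if (nrow(peaks) == 0)
    return(list(distances = cbind(peaks, tss_distance = numeric(0)),
                fraction_within = NA_real_, flagged = TRUE,
                window = window, n_peaks = 0L))
  dist <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- genes$tss[genes$chrom == peaks$chrom[i]]
    if (!length(tss)) return(Inf)
    inside <- tss >= peaks$start[i] & tss < peaks$end[i]
    if (any(inside)) 0 else min(abs(tss - peaks$summit[i]))
  }, numeric(1))
  out <- peaks
  out$tss_distance <- dist
  list(distances = out,
       fraction_within = mean(dist <= window),
       flagged = FALSE, window = window, n_peaks = nrow(peaks))
}

#' TSS-proximal windows
#'
#' @param genes gene data frame with `chrom` and `tss`.
#' @param window half-width in bp.
#' @param chrom_sizes named vector used for clipping.
#' @return data frame chrom/start/end of TSS +/- window intervals.
#' @export
tss_windows <- function(genes, window = 5000, chrom_sizes = NULL) {
  out <- data.frame(chrom = genes$chrom,
                    start = genes$tss - window,
                    end = genes$tss + window)
  out$start <- pmax(out$start, 0)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- as_chrom_sizes(chrom_sizes)
    out$end <- pmin(out$end, unname(chrom_sizes[out$chrom]))
  }
  out
}

#' Genome fraction covered by an interval set
#'
#' Length of the merged union of the intervals (clipped to the
#' chromosomes) divided by total genome length. Duplicated or
#' overlapping intervals are never double-counted.
#'
#' @param intervals data frame chrom/start/end (0-based half-open).
#' @param chrom_sizes named vector or two-column data frame.
#' @return proportion of the genome covered.
#' @export
genome_fraction <- function(intervals, chrom_sizes) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (nrow(intervals) == 0) return(0)
  intervals <- intervals[intervals$chrom %in% names(chrom_sizes), , drop = FALSE]
  if (nrow(intervals) == 0) return(0)
  len <- chrom_sizes[intervals$chrom]
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = pmax(intervals$start, 0) + 1,
                     end = pmin(intervals$end, len)))
  sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / sum(chrom_sizes)
}

#' CpG-island association odds ratio
#'
#' Compares the fraction of peak-associated TSSs lying within `dist` of a
#' CpG island (p) with the same fraction among all TSSs (q):
#' `OR = (p/(1-p)) / (q/(1-q))`. Degenerate cases (p or q equal to 0
#' or 1, or an empty CGI set) are flagged.
#'
#' @param peak_tss data frame with `chrom` and `tss` for TSSs near peaks.
#' @param all_tss data frame with `chrom` and `tss` for all TSSs.
#' @param cgi data frame chrom/start/end of CpG-island intervals.
#' @param dist association distance in bp (default 1000).
#' @return list `odds_ratio`, `p`, `q`, `counts`, `degenerate`.
#' @export
cgi_enrichment <- function(peak_tss, all_tss, cgi, dist = 1000) {
  stopifnot(nrow(peak_tss) > 0, nrow(all_tss) > 0)
  if (nrow(cgi) == 0)
    return(list(odds_ratio = NA_real_, p = NA_real_, q = NA_real_,
                counts = NULL, degenerate = TRUE))
  cgi_gr <- GenomicRanges::GRanges(cgi$chrom,
                                   IRanges::IRanges(cgi$start + 1, cgi$end))
  assoc <- function(tss_df) {
    gr <- GenomicRanges::GRanges(tss_df$chrom,
                                 IRanges::IRanges(tss_df$tss + 1, width = 1))
    d <- rep(Inf, length(gr))
    hits <- GenomicRanges::distanceToNearest(gr, cgi_gr)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    d <= dist
  }
  a_peak <- assoc(peak_tss)
  a_all <- assoc(all_tss)
  p <- mean(a_peak)
  q <- mean(a_all)
  degenerate <- p %in% c(0, 1) || q %in% c(0, 1)
  or <- if (degenerate) if (p > q) Inf else 0 else (p / (1 - p)) / (q / (1 - q))
  list(odds_ratio = or, p = p, q = q,
       counts = c(peak_cgi = sum(a_peak), peak_total = length(a_peak),
                  all_cgi = sum(a_all), all_total = length(a_all)),
       degenerate = degenerate)
}

#' Stratify genes by expression
#'
#' Stable descending sort (ties broken by gene id), split into four
#' groups with greedy ceiling sizes (for n = 10: 3/3/2/2), plus the
#' top-decile and bottom-half sets used for high/low expression
#' contrasts. Genes without an expression value are excluded and
#' counted.
#'
#' @param genes gene data frame with `id` and `expression`.
#' @return list `quartiles` (list of 4 id vectors, highest first),
#'   `top_decile`, `bottom_half`, `ranked` (ordered data frame),
#'   `n_excluded`.
#' @export
expression_stratify <- function(genes) {
  stopifnot(all(c("id", "expression") %in% names(genes)))
  usable <- !is.na(genes$expression)
  n_excluded <- sum(!usable)
  g <- genes[usable, , drop = FALSE]
  if (nrow(g) < 4) stop("need at least 4 genes with expression values")
  ord <- order(-g$expression, g$id)
  g <- g[ord, , drop = FALSE]
  n <- nrow(g)
  sizes <- integer(4)
  rem <- n
  for (k in 1:4) {
    sizes[k] <- ceiling(rem / (5 - k))
    rem <- rem - sizes[k]
  }
  bounds <- cumsum(sizes)
  quartiles <- lapply(1:4, function(k) {
    lo <- if (k == 1) 1L else bounds[k - 1] + 1L
    g$id[lo:bounds[k]]
  })
  list(quartiles = quartiles,
       top_decile = g$id[seq_len(ceiling(n / 10))],
       bottom_half = g$id[(n - ceiling(n / 2) + 1):n],
       ranked = g, n_excluded = n_excluded)
}

#' Gene-set overlap enrichment test
#'
#' One-sided hypergeometric (Fisher's exact) upper-tail probability of
#' observing at least the realized overlap between two gene sets drawn
#' from a common universe. A two-sided alternative is exposed but
#' enrichment (greater) is the default.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe character vector of all gene ids.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @return list `p_value`, `overlap`, `expected`, `n_a`, `n_b`,
#'   `n_universe`.
#' @export
geneset_overlap_test <- function(set_a, set_b, universe,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  N <- length(universe)
  a <- length(set_a)
  b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  } else {
    m <- matrix(c(k, a - k, b - k, N - a - b + k), nrow = 2)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  list(p_value = p, overlap = k, expected = a * b / N,
       n_a = a, n_b = b, n_universe = N)
}

#' Genome-wide correlation of two profiles
#'
#' Pearson correlation over jointly unmasked bins, overall and per
#' annotation category. Each bin is assigned a single category with
#' priority centromere > rDNA > tRNA > other, so the scatter coloring is
#' unambiguous.
#'
#' @param profile_a,profile_b profiles or `binned_track`s on one grid.
#' @param categories optional data frame chrom/start/end/category with
#'   categories among `"centromere"`, `"rDNA"`, `"tRNA"`.
#' @return list `overall` (Pearson r), `by_category` (data frame
#'   category/n/r), `scatter` (data frame a/b/category per bin).
#' @export
track_correlation <- function(profile_a, profile_b, categories = NULL) {
  a <- as_binned_track(profile_a)
  b <- as_binned_track(profile_b)
  if (!same_binning(a, b)) stop("profiles have different binning")
  priority <- c("centromere", "rDNA", "tRNA")
  rows <- lapply(names(a$values), function(chrom) {
    ok <- !a$mask[[chrom]] & !b$mask[[chrom]]
    if (!any(ok)) return(NULL)
    bins <- which(ok)
    cat_bin <- rep("other", length(bins))
    if (!is.null(categories)) {
      sel <- categories[categories$chrom == chrom, , drop = FALSE]
      centers <- (bins - 0.5) * a$bin_size
      for (cls in rev(priority)) {  # apply in reverse so top priority wins
        ints <- sel[sel$category == cls, , drop = FALSE]
        for (i in seq_len(nrow(ints)))
          cat_bin[centers >= ints$start[i] & centers < ints$end[i]] <- cls
      }
    }
    data.frame(a = a$values[[chrom]][bins], b = b$values[[chrom]][bins],
               category = cat_bin, stringsAsFactors = FALSE)
  })
  scatter <- do.call(rbind, rows)
  if (is.null(scatter) || nrow(scatter) < 2)
    stop("fewer than 2 jointly unmasked bins")
  by_cat <- do.call(rbind, lapply(split(scatter, scatter$category), function(d)
    data.frame(category = d$category[1], n = nrow(d),
               r = if (nrow(d) >= 2 && stats::sd(d$a) > 0 && stats::sd(d$b) > 0)
                 stats::cor(d$a, d$b) else NA_real_)))
  rownames(by_cat) <- NULL
  list(overall = stats::cor(scatter$a, scatter$b),
       by_category = by_cat, scatter = scatter)
}
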