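#' Simulation configuration
#'
#' Parameters of the synthetic genome/occupancy generator. The generator
#' emulates the statistical structure the profiling pipeline assumes:
#' expression-proportional protein occupancy over gene bodies with a
#' TTS-biased shape (`mode = "yeast_tts"`) or a TSS spike
#' (`mode = "human_tss"`), a uniform basal level along the arms,
#' Poisson-sampled ChIP and input coverage, contiguous mappability
#' dropouts, and noisy qPCR percent-input readouts proportional to true
#' occupancy.
#'
#' @param seed integer seed controlling every random draw.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes number of genes across the genome.
#' @param gene_length_range transcript length range in bp.
#' @param expression_meanlog,expression_sdlog log-normal expression model
#'   for mitotically active genes (heavy-tailed, so "top 10%" vs
#'   "bottom 50%" stratification is meaningful).
#' @param active_fraction fraction of genes transcribed in mitosis;
#'   the remainder get expression 0, emulating the restriction of
#'   mitotic transcription to a minority of genes.
#' @param basal_occupancy uniform occupancy along arms (dimensionless).
#' @param occupancy_gain occupancy added per unit expression at the shape
#'   maximum.
#' @param mode `"yeast_tts"` (ramp from TSS to TTS, 300-bp decay past the
#'   TTS) or `"human_tss"` (triangular spike of half-width 500 bp at the
#'   TSS).
#' @param chip_depth,input_depth expected total reads per genome.
#' @param fragment_length library fragment size in bp.
#' @param bin_size analysis bin width in bp.
#' @param unmappable_fraction fraction of bins forced unmappable, drawn as
#'   contiguous blocks with geometric lengths (mean 500 bp).
#' @param qpcr_sigma relative s.d. of qPCR replicate noise.
#' @param qpcr_scale percent-input per unit of true occupancy.
#' @param cgi_fraction fraction of genes given a CpG-island interval over
#'   their TSS (human mode).
#' @param utr_annotated_fraction fraction of genes with explicit UTR
#'   lengths; the remainder are built with the default UTR lengths so TSS
#'   inference from defaults is exact.
#' @param utr5_default,utr3_default default UTR lengths in bp.
#' @param min_gene_gap minimum distance between transcripts in bp.
#' @param peak_fold normalized-occupancy threshold defining planted peak
#'   intervals in the ground-truth manifest.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 2e6,
                       n_genes = 100L,
                       gene_length_range = c(1000, 4000),
                       expression_meanlog = 0,
                       expression_sdlog = 1,
                       active_fraction = 0.4,
                       basal_occupancy = 0.2,
                       occupancy_gain = 1,
                       mode = c("yeast_tts", "human_tss"),
                       chip_depth = 1e6,
                       input_depth = 1e6,
                       fragment_length = 150,
                       bin_size = 10,
                       unmappable_fraction = 0.02,
                       qpcr_sigma = 0.05,
                       qpcr_scale = 2,
                       cgi_fraction = 0.6,
                       utr_annotated_fraction = 0.7,
                       utr5_default = 293,
                       utr3_default = 430,
                       min_gene_gap = 500,
                       peak_fold = 2) {
  mode <- match.arg(mode)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              active_fraction = active_fraction,
              basal_occupancy = basal_occupancy,
              occupancy_gain = occupancy_gain, mode = mode,
              chip_depth = chip_depth, input_depth = input_depth,
              fragment_length = fragment_length, bin_size = bin_size,
              unmappable_fraction = unmappable_fraction,
              qpcr_sigma = qpcr_sigma, qpcr_scale = qpcr_scale,
              cgi_fraction = cgi_fraction,
              utr_annotated_fraction = utr_annotated_fraction,
              utr5_default = utr5_default, utr3_default = utr3_default,
              min_gene_gap = min_gene_gap, peak_fold = peak_fold)
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
              length(gene_length_range) == 2,
              gene_length_range[1] > 0,
              gene_length_range[1] <= gene_length_range[2],
              active_fraction >= 0, active_fraction <= 1,
              basal_occupancy >= 0, occupancy_gain >= 0,
              chip_depth >= 0, input_depth > 0,
              fragment_length > 0, bin_size > 0,
              unmappable_fraction >= 0, unmappable_fraction < 1,
              qpcr_sigma >= 0, qpcr_scale > 0,
              cgi_fraction >= 0, cgi_fraction <= 1,
              utr5_default >= 0, utr3_default >= 0, min_gene_gap >= 0)
  })
  structure(cfg, class = "sim_config")
}

sim_flank <- 1000  # clearance kept free at each chromosome end

#' Generate a toy genome annotation
#'
#' Places non-overlapping genes (rejection sampling with a fixed
#' inter-gene gap floor), assigns strands, log-normal expression, UTR
#' lengths (explicit for a configurable fraction of genes, defaults
#' otherwise) and, in human mode, CpG-island intervals over a subset of
#' TSSs. Deterministic for a fixed config + seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_annotation` with `chrom_sizes`, `genes`
#'   (data frame: id, chrom, strand, cds_start, cds_end, utr5_len,
#'   utr3_len, tss, tts, biotype, expression; coordinates 0-based
#'   half-open), `cgi` (data frame chrom/start/end), `expression` (named
#'   vector) and `config`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(config$n_chroms))))
  chrom_sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)

  usable <- sum(chrom_sizes - 2 * sim_flank)
  min_span <- config$n_genes * (config$gene_length_range[1] + config$min_gene_gap)
  if (min_span > usable)
    stop("infeasible gene packing: ", config$n_genes,
         " genes of >= ", config$gene_length_range[1],
         " bp (+ gap) exceed the usable genome (", usable, " bp)")

  genes <- NULL
  if (config$n_genes > 0) {
    lens <- round(stats::runif(config$n_genes,
                               config$gene_length_range[1],
                               config$gene_length_range[2]))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    expr <- stats::rlnorm(config$n_genes, config$expression_meanlog,
                          config$expression_sdlog) *
      stats::rbinom(config$n_genes, 1, config$active_fraction)
    annotated <- stats::runif(config$n_genes) < config$utr_annotated_fraction
    utr5 <- ifelse(annotated, round(stats::runif(config$n_genes, 100, 400)),
                   config$utr5_default)
    utr3 <- ifelse(annotated, round(stats::runif(config$n_genes, 200, 600)),
                   config$utr3_default)

    placed <- vector("list", config$n_genes)
    occupied <- stats::setNames(vector("list", length(chroms)), chroms)
    attempts <- 0L
    max_attempts <- 10000L + 200L * config$n_genes
    for (g in seq_len(config$n_genes)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("infeasible gene packing: placement failed after ",
               max_attempts, " attempts")
        chrom <- sample(chroms, 1, prob = chrom_sizes)
        hi <- chrom_sizes[[chrom]] - sim_flank - lens[g]
        if (hi <= sim_flank) next
        start <- round(stats::runif(1, sim_flank, hi))
        end <- start + lens[g]
        occ <- occupied[[chrom]]
        clash <- FALSE
        if (length(occ))
          clash <- any(start - config$min_gene_gap < occ[, 2] &
                       end + config$min_gene_gap > occ[, 1])
        if (!clash) {
          occupied[[chrom]] <- rbind(occ, c(start, end))
          placed[[g]] <- list(chrom = chrom, start = start, end = end)
          break
        }
      }
    }
    p <- do.call(rbind, lapply(placed, as.data.frame))
    tss <- ifelse(strand == "+", p$start, p$end)
    tts <- ifelse(strand == "+", p$end, p$start)
    cds_start <- ifelse(strand == "+", p$start + utr5, p$start + utr3)
    cds_end <- ifelse(strand == "+", p$end - utr3, p$end - utr5)
    genes <- data.frame(
      id = sprintf("gene%04d", seq_len(config$n_genes)),
      chrom = p$chrom, strand = strand,
      cds_start = cds_start, cds_end = cds_end,
      utr5_len = ifelse(annotated, utr5, NA_real_),
      utr3_len = ifelse(annotated, utr3, NA_real_),
      tss = tss, tts = tts,
      biotype = "coding", expression = expr,
      stringsAsFactors = FALSE)
    if (any(genes$cds_start >= genes$cds_end))
      stop("gene length range too short for the UTR lengths drawn")
  } else {
    genes <- data.frame(id = character(), chrom = character(),
                        strand = character(), cds_start = numeric(),
                        cds_end = numeric(), utr5_len = numeric(),
                        utr3_len = numeric(), tss = numeric(),
                        tts = numeric(), biotype = character(),
                        expression = numeric(), stringsAsFactors = FALSE)
  }

  cgi <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (config$mode == "human_tss" && nrow(genes) > 0) {
    n_cgi <- round(config$cgi_fraction * nrow(genes))
    if (n_cgi > 0) {
      pick <- sort(sample(nrow(genes), n_cgi))
      cgi <- data.frame(chrom = genes$chrom[pick],
                        start = pmax(0, genes$tss[pick] - 200),
                        end = pmin(chrom_sizes[genes$chrom[pick]],
                                   genes$tss[pick] + 200))
      cgi <- cgi[order(cgi$chrom, cgi$start), , drop = FALSE]
      rownames(cgi) <- NULL
    }
  }

  structure(list(chrom_sizes = chrom_sizes, genes = genes, cgi = cgi,
                 expression = stats::setNames(genes$expression, genes$id),
                 config = config),
            class = "sim_annotation")
}

# Occupancy shape of one gene, evaluated at bin centers, on the
# normalized 0..1 scale.
gene_shape <- function(centers, tss, tts, mode) {
  s <- numeric(length(centers))
  if (mode == "yeast_tts") {
    len <- abs(tts - tss)
    dirn <- sign(tts - tss)
    along <- (centers - tss) * dirn      # bp into the gene body
    body <- along >= 0 & along < len
    s[body] <- along[body] / len
    past <- along - len                  # bp past the TTS
    decay <- past >= 0 & past < 300
    s[decay] <- 1 - past[decay] / 300
  } else {
    d <- abs(centers - tss)
    spike <- d < 500
    s[spike] <- 1 - d[spike] / 500
  }
  s
}

#' Simulate ground-truth occupancy
#'
#' Per-bin true occupancy is `basal + sum_g gain * expression_g *
#' shape_g`, where the shape ramps linearly from 0 at the TSS to 1 at the
#' TTS and decays over 300 bp (yeast mode), or is a 500-bp half-width
#' triangular spike at the TSS (human mode). Unmappable blocks (geometric
#' lengths, mean 500 bp) are drawn to hit the configured bin fraction
#' exactly, and the track is rescaled to mean 1 over mappable bins.
#'
#' @param annotation a [generate_annotation()] result.
#' @param expression named per-gene expression vector; defaults to the
#'   annotation's ground-truth expression.
#' @param config a [sim_config()]; defaults to the annotation's config.
#' @return list of class `ground_truth` with `occupancy` (mean-1
#'   `binned_track` masked at unmappable bins), `planted_peaks` (data
#'   frame chrom/start/end/max_fold of regions where normalized occupancy
#'   exceeds `peak_fold`), `unmappable` (data frame chrom/start/end) and
#'   `expression`.
#' @export
simulate_occupancy <- function(annotation, expression = annotation$expression,
                               config = annotation$config) {
  stopifnot(inherits(annotation, "sim_annotation"))
  set.seed(config$seed + 1L)
  bs <- config$bin_size
  sizes <- annotation$chrom_sizes
  occ <- lapply(sizes, function(len) rep(config$basal_occupancy, n_bins(len, bs)))

  genes <- annotation$genes
  if (nrow(genes) > 0) {
    expr <- expression[genes$id]
    expr[is.na(expr)] <- 0
    for (g in seq_len(nrow(genes))) {
      chrom <- genes$chrom[g]
      lo <- min(genes$tss[g], genes$tts[g]) - 1000
      hi <- max(genes$tss[g], genes$tts[g]) + 1000
      b1 <- max(1L, floor(lo / bs) + 1L)
      b2 <- min(length(occ[[chrom]]), ceiling(hi / bs))
      centers <- ((b1:b2) - 0.5) * bs
      s <- gene_shape(centers, genes$tss[g], genes$tts[g], config$mode)
      occ[[chrom]][b1:b2] <- occ[[chrom]][b1:b2] +
        config$occupancy_gain * expr[g] * s
    }
  }

  # unmappable blocks: contiguous, geometric block lengths, exact total
  tot <- sum(vapply(occ, length, integer(1)))
  target <- round(config$unmappable_fraction * tot)
  mask <- lapply(occ, function(v) rep(FALSE, length(v)))
  placed <- 0L
  guard <- 0L
  while (placed < target) {
    guard <- guard + 1L
    if (guard > 100000L) stop("failed to place unmappable blocks")
    chrom <- sample(names(sizes), 1, prob = sizes)
    n <- length(mask[[chrom]])
    blen <- min(stats::rgeom(1, bs / 500) + 1L, target - placed)
    b1 <- sample.int(n - blen + 1L, 1)
    span <- b1:(b1 + blen - 1L)
    span <- span[!mask[[chrom]][span]]
    mask[[chrom]][span] <- TRUE
    placed <- placed + length(span)
    if (placed > target) {  # trim overshoot from this block
      extra <- placed - target
      mask[[chrom]][utils::tail(span, extra)] <- FALSE
      placed <- target
    }
  }

  mappable_mean <- mean(unlist(Map(function(v, m) v[!m], occ, mask),
                               use.names = FALSE))
  if (!is.finite(mappable_mean) || mappable_mean <= 0)
    stop("degenerate occupancy: zero mean over mappable bins")
  occ <- lapply(occ, function(v) v / mappable_mean)

  planted <- lapply(names(occ), function(chrom) {
    pass <- occ[[chrom]] >= config$peak_fold & !mask[[chrom]]
    if (!any(pass)) return(NULL)
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = chrom,
               start = (starts[keep] - 1) * bs,
               end = ends[keep] * bs,
               max_fold = vapply(keep, function(k)
                 max(occ[[chrom]][starts[k]:ends[k]]), numeric(1)))
  })
  planted <- do.call(rbind, planted)
  if (is.null(planted))
    planted <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), max_fold = numeric())

  unmap <- do.call(rbind, lapply(names(mask), function(chrom) {
    m <- mask[[chrom]]
    if (!any(m)) return(NULL)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(chrom = chrom, start = (starts[keep] - 1) * bs,
               end = ends[keep] * bs)
  }))
  if (is.null(unmap))
    unmap <- data.frame(chrom = character(), start = numeric(), end = numeric())

  structure(list(
    occupancy = binned_track(occ, sizes, bs, mask = mask),
    planted_peaks = planted,
    unmappable = unmap,
    expression = expression,
    config = config
  ), class = "ground_truth")
}

#' Simulate ChIP and input bin counts
#'
#' Per mappable bin, `chip ~ Poisson(chip_depth * occupancy / n_bins)` and
#' `input ~ Poisson(input_depth / n_bins)`; unmappable bins receive zero
#' in both. Counts are simulated directly per bin (equivalent to
#' read-level sampling under Poisson thinning).
#'
#' @param truth a [simulate_occupancy()] result.
#' @param config a [sim_config()]; defaults to the truth's config.
#' @return list with `chip` and `input` `binned_track`s of counts.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 2L)
  occ <- truth$occupancy
  nb <- total_bins(occ)
  chip <- Map(function(v, m) {
    lam <- config$chip_depth * v / nb
    x <- stats::rpois(length(v), lam)
    x[m] <- 0
    as.numeric(x)
  }, occ$values, occ$mask)
  input <- Map(function(v, m) {
    x <- stats::rpois(length(v), config$input_depth / nb)
    x[m] <- 0
    as.numeric(x)
  }, occ$values, occ$mask)
  list(chip = binned_track(chip, occ$chrom_sizes, occ$bin_size),
       input = binned_track(input, occ$chrom_sizes, occ$bin_size))
}

#' Simulate noisy qPCR anchor measurements
#'
#' For each amplicon, the percent-input readout is `qpcr_scale * (mean
#' true occupancy over the amplicon's mappable bins) * (1 + eps)` with
#' `eps ~ Normal(0, qpcr_sigma)`, drawn independently for two technical
#' replicates; the anchor records their mean, s.d. and n = 2.
#'
#' @param truth a [simulate_occupancy()] result.
#' @param amplicons data frame with columns `site`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param config a [sim_config()]; defaults to the truth's config.
#' @return data frame of anchors: site, chrom, start, end, percent_input,
#'   sd, n.
#' @export
simulate_qpcr <- function(truth, amplicons, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"),
            all(c("site", "chrom", "start", "end") %in% names(amplicons)))
  set.seed(config$seed + 3L)
  occ <- truth$occupancy
  bs <- occ$bin_size
  out <- amplicons
  out$percent_input <- NA_real_
  out$sd <- NA_real_
  out$n <- 2L
  for (j in seq_len(nrow(amplicons))) {
    chrom <- amplicons$chrom[j]
    if (!chrom %in% names(occ$values))
      stop("amplicon ", amplicons$site[j], " on unknown chromosome ", chrom)
    b1 <- floor(amplicons$start[j] / bs) + 1L
    b2 <- min(length(occ$values[[chrom]]), ceiling(amplicons$end[j] / bs))
    ok <- !occ$mask[[chrom]][b1:b2]
    if (!any(ok))
      stop("amplicon ", amplicons$site[j], " is fully unmappable")
    m <- mean(occ$values[[chrom]][b1:b2][ok])
    reps <- config$qpcr_scale * m *
      (1 + stats::rnorm(2, 0, config$qpcr_sigma))
    out$percent_input[j] <- mean(reps)
    out$sd[j] <- stats::sd(reps)
  }
  out
}

#' Default qPCR amplicon panel for a simulated genome
#'
#' Picks genes spanning the expression range (so anchors cover a wide
#' dynamic range of occupancy) and places a 200-bp amplicon at each
#' gene's occupancy maximum (TTS in yeast mode, TSS in human mode), plus
#' basal-level amplicons in intergenic space if genes run short.
#'
#' @param annotation a [generate_annotation()] result.
#' @param n number of amplicons (default 12).
#' @param truth optional [simulate_occupancy()] result; when given,
#'   candidate sites falling entirely into unmappable blocks are skipped.
#' @return amplicon data frame suitable for [simulate_qpcr()].
#' @export
default_amplicons <- function(annotation, n = 12, truth = NULL) {
  genes <- annotation$genes
  cfg <- annotation$config
  mappable <- function(chrom, start, end) {
    if (is.null(truth)) return(TRUE)
    occ <- truth$occupancy
    b1 <- floor(start / occ$bin_size) + 1L
    b2 <- min(length(occ$values[[chrom]]), ceiling(end / occ$bin_size))
    !all(occ$mask[[chrom]][b1:b2])
  }
  rows <- list()
  if (nrow(genes) > 0) {
    ord <- order(-genes$expression, genes$id)
    # spread across the expression range first, remaining genes as backup
    spread <- unique(round(seq(1, length(ord),
                               length.out = min(n, length(ord)))))
    for (i in unique(c(spread, seq_along(ord)))) {
      if (length(rows) >= n) break
      g <- genes[ord[i], ]
      pos <- if (cfg$mode == "yeast_tts") g$tts else g$tss
      start <- max(0, pos - 100)
      if (!mappable(g$chrom, start, pos + 100)) next
      rows[[length(rows) + 1]] <-
        data.frame(site = paste0("amp_", g$id), chrom = g$chrom,
                   start = start, end = pos + 100)
    }
  }
  need <- n - length(rows)
  if (need > 0) {
    pos <- round(seq(2000, annotation$chrom_sizes[[1]] - 2000,
                     length.out = need + 2))[seq_len(need) + 1]
    for (p in pos)
      if (mappable(names(annotation$chrom_sizes)[1], p - 100, p + 100))
        rows[[length(rows) + 1]] <-
          data.frame(site = paste0("amp_bg", length(rows) + 1),
                     chrom = names(annotation$chrom_sizes)[1],
                     start = p - 100, end = p + 100)
  }
  amps <- do.call(rbind, rows)
  rownames(amps) <- NULL
  amps
}

#' Emit read intervals reproducing a count track
#'
#' For I/O round-trip testing: produces plus-strand read intervals whose
#' extended-fragment midpoints fall in the bins of `counts`, so that
#' [bin_reads()] with the same fragment length recovers the counts
#' exactly.
#'
#' @param counts a `binned_track` of integer counts.
#' @param fragment_length fragment length that will be used when binning.
#' @param read_length emitted read length in bp.
#' @return data frame chrom/start/end/name/score/strand (BED6 fields).
#' @export
reads_from_counts <- function(counts, fragment_length = 150, read_length = 50) {
  bs <- counts$bin_size
  out <- lapply(names(counts$values), function(chrom) {
    v <- counts$values[[chrom]]
    idx <- rep(seq_along(v), times = v)
    if (!length(idx)) return(NULL)
    center <- (idx - 0.5) * bs
    # plus-strand placement where the fragment fits; bins too close to
    # the chromosome start get minus-strand reads (midpoint = end - f/2)
    start <- round(center - fragment_length / 2)
    strand <- rep("+", length(start))
    flip <- start < 0
    end <- start + read_length
    end[flip] <- round(center[flip] + fragment_length / 2)
    start[flip] <- end[flip] - read_length
    strand[flip] <- "-"
    data.frame(chrom = chrom, start = start, end = end,
               name = paste0("r", seq_along(start)), score = 0L,
               strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = integer(), strand = character())
  rownames(out) <- NULL
  out
}

#' One-call synthetic data set
#'
#' Convenience wrapper running [generate_annotation()],
#' [simulate_occupancy()], [simulate_reads()] and [simulate_qpcr()] on the
#' default amplicon panel.
#'
#' @param config a [sim_config()].
#' @param n_amplicons number of qPCR anchor sites.
#' @return list with `annotation`, `truth`, `chip`, `input`, `anchors`.
#' @export
simulate_dataset <- function(config, n_amplicons = 12) {
  ann <- generate_annotation(config)
  truth <- simulate_occupancy(ann)
  reads <- simulate_reads(truth)
  amps <- default_amplicons(ann, n_amplicons, truth)
  anchors <- simulate_qpcr(truth, amps)
  list(annotation = ann, truth = truth, chip = reads$chip,
       input = reads$input, anchors = anchors, config = config)
}
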