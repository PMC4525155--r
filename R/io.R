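# File I/O and the end-to-end pipeline. Internal coordinates are 0-based
# half-open (BED convention); GFF3 is 1-based inclusive and converted at
# this boundary only.

#' Read a chromosome-size table
#'
#' @param path two-column TSV (chromosome, length) without a header.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  as_chrom_sizes(stats::setNames(d$size, d$chrom))
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named vector of lengths.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned read positions from BED or SAM
#'
#' BED records are taken as-is (0-based half-open, strand from column 6).
#' SAM files are converted with Rsamtools; unmapped and secondary records
#' are skipped and their counts reported.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @param chrom_sizes optional named vector; reads on chromosomes absent
#'   from it raise an error listing the offenders.
#' @return data frame chrom/start/end/strand with attribute `n_skipped`.
#' @export
read_alignments <- function(path, format = c("auto", "bed", "sam"),
                            chrom_sizes = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  n_skipped <- 0L
  if (format == "bed") {
    if (file.size(path) == 0) {
      warning("empty alignment file: ", path)
      reads <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), strand = character())
    } else {
      gr <- rtracklayer::import(path, format = "BED")
      reads <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1,
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          stringsAsFactors = FALSE)
      reads$strand[reads$strand == "*"] <- "+"
    }
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      flag = flags, what = c("rname", "pos", "qwidth", "strand")))[[1]]
    total <- Rsamtools::countBam(bam)$records
    n_skipped <- total - length(res$pos)
    if (n_skipped > 0)
      message(n_skipped, " unmapped/secondary record(s) skipped")
    reads <- data.frame(chrom = as.character(res$rname),
                        start = res$pos - 1,
                        end = res$pos - 1 + res$qwidth,
                        strand = as.character(res$strand),
                        stringsAsFactors = FALSE)
    unlink(bam)
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(reads$chrom), names(as_chrom_sizes(chrom_sizes)))
    if (length(unknown))
      stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  attr(reads, "n_skipped") <- n_skipped
  reads
}

track_to_granges <- function(track) {
  grs <- lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    m <- track$mask[[chrom]]
    keep <- which(!m)
    if (!length(keep)) return(NULL)
    bs <- track$bin_size
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (keep - 1) * bs + 1,
                       end = pmin(keep * bs, track$chrom_sizes[[chrom]])),
      score = v[keep])
  })
  do.call(c, Filter(Negate(is.null), grs))
}

#' Write a binned track as bedGraph or fixedStep wiggle
#'
#' Masked bins are omitted; they can be restored as masked on re-read.
#' fixedStep blocks are emitted per contiguous unmasked run.
#'
#' @param track a `binned_track` (or profile; coerced).
#' @param path output file.
#' @param format `"bedGraph"` or `"wig"` (fixedStep).
#' @return the path, invisibly.
#' @export
write_track <- function(track, path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  track <- as_binned_track(track)
  if (format == "bedGraph") {
    gr <- track_to_granges(track)
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    bs <- track$bin_size
    for (chrom in names(track$values)) {
      v <- track$values[[chrom]]
      m <- track$mask[[chrom]]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(!r$values)) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                           chrom, (starts[k] - 1L) * bs + 1L, bs, bs), con)
        writeLines(format(v[starts[k]:ends[k]], digits = 10, trim = TRUE,
                          scientific = FALSE), con)
      }
    }
  }
  invisible(path)
}

#' Read a track written by [write_track()]
#'
#' Bins without a record are restored as masked.
#'
#' @param path bedGraph or wiggle file (format detected by rtracklayer).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size expected bin width; a record wider than it is an
#'   error.
#' @return a `binned_track`.
#' @export
read_track <- function(path, chrom_sizes, bin_size = 10) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  vals <- lapply(chrom_sizes, function(len) rep(NA_real_, n_bins(len, bin_size)))
  mask <- lapply(chrom_sizes, function(len) rep(TRUE, n_bins(len, bin_size)))
  if (any(GenomicRanges::width(gr) > bin_size))
    stop("record wider than the stated bin size (", bin_size, " bp)")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown))
    stop("track records on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  start0 <- GenomicRanges::start(gr) - 1
  if (any(start0 %% bin_size != 0))
    stop("record not aligned to the ", bin_size, "-bp bin grid")
  idx <- start0 %/% bin_size + 1L
  score <- S4Vectors::mcols(gr)$score
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    vals[[chrom]][idx[sel]] <- score[sel]
    mask[[chrom]][idx[sel]] <- FALSE
  }
  binned_track(vals, chrom_sizes, bin_size, mask = mask)
}

#' Write / read interval tables as BED
#'
#' @param intervals data frame chrom/start/end (0-based half-open).
#' @param path file path.
#' @return `write_bed` the path invisibly; `read_bed` a data frame.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  d <- utils::read.table(path, sep = "\t", header = FALSE)
  stats::setNames(d[, 1:3], c("chrom", "start", "end"))
}

#' Write peaks as BED6+ and TSV
#'
#' BED columns: chrom, start, end, name, max_score, strand (`.`), plus a
#' seventh column with the summit offset from the peak start.
#'
#' @param peaks peak data frame from the peak callers.
#' @param path output path (BED).
#' @return the path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  d <- data.frame(peaks$chrom, peaks$start, peaks$end,
                  name = sprintf("peak_%04d", seq_len(nrow(peaks))),
                  score = round(peaks$max_score, 4), strand = ".",
                  summit_offset = peaks$summit - peaks$start)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read gene tables
#'
#' The flat TSV keeps explicit UTR columns (NA = unannotated); the GFF3
#' export converts to 1-based inclusive coordinates with CDS features.
#'
#' @param genes gene data frame.
#' @param path file path.
#' @return paths invisibly; `read_genes_tsv` a data frame.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genes_tsv
#' @export
read_genes_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(id = "character", chrom = "character",
                                   strand = "character"))
}

#' @rdname write_genes_tsv
#' @param chrom_sizes named vector of chromosome lengths.
#' @export
write_genes_gff3 <- function(genes, path, chrom_sizes) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$cds_start + 1, end = genes$cds_end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$id
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write / read qPCR anchor tables
#'
#' TSV columns: site, chrom, start, end, percent_input, sd, n.
#'
#' @param anchors anchor data frame.
#' @param path file path.
#' @export
write_anchors_tsv <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchors_tsv
#' @export
read_anchors_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(site = "character", chrom = "character"))
}

#' Pipeline configuration
#'
#' All tunable constants of the profiling/analysis pipeline with their
#' standard defaults: 10-bp bins, 100-bp smoothing, 20% input-coverage
#' masking, 150-bp fragments, rER/intensity peak thresholds
#' (ethre 2, ithre 2, ipm 7), 1-kb metagene flanks, a 5-kb TSS
#' association window, 1-kb CGI association distance and 293/430-bp
#' default UTR lengths.
#'
#' @param ... overrides of the defaults listed above.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(bin_size = 10, smoothing_window = 100, mask_fraction = 0.20,
              fragment_length = 150, ethre = 2, ithre = 2, ipm = 7,
              min_width = 100, merge_gap = 100, fdr_target = 0.05,
              input_guard = 2, metagene_flank = 1000, n_body_bins = 100,
              association_window = 5000, cgi_distance = 1000,
              utr5_default = 293, utr3_default = 430, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate -> profile -> peaks -> calibrate -> analyze
#' pipeline
#'
#' Simulates a data set, builds the rER profile, calls peaks, fits and
#' validates the qPCR anchor regression, computes metagene profiles for
#' the top-decile and bottom-half expression strata and the peak-TSS
#' association report, and writes every artifact (tracks as bedGraph,
#' mask and peaks as BED, genes as TSV + GFF3, anchors as TSV, reports
#' and provenance as JSON) into `outdir`. Deterministic for a fixed
#' simulation seed.
#'
#' @param sim a [sim_config()] describing the synthetic data set.
#' @param outdir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the in-memory objects (`profile`,
#'   `peaks`, `fit`, `validation`, `metagenes`, `association`, `fdr`).
#' @export
run_pipeline <- function(sim, outdir, config = pipeline_config(),
                         quiet = FALSE) {
  stage <- function(name)
    if (!quiet) message(sprintf("[%s] %s", format(name, width = 9), outdir))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage("simulate")
  ds <- simulate_dataset(sim)
  ann <- ds$annotation
  write_chrom_sizes(ann$chrom_sizes, file.path(outdir, "chrom.sizes"))
  write_genes_tsv(ann$genes, file.path(outdir, "genes.tsv"))
  write_genes_gff3(ann$genes, file.path(outdir, "genes.gff3"), ann$chrom_sizes)
  write_bed(ds$truth$unmappable, file.path(outdir, "unmappable.bed"))
  if (nrow(ann$cgi)) write_bed(ann$cgi, file.path(outdir, "cgi.bed"))
  write_anchors_tsv(ds$anchors, file.path(outdir, "anchors.tsv"))
  jsonlite::write_json(
    list(planted_peaks = ds$truth$planted_peaks,
         expression = as.list(ds$truth$expression)),
    file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

  stage("profile")
  profile <- compute_rer(ds$chip, ds$input, config$smoothing_window,
                         config$mask_fraction)
  write_track(profile, file.path(outdir, "rer.bedGraph"))
  mask_df <- do.call(rbind, lapply(names(profile$track$mask), function(chrom) {
    m <- profile$track$mask[[chrom]]
    if (!any(m)) return(NULL)
    r <- rle(m); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    k <- which(r$values)
    data.frame(chrom = chrom, start = (s[k] - 1) * profile$track$bin_size,
               end = e[k] * profile$track$bin_size)
  }))
  if (is.null(mask_df))
    mask_df <- data.frame(chrom = character(), start = numeric(),
                          end = numeric())
  write_bed(mask_df, file.path(outdir, "mask.bed"))

  stage("peaks")
  pk_cfg <- peak_config(ethre = config$ethre, ithre = config$ithre,
                        ipm = config$ipm, min_width = config$min_width,
                        merge_gap = config$merge_gap,
                        fdr_target = config$fdr_target,
                        input_guard = config$input_guard)
  peaks <- call_peaks_rer(profile, pk_cfg)
  write_peaks_bed(peaks, file.path(outdir, "peaks.bed"))
  fdr <- estimate_fdr_swap(ds$chip, ds$input, pk_cfg, mode = "rer",
                           smoothing_window = config$smoothing_window,
                           mask_fraction = config$mask_fraction)

  stage("calibrate")
  fit <- fit_anchor_regression(ds$anchors, profile)
  validation <- validate_profile(ds$anchors, profile)
  jsonlite::write_json(
    list(slope = fit$slope, pearson_r = fit$pearson_r, n = fit$n,
         pass = validation$pass),
    file.path(outdir, "anchor_fit.json"), auto_unbox = TRUE, digits = NA)

  stage("analyze")
  strata <- expression_stratify(ann$genes)
  mg <- lapply(list(top_decile = strata$top_decile,
                    bottom_half = strata$bottom_half), function(ids)
    metagene(profile, ann$genes[ann$genes$id %in% ids, , drop = FALSE],
             flank = config$metagene_flank,
             n_body_bins = config$n_body_bins))
  assoc <- peak_tss_association(peaks, ann$genes,
                                window = config$association_window)
  report <- list(
    n_peaks = nrow(peaks),
    swap_fdr = fdr$fdr,
    tss_fraction_within = assoc$fraction_within,
    genome_fraction_tss = genome_fraction(
      tss_windows(ann$genes, config$association_window, ann$chrom_sizes),
      ann$chrom_sizes),
    anchor_r = fit$pearson_r)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  prov <- list(package = "rertools",
               version = as.character(utils::packageVersion("rertools")),
               config = unclass(config), sim = unclass(sim),
               config_md5 = unname(tools::md5sum(
                 local({ f <- tempfile(); writeLines(cfg_json, f); f }))),
               input_md5 = as.list(tools::md5sum(
                 file.path(outdir, c("chrom.sizes", "genes.tsv")))))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, profile = profile, peaks = peaks, fdr = fdr,
                 fit = fit, validation = validation, metagenes = mg,
                 association = assoc, report = report))
}
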