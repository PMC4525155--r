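test_that("annotation generation is seed-deterministic and validates packing", {
  cfg <- small_sim(seed = 5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))

  # genes non-overlapping with the gap floor, per chromosome
  g <- a1$genes
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, ]
    lo <- pmin(gc$tss, gc$tts)
    hi <- pmax(gc$tss, gc$tts)
    ord <- order(lo)
    expect_true(all(lo[ord][-1] - hi[ord][-length(ord)] >= cfg$min_gene_gap))
  }

  empty <- generate_annotation(small_sim(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)

  expect_error(generate_annotation(small_sim(n_genes = 1000)),
               "infeasible")
})

test_that("occupancy follows the additive shape model", {
  # single gene: normalized occupancy at the TTS bin relative to a basal
  # bin must equal (basal + gain*e*shape) / basal with the shape
  # evaluated at the bin center
  cfg <- sim_config(seed = 21, chrom_length = 2e5, n_genes = 1,
                    basal_occupancy = 0.5, occupancy_gain = 2,
                    active_fraction = 1, unmappable_fraction = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_occupancy(ann)
  g <- ann$genes[1, ]
  bs <- cfg$bin_size
  occ <- truth$occupancy$values[[g$chrom]]
  tts_bin <- if (g$strand == "+") floor((g$tts - 1) / bs) + 1 else
    floor(g$tts / bs) + 1
  center <- (tts_bin - 0.5) * bs
  s <- rertools:::gene_shape(center, g$tss, g$tts, "yeast_tts")
  e <- g$expression
  basal_bin <- 10  # far from the single gene (genes sit >= 1 kb from ends)
  expect_gt(abs((g$tss - basal_bin * bs)), 1000)
  expect_equal(occ[tts_bin] / occ[basal_bin],
               (0.5 + 2 * e * s) / 0.5, tolerance = 1e-12)

  # all expression zero -> constant occupancy, normalized to 1
  t0 <- simulate_occupancy(ann, expression = stats::setNames(0, g$id))
  expect_true(all(abs(unmasked_values(t0$occupancy) - 1) < 1e-12))

  # scale invariance with zero basal
  cfg0 <- sim_config(seed = 21, chrom_length = 2e5, n_genes = 1,
                     basal_occupancy = 0, occupancy_gain = 2,
                     active_fraction = 1, unmappable_fraction = 0)
  ann0 <- generate_annotation(cfg0)
  e0 <- ann0$expression
  o1 <- simulate_occupancy(ann0, expression = e0)
  o2 <- simulate_occupancy(ann0, expression = 2 * e0)
  expect_equal(o1$occupancy$values, o2$occupancy$values, tolerance = 1e-12)
})

test_that("planted peaks stay inside gene extents and above basal", {
  for (mode in c("yeast_tts", "human_tss")) {
    cfg <- small_sim(seed = 9, mode = mode)
    ann <- generate_annotation(cfg)
    truth <- simulate_occupancy(ann)
    g <- ann$genes
    if (nrow(truth$planted_peaks) > 0) {
      ok <- vapply(seq_len(nrow(truth$planted_peaks)), function(i) {
        pk <- truth$planted_peaks[i, ]
        sel <- g$chrom == pk$chrom
        if (mode == "yeast_tts") {
          # body plus the 300-bp decay on the TTS side (either strand)
          any(pk$start >= pmin(g$tss, g$tts)[sel] - 300 - cfg$bin_size &
              pk$end <= pmax(g$tss, g$tts)[sel] + 300 + cfg$bin_size)
        } else {
          any(abs((pk$start + pk$end) / 2 - g$tss[sel]) <= 500 + cfg$bin_size)
        }
      }, logical(1))
      expect_true(all(ok))
    }
    # normalized basal floor: bins far from any gene all sit at the
    # common minimum, and nothing mappable falls below it
    v <- unmasked_values(truth$occupancy)
    expect_true(all(v >= min(v) - 1e-12))
    expect_gt(min(v), 0)
  }
})

test_that("read counts are Poisson with the stated intensities", {
  cfg <- sim_config(seed = 4, chrom_length = 1e6, n_genes = 0,
                    basal_occupancy = 1, unmappable_fraction = 0,
                    chip_depth = 1e6, input_depth = 1e6)
  ann <- generate_annotation(cfg)
  truth <- simulate_occupancy(ann)
  reads <- simulate_reads(truth)
  counts <- unlist(reads$chip$values, use.names = FALSE)
  n <- length(counts)        # 1e5 bins, lambda = 10
  se <- sqrt(10 / n)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_lt(abs(var(counts) / 10 - 1), 0.05)

  cfg0 <- small_sim(chip_depth = 0)
  tr0 <- simulate_reads(simulate_occupancy(generate_annotation(cfg0)))
  expect_true(all(unlist(tr0$chip$values) == 0))
})

test_that("unmappable blocks hit the configured fraction exactly", {
  cfg <- small_sim(seed = 12, unmappable_fraction = 0.05)
  truth <- simulate_occupancy(generate_annotation(cfg))
  nb <- sum(lengths(truth$occupancy$values))
  masked <- sum(vapply(truth$occupancy$mask, sum, numeric(1)))
  expect_identical(masked, round(0.05 * nb))
  # both count tracks are zero at unmappable bins
  reads <- simulate_reads(truth)
  for (chrom in names(truth$occupancy$mask)) {
    m <- truth$occupancy$mask[[chrom]]
    expect_true(all(reads$chip$values[[chrom]][m] == 0))
    expect_true(all(reads$input$values[[chrom]][m] == 0))
  }
})

test_that("qPCR anchors are proportional to true occupancy", {
  cfg <- small_sim(seed = 8, qpcr_sigma = 0)
  ann <- generate_annotation(cfg)
  truth <- simulate_occupancy(ann)
  amps <- default_amplicons(ann, 12)
  anchors <- simulate_qpcr(truth, amps, cfg)
  bs <- cfg$bin_size
  true_mean <- vapply(seq_len(nrow(amps)), function(j) {
    v <- truth$occupancy$values[[amps$chrom[j]]]
    m <- truth$occupancy$mask[[amps$chrom[j]]]
    b <- (floor(amps$start[j] / bs) + 1):ceiling(amps$end[j] / bs)
    mean(v[b][!m[b]])
  }, numeric(1))
  expect_equal(anchors$percent_input, cfg$qpcr_scale * true_mean,
               tolerance = 1e-12)
  expect_equal(stats::cor(anchors$percent_input, true_mean), 1,
               tolerance = 1e-12)

  # flat occupancy: every anchor reads the global scale
  cfg1 <- sim_config(seed = 2, chrom_length = 2e5, n_genes = 0,
                     basal_occupancy = 1, qpcr_sigma = 0, qpcr_scale = 3)
  ann1 <- generate_annotation(cfg1)
  truth1 <- simulate_occupancy(ann1)
  a1 <- simulate_qpcr(truth1, default_amplicons(ann1, 6), cfg1)
  expect_equal(a1$percent_input, rep(3, 6), tolerance = 1e-9)

  # sigma = 0.05: zero-intercept regression on truth recovers the scale
  cfg2 <- small_sim(seed = 31, qpcr_sigma = 0.05, qpcr_scale = 2)
  ann2 <- generate_annotation(cfg2)
  truth2 <- simulate_occupancy(ann2)
  amps2 <- default_amplicons(ann2, 12)
  anchors2 <- simulate_qpcr(truth2, amps2, cfg2)
  tm <- vapply(seq_len(nrow(amps2)), function(j) {
    v <- truth2$occupancy$values[[amps2$chrom[j]]]
    m <- truth2$occupancy$mask[[amps2$chrom[j]]]
    b <- (floor(amps2$start[j] / 10) + 1):ceiling(amps2$end[j] / 10)
    mean(v[b][!m[b]])
  }, numeric(1))
  slope <- sum(anchors2$percent_input * tm) / sum(tm^2)
  expect_lt(abs(slope / 2 - 1), 0.05)

  # fully unmappable amplicon is an error
  if (nrow(truth$unmappable) > 0) {
    blk <- truth$unmappable[which.max(truth$unmappable$end -
                                        truth$unmappable$start), ]
    bad <- data.frame(site = "dead", chrom = blk$chrom,
                      start = blk$start, end = blk$end)
    expect_error(simulate_qpcr(truth, bad, cfg), "unmappable")
  }
})

test_that("count tracks round-trip through emitted read intervals", {
  cfg <- small_sim(seed = 14)
  reads <- simulate_reads(simulate_occupancy(generate_annotation(cfg)))
  bed <- reads_from_counts(reads$chip, fragment_length = 150)
  rebinned <- bin_reads(bed, reads$chip$chrom_sizes, bin_size = 10,
                        fragment_length = 150)
  expect_equal(rebinned$values, reads$chip$values)
})
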