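test_that("TSS/TTS inference applies UTR defaults and strand mirroring", {
  g <- data.frame(id = c("g1", "g2", "g3"), chrom = "chr1",
                  strand = c("+", "-", "+"),
                  cds_start = 1000, cds_end = 2000,
                  utr5_len = c(NA, NA, 50), utr3_len = c(NA, NA, 100))
  out <- infer_tss_tts(g)
  expect_equal(out$tss[1], 1000 - 293)
  expect_equal(out$tts[1], 2000 + 430)
  expect_equal(out$tss[2], 2000 + 293)  # minus strand mirrored
  expect_equal(out$tts[2], 1000 - 430)
  expect_equal(out$tss[3], 950)         # annotated UTR wins
  expect_equal(out$tts[3], 2100)

  # clipping flag at chromosome bounds
  gc <- data.frame(id = "g", chrom = "chr1", strand = "+",
                   cds_start = 100, cds_end = 300,
                   utr5_len = NA, utr3_len = NA)
  out2 <- infer_tss_tts(gc, chrom_sizes = c(chr1 = 500))
  expect_equal(out2$tss, 0)
  expect_true(out2$clipped)

  gneg <- g[1, ]
  gneg$utr5_len <- -5
  expect_error(infer_tss_tts(gneg), "negative")
})

# one + strand gene whose body covers bins with values 1..20 exactly:
# track has 40 bins, body bins 11..30, 1-kb-equivalent flanks of 10 bins
body_track <- function() {
  toy_track(c(rep(0, 10), 1:20, rep(0, 10)))
}
body_gene <- function(strand = "+") {
  data.frame(id = "g1", chrom = "chrT", strand = strand,
             tss = if (strand == "+") 100 else 300,
             tts = if (strand == "+") 300 else 100)
}

test_that("metagene scales gene bodies with fractional-overlap averaging", {
  mg <- metagene(body_track(), body_gene("+"), flank = 100, n_body_bins = 10)
  expect_equal(mg$body, seq(1.5, 19.5, by = 2))
  expect_equal(mg$upstream, rep(0, 10))
  expect_equal(mg$n_genes, 1)

  # minus-strand gene over the same values is the exact reverse
  mgm <- metagene(body_track(), body_gene("-"), flank = 100, n_body_bins = 10)
  expect_equal(mgm$body, rev(mg$body))

  # constant track: flat at the constant everywhere
  const <- toy_track(rep(2.5, 40))
  mgc <- metagene(const, body_gene("+"), flank = 100, n_body_bins = 7)
  expect_true(all(abs(c(mgc$upstream, mgc$body, mgc$downstream) - 2.5) < 1e-12))

  # masked bins are excluded from body averages
  m <- rep(FALSE, 40); m[11] <- TRUE
  tr <- toy_track(c(rep(0, 10), 1:20, rep(0, 10)), mask = m)
  mgk <- metagene(tr, body_gene("+"), flank = 100, n_body_bins = 10)
  expect_equal(mgk$body[1], 2)  # bin value 1 masked, only value 2 remains
  expect_equal(mgk$body[-1], mg$body[-1])

  expect_error(metagene(body_track(), body_gene()[0, ], flank = 100), "empty")
})

test_that("heat map rows sort by body mean with deterministic ties", {
  vals <- c(rep(0, 10), rep(1, 10), rep(0, 10), rep(2, 10), rep(0, 10))
  tr <- toy_track(vals)  # 50 bins
  g <- data.frame(id = c("gA", "gB"), chrom = "chrT", strand = "+",
                  tss = c(100, 300), tts = c(200, 400))
  hm <- enrichment_heatmap(tr, g, flank = 100, n_body_bins = 5)
  expect_equal(rownames(hm), c("gB", "gA"))  # body means 2 > 1

  # row body means equal the per-gene metagene body means
  mgA <- metagene(tr, g[1, ], flank = 100, n_body_bins = 5)
  expect_equal(unname(rowMeans(hm[, 11:15])["gA"]), mean(mgA$body))

  # identical genes: id-lexicographic order, deterministic
  g2 <- data.frame(id = c("gB", "gA"), chrom = "chrT", strand = "+",
                   tss = 100, tts = 200)
  hm2 <- enrichment_heatmap(tr, g2, flank = 100, n_body_bins = 5)
  expect_equal(rownames(hm2), c("gA", "gB"))
})

test_that("GC track arithmetic", {
  expect_equal(gc_track("ATGCGC", window = 6)[3], 4 / 6)
  expect_true(all(gc_track(strrep("GC", 20), window = 5) == 1))
  alt <- gc_track(strrep("AG", 50), window = 4)
  expect_true(all(abs(alt[3:97] - 0.5) < 1e-12))
  expect_error(gc_track("ACGT", window = 0), "window")

  gb <- gc_binned(list(chrT = strrep("ACGT", 100)), bin_size = 10, window = 4)
  expect_equal(length(gb$values$chrT), 40)
  expect_true(all(abs(gb$values$chrT[2:39] - 0.5) < 0.06))
})

test_that("gene binding level averages unmasked transcript bins", {
  tr <- toy_track(c(1, 1, 3, 5, 1))
  g <- data.frame(id = "g1", chrom = "chrT", strand = "+", tss = 20, tts = 40)
  expect_equal(gene_binding_level(tr, g)$binding, 4)
  expect_equal(gene_binding_level(tr, g, external_scale = 0.5)$binding, 2)

  flat <- toy_track(rep(1, 5))
  expect_equal(gene_binding_level(flat, g, external_scale = 3)$binding, 3)

  masked <- toy_track(c(1, 1, 3, 5, 1), mask = c(F, F, T, T, F))
  expect_true(is.na(gene_binding_level(masked, g)$binding))
})

test_that("peak-TSS distances use containment-then-summit rules", {
  genes <- data.frame(id = c("g1", "g2"), chrom = "chr1",
                      tss = c(12050, 40000))
  pk <- data.frame(chrom = "chr1", start = 10000, end = 10100, summit = 10050)
  rep1 <- peak_tss_association(pk, genes, window = 5000)
  expect_equal(rep1$distances$tss_distance, 2000)
  expect_equal(rep1$fraction_within, 1)

  inside <- data.frame(chrom = "chr1", start = 12000, end = 12100,
                       summit = 12010)
  expect_equal(peak_tss_association(inside, genes)$distances$tss_distance, 0)

  far <- data.frame(chrom = "chr1", start = 90000, end = 90100, summit = 90050)
  expect_equal(peak_tss_association(far, genes, window = 5000)$fraction_within, 0)

  none <- peak_tss_association(far[0, ], genes)
  expect_true(none$flagged)
  expect_true(is.na(none$fraction_within))
})

test_that("genome fraction merges interval unions", {
  sizes <- c(chr1 = 1e5)
  tss <- data.frame(id = c("a", "b"), chrom = "chr1", tss = c(20000, 28000))
  iv <- tss_windows(tss, window = 5000, chrom_sizes = sizes)
  expect_equal(genome_fraction(iv, sizes), 0.18)

  expect_equal(genome_fraction(iv[0, ], sizes), 0)
  # duplication never double-counts
  expect_equal(genome_fraction(rbind(iv, iv, iv[2:1, ]), sizes), 0.18)
})

test_that("CGI enrichment odds ratio", {
  # 1000 TSSs at 10-kb spacing; CGIs over the first 600; peak-associated
  # set holds 187 CGI and 13 non-CGI TSSs -> p = 0.935, q = 0.60
  all_tss <- data.frame(chrom = "chr1", tss = seq_len(1000) * 1e4)
  cgi <- data.frame(chrom = "chr1", start = seq_len(600) * 1e4 - 50,
                    end = seq_len(600) * 1e4 + 50)
  peak_tss <- all_tss[c(1:187, 601:613), ]
  res <- cgi_enrichment(peak_tss, all_tss, cgi, dist = 1000)
  expect_equal(res$p, 0.935)
  expect_equal(res$q, 0.60)
  expect_equal(res$odds_ratio, (0.935 / 0.065) / (0.6 / 0.4))
  expect_equal(round(res$odds_ratio, 1), 9.6)
  expect_false(res$degenerate)

  # p = q -> OR 1
  same <- cgi_enrichment(all_tss, all_tss, cgi)
  expect_equal(same$odds_ratio, 1)

  # q = 0.5 reduces to p/(1-p)
  cgi_half <- cgi[1:500, ]
  res2 <- cgi_enrichment(all_tss[c(1:90, 501:510), ], all_tss, cgi_half)
  expect_equal(res2$odds_ratio, (0.9 / 0.1))

  deg <- cgi_enrichment(all_tss[1:10, ], all_tss, cgi)  # p = 1
  expect_true(deg$degenerate)
  empty <- cgi_enrichment(all_tss[1:10, ], all_tss, cgi[0, ])
  expect_true(empty$degenerate)
})

test_that("expression stratification uses greedy ceiling quartiles", {
  g8 <- data.frame(id = sprintf("g%02d", 1:8), expression = 8:1)
  s8 <- expression_stratify(g8)
  expect_equal(lengths(s8$quartiles), rep(2L, 4))
  expect_equal(s8$quartiles[[1]], c("g01", "g02"))

  g10 <- data.frame(id = sprintf("g%02d", 1:10), expression = 10:1)
  s10 <- expression_stratify(g10)
  expect_equal(lengths(s10$quartiles), c(3L, 3L, 2L, 2L))
  expect_equal(s10$top_decile, "g01")
  expect_equal(s10$bottom_half, sprintf("g%02d", 6:10))

  # ties broken by id -> deterministic grouping
  gt <- data.frame(id = c("b", "d", "a", "c"), expression = 1)
  st <- expression_stratify(gt)
  expect_equal(unlist(st$quartiles), c("a", "b", "c", "d"))

  gna <- rbind(g8, data.frame(id = "gNA", expression = NA))
  expect_equal(expression_stratify(gna)$n_excluded, 1)
})

test_that("gene-set overlap test matches the exact tail sum", {
  u <- sprintf("g%02d", 1:20)
  res <- geneset_overlap_test(u[1:5], u[c(1:4, 10)], u)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 4)

  # zero overlap: the full upper tail is 1
  expect_equal(geneset_overlap_test(u[1:5], u[6:10], u)$p_value, 1)
  # A = universe forces overlap = |B|
  expect_equal(geneset_overlap_test(u, u[1:7], u)$p_value, 1)
  expect_error(geneset_overlap_test(c(u[1], "zz"), u[1:2], u), "subsets")
})

test_that("track correlation is computed over jointly unmasked bins", {
  a <- toy_profile(c(1, 2, 3, 4))
  expect_equal(track_correlation(a, a)$overall, 1)
  b <- toy_profile(c(2, 4, 6, 8))
  expect_equal(track_correlation(a, b)$overall, 1)
  anti <- toy_profile(10 - c(1, 2, 3, 4))
  expect_equal(track_correlation(a, anti)$overall, -1)

  # category priority: a bin inside both centromere and tRNA is centromere
  cats <- data.frame(chrom = "chrT", start = c(0, 0), end = c(20, 30),
                     category = c("centromere", "tRNA"))
  sc <- track_correlation(a, b, cats)$scatter
  expect_equal(sc$category, c("centromere", "centromere", "tRNA", "other"))

  solo <- toy_profile(c(1, 2), mask = c(FALSE, TRUE))
  expect_error(track_correlation(solo, solo), "fewer than 2")
})
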