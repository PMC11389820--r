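test_that("splicing-event filter applies strict and inclusive bounds correctly", {
  events <- rbind(
    make_event("KEEP", delta = 0.06, fdr = 0.01, reads = 200),
    make_event("DELTA_AT_BOUND", delta = 0.05, fdr = 0.01, reads = 200),
    make_event("FDR_AT_BOUND", delta = 0.20, fdr = 0.05, reads = 200),
    make_event("READS_149", delta = 0.20, fdr = 0.01, reads = 149),
    make_event("READS_150", delta = 0.20, fdr = 0.01, reads = 150),
    make_event("NEG_DELTA", delta = -0.20, fdr = 0.01, reads = 200)
  )
  kept <- filter_se_events(events)
  expect_setequal(kept$GeneID, c("KEEP", "READS_150", "NEG_DELTA"))

  # containment and commutation of the three filters
  f_delta <- filter_se_events(events, min_delta = 0.05, max_fdr = 1, min_reads = 0)
  f_then <- filter_se_events(f_delta, min_delta = 0, max_fdr = 0.05, min_reads = 150)
  expect_setequal(f_then$GeneID, kept$GeneID)
  expect_true(all(kept$GeneID %in% events$GeneID))

  expect_error(filter_se_events(events[, setdiff(names(events), "FDR")]),
               class = "ts_schema_error")
  expect_error(filter_se_events(events[, setdiff(names(events), "FDR")]),
               "FDR")
})

test_that("direction labels follow the sign of the inclusion change", {
  ev <- rbind(make_event("A", delta = -0.2), make_event("B", delta = 0.2))
  expect_equal(direction_label(ev),
               c("skipping_after_knockdown", "inclusion_after_knockdown"))
  expect_error(direction_label(make_event("C", delta = 0)),
               class = "ts_consistency_error")
})

test_that("expressed gene set honors the two inclusivity modes", {
  tpm <- data.frame(gene_id = c("A", "B", "C"), TPM = c(10, 9.99, 200),
                    stringsAsFactors = FALSE)
  expect_setequal(expressed_gene_set(tpm, 10, inclusive = TRUE), c("A", "C"))
  expect_setequal(expressed_gene_set(tpm, 10, inclusive = FALSE), "C")
  expect_equal(expressed_gene_set(tpm[0, ]), character(0))
  expect_error(expressed_gene_set(data.frame(gene_id = "A", TPM = -1)),
               class = "ts_invalid_measurement")
})

test_that("bound-fraction enrichment matches the hypergeometric oracle", {
  # 3/1 bound among sensitive vs 1/3 among insensitive
  windows <- make_window(c(0, 10, 20, 30), c(5, 15, 25, 35),
                         gene = c("S1", "S2", "S3", "I1"))
  expressed <- c("S1", "S2", "S3", "S4", "I1", "I2", "I3", "I4")
  res <- bound_fraction_enrichment(windows, c("S1", "S2", "S3", "S4"), expressed)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_equal(res$fraction_bound_sensitive, 0.75)
  expect_equal(res$fraction_bound_insensitive, 0.25)

  # identical bound fractions: no enrichment
  win2 <- make_window(c(0, 10), c(5, 15), gene = c("S1", "I1"))
  res2 <- bound_fraction_enrichment(win2, c("S1", "S2"), c("S1", "S2", "I1", "I2"))
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p_value, 0.5)

  # complete separation: infinite OR, p equals the extreme-table point mass
  win3 <- make_window(c(0, 10), c(5, 15), gene = c("S1", "S2"))
  res3 <- bound_fraction_enrichment(win3, c("S1", "S2"), c("S1", "S2", "I1", "I2"))
  expect_equal(res3$odds_ratio, Inf)
  expect_equal(res3$p_value, oracle_fisher_p(2, 0, 0, 2), tolerance = 1e-12)
  expect_equal(res3$p_value, 1 / choose(4, 2), tolerance = 1e-12)

  # sensitive genes outside the expressed denominator are dropped with warning
  expect_warning(
    bound_fraction_enrichment(win2, c("S1", "GHOST"), c("S1", "I1")),
    "dropped"
  )
  expect_error(bound_fraction_enrichment(win2, "S1", character(0)),
               class = "ts_degenerate_data")
})

test_that("window midpoints are assigned to strand-aware features", {
  ev_plus <- make_event("G1", strand = "+")
  # features: up exon [100,200) | up intron [200,500) | cassette [500,600)
  #           | down intron [600,900) | down exon [900,1000)
  expect_equal(assign_window_feature(540, 560, ev_plus), "cassette_exon")
  expect_equal(assign_window_feature(300, 320, ev_plus), "upstream_intron")
  expect_equal(assign_window_feature(700, 720, ev_plus), "downstream_intron")
  expect_equal(assign_window_feature(110, 130, ev_plus), "upstream_exon")
  expect_equal(assign_window_feature(950, 960, ev_plus), "downstream_exon")
  expect_true(is.na(assign_window_feature(2000, 2100, ev_plus)))
  expect_true(is.na(assign_window_feature(540, 560, ev_plus, window_chrom = "chr2")))

  # minus strand: genomically-left intron is the downstream intron
  ev_minus <- make_event("G1", strand = "-")
  expect_equal(assign_window_feature(300, 320, ev_minus), "downstream_intron")
  expect_equal(assign_window_feature(700, 720, ev_minus), "upstream_intron")
  expect_equal(assign_window_feature(110, 130, ev_minus), "downstream_exon")

  # a window straddling a boundary follows its midpoint
  expect_equal(assign_window_feature(480, 540, ev_plus), "cassette_exon")
  expect_equal(assign_window_feature(460, 520, ev_plus), "upstream_intron")
})

test_that("positional map takes the median window per feature", {
  ev <- make_event("G1", delta = -0.3)
  # three windows on the downstream intron: median midpoint wins
  wins <- make_window(c(610, 700, 880), c(630, 720, 898))
  pm <- positional_map(wins, ev)
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$feature, "downstream_intron")
  expect_equal(pm$midpoint, 710)
  expect_equal(pm$delta_psi, -0.3)

  # even count: the lower-middle window (2nd of 4 after sorting by start)
  wins4 <- make_window(c(610, 640, 700, 880), c(630, 660, 720, 898))
  pm4 <- positional_map(wins4, ev)
  expect_equal(pm4$midpoint, 650)

  # one window: its own midpoint; at most one point per (event, feature)
  wins1 <- make_window(c(610, 205), c(630, 215))
  pm1 <- positional_map(wins1, ev)
  expect_equal(nrow(pm1), 2L)
  expect_equal(anyDuplicated(pm1[, c("event_id", "feature")]), 0L)

  # windows of other genes are ignored
  pm_other <- positional_map(make_window(610, 630, gene = "OTHER"), ev)
  expect_equal(nrow(pm_other), 0L)
})

test_that("transcript positions mirror correctly between strands", {
  # same genomic window against a plus and a minus event: upstream offsets
  # land at the same transcript distance
  ev_plus <- make_event("G1", strand = "+")
  ev_minus <- make_event("G1", strand = "-")
  # 180 nt transcript-upstream of the cassette start on the plus strand
  pm_p <- positional_map(make_window(310, 330, gene = "G1"), ev_plus)
  expect_equal(pm_p$transcript_position, 320 - 500)
  # mirrored position on the minus strand: genomically right of the cassette
  pm_m <- positional_map(make_window(770, 790, gene = "G1"), ev_minus)
  expect_equal(pm_m$feature, "upstream_intron")
  expect_equal(pm_m$transcript_position, 600 - 780)
  expect_equal(pm_m$transcript_position, pm_p$transcript_position)
})

test_that("flanking-intron binding rates are compared by plain chi-squared", {
  # build two exon sets with planted flanking binding rates 40% and 10%
  set_a <- do.call(rbind, lapply(1:100, function(i) {
    ev <- make_event(sprintf("A%03d", i), chrom = sprintf("cA%03d", i))
    ev
  }))
  set_b <- do.call(rbind, lapply(1:100, function(i) {
    make_event(sprintf("B%03d", i), chrom = sprintf("cB%03d", i))
  }))
  wins <- rbind(
    make_window(300, 320, gene = "x", chrom = sprintf("cA%03d", 1:40)),
    make_window(300, 320, gene = "x", chrom = sprintf("cB%03d", 1:10))
  )
  res <- flanking_intron_binding_test(wins, set_a, set_b)
  expect_equal(res$percent_a, 40)
  expect_equal(res$percent_b, 10)
  # Pearson statistic computed by hand from expected counts (no Yates):
  # cells 40/60 vs 10/90, margins 50/150, N = 200 -> X^2 = 24
  expect_equal(res$chi2, 24, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(24, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical rates: statistic 0, p 1
  res0 <- flanking_intron_binding_test(wins[c(1:10, 41:50), ],
                                       set_a[1:50, ], set_b[1:50, ])
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)

  expect_error(flanking_intron_binding_test(wins, set_a[0, ], set_b),
               class = "ts_degenerate_data")
})
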