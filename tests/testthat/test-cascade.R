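test_that("one-tailed pooled t-test matches its definition and flags degeneracy", {
  # identical groups sit exactly on the null median
  res <- one_tailed_two_sample_t(c(0.3, 0.4), c(0.3, 0.4), "greater")
  expect_equal(res$p_value, 0.5)
  expect_equal(res$statistic, 0)

  # frozen from the numerical-integration oracle (df = 4)
  res <- one_tailed_two_sample_t(c(0.4, 0.42, 0.38), c(0, 0.01, -0.01), "greater")
  expect_equal(res$df, 4)
  expect_equal(res$p_value,
               oracle_t_p(c(0.4, 0.42, 0.38), c(0, 0.01, -0.01)),
               tolerance = 1e-9)

  expect_error(one_tailed_two_sample_t(c(0, 0, 0), c(0, 0, 0)),
               class = "ts_degenerate_data")
  expect_error(one_tailed_two_sample_t(0.4, c(0.1, 0.2)),
               class = "ts_degenerate_data")

  # the two directions are complementary
  g <- one_tailed_two_sample_t(c(1, 2, 3), c(2, 3, 4), "greater")$p_value
  l <- one_tailed_two_sample_t(c(1, 2, 3), c(2, 3, 4), "less")$p_value
  expect_equal(g + l, 1)
})

test_that("call_round tests candidates against plate-matched NC replicates", {
  # strong planted effect: all constructs pass; nulls do not
  truth <- screen_truth(c(HIT1 = 0.3, HIT2 = 0.3, NULL1 = 0), "30D")
  cfg <- simulation_config(noise_cv = 0.02, seed = 5)
  calls <- call_round(estimate_psi_table(simulate_screen(truth, cfg)))
  expect_setequal(calls$construct_id[calls$pass], c("HIT1", "HIT2"))
  expect_true(all(calls$p_value[calls$construct_id != "NULL1"] < 1e-3))

  # empty candidate set -> empty pass set, correct shape
  nc_only <- estimate_psi_table(simulate_screen(truth, cfg))
  empty <- call_round(nc_only[nc_only$role != "candidate", ])
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("construct_id", "reporter_id", "plate_id", "mean_psi",
                        "statistic", "p_value", "pass", "note"))

  # degenerate constructs (zero variance in both groups) are indeterminate,
  # never hits
  rec <- records_from_ratios(c(0.3, 0.3, 0.3), c(0.5, 0.5, 0.5))
  calls <- call_round(estimate_psi_table(rec))
  expect_false(calls$pass)
  expect_true(is.na(calls$p_value))
  expect_match(calls$note, "indeterminate")
})

test_that("pass sets are monotone in alpha", {
  truth <- screen_truth(stats::setNames(runif(40, 0, 0.25), sprintf("C%02d", 1:40)),
                        "30D")
  psi <- estimate_psi_table(simulate_screen(truth, simulation_config(seed = 9)))
  passes <- lapply(c(0.01, 0.05, 0.1, 0.2), function(a) {
    calls <- call_round(psi, alpha = a)
    calls$construct_id[calls$pass]
  })
  for (i in seq_len(length(passes) - 1L)) {
    expect_true(all(passes[[i]] %in% passes[[i + 1L]]))
  }
})

test_that("gel validation applies the band-ratio statistic and Bonferroni gate", {
  lanes <- data.frame(
    construct_id = c("A", "A", rep("CTRL", 4)),
    replicate_index = c(1, 2, 1:4),
    inclusion_intensity = c(80, 79, 20, 21, 19, 20),
    skipping_intensity = c(20, 21, 80, 79, 81, 80),
    stringsAsFactors = FALSE
  )
  res <- gel_validation(lanes, "CTRL", family_size = 50)
  expect_equal(res$alpha_bonferroni, 0.05 / 50)
  expect_equal(res$p_value,
               oracle_t_p(c(0.80, 0.79), c(0.20, 0.21, 0.19, 0.20)),
               tolerance = 1e-9)
  expect_true(res$pass)

  # candidate at the control mean never passes
  lanes_null <- lanes
  lanes_null$inclusion_intensity[1:2] <- c(20, 20)
  lanes_null$skipping_intensity[1:2] <- c(80, 80)
  expect_false(gel_validation(lanes_null, "CTRL", family_size = 50)$pass)

  # Bonferroni arithmetic: the same evidence passes at family 2 only if
  # p < alpha / 2
  res2 <- gel_validation(lanes, "CTRL", family_size = 2)
  expect_equal(res2$pass, res2$p_value < 0.025)

  # zero-intensity lanes are dropped with a warning; a construct left with
  # one lane is indeterminate
  lanes_zero <- lanes
  lanes_zero$inclusion_intensity[1] <- 0
  lanes_zero$skipping_intensity[1] <- 0
  expect_warning(res3 <- gel_validation(lanes_zero, "CTRL", family_size = 2),
                 "zero total intensity")
  expect_false(res3$pass)
  expect_match(res3$note, "fewer than 2")
})

test_that("cross-reporter retest promotes only significant exclusive hits", {
  cats <- c(A = "30D_only", B = "30D_only", C = "both")
  retest <- data.frame(construct_id = c("A", "B"), p_value = c(0.01, 0.40),
                       stringsAsFactors = FALSE)
  upd <- cross_reporter_retest(cats, retest)
  expect_equal(unname(upd$categories["A"]), "both")
  expect_equal(unname(upd$categories["B"]), "30D_only")
  expect_equal(unname(upd$categories["C"]), "both")

  # missing retest data: skipped with a warning, category unchanged
  expect_warning(
    upd2 <- cross_reporter_retest(c(Z = "30U_only"),
                                  data.frame(construct_id = "A", p_value = 0.01)),
    "skipped"
  )
  expect_equal(unname(upd2$categories["Z"]), "30U_only")

  # empty exclusive set -> no changes
  upd3 <- cross_reporter_retest(c(C = "both"), retest)
  expect_equal(upd3$categories, c(C = "both"))
})

test_that("the cascade recovers a planted design through the serial gates", {
  design <- planted_design(10, 5, 5, 0, delta_psi = 0.3)
  res <- run_synthetic_screen(design, simulation_config(noise_cv = 0.02, seed = 7))
  hc <- res$cascade$hit_calls

  # pre-retest reporter-wise hit sets equal the planted sets exactly:
  # every planted effector clears round1 -> round2 -> gel on its planted
  # reporter(s); nothing clears the serial gates falsely
  d_hits <- hc$construct_id[!is.na(hc$p_gel_30D) & hc$gel_bonferroni_pass_30D]
  u_hits <- hc$construct_id[!is.na(hc$p_gel_30U) & hc$gel_bonferroni_pass_30U]
  expect_setequal(d_hits,
                  design$construct_id[design$planted_class %in% c("30D_only", "both")])
  expect_setequal(u_hits,
                  design$construct_id[design$planted_class %in% c("30U_only", "both")])

  # categories are disjoint and partition the hit set
  cats <- hc$category
  expect_true(all(cats %in% c("30D_only", "30U_only", "both", "non_hit")))
  expect_equal(sum(res$cascade$counts), sum(cats != "non_hit"))

  # every final hit passed all mandatory gates on at least one reporter
  hits <- hc[hc$category != "non_hit", ]
  expect_true(all(hits$gel_bonferroni_pass_30D | hits$gel_bonferroni_pass_30U))
})

test_that("run_cascade rejects stage tables that skip earlier gates", {
  mk <- function(ids, pass) {
    data.frame(construct_id = ids, p_value = rep(0.01, length(ids)),
               pass = pass, stringsAsFactors = FALSE)
  }
  round1 <- list("30D" = mk(c("A", "B"), c(TRUE, FALSE)),
                 "30U" = mk(c("A", "B"), c(FALSE, FALSE)))
  bad_round2 <- list("30D" = mk(c("A", "B"), TRUE),   # B never passed round 1
                     "30U" = mk(character(0), logical(0)))
  gel <- list("30D" = mk("A", TRUE), "30U" = mk(character(0), logical(0)))
  expect_error(run_cascade(round1, bad_round2, gel),
               class = "ts_consistency_error")

  good_round2 <- list("30D" = mk("A", TRUE), "30U" = mk(character(0), logical(0)))
  res <- run_cascade(round1, good_round2, gel)
  expect_equal(unname(res$counts), c(1, 0, 0))
  expect_equal(res$hit_calls$category[res$hit_calls$construct_id == "A"],
               "30D_only")
})

test_that("detection frequency is non-decreasing in planted effect size", {
  deltas <- c(0, 0.05, 0.15, 0.3)
  freq <- vapply(deltas, function(d) {
    hits <- 0L
    for (s in 1:3) {
      truth <- screen_truth(stats::setNames(rep(d, 15), sprintf("C%02d", 1:15)),
                            "30D")
      cfg <- simulation_config(noise_cv = 0.05, seed = 100 + s)
      calls <- call_round(estimate_psi_table(simulate_screen(truth, cfg)))
      hits <- hits + sum(calls$pass)
    }
    hits / (15 * 3)
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
  expect_lt(freq[1], 0.2)   # null near alpha
  expect_equal(freq[4], 1)  # saturated power at delta 0.3
})
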