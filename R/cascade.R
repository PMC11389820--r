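#' One-tailed pooled-variance two-sample t-test
#'
#' The screen's elementary significance test: an independent two-sample
#' t-test with pooled (equal) variance, one-tailed in the stated direction.
#' `direction = "greater"` tests whether the candidate values exceed the
#' control values (the inclusion screen); `"less"` is used for skipping
#' screens.
#'
#' @param candidate_values,control_values Numeric vectors, each of length
#'   >= 2.
#' @param direction `"greater"` or `"less"`.
#' @return List with `statistic`, `p_value` and `df`.
#' @export
#' @examples
#' one_tailed_two_sample_t(c(0.4, 0.42, 0.38), c(0, 0.01, -0.01))
one_tailed_two_sample_t <- function(candidate_values, control_values,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(candidate_values) < 2L || length(control_values) < 2L) {
    stop_degenerate_data("both groups need at least 2 values")
  }
  if (stats::var(candidate_values) + stats::var(control_values) <= 0) {
    stop_degenerate_data("zero pooled variance: t-test undefined for these values")
  }
  fit <- stats::t.test(candidate_values, control_values,
                       alternative = direction, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Call one round of the screen against plate-matched negative controls
#'
#' For every candidate construct, tests its raw (unclipped) replicate psi
#' values against the raw psi values of the negative-control wells on the
#' same plate and reporter, by one-tailed pooled-variance t-test. Unclipped
#' values are used so that under the null the test keeps its nominal size;
#' clipping negative estimates to zero before testing would truncate the
#' null distribution. Constructs with degenerate replicate variance are
#' reported as indeterminate (`NA` p, no pass), never as hits.
#'
#' @param psi_table Output of [estimate_psi_table()]; must include the
#'   negative-control rows (`role == "negative_control"`).
#' @param alpha Per-test significance level (default 0.05).
#' @param direction Test direction, `"greater"` for inclusion screens.
#' @return Data frame with one row per candidate: `construct_id`,
#'   `reporter_id`, `plate_id`, `mean_psi`, `statistic`, `p_value`, `pass`,
#'   `note`.
#' @export
call_round <- function(psi_table, alpha = 0.05,
                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid_config("alpha must lie in (0, 1)")
  }
  require_columns(psi_table, c("construct_id", "reporter_id", "plate_id",
                               "role", "mean_psi", "psi_raw_replicates"),
                  "psi table")
  cand <- psi_table[psi_table$role == "candidate", , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(construct_id = character(), reporter_id = character(),
                      plate_id = character(), mean_psi = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      pass = logical(), note = character(),
                      stringsAsFactors = FALSE))
  }
  nc_key <- paste(psi_table$plate_id, psi_table$reporter_id, sep = "\r")
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    key <- paste(cand$plate_id[i], cand$reporter_id[i], sep = "\r")
    nc_rows <- which(psi_table$role == "negative_control" & nc_key == key)
    if (length(nc_rows) == 0L) {
      stop_degenerate_data(sprintf(
        "no plate-matched negative control for plate '%s'", cand$plate_id[i]
      ))
    }
    nc_psi <- unlist(psi_table$psi_raw_replicates[nc_rows])
    cand_psi <- cand$psi_raw_replicates[[i]]
    res <- tryCatch(
      one_tailed_two_sample_t(cand_psi, nc_psi, direction),
      ts_degenerate_data = function(e) e
    )
    if (inherits(res, "condition")) {
      data.frame(construct_id = cand$construct_id[i],
                 reporter_id = cand$reporter_id[i],
                 plate_id = cand$plate_id[i],
                 mean_psi = cand$mean_psi[i],
                 statistic = NA_real_, p_value = NA_real_, pass = FALSE,
                 note = "indeterminate: degenerate replicate variance",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(construct_id = cand$construct_id[i],
                 reporter_id = cand$reporter_id[i],
                 plate_id = cand$plate_id[i],
                 mean_psi = cand$mean_psi[i],
                 statistic = res$statistic, p_value = res$p_value,
                 pass = res$p_value < alpha, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gel-based RNA-level validation with a Bonferroni gate
#'
#' Quantifies each lane as `inclusion / (inclusion + skipping)` (the bounded
#' band-intensity statistic), pools all control lanes, and tests each
#' construct's lane ratios against the control pool by one-tailed
#' pooled-variance t-test. A construct passes if its unadjusted p-value is
#' below `alpha / family_size` (Bonferroni over the validation family).
#' Lanes with zero total intensity are unquantifiable and dropped with a
#' warning; a construct left with fewer than two lanes is indeterminate.
#'
#' @param lanes Gel-lane data frame with columns `construct_id`,
#'   `replicate_index`, `inclusion_intensity`, `skipping_intensity`.
#' @param control_construct_ids Ids of the control lanes (pooled).
#' @param family_size Bonferroni family size; defaults to the number of
#'   non-control constructs on the gel.
#' @param alpha Family-wise level before correction (default 0.05).
#' @param direction Test direction (default `"greater"`).
#' @return Data frame per construct: `construct_id`, `n_lanes`, `mean_ratio`,
#'   `p_value`, `alpha_bonferroni`, `pass`, `note`.
#' @export
gel_validation <- function(lanes, control_construct_ids,
                           family_size = NULL, alpha = 0.05,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  require_columns(lanes, c("construct_id", "replicate_index",
                           "inclusion_intensity", "skipping_intensity"),
                  "gel lane table")
  total <- lanes$inclusion_intensity + lanes$skipping_intensity
  if (any(total <= 0)) {
    warning(sprintf("excluding %d lane(s) with zero total intensity",
                    sum(total <= 0)))
    lanes <- lanes[total > 0, , drop = FALSE]
  }
  lanes$.ratio <- lanes$inclusion_intensity /
    (lanes$inclusion_intensity + lanes$skipping_intensity)
  is_ctrl <- lanes$construct_id %in% control_construct_ids
  ctrl <- lanes$.ratio[is_ctrl]
  if (sum(is_ctrl) < 2L) stop_degenerate_data("need at least 2 control lanes")
  test_ids <- unique(lanes$construct_id[!is_ctrl])
  if (is.null(family_size)) family_size <- length(test_ids)
  if (!is_count(family_size, min = 1L)) {
    stop_invalid_config("family_size must be a positive integer")
  }
  cutoff <- alpha / family_size
  rows <- lapply(test_ids, function(id) {
    r <- lanes$.ratio[lanes$construct_id == id]
    if (length(r) < 2L) {
      return(data.frame(construct_id = id, n_lanes = length(r),
                        mean_ratio = mean(r), p_value = NA_real_,
                        alpha_bonferroni = cutoff, pass = FALSE,
                        note = "indeterminate: fewer than 2 quantifiable lanes",
                        stringsAsFactors = FALSE))
    }
    res <- tryCatch(one_tailed_two_sample_t(r, ctrl, direction),
                    ts_degenerate_data = function(e) e)
    if (inherits(res, "condition")) {
      data.frame(construct_id = id, n_lanes = length(r), mean_ratio = mean(r),
                 p_value = NA_real_, alpha_bonferroni = cutoff, pass = FALSE,
                 note = "indeterminate: degenerate variance",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(construct_id = id, n_lanes = length(r), mean_ratio = mean(r),
                 p_value = res$p_value, alpha_bonferroni = cutoff,
                 pass = res$p_value < cutoff, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-reporter retest of single-reporter hits
#'
#' Hits that passed the full cascade for exactly one reporter are measured
#' one more time with the opposite reporter, in case they were missed by the
#' initial screen of that reporter. An exclusive hit whose retest p-value is
#' below `alpha` is promoted to the `both` category; otherwise its category
#' is unchanged. Exclusive hits with no opposite-reporter measurements are
#' skipped with a warning.
#'
#' @param categories Named character vector (names = construct ids, values in
#'   `"30D_only"`, `"30U_only"`, `"both"`).
#' @param retest_calls Data frame from [call_round()] run on the
#'   opposite-reporter retest measurements (columns `construct_id`,
#'   `p_value`).
#' @param alpha Significance level (default 0.05).
#' @return List with `categories` (updated vector) and `retest_p` (named
#'   vector of retest p-values for the constructs examined).
#' @export
cross_reporter_retest <- function(categories, retest_calls, alpha = 0.05) {
  exclusive <- names(categories)[categories %in% c("30D_only", "30U_only")]
  retest_p <- stats::setNames(rep(NA_real_, length(exclusive)), exclusive)
  if (length(exclusive) == 0L) {
    return(list(categories = categories, retest_p = retest_p))
  }
  require_columns(retest_calls, c("construct_id", "p_value"), "retest call table")
  for (id in exclusive) {
    hit_row <- which(retest_calls$construct_id == id)
    if (length(hit_row) == 0L) {
      warning(sprintf("no opposite-reporter retest data for '%s'; skipped", id))
      next
    }
    p <- retest_calls$p_value[hit_row[1L]]
    retest_p[id] <- p
    if (!is.na(p) && p < alpha) categories[id] <- "both"
  }
  list(categories = categories, retest_p = retest_p)
}

#' Run the full multi-round hit-calling cascade
#'
#' Gate order per reporter: round-1 t-test, round-2 t-test on the round-1
#' passers, gel validation with a Bonferroni gate; a construct is a hit for a
#' reporter only if it passes all three. Hits exclusive to one reporter are
#' then retested with the opposite reporter and promoted to `both` on a
#' significant retest. The final categories (`30D_only`, `30U_only`, `both`)
#' are disjoint and partition the hit set.
#'
#' @param round1,round2 Named lists with components `"30D"` and `"30U"`, each
#'   a [call_round()]-style data frame (columns `construct_id`, `p_value`,
#'   `pass`). `round2` tables must only contain round-1 passers.
#' @param gel Named list (`"30D"`, `"30U"`) of [gel_validation()]-style data
#'   frames (columns `construct_id`, `p_value`, `pass`), covering the round-2
#'   passers.
#' @param retest Named list (`"30D"`, `"30U"`) of retest call tables measured
#'   on that reporter, used to re-examine hits exclusive to the *other*
#'   reporter; entries may be `NULL` when there is nothing to retest.
#' @param alpha Retest significance level (default 0.05).
#' @return List with `hit_calls` (per-construct trajectory: per-stage
#'   p-values, pass flags and final `category`) and `counts` (named numeric:
#'   `30D_only`, `30U_only`, `both`).
#' @export
run_cascade <- function(round1, round2, gel, retest = list(), alpha = 0.05) {
  reporters <- c("30D", "30U")
  for (rp in reporters) {
    if (is.null(round1[[rp]]) || is.null(round2[[rp]]) || is.null(gel[[rp]])) {
      stop_invalid_config(sprintf("round1, round2 and gel tables required for reporter %s", rp))
    }
    late <- setdiff(round2[[rp]]$construct_id,
                    round1[[rp]]$construct_id[round1[[rp]]$pass])
    if (length(late) > 0L) {
      stop_consistency(sprintf(
        "constructs in round 2 (%s) never passed round 1: %s",
        rp, paste(late, collapse = ", ")
      ))
    }
    late_gel <- setdiff(gel[[rp]]$construct_id,
                        c(round2[[rp]]$construct_id[round2[[rp]]$pass],
                          "GEL_CONTROL"))
    if (length(late_gel) > 0L) {
      stop_consistency(sprintf(
        "constructs on the %s gel never passed round 2: %s",
        rp, paste(late_gel, collapse = ", ")
      ))
    }
  }

  stage_p <- function(tab, ids) tab$p_value[match(ids, tab$construct_id)]
  stage_pass <- function(tab, ids) {
    out <- tab$pass[match(ids, tab$construct_id)]
    out[is.na(out)] <- FALSE
    out
  }

  all_ids <- sort(unique(c(round1[["30D"]]$construct_id,
                           round1[["30U"]]$construct_id)))
  per_rep <- lapply(reporters, function(rp) {
    hit <- stage_pass(round1[[rp]], all_ids) &
      stage_pass(round2[[rp]], all_ids) &
      stage_pass(gel[[rp]], all_ids)
    data.frame(
      construct_id = all_ids,
      p_round1 = stage_p(round1[[rp]], all_ids),
      p_round2 = stage_p(round2[[rp]], all_ids),
      p_gel = stage_p(gel[[rp]], all_ids),
      gel_pass = stage_pass(gel[[rp]], all_ids),
      hit = hit,
      stringsAsFactors = FALSE
    )
  })
  names(per_rep) <- reporters

  hit_d <- per_rep[["30D"]]$hit
  hit_u <- per_rep[["30U"]]$hit
  category <- rep("non_hit", length(all_ids))
  category[hit_d & !hit_u] <- "30D_only"
  category[!hit_d & hit_u] <- "30U_only"
  category[hit_d & hit_u] <- "both"
  names(category) <- all_ids

  retest_p <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  # 30D-exclusive hits are retested on the 30U reporter and vice versa
  for (rp in reporters) {
    other <- setdiff(reporters, rp)
    excl <- names(category)[category == paste0(other, "_only")]
    if (length(excl) == 0L || is.null(retest[[rp]])) next
    sub <- category[excl]
    upd <- cross_reporter_retest(sub, retest[[rp]], alpha = alpha)
    category[excl] <- upd$categories
    retest_p[names(upd$retest_p)] <- upd$retest_p
  }

  hit_calls <- data.frame(
    construct_id = all_ids,
    p_round1_30D = per_rep[["30D"]]$p_round1,
    p_round1_30U = per_rep[["30U"]]$p_round1,
    p_round2_30D = per_rep[["30D"]]$p_round2,
    p_round2_30U = per_rep[["30U"]]$p_round2,
    p_gel_30D = per_rep[["30D"]]$p_gel,
    p_gel_30U = per_rep[["30U"]]$p_gel,
    gel_bonferroni_pass_30D = per_rep[["30D"]]$gel_pass,
    gel_bonferroni_pass_30U = per_rep[["30U"]]$gel_pass,
    cross_retest_p = unname(retest_p),
    category = unname(category),
    stringsAsFactors = FALSE
  )
  counts <- c("30D_only" = sum(category == "30D_only"),
              "30U_only" = sum(category == "30U_only"),
              "both" = sum(category == "both"))
  list(hit_calls = hit_calls, counts = counts)
}
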