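#' Filter a skipped-exon event table to significant events
#'
#' Applies the differential-splicing significance thresholds: absolute
#' inclusion-level difference strictly greater than `min_delta`, FDR strictly
#' below `max_fdr`, and a total of at least `min_reads` junction reads summed
#' over all samples and conditions (inclusive bound).
#'
#' @param events Skipped-exon data frame from [read_se_table()] or
#'   [simulate_integration_tables()]; needs columns `IncLevelDifference`,
#'   `FDR` and either `total_reads` or the four IJC/SJC count columns.
#' @param min_delta Minimum |inclusion-level difference| (strict; default 0.05).
#' @param max_fdr Maximum FDR (strict; default 0.05).
#' @param min_reads Minimum total junction reads (inclusive; default 150).
#' @return The subset of `events` passing all three thresholds, with a
#'   `total_reads` column added when absent.
#' @export
filter_se_events <- function(events, min_delta = 0.05, max_fdr = 0.05,
                             min_reads = 150) {
  require_columns(events, c("IncLevelDifference", "FDR"), "skipped-exon table")
  if (!("total_reads" %in% names(events))) {
    count_cols <- c("IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2")
    require_columns(events, count_cols, "skipped-exon table")
    sum_counts <- function(s) {
      vapply(strsplit(as.character(s), ","),
             function(x) sum(as.numeric(x), na.rm = TRUE), numeric(1))
    }
    events$total_reads <- Reduce(`+`, lapply(events[count_cols], sum_counts))
  }
  keep <- abs(events$IncLevelDifference) > min_delta &
    events$FDR < max_fdr &
    events$total_reads >= min_reads
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction of a significant splicing change
#'
#' Labels each filtered event by the sign of its inclusion-level difference
#' (knockdown minus control): negative means the exon is skipped more after
#' knockdown, positive means it is included more. A zero difference cannot
#' pass the strict filter, so encountering one indicates the table was not
#' filtered and raises a consistency error.
#'
#' @param events Filtered skipped-exon data frame.
#' @return Character vector, `"skipping_after_knockdown"` or
#'   `"inclusion_after_knockdown"` per event.
#' @export
direction_label <- function(events) {
  require_columns(events, "IncLevelDifference", "skipped-exon table")
  d <- events$IncLevelDifference
  if (any(d == 0)) {
    stop_consistency("event with IncLevelDifference == 0: table was not filtered")
  }
  ifelse(d < 0, "skipping_after_knockdown", "inclusion_after_knockdown")
}

#' Expressed gene set from a TPM table
#'
#' @param tpm Data frame with columns `gene_id` and `TPM` (>= 0).
#' @param threshold Expression threshold (default 10).
#' @param inclusive If `TRUE` (default), keep genes with `TPM >= threshold`
#'   (the CLIP size-matched-input denominator); if `FALSE`, require
#'   `TPM > threshold` (the differential-expression prefilter).
#' @return Character vector of gene ids.
#' @export
expressed_gene_set <- function(tpm, threshold = 10, inclusive = TRUE) {
  require_columns(tpm, c("gene_id", "TPM"), "TPM table")
  if (any(!is.finite(tpm$TPM)) || any(tpm$TPM < 0)) {
    stop_invalid_measurement("TPM values must be finite and >= 0")
  }
  keep <- if (inclusive) tpm$TPM >= threshold else tpm$TPM > threshold
  unique(tpm$gene_id[keep])
}

#' One-tailed Fisher exact p-value for a 2x2 table
#'
#' Tail probability of the hypergeometric distribution of the top-left cell
#' `a` given the table margins, in the direction of larger `a` (more overlap
#' than expected). Identical to `fisher.test(alternative = "greater")` for a
#' 2x2 table, computed directly so it vectorizes.
#'
#' @param a,b,c,d Cell counts: `a` = bound & sensitive, `b` = unbound &
#'   sensitive, `c` = bound & insensitive, `d` = unbound & insensitive.
#' @return One-tailed p-value(s).
#' @export
fisher_one_tailed <- function(a, b, c, d) {
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Binding enrichment in knockdown-sensitive genes
#'
#' Classifies every expressed gene as bound (at least one enriched window
#' carries its gene id) or unbound, and as knockdown-sensitive or not, and
#' tests whether sensitive genes are bound more often than insensitive genes
#' by one-tailed Fisher exact test. The odds ratio is the sample
#' cross-product ratio (infinite when `b` or `c` is zero with a nonzero
#' numerator).
#'
#' @param windows Enriched-window data frame with a `gene_id` column.
#' @param kd_sensitive_genes Character vector of genes with significant
#'   knockdown-sensitive skipped-exon events. Genes not in
#'   `expressed_genes` are dropped with a warning.
#' @param expressed_genes Character vector: the expressed-gene denominator.
#' @return List: `fraction_bound_sensitive`, `fraction_bound_insensitive`,
#'   `odds_ratio`, `p_value`, and the 2x2 `table` (bound x sensitive).
#' @export
bound_fraction_enrichment <- function(windows, kd_sensitive_genes,
                                      expressed_genes) {
  require_columns(windows, "gene_id", "enriched-window table")
  expressed_genes <- unique(expressed_genes)
  if (length(expressed_genes) == 0L) {
    stop_degenerate_data("expressed gene set is empty: denominator undefined")
  }
  kd_sensitive_genes <- unique(kd_sensitive_genes)
  outside <- setdiff(kd_sensitive_genes, expressed_genes)
  if (length(outside) > 0L) {
    warning(sprintf("%d sensitive gene(s) not in the expressed set; dropped",
                    length(outside)))
    kd_sensitive_genes <- intersect(kd_sensitive_genes, expressed_genes)
  }
  bound_genes <- intersect(unique(windows$gene_id), expressed_genes)
  sens <- expressed_genes %in% kd_sensitive_genes
  bnd <- expressed_genes %in% bound_genes
  a <- sum(bnd & sens); b <- sum(!bnd & sens)
  c_ <- sum(bnd & !sens); d <- sum(!bnd & !sens)
  or <- if (b == 0L || c_ == 0L) {
    if (a * d > 0L) Inf else NaN
  } else {
    (a * d) / (b * c_)
  }
  list(
    fraction_bound_sensitive = if (a + b > 0L) a / (a + b) else NaN,
    fraction_bound_insensitive = if (c_ + d > 0L) c_ / (c_ + d) else NaN,
    odds_ratio = or,
    p_value = fisher_one_tailed(a, b, c_, d),
    table = matrix(c(a, b, c_, d), nrow = 2L,
                   dimnames = list(c("bound", "unbound"),
                                   c("sensitive", "insensitive")))
  )
}

event_feature_table <- function(event) {
  minus <- event$strand == "-"
  left_exon <- c(min(event$upstreamES, event$downstreamES),
                 min(event$upstreamEE, event$downstreamEE))
  right_exon <- c(max(event$upstreamES, event$downstreamES),
                  max(event$upstreamEE, event$downstreamEE))
  starts <- c(left_exon[1L], left_exon[2L], event$exonStart_0base,
              event$exonEnd, right_exon[1L])
  ends <- c(left_exon[2L], event$exonStart_0base, event$exonEnd,
            right_exon[1L], right_exon[2L])
  feat_plus <- c("upstream_exon", "upstream_intron", "cassette_exon",
                 "downstream_intron", "downstream_exon")
  feature <- if (minus) rev(feat_plus) else feat_plus
  data.frame(feature = feature, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Assign an enriched window to a feature of a skipped-exon event
#'
#' Places the window's genomic midpoint into exactly one of the event's five
#' transcript-oriented features (upstream exon, upstream intron, cassette
#' exon, downstream intron, downstream exon) or none. On the minus strand
#' the genomically-left intron is the transcript's downstream intron.
#' Windows straddling a boundary follow their midpoint.
#'
#' @param window_start,window_end 0-based half-open window coordinates.
#' @param event One row of a skipped-exon table (rMATS-dialect columns, with
#'   `upstreamES`/`upstreamEE` etc. transcript-oriented).
#' @param window_chrom Optional chromosome of the window; if given and
#'   different from `event$chr`, returns `NA`.
#' @return Feature label, or `NA_character_` if the midpoint falls in no
#'   feature (or chromosomes differ).
#' @export
assign_window_feature <- function(window_start, window_end, event,
                                  window_chrom = NULL) {
  if (!is.null(window_chrom) && window_chrom != event$chr) {
    return(NA_character_)
  }
  mid <- (window_start + window_end) / 2
  feats <- event_feature_table(event)
  hit <- which(mid >= feats$start & mid < feats$end)
  if (length(hit) == 0L) NA_character_ else feats$feature[hit[1L]]
}

#' Position-dependent binding map of significant splicing events
#'
#' For every (event, feature) pair with at least one assigned enriched
#' window, emits one point: the midpoint of the median window (windows
#' sorted by start then end; for an even count the lower-middle element,
#' index `floor((n - 1) / 2)` 0-based, is taken) paired with the event's
#' inclusion-level difference. Positions are transcript-oriented offsets of
#' the window midpoint from the cassette exon's transcript start (5' end of
#' the exon), so that upstream binding is negative on either strand.
#'
#' @param windows Enriched-window data frame (`chrom`, `start`, `end`,
#'   `gene_id`).
#' @param events Filtered skipped-exon data frame; must carry `GeneID`.
#' @return Data frame with columns `event_id`, `feature`,
#'   `transcript_position`, `midpoint`, `delta_psi`.
#' @export
positional_map <- function(windows, events) {
  require_columns(windows, c("chrom", "start", "end", "gene_id"),
                  "enriched-window table")
  require_columns(events, c("GeneID", "chr", "strand", "exonStart_0base",
                            "exonEnd", "upstreamES", "upstreamEE",
                            "downstreamES", "downstreamEE",
                            "IncLevelDifference"), "skipped-exon table")
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    w <- windows[windows$gene_id == ev$GeneID & windows$chrom == ev$chr, ,
                 drop = FALSE]
    if (nrow(w) == 0L) next
    w$feature <- vapply(seq_len(nrow(w)), function(j) {
      assign_window_feature(w$start[j], w$end[j], ev)
    }, character(1))
    w <- w[!is.na(w$feature), , drop = FALSE]
    if (nrow(w) == 0L) next
    for (feat in unique(w$feature)) {
      wf <- w[w$feature == feat, , drop = FALSE]
      wf <- wf[order(wf$start, wf$end), , drop = FALSE]
      med <- wf[floor((nrow(wf) - 1) / 2) + 1L, ]
      mid <- (med$start + med$end) / 2
      pos <- if (ev$strand == "+") mid - ev$exonStart_0base
             else ev$exonEnd - mid
      out[[length(out) + 1L]] <- data.frame(
        event_id = sprintf("%s:%d-%d", ev$GeneID, ev$exonStart_0base, ev$exonEnd),
        feature = feat,
        transcript_position = pos,
        midpoint = mid,
        delta_psi = ev$IncLevelDifference,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(event_id = character(), feature = character(),
                      transcript_position = numeric(), midpoint = numeric(),
                      delta_psi = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare flanking-intron binding rates between two exon sets
#'
#' An exon "contains flanking-intron binding" when at least one enriched
#' window midpoint falls in its upstream or downstream intron. The binding
#' rates of two exon sets (e.g. exons skipped vs included after knockdown of
#' an upstream regulator) are compared by a two-sided chi-squared test on
#' the 2x2 bound-by-set table, without continuity correction.
#'
#' @param windows Enriched-window data frame.
#' @param events_a,events_b Two non-empty skipped-exon data frames.
#' @return List: `percent_a`, `percent_b` (percent of exons with
#'   flanking-intron binding), `chi2`, `p_value`, `table`.
#' @export
flanking_intron_binding_test <- function(windows, events_a, events_b) {
  if (nrow(events_a) == 0L || nrow(events_b) == 0L) {
    stop_degenerate_data("both exon sets must be non-empty")
  }
  has_flank <- function(events) {
    vapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      w <- windows[windows$chrom == ev$chr, , drop = FALSE]
      if (nrow(w) == 0L) return(FALSE)
      feats <- vapply(seq_len(nrow(w)), function(j) {
        assign_window_feature(w$start[j], w$end[j], ev)
      }, character(1))
      any(feats %in% c("upstream_intron", "downstream_intron"))
    }, logical(1))
  }
  a_bound <- has_flank(events_a)
  b_bound <- has_flank(events_b)
  tab <- rbind(a = c(bound = sum(a_bound), unbound = sum(!a_bound)),
               b = c(bound = sum(b_bound), unbound = sum(!b_bound)))
  if (any(colSums(tab) == 0L)) {
    stop_degenerate_data("degenerate 2x2 table: a margin is zero")
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(percent_a = 100 * mean(a_bound),
       percent_b = 100 * mean(b_bound),
       chi2 = unname(fit$statistic),
       p_value = fit$p.value,
       table = tab)
}
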