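#' Simulate a set of toy cassette-exon gene models
#'
#' Each gene carries five features in transcript order: upstream exon,
#' upstream intron, cassette (alternative) exon, downstream intron and
#' downstream exon. Coordinates are 0-based half-open genomic positions on a
#' single synthetic chromosome; on minus-strand genes the transcript-upstream
#' features sit at the genomically larger coordinates.
#'
#' @param n_genes Number of genes.
#' @param exon_length_range Length range (nt) for each exon (default 50-300).
#' @param intron_length_range Length range (nt) for each intron (default
#'   200-2000); minimum allowed is 50 so binding windows fit inside.
#' @param strand Either `"random"` (default), `"+"` or `"-"`.
#' @param gap Intergenic gap between consecutive loci (default 5000 nt).
#' @param chrom Chromosome label (default `"chrS"`).
#' @param seed Integer seed.
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   and genomic-order exon coordinates `e1_start`, `e1_end`, `e2_start`,
#'   `e2_end` (cassette), `e3_start`, `e3_end`.
#' @export
simulate_locus_set <- function(n_genes, exon_length_range = c(50L, 300L),
                               intron_length_range = c(200L, 2000L),
                               strand = "random", gap = 5000L,
                               chrom = "chrS", seed = 1L) {
  if (!is_count(n_genes, min = 1L)) stop_invalid_config("n_genes must be >= 1")
  if (min(intron_length_range) < 50L) {
    stop_invalid_config("intron lengths must be >= 50 nt")
  }
  if (min(exon_length_range) < 1L) {
    stop_invalid_config("exon lengths must be >= 1 nt")
  }
  set.seed(seed)
  exon_len <- matrix(sample(seq(exon_length_range[1L], exon_length_range[2L]),
                            3L * n_genes, replace = TRUE), ncol = 3L)
  intron_len <- matrix(sample(seq(intron_length_range[1L], intron_length_range[2L]),
                              2L * n_genes, replace = TRUE), ncol = 2L)
  strands <- switch(strand,
    random = sample(c("+", "-"), n_genes, replace = TRUE),
    `+` = rep("+", n_genes),
    `-` = rep("-", n_genes),
    stop_invalid_config("strand must be 'random', '+' or '-'")
  )
  span <- rowSums(exon_len) + rowSums(intron_len)
  start <- cumsum(c(1000L, span[-n_genes] + gap))
  e1_start <- start
  e1_end <- e1_start + exon_len[, 1L]
  e2_start <- e1_end + intron_len[, 1L]
  e2_end <- e2_start + exon_len[, 2L]
  e3_start <- e2_end + intron_len[, 2L]
  e3_end <- e3_start + exon_len[, 3L]
  data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = chrom,
    strand = strands,
    e1_start = e1_start, e1_end = e1_end,
    e2_start = e2_start, e2_end = e2_end,
    e3_start = e3_start, e3_end = e3_end,
    stringsAsFactors = FALSE
  )
}

#' Transcript-oriented feature intervals of one gene model
#'
#' Expands a gene-model row into the five transcript-oriented features.
#' Intron intervals are the genomic gaps between consecutive exons; on the
#' minus strand the genomically-left flanking exon is the transcript's
#' downstream exon.
#'
#' @param locus One row of a [simulate_locus_set()] table (or any object with
#'   the same fields).
#' @return Data frame with columns `feature` (`upstream_exon`,
#'   `upstream_intron`, `cassette_exon`, `downstream_intron`,
#'   `downstream_exon`), `start`, `end` (0-based half-open genomic).
#' @export
locus_features <- function(locus) {
  starts <- c(locus$e1_start, locus$e1_end, locus$e2_start, locus$e2_end,
              locus$e3_start)
  ends <- c(locus$e1_end, locus$e2_start, locus$e2_end, locus$e3_start,
            locus$e3_end)
  genomic <- c("left_exon", "left_intron", "cassette", "right_intron",
               "right_exon")
  feat_plus <- c("upstream_exon", "upstream_intron", "cassette_exon",
                 "downstream_intron", "downstream_exon")
  feature <- if (locus$strand == "+") feat_plus else rev(feat_plus)
  data.frame(feature = feature, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Reflect a locus set about the far end of its coordinate span
#'
#' Maps every coordinate x to `L - x` (so intervals \[s, e) become
#' \[L - e, L - s)), leaving strand labels untouched. Mirroring a locus
#' reverses its transcript orientation: features upstream of the cassette
#' exon become downstream features at the same distance. Useful for
#' symmetry checks of strand-aware feature assignment.
#'
#' @param loci A [simulate_locus_set()] table.
#' @param L Reflection constant; defaults to `max(e3_end) + 1000`.
#' @return Locus table of the same shape with reflected coordinates.
#' @export
reflect_locus_set <- function(loci, L = NULL) {
  if (is.null(L)) L <- max(loci$e3_end) + 1000L
  out <- loci
  out$e1_start <- L - loci$e3_end
  out$e1_end <- L - loci$e3_start
  out$e2_start <- L - loci$e2_end
  out$e2_end <- L - loci$e2_start
  out$e3_start <- L - loci$e1_end
  out$e3_end <- L - loci$e1_start
  out
}

#' Simulate linked CLIP-window, skipped-exon and TPM tables
#'
#' Generates the three inputs of the integration stage with planted ground
#' truth. A fraction of genes is knockdown-sensitive (their cassette exon
#' shifts by `kd_delta` after knockdown); binding is planted so that the odds
#' of a sensitive gene being bound are `bound_gene_or` times the odds of an
#' insensitive gene. Skipped-exon junction read counts are binomial draws
#' given the per-condition inclusion level and sequencing depth, p-values
#' come from a two-proportion z-test on pooled counts with
#' Benjamini-Hochberg adjustment (a generator-internal stand-in for a
#' likelihood-ratio test on the same counts), and the TPM table marks all
#' genes as expressed unless `frac_low_expressed > 0`.
#'
#' @param gene_models A [simulate_locus_set()] table.
#' @param bound_gene_or Planted binding odds ratio (> 0; `Inf` means all and
#'   only sensitive genes are bound).
#' @param kd_delta Absolute inclusion-level change of sensitive cassette
#'   exons after knockdown (default 0.3); sign is drawn per gene with
#'   probability `prob_skipping` of skipping after knockdown.
#' @param prob_sensitive Fraction of genes that are knockdown-sensitive
#'   (default 0.25).
#' @param prob_bound_insensitive Binding probability of insensitive genes
#'   (default 0.25); sets the binding base rate.
#' @param prob_skipping Probability that a sensitive event loses inclusion
#'   after knockdown (default 0.5).
#' @param read_depth Expected junction reads per replicate and event
#'   (default 100).
#' @param n_replicates Replicates per condition (default 2).
#' @param max_windows_per_gene Bound genes receive 1..this many windows
#'   (default 3), placed uniformly within the locus span.
#' @param window_width Width of each enriched window (default 50 nt).
#' @param frac_low_expressed Fraction of genes simulated below the TPM
#'   threshold (default 0).
#' @param seed Integer seed.
#' @return List with `windows` (BED-style data frame: `chrom`, `start`,
#'   `end`, `gene_id`, `score`, `strand`), `events` (rMATS-dialect
#'   skipped-exon data frame), `tpm` (two-column data frame), and `truth`
#'   (per-gene `gene_id`, `sensitive`, `bound`, `true_delta`).
#' @export
simulate_integration_tables <- function(gene_models, bound_gene_or = 4,
                                        kd_delta = 0.3,
                                        prob_sensitive = 0.25,
                                        prob_bound_insensitive = 0.25,
                                        prob_skipping = 0.5,
                                        read_depth = 100,
                                        n_replicates = 2L,
                                        max_windows_per_gene = 3L,
                                        window_width = 50L,
                                        frac_low_expressed = 0,
                                        seed = 1L) {
  if (!is.numeric(bound_gene_or) || bound_gene_or <= 0) {
    stop_invalid_config("bound_gene_or must be > 0 (Inf allowed)")
  }
  set.seed(seed)
  n <- nrow(gene_models)
  sensitive <- stats::runif(n) < prob_sensitive
  if (is.infinite(bound_gene_or)) {
    bound <- sensitive
  } else {
    odds0 <- prob_bound_insensitive / (1 - prob_bound_insensitive)
    odds1 <- odds0 * bound_gene_or
    p_bound <- ifelse(sensitive, odds1 / (1 + odds1), prob_bound_insensitive)
    bound <- stats::runif(n) < p_bound
  }
  sign <- ifelse(stats::runif(n) < prob_skipping, -1, 1)
  true_delta <- ifelse(sensitive, sign * kd_delta, 0)

  # windows for bound genes, uniform within the locus span
  win_list <- lapply(which(bound), function(i) {
    g <- gene_models[i, ]
    k <- sample.int(max_windows_per_gene, 1L)
    lo <- g$e1_start
    hi <- max(g$e3_end - window_width, lo + 1L)
    s <- sort(sample(seq(lo, hi), k, replace = FALSE))
    data.frame(chrom = g$chrom, start = s, end = s + window_width,
               gene_id = g$gene_id,
               score = round(stats::runif(k, 1, 10), 3), strand = g$strand,
               stringsAsFactors = FALSE)
  })
  windows <- if (length(win_list) > 0L) {
    do.call(rbind, win_list)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               gene_id = character(), score = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  }

  # skipped-exon events: one per gene, binomial junction counts
  psi_nt <- stats::runif(n, 0.3, 0.7)
  psi_kd <- pmin(pmax(psi_nt + true_delta, 0.01), 0.99)
  draw_cond <- function(psi) {
    tot <- matrix(stats::rpois(n * n_replicates, read_depth), nrow = n)
    inc <- matrix(stats::rbinom(n * n_replicates, as.vector(tot), rep(psi, n_replicates)),
                  nrow = n)
    list(inc = inc, skp = tot - inc)
  }
  kd <- draw_cond(psi_kd)   # SAMPLE_1 = knockdown
  nt <- draw_cond(psi_nt)   # SAMPLE_2 = non-targeting control
  inc_level <- function(inc, skp) inc / pmax(inc + skp, 1L)
  lvl1 <- inc_level(kd$inc, kd$skp)
  lvl2 <- inc_level(nt$inc, nt$skp)

  # two-proportion z-test on pooled counts, BH-adjusted
  x1 <- rowSums(kd$inc); n1 <- rowSums(kd$inc + kd$skp)
  x2 <- rowSums(nt$inc); n2 <- rowSums(nt$inc + nt$skp)
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (x1 / n1 - x2 / n2) / se, 0)
  pval <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(pval, method = "BH")

  fmt_lvls <- function(m) apply(round(m, 4), 1L, paste, collapse = ",")
  fmt_counts <- function(m) apply(m, 1L, paste, collapse = ",")
  minus <- gene_models$strand == "-"
  up_s <- ifelse(minus, gene_models$e3_start, gene_models$e1_start)
  up_e <- ifelse(minus, gene_models$e3_end, gene_models$e1_end)
  dn_s <- ifelse(minus, gene_models$e1_start, gene_models$e3_start)
  dn_e <- ifelse(minus, gene_models$e1_end, gene_models$e3_end)
  events <- data.frame(
    GeneID = gene_models$gene_id,
    geneSymbol = gene_models$gene_id,
    chr = gene_models$chrom,
    strand = gene_models$strand,
    exonStart_0base = gene_models$e2_start,
    exonEnd = gene_models$e2_end,
    upstreamES = up_s, upstreamEE = up_e,
    downstreamES = dn_s, downstreamEE = dn_e,
    IncLevel1 = fmt_lvls(lvl1),
    IncLevel2 = fmt_lvls(lvl2),
    IncLevelDifference = round(rowMeans(lvl1) - rowMeans(lvl2), 4),
    FDR = fdr,
    IJC_SAMPLE_1 = fmt_counts(kd$inc), SJC_SAMPLE_1 = fmt_counts(kd$skp),
    IJC_SAMPLE_2 = fmt_counts(nt$inc), SJC_SAMPLE_2 = fmt_counts(nt$skp),
    stringsAsFactors = FALSE
  )

  low <- stats::runif(n) < frac_low_expressed
  tpm <- data.frame(
    gene_id = gene_models$gene_id,
    TPM = round(ifelse(low, stats::runif(n, 0, 9.99),
                       stats::rlnorm(n, meanlog = log(60), sdlog = 0.8) + 10), 3),
    stringsAsFactors = FALSE
  )

  list(windows = windows, events = events, tpm = tpm,
       truth = data.frame(gene_id = gene_models$gene_id,
                          sensitive = sensitive, bound = bound,
                          true_delta = true_delta, stringsAsFactors = FALSE))
}
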