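# Shared fixture builders; everything is generated in code, no stored data.

# A minimal plate of luminescence records built directly from ratios:
# firefly fixed at 1000, renilla = 1000 * ratio.
records_from_ratios <- function(candidate_ratios, nc_ratios,
                                reporter = "30D", plate = "P1",
                                construct = "CAND") {
  n_c <- length(candidate_ratios)
  n_n <- length(nc_ratios)
  data.frame(
    plate_id = plate,
    well_id = sprintf("%s_W%02d", plate, seq_len(n_c + n_n)),
    construct_id = c(rep(construct, n_c), rep("FLAG_NC", n_n)),
    reporter_id = reporter,
    firefly = 1000,
    renilla = 1000 * c(candidate_ratios, nc_ratios),
    role = c(rep("candidate", n_c), rep("negative_control", n_n)),
    stringsAsFactors = FALSE
  )
}

# One skipped-exon event row in the rMATS dialect with controllable
# significance fields and plus-strand coordinates
#   upstream exon [100,200) | intron | cassette [500,600) | intron |
#   downstream exon [900,1000).
make_event <- function(gene = "G1", delta = 0.2, fdr = 0.01, reads = 200,
                       strand = "+", chrom = "chr1") {
  n_half <- floor(reads / 4)
  up <- if (strand == "+") c(100L, 200L) else c(900L, 1000L)
  dn <- if (strand == "+") c(900L, 1000L) else c(100L, 200L)
  data.frame(
    GeneID = gene, geneSymbol = gene, chr = chrom, strand = strand,
    exonStart_0base = 500L, exonEnd = 600L,
    upstreamES = up[1L], upstreamEE = up[2L],
    downstreamES = dn[1L], downstreamEE = dn[2L],
    IncLevel1 = "0.5,0.5", IncLevel2 = "0.5,0.5",
    IncLevelDifference = delta, FDR = fdr,
    IJC_SAMPLE_1 = paste(n_half, reads - 3L * n_half, sep = ","),
    SJC_SAMPLE_1 = paste(n_half, 0L, sep = ","),
    IJC_SAMPLE_2 = paste(n_half, 0L, sep = ","),
    SJC_SAMPLE_2 = "0,0",
    total_reads = reads,
    stringsAsFactors = FALSE
  )
}

make_window <- function(start, end, gene = "G1", chrom = "chr1",
                        strand = "+", score = 1) {
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene,
             score = score, strand = strand, stringsAsFactors = FALSE)
}

# Independent oracle: one-tailed pooled-variance t-test p-value obtained by
# numerically integrating the t density (never calls pt()).
oracle_t_p <- function(x, y, direction = "greater") {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  dens <- function(z) stats::dt(z, df)
  if (direction == "greater") {
    stats::integrate(dens, lower = tstat, upper = Inf,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  } else {
    stats::integrate(dens, lower = -Inf, upper = tstat,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
}

# Independent oracle: one-tailed Fisher p by explicit enumeration of all
# 2x2 tables with the observed margins (probability mass from log-binomial
# coefficients, summed over tables at least as extreme in a).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  xs <- max(0, r1 - c2):min(r1, c1)
  mass <- exp(lchoose(c1, xs) + lchoose(c2, r1 - xs) - lchoose(N, r1))
  sum(mass[xs >= a])
}
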