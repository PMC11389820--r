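#' Read an enriched-window BED file (BED6 with gene id in the name column)
#'
#' Tab-delimited, headerless, 0-based half-open intervals. Column 4 carries
#' the gene assignment of the window. Malformed lines are rejected with the
#' offending line number; nothing is silently coerced.
#'
#' @param path Path to the BED file.
#' @return Data frame: `chrom`, `start`, `end`, `gene_id`, `score`, `strand`.
#' @export
read_bed_windows <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      gene_id = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_line <- function(i) {
    f <- fields[[i]]
    if (length(f) < 6L) {
      stop_parse(sprintf("line %d: expected 6 tab-separated fields, got %d",
                         i, length(f)))
    }
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    score <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end)) {
      stop_parse(sprintf("line %d: non-integer coordinates '%s'/'%s'",
                         i, f[2L], f[3L]))
    }
    if (start < 0 || start >= end) {
      stop_parse(sprintf("line %d: invalid interval [%s, %s)", i, f[2L], f[3L]))
    }
    if (!(f[6L] %in% c("+", "-"))) {
      stop_parse(sprintf("line %d: unknown strand symbol '%s'", i, f[6L]))
    }
    if (is.na(score)) {
      stop_parse(sprintf("line %d: non-numeric score '%s'", i, f[5L]))
    }
    data.frame(chrom = f[1L], start = as.integer(start), end = as.integer(end),
               gene_id = f[4L], score = score, strand = f[6L],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(lines), parse_line))
  rownames(out) <- NULL
  out
}

#' Write enriched windows as BED6(+gene)
#'
#' Inverse of [read_bed_windows()]: `write_bed_windows(read_bed_windows(f), f2)`
#' reproduces `f` byte for byte for well-formed input.
#'
#' @param windows Data frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed_windows <- function(windows, path) {
  require_columns(windows, c("chrom", "start", "end", "gene_id", "score",
                             "strand"), "enriched-window table")
  score <- vapply(windows$score,
                  function(s) format(s, trim = TRUE, scientific = FALSE),
                  character(1))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   windows$chrom, as.integer(windows$start),
                   as.integer(windows$end), windows$gene_id, score,
                   windows$strand)
  writeLines(lines, path)
  invisible(path)
}

se_required_cols <- c(
  "GeneID", "geneSymbol", "chr", "strand", "exonStart_0base", "exonEnd",
  "upstreamES", "upstreamEE", "downstreamES", "downstreamEE",
  "IncLevel1", "IncLevel2", "IncLevelDifference", "FDR",
  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2"
)

#' Read a skipped-exon event table (rMATS SE column dialect)
#'
#' Parses the comma-separated per-replicate inclusion levels, drops `"NA"`
#' replicate entries while recording how many were dropped per event, and
#' computes each event's total junction read count over all IJC/SJC columns.
#'
#' @param path Path to the tab-separated table (header row required).
#' @return Data frame with the rMATS columns plus list-columns
#'   `inc_level_kd` (`IncLevel1` parsed) and `inc_level_nt` (`IncLevel2`
#'   parsed), and numeric columns `n_na_replicates` and `total_reads`.
#' @export
read_se_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(se_required_cols, names(tab))
  if (length(missing) > 0L) {
    stop_schema(sprintf("skipped-exon table is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  parse_levels <- function(s) {
    lapply(strsplit(as.character(s), ","), function(x) {
      v <- suppressWarnings(as.numeric(x))
      v[!is.na(v)]
    })
  }
  n_na <- function(s) {
    vapply(strsplit(as.character(s), ","),
           function(x) sum(is.na(suppressWarnings(as.numeric(x)))), numeric(1))
  }
  tab$inc_level_kd <- I(parse_levels(tab$IncLevel1))
  tab$inc_level_nt <- I(parse_levels(tab$IncLevel2))
  tab$n_na_replicates <- n_na(tab$IncLevel1) + n_na(tab$IncLevel2)
  count_cols <- c("IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2")
  sum_counts <- function(s) {
    vapply(strsplit(as.character(s), ","),
           function(x) sum(as.numeric(x), na.rm = TRUE), numeric(1))
  }
  tab$total_reads <- Reduce(`+`, lapply(tab[count_cols], sum_counts))
  tab
}

#' Write a skipped-exon event table in the rMATS SE dialect
#'
#' @param events Data frame carrying the rMATS columns (extra parsed columns
#'   are dropped on write).
#' @param path Output path.
#' @export
write_se_table <- function(events, path) {
  require_columns(events, se_required_cols, "skipped-exon table")
  utils::write.table(events[, se_required_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column TPM table (gene_id, TPM)
#'
#' @param path Path to the tab-separated table (header row required).
#' @return Data frame with columns `gene_id` and `TPM`.
#' @export
read_tpm_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  require_columns(tab, c("gene_id", "TPM"), "TPM table")
  if (any(!is.finite(tab$TPM)) || any(tab$TPM < 0)) {
    stop_invalid_measurement("TPM values must be finite and >= 0")
  }
  tab
}

#' Write a TPM table
#' @param tpm Data frame with `gene_id`, `TPM`.
#' @param path Output path.
#' @export
write_tpm_table <- function(tpm, path) {
  require_columns(tpm, c("gene_id", "TPM"), "TPM table")
  utils::write.table(tpm[, c("gene_id", "TPM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plate-formatted luminescence CSV
#'
#' @param path CSV with columns `plate_id`, `well_id`, `construct_id`,
#'   `reporter_id`, `firefly`, `renilla`, `role`.
#' @return Luminescence record data frame.
#' @export
read_plate_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(tab, c("plate_id", "well_id", "construct_id", "reporter_id",
                         "firefly", "renilla", "role"), "plate CSV")
  if (!is.numeric(tab$firefly) || !is.numeric(tab$renilla)) {
    stop_parse("firefly and renilla columns must be numeric")
  }
  tab
}

#' Write a plate-formatted luminescence CSV
#' @param records Luminescence record data frame.
#' @param path Output path.
#' @export
write_plate_csv <- function(records, path) {
  require_columns(records, c("plate_id", "well_id", "construct_id",
                             "reporter_id", "firefly", "renilla", "role"),
                  "luminescence record table")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gel-lane CSV
#' @param path CSV with columns `construct_id`, `replicate_index`,
#'   `inclusion_intensity`, `skipping_intensity`.
#' @return Gel-lane data frame.
#' @export
read_gel_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(tab, c("construct_id", "replicate_index",
                         "inclusion_intensity", "skipping_intensity"),
                  "gel-lane CSV")
  tab
}

#' Write a gel-lane CSV
#' @param lanes Gel-lane data frame.
#' @param path Output path.
#' @export
write_gel_csv <- function(lanes, path) {
  require_columns(lanes, c("construct_id", "replicate_index",
                           "inclusion_intensity", "skipping_intensity"),
                  "gel-lane table")
  utils::write.csv(lanes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a psi-estimate table as TSV
#'
#' Replicate list-columns are serialized as comma-separated values.
#'
#' @param psi_table Output of [estimate_psi_table()].
#' @param path Output path.
#' @export
write_psi_table <- function(psi_table, path) {
  flat <- psi_table
  flat$psi_replicates <- vapply(psi_table$psi_replicates,
                                function(x) paste(signif(x, 8), collapse = ","),
                                character(1))
  flat$psi_raw_replicates <- vapply(psi_table$psi_raw_replicates,
                                    function(x) paste(signif(x, 8), collapse = ","),
                                    character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
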