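#' Renilla/Firefly luminescence ratio
#'
#' The raw statistic behind the reporter readout. Firefly luciferase sits
#' upstream of the alternative exon and is translated regardless of the
#' splicing outcome, so it measures per-well transfection efficiency; Renilla
#' luciferase is translated only from the skipping isoform (exon inclusion
#' introduces a premature stop codon). Their ratio is therefore a
#' transfection-normalized measure of exon skipping.
#'
#' @param firefly Firefly relative light units, must be > 0.
#' @param renilla Renilla relative light units, must be >= 0.
#' @return Numeric vector `renilla / firefly`.
#' @export
#' @examples
#' luminescence_ratio(1000, 500) # 0.5
luminescence_ratio <- function(firefly, renilla) {
  if (!is.numeric(firefly) || !is.numeric(renilla)) {
    stop_invalid_measurement("firefly and renilla must be numeric")
  }
  if (any(!is.finite(firefly)) || any(firefly <= 0)) {
    stop_invalid_measurement("firefly must be finite and > 0 for every well")
  }
  if (any(!is.finite(renilla)) || any(renilla < 0)) {
    stop_invalid_measurement("renilla must be finite and >= 0 for every well")
  }
  renilla / firefly
}

#' Relative percent-spliced-in from luminescence ratios
#'
#' Converts a candidate well's Renilla/Firefly ratio into a relative
#' percent-spliced-in (psi) against the negative-control baseline measured on
#' the same plate:
#' `psi = 1 - candidate_ratio / nc_baseline_ratio`, clipped to \[0, 1\].
#' The negative control tethers an inert FLAG peptide, so its ratio reflects
#' the reporter's baseline (near-complete skipping); any drop in the candidate
#' ratio below baseline is attributed to induced exon inclusion.
#'
#' @param candidate_ratio Renilla/Firefly ratio(s) of candidate wells.
#' @param nc_baseline_ratio Plate-matched negative-control baseline ratio
#'   (mean over NC replicate wells); must be > 0.
#' @param clip Clip the estimate into \[0, 1\] (default). Unclipped values are
#'   useful as diagnostics and for significance testing, where clipping the
#'   null distribution at zero would bias the test.
#' @return psi estimate(s), in \[0, 1\] when `clip = TRUE`.
#' @export
#' @examples
#' psi_from_luminescence(0.3, 0.5) # 0.4
psi_from_luminescence <- function(candidate_ratio, nc_baseline_ratio, clip = TRUE) {
  if (!is.numeric(nc_baseline_ratio) || length(nc_baseline_ratio) != 1L ||
      !is.finite(nc_baseline_ratio) || nc_baseline_ratio <= 0) {
    stop_invalid_measurement("nc_baseline_ratio must be a single finite value > 0")
  }
  psi <- 1 - candidate_ratio / nc_baseline_ratio
  if (clip) psi <- pmin(pmax(psi, 0), 1)
  psi
}

#' Per-construct psi estimates from a plate table of luminescence records
#'
#' Groups wells by plate and reporter, computes the negative-control baseline
#' ratio for each group as the mean Renilla/Firefly ratio over that plate's
#' NC wells, converts every well to a relative psi, and summarizes replicates
#' per construct (mean and n-1 standard deviation). Both clipped psi and the
#' raw unclipped values are kept: clipped values are the reported estimates,
#' raw values feed the significance tests downstream.
#'
#' @param records Data frame with columns `plate_id`, `well_id`,
#'   `construct_id`, `reporter_id`, `firefly`, `renilla`, `role`
#'   (one of `"candidate"`, `"negative_control"`, `"positive_control"`).
#' @param min_nc_wells Minimum NC replicate wells required per
#'   (plate, reporter) group (default 2).
#' @return Data frame with one row per (construct, reporter, plate): columns
#'   `construct_id`, `reporter_id`, `plate_id`, `role`, `n`, `mean_psi`,
#'   `sd_psi`, and list-columns `psi_replicates` (clipped) and
#'   `psi_raw_replicates` (unclipped).
#' @export
estimate_psi_table <- function(records, min_nc_wells = 2L) {
  require_columns(records, c("plate_id", "well_id", "construct_id",
                             "reporter_id", "firefly", "renilla", "role"),
                  "luminescence record table")
  bad_role <- setdiff(unique(records$role),
                      c("candidate", "negative_control", "positive_control"))
  if (length(bad_role) > 0L) {
    stop_schema(paste("unknown role label(s):", paste(bad_role, collapse = ", ")))
  }
  ratio <- luminescence_ratio(records$firefly, records$renilla)

  plate_key <- paste(records$plate_id, records$reporter_id, sep = "\r")
  is_nc <- records$role == "negative_control"
  nc_n <- table(plate_key[is_nc])
  short <- setdiff(unique(plate_key), names(nc_n)[nc_n >= min_nc_wells])
  if (length(short) > 0L) {
    bad <- strsplit(short[1L], "\r", fixed = TRUE)[[1L]]
    stop_degenerate_data(sprintf(
      "plate '%s' (reporter %s) has %d negative-control wells; >= %d required",
      bad[1L], bad[2L], sum(is_nc & plate_key == short[1L]), min_nc_wells
    ))
  }
  baseline <- vapply(split(ratio[is_nc], plate_key[is_nc]), mean, numeric(1))
  psi_raw <- unname(1 - ratio / baseline[plate_key])
  psi <- pmin(pmax(psi_raw, 0), 1)

  grp_key <- paste(records$construct_id, plate_key, sep = "\r")
  idx <- split(seq_len(nrow(records)), grp_key)
  first <- vapply(idx, `[`, integer(1), 1L)
  res <- data.frame(
    construct_id = records$construct_id[first],
    reporter_id = records$reporter_id[first],
    plate_id = records$plate_id[first],
    role = records$role[first],
    n = lengths(idx),
    mean_psi = vapply(idx, function(i) mean(psi[i]), numeric(1)),
    sd_psi = vapply(idx, function(i) {
      if (length(i) >= 2L) stats::sd(psi[i]) else NA_real_
    }, numeric(1)),
    psi_replicates = I(lapply(idx, function(i) psi[i])),
    psi_raw_replicates = I(lapply(idx, function(i) psi_raw[i])),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$plate_id, res$construct_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
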