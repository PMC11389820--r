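#' Simulation configuration for the luminescence screen generator
#'
#' Collects the generative parameters of the dual-luciferase model. Firefly
#' light units model per-well transfection efficiency shared by both
#' luciferases (log-normal); Renilla is coupled to Firefly through
#' `renilla_gain` and attenuated by the construct's true exon inclusion,
#' since only the skipping isoform translates Renilla:
#' `R = F * renilla_gain * (1 - true_psi) * eps`, with `eps` multiplicative
#' log-normal noise of coefficient of variation `noise_cv`.
#'
#' @param replicates_per_construct Replicate transfections per construct
#'   (default 3, the screen's design); must be >= 2 or t-tests are undefined.
#' @param firefly_location,firefly_scale meanlog/sdlog of the Firefly
#'   transfection-efficiency log-normal (defaults give a median of 1e4 RLU
#'   with ~40% well-to-well variability, typical of arrayed transfections).
#' @param renilla_gain Dimensionless Renilla/Firefly coupling at zero
#'   inclusion (default 0.5).
#' @param noise_cv Coefficient of variation of the multiplicative measurement
#'   noise on the Renilla channel (default 0.05).
#' @param nmd_leakage Fraction in \[0, 1). Documented no-op hook: the
#'   inclusion isoform produces no Renilla, so nonsense-mediated decay of that
#'   isoform cannot change the luminescence readout; the parameter is kept so
#'   that configurations are explicit about the assumption.
#' @param plate_effect_sd Standard deviation of a per-plate log-scale batch
#'   effect applied to all luminescence on a plate (default 0). Ratios within
#'   a plate are invariant to it; it exists to exercise the plate-matched
#'   baseline logic.
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(replicates_per_construct = 3L,
                              firefly_location = log(1e4),
                              firefly_scale = 0.4,
                              renilla_gain = 0.5,
                              noise_cv = 0.05,
                              nmd_leakage = 0,
                              plate_effect_sd = 0,
                              seed = 1L) {
  if (!is_count(replicates_per_construct, min = 2L)) {
    stop_invalid_config("replicates_per_construct must be an integer >= 2 (t-tests undefined otherwise)")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop_invalid_config("noise_cv must be >= 0")
  }
  if (!is.numeric(nmd_leakage) || nmd_leakage < 0 || nmd_leakage >= 1) {
    stop_invalid_config("nmd_leakage must lie in [0, 1)")
  }
  if (!is.numeric(renilla_gain) || renilla_gain <= 0) {
    stop_invalid_config("renilla_gain must be > 0")
  }
  if (!is.numeric(plate_effect_sd) || plate_effect_sd < 0) {
    stop_invalid_config("plate_effect_sd must be >= 0")
  }
  if (!is_count(seed, min = 0L)) stop_invalid_config("seed must be a non-negative integer")
  structure(
    list(replicates_per_construct = as.integer(replicates_per_construct),
         firefly_location = firefly_location,
         firefly_scale = firefly_scale,
         renilla_gain = renilla_gain,
         noise_cv = noise_cv,
         nmd_leakage = nmd_leakage,
         plate_effect_sd = plate_effect_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Ground-truth table for a synthetic screen
#'
#' Lays out candidate constructs on plates, each plate carrying its own
#' negative control (inert FLAG fusion, true psi equal to the reporter
#' baseline of 0) and positive control, mirroring the plate design of an
#' arrayed tethering screen.
#'
#' @param true_psi Named or unnamed numeric vector of per-construct true
#'   inclusion responses in \[0, 1\] (one value per candidate construct).
#' @param reporter_id Reporter label, conventionally `"30D"` (tether 30 nt
#'   downstream of the 5' splice site) or `"30U"` (30 nt upstream of the
#'   3' splice site).
#' @param constructs_per_plate Candidates per plate (default 30).
#' @param pc_psi True psi of the positive-control construct (default 0.5).
#' @return Data frame with columns `construct_id`, `reporter_id`, `true_psi`,
#'   `plate_id`, `role`.
#' @export
screen_truth <- function(true_psi, reporter_id = "30D",
                         constructs_per_plate = 30L, pc_psi = 0.5) {
  if (length(true_psi) == 0L) stop_invalid_config("true_psi must be non-empty")
  if (any(!is.finite(true_psi)) || any(true_psi < 0) || any(true_psi > 1)) {
    stop_invalid_config("every true_psi must lie in [0, 1]")
  }
  if (!is_count(constructs_per_plate, min = 1L)) {
    stop_invalid_config("constructs_per_plate must be a positive integer")
  }
  ids <- names(true_psi)
  if (is.null(ids)) ids <- sprintf("RBP%04d", seq_along(true_psi))
  plate_idx <- ceiling(seq_along(true_psi) / constructs_per_plate)
  plate_id <- sprintf("%s_P%03d", reporter_id, plate_idx)
  cand <- data.frame(construct_id = ids, reporter_id = reporter_id,
                     true_psi = unname(true_psi), plate_id = plate_id,
                     role = "candidate", stringsAsFactors = FALSE)
  ctrl <- do.call(rbind, lapply(unique(plate_id), function(p) {
    data.frame(construct_id = c("FLAG_NC", "PC"),
               reporter_id = reporter_id,
               true_psi = c(0, pc_psi),
               plate_id = p,
               role = c("negative_control", "positive_control"),
               stringsAsFactors = FALSE)
  }))
  rbind(cand, ctrl)
}

#' Simulate dual-luciferase plate readouts from a ground-truth table
#'
#' Generative inverse of the psi-inference workflow: draws per-well Firefly
#' from the transfection-efficiency distribution and couples Renilla to it
#' through the skipping fraction `1 - true_psi` with multiplicative noise.
#' At `noise_cv = 0` the inference stage inverts this model exactly.
#'
#' @param truth Ground-truth table from [screen_truth()] (columns
#'   `construct_id`, `reporter_id`, `true_psi`, `plate_id`, `role`).
#' @param config A [simulation_config()].
#' @return Luminescence record data frame with columns `plate_id`, `well_id`,
#'   `construct_id`, `reporter_id`, `firefly`, `renilla`, `role`.
#' @export
simulate_screen <- function(truth, config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid_config("config must come from simulation_config()")
  }
  require_columns(truth, c("construct_id", "reporter_id", "true_psi",
                           "plate_id", "role"), "screen truth table")
  if (nrow(truth) == 0L) stop_invalid_config("truth table must be non-empty")
  for (p in unique(truth$plate_id)) {
    roles <- truth$role[truth$plate_id == p]
    if (!("negative_control" %in% roles) || !("positive_control" %in% roles)) {
      stop_invalid_config(sprintf(
        "plate '%s' must carry at least one negative and one positive control", p
      ))
    }
  }
  set.seed(config$seed)
  reps <- config$replicates_per_construct
  n <- nrow(truth) * reps
  idx <- rep(seq_len(nrow(truth)), each = reps)
  plate <- truth$plate_id[idx]
  plate_shift <- stats::setNames(
    stats::rnorm(length(unique(truth$plate_id)), 0, config$plate_effect_sd),
    unique(truth$plate_id)
  )
  firefly <- stats::rlnorm(n, meanlog = config$firefly_location + plate_shift[plate],
                           sdlog = config$firefly_scale)
  eps <- rnoise_cv(n, config$noise_cv)
  renilla <- firefly * config$renilla_gain * (1 - truth$true_psi[idx]) * eps
  out <- data.frame(
    plate_id = plate,
    well_id = sprintf("%s_W%03d", plate, stats::ave(idx, plate, FUN = seq_along)),
    construct_id = truth$construct_id[idx],
    reporter_id = truth$reporter_id[idx],
    firefly = firefly,
    renilla = renilla,
    role = truth$role[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Simulate RT-PCR gel band intensities for validation of screen hits
#'
#' Per construct, generates `n_reps` lanes whose inclusion band intensity is
#' proportional to the construct's RNA-level inclusion and whose skipping
#' band is proportional to its complement, with multiplicative noise on each
#' band. Control lanes (the inert-fusion condition, at the reporter's
#' baseline inclusion) are interleaved throughout the gel, as on a real
#' validation gel.
#'
#' @param hit_constructs Character vector of construct ids to run on the gel.
#' @param truth Ground-truth table containing these constructs.
#' @param noise_cv Multiplicative noise CV per band (default 0.05).
#' @param n_reps Lanes per construct (default 2, duplicate as in the screen).
#' @param n_control_lanes Number of control lanes (default 6).
#' @param control_psi RNA-level baseline inclusion of the control condition
#'   (default 0.05: the reporter exon is predominantly, not perfectly,
#'   excluded at the RNA level).
#' @param seed Integer seed.
#' @return Data frame with columns `construct_id`, `replicate_index`,
#'   `inclusion_intensity`, `skipping_intensity`, `is_control`.
#' @export
simulate_gel <- function(hit_constructs, truth, noise_cv = 0.05, n_reps = 2L,
                         n_control_lanes = 6L, control_psi = 0.05, seed = 1L) {
  require_columns(truth, c("construct_id", "true_psi"), "screen truth table")
  missing <- setdiff(hit_constructs, truth$construct_id)
  if (length(missing) > 0L) {
    stop_lookup(paste("construct(s) absent from truth table:",
                      paste(missing, collapse = ", ")))
  }
  if (!is_count(n_reps, min = 1L)) stop_invalid_config("n_reps must be >= 1")
  set.seed(seed)
  psi <- truth$true_psi[match(hit_constructs, truth$construct_id)]
  lane_psi <- c(rep(psi, each = n_reps), rep(control_psi, n_control_lanes))
  lane_id <- c(rep(hit_constructs, each = n_reps),
               rep("GEL_CONTROL", n_control_lanes))
  lane_rep <- c(rep(seq_len(n_reps), times = length(hit_constructs)),
                seq_len(n_control_lanes))
  amount <- 1000 * rnoise_cv(length(lane_psi), noise_cv)
  inc <- amount * lane_psi * rnoise_cv(length(lane_psi), noise_cv)
  skp <- amount * (1 - lane_psi) * rnoise_cv(length(lane_psi), noise_cv)
  out <- data.frame(
    construct_id = lane_id,
    replicate_index = lane_rep,
    inclusion_intensity = inc,
    skipping_intensity = skp,
    is_control = lane_id == "GEL_CONTROL",
    stringsAsFactors = FALSE
  )
  # spread control lanes through the gel rather than clustering them at the end
  n_lane <- nrow(out)
  slots <- c(seq_len(n_lane - n_control_lanes),
             seq(1, n_lane - n_control_lanes, length.out = n_control_lanes) + 0.5)
  out <- out[order(slots), , drop = FALSE]
  rownames(out) <- NULL
  out
}
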