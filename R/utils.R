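#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish bad measurements, bad
# configuration, schema problems and degenerate statistics programmatically.
ts_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "tetherscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid_measurement <- function(msg) ts_stop(msg, "ts_invalid_measurement")
stop_invalid_config      <- function(msg) ts_stop(msg, "ts_invalid_config")
stop_degenerate_data     <- function(msg) ts_stop(msg, "ts_degenerate_data")
stop_schema              <- function(msg) ts_stop(msg, "ts_schema_error")
stop_parse               <- function(msg) ts_stop(msg, "ts_parse_error")
stop_lookup              <- function(msg) ts_stop(msg, "ts_lookup_error")
stop_consistency         <- function(msg) ts_stop(msg, "ts_consistency_error")

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Multiplicative noise with a given coefficient of variation: log-normal with
# mean exactly 1, so E[x * eps] = x for every noise level.
rnoise_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Derive a stream-specific 32-bit seed from a master seed, so that the
# screening rounds, gels and retests use distinct but reproducible streams.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483647
}
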