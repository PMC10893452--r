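# Classifier configuration objects and the YAML config file round trip.

#' Classifier configurations
#'
#' Constructors for the per-classifier parameter bundles. All thresholds are
#' strictly positive; durations are in milliseconds and converted to sample
#' counts at the trace rate via [ms_to_samples()].
#'
#' @param n_sd number of baseline standard deviations defining the elliptic
#'   velocity threshold (fitted over a 0.2-4.0 grid).
#' @param baseline_window_ms length of the pre-trial stationary window used
#'   to estimate the baseline velocity distribution.
#' @param robust use the median-based noise-scale estimator
#'   (sqrt(median(v^2) - median(v)^2), the microsaccade-detection variant)
#'   instead of mean/SD.
#' @return a classed list of parameters.
#' @name configs
NULL

#' @rdname configs
#' @export
bmat_config <- function(n_sd = 1.64, baseline_window_ms = 500,
                        robust = FALSE) {
  stopifnot(n_sd > 0, baseline_window_ms > 0)
  structure(list(n_sd = n_sd, baseline_window_ms = baseline_window_ms,
                 robust = robust), class = "bmat_config")
}

#' @rdname configs
#' @param speed_threshold angular-speed threshold (deg/s).
#' @param savgol_window_ms Savitzky-Golay smoothing window (ms).
#' @param savgol_polyorder Savitzky-Golay polynomial order.
#' @param accel_tol acceleration magnitude (deg/s^2) treated as zero during
#'   the boundary walk (plateau tolerance).
#' @export
svt_config <- function(speed_threshold = 18.41, savgol_window_ms = 122,
                       savgol_polyorder = 3L, accel_tol = 1) {
  stopifnot(speed_threshold > 0)
  structure(list(speed_threshold = speed_threshold,
                 savgol_window_ms = savgol_window_ms,
                 savgol_polyorder = savgol_polyorder,
                 accel_tol = accel_tol), class = "svt_config")
}

#' @rdname configs
#' @param onset_window_ms sliding onset-detection window (ms; 100 ms = 9
#'   samples at 90 Hz).
#' @param offset_window_ms offset-detection window (ms; 22 ms = 2 samples at
#'   90 Hz).
#' @param frac fraction of window samples that must satisfy the threshold
#'   rule (counts compared as >= ceiling(frac * window)).
#' @param max_consecutive_below a candidate onset window is disqualified if
#'   it contains this many (or more) consecutive below-threshold samples.
#' @export
cw_config <- function(speed_threshold = 6, onset_window_ms = 100,
                      offset_window_ms = 22, frac = 0.72,
                      max_consecutive_below = 3L) {
  stopifnot(speed_threshold > 0, frac > 0, frac <= 1)
  structure(list(speed_threshold = speed_threshold,
                 onset_window_ms = onset_window_ms,
                 offset_window_ms = offset_window_ms,
                 frac = frac,
                 max_consecutive_below = as.integer(max_consecutive_below)),
            class = "cw_config")
}

#' @rdname configs
#' @param accel_magnitude_threshold per-axis acceleration magnitude
#'   (deg/s^2) below which a segment counts as resting on that axis; `NULL`
#'   selects the data-driven default (95th percentile of filtered
#'   acceleration magnitude during pre-trial rest windows).
#' @param cutoff_hz low-pass cutoff applied to the per-axis accelerations.
#' @export
dizco_config <- function(accel_magnitude_threshold = NULL, cutoff_hz = 10) {
  if (!is.null(accel_magnitude_threshold)) {
    stopifnot(accel_magnitude_threshold > 0)
  }
  stopifnot(cutoff_hz > 0)
  structure(list(accel_magnitude_threshold = accel_magnitude_threshold,
                 cutoff_hz = cutoff_hz), class = "dizco_config")
}

#' @rdname configs
#' @param max_depth maximum decision-tree depth.
#' @param min_interval_fraction post-processing cutoff: predicted intervals
#'   shorter than this fraction of the raters' mean interval are discarded.
#' @export
tree_config <- function(max_depth = 10L, min_interval_fraction = 0.5) {
  stopifnot(max_depth >= 1, min_interval_fraction > 0)
  structure(list(max_depth = as.integer(max_depth),
                 criterion = "gini",
                 min_interval_fraction = min_interval_fraction),
            class = "tree_config")
}

#' Read / write a classifier config file
#'
#' Configs are stored as a YAML mapping with one section per classifier
#' (`bmat`, `svt`, `cw`, `dizco`, `tree`); missing sections or fields take
#' the constructor defaults.
#'
#' @param path file path.
#' @return `read_config`: a named list of config objects.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, vals) {
    vals <- vals %||% list()
    do.call(ctor, vals[names(vals) %in% names(formals(ctor))])
  }
  list(bmat = build(bmat_config, raw$bmat),
       svt = build(svt_config, raw$svt),
       cw = build(cw_config, raw$cw),
       dizco = build(dizco_config, raw$dizco),
       tree = build(tree_config, raw$tree))
}

#' @rdname read_config
#' @param configs named list of config objects (as from [read_config()]).
#' @export
write_config <- function(configs, path) {
  yaml::write_yaml(lapply(configs, function(cf) {
    cf <- unclass(cf)
    cf[!vapply(cf, is.null, logical(1))]
  }), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
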