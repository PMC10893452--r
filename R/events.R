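# Movement events and per-sample label series, plus the conversions between
# them. Events use half-open [onset, offset) semantics on the uniform grid:
# an event created from a run of moving samples starts at the first sample's
# time and ends at the last sample's time + dt.

#' Compass direction labels
#'
#' The eight compass labels used by the direction-coding classifier, indexed
#' by screen angle: 0 deg = E (rightward), counter-clockwise.
#' @keywords internal
.compass <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

#' Construct a movement-event table
#'
#' @param onset,offset event boundaries in seconds (offset > onset).
#' @param direction optional compass label (`"N"`, `"NE"`, ..., `"NW"`) or NA.
#' @param amplitude optional net angular displacement (deg).
#' @param peak_velocity optional maximum angular speed within the event
#'   (deg/s).
#' @param ... further per-event columns (e.g. `subject`, `block`,
#'   `algorithm`).
#' @return a data frame of class `head_events`, sorted by onset.
#' @export
head_events <- function(onset = numeric(), offset = numeric(),
                        direction = NA_character_, amplitude = NA_real_,
                        peak_velocity = NA_real_, ...) {
  ev <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   direction = if (length(onset)) rep_len(as.character(direction), length(onset)) else character(),
                   amplitude = if (length(onset)) rep_len(as.numeric(amplitude), length(onset)) else numeric(),
                   peak_velocity = if (length(onset)) rep_len(as.numeric(peak_velocity), length(onset)) else numeric(),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) ev[[nm]] <- if (nrow(ev)) rep_len(extra[[nm]], nrow(ev)) else extra[[nm]][0]
  if (nrow(ev)) {
    if (any(ev$offset <= ev$onset)) stop("every event must have offset > onset")
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$onset[-1] < ev$offset[-nrow(ev)] - 1e-12)) {
      stop("events must be pairwise disjoint")
    }
    rownames(ev) <- NULL
  }
  class(ev) <- c("head_events", "data.frame")
  ev
}

#' @export
print.head_events <- function(x, ...) {
  cat(sprintf("<head_events> %d events\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Construct a per-sample label series
#'
#' The currency of sample-by-sample agreement scoring: a binary
#' moving/stationary label per sample, with an optional eligibility mask
#' (e.g. within-trial samples only).
#'
#' @param time sample timestamps (s).
#' @param moving logical (or 0/1) vector, `TRUE` where the head is moving.
#' @param mask optional logical vector of samples eligible for scoring.
#' @return an object of class `label_series`.
#' @export
label_series <- function(time, moving, mask = NULL) {
  time <- as.numeric(time)
  moving <- as.logical(moving)
  if (length(moving) != length(time)) stop("time and moving lengths differ")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(time)) stop("time and mask lengths differ")
  }
  structure(list(time = time, moving = moving, mask = mask),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series> %d samples, %.1f%% moving%s\n",
              length(x$time), 100 * mean(x$moving),
              if (is.null(x$mask)) "" else sprintf(", %d masked-in", sum(x$mask))))
  invisible(x)
}

#' Convert per-sample labels to movement events
#'
#' Maximal runs of moving samples become single events spanning
#' `[first sample, last sample + dt)`. Inverse of [events_to_labels()] for
#' non-adjacent events.
#'
#' @param labels a [label_series()].
#' @return a [head_events()] table.
#' @export
labels_to_events <- function(labels) {
  stopifnot(inherits(labels, "label_series"))
  m <- labels$moving
  if (!length(m) || !any(m)) return(head_events())
  dt <- if (length(labels$time) > 1L) stats::median(diff(labels$time)) else 0
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  head_events(onset = labels$time[starts[keep]],
              offset = labels$time[ends[keep]] + dt)
}

#' Convert movement events to per-sample labels
#'
#' A sample is moving iff its timestamp lies in some event's half-open
#' `[onset, offset)` window.
#'
#' @param events a [head_events()] table.
#' @param time sample timestamps to label (s).
#' @param mask optional eligibility mask carried onto the result.
#' @return a [label_series()].
#' @export
events_to_labels <- function(events, time, mask = NULL) {
  moving <- rep(FALSE, length(time))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      moving <- moving | (time >= events$onset[i] - 1e-12 &
                            time < events$offset[i] - 1e-12)
    }
  }
  label_series(time, moving, mask)
}

#' Fill event amplitude and peak velocity from kinematics
#'
#' Peak velocity is the maximum angular speed within `[onset, offset]`;
#' amplitude is the net angular displacement — the geodesic angle between
#' the orientations at onset and offset (deg). Optionally the path length
#' (sum of per-sample geodesic steps) is added as column `path_deg`.
#'
#' @param events a [head_events()] table.
#' @param kin a [head_kinematics()] object spanning the events.
#' @param path also compute path length per event.
#' @return the events table with `amplitude` and `peak_velocity` filled.
#' @export
annotate_events <- function(events, kin, path = FALSE) {
  stopifnot(inherits(events, "head_events"), inherits(kin, "head_kinematics"))
  if (!nrow(events)) return(events)
  tmin <- kin$time[1] - kin$dt / 2
  tmax <- kin$time[length(kin$time)] + kin$dt
  if (any(events$onset < tmin) || any(events$offset > tmax + 1e-9)) {
    stop("event outside the kinematic trace span")
  }
  q <- kin$trace$quat
  if (path) events$path_deg <- NA_real_
  for (i in seq_len(nrow(events))) {
    i0 <- which.min(abs(kin$time - events$onset[i]))
    i1 <- which.min(abs(kin$time - events$offset[i]))
    if (i1 < i0) i1 <- i0
    events$peak_velocity[i] <- max(kin$speed[i0:i1])
    events$amplitude[i] <- quat_angle(q[i0, ], q[i1, ])
    if (path) {
      idx <- i0:i1
      events$path_deg[i] <- if (length(idx) > 1L)
        sum(quat_angle(q[idx[-length(idx)], , drop = FALSE],
                       q[idx[-1L], , drop = FALSE])) else 0
    }
  }
  events
}

#' Drop implausibly short events
#'
#' Removes events shorter than `fraction` of a reference mean duration
#' (strict inequality: events exactly at the cutoff are kept). Used to
#' post-process per-sample classifiers against the raters' mean coded
#' interval length.
#'
#' @param events a [head_events()] table.
#' @param reference_mean_duration reference mean event duration (s), > 0.
#' @param fraction cutoff fraction of the reference mean (default 0.5).
#' @return the filtered events table, order preserved.
#' @export
prune_short_intervals <- function(events, reference_mean_duration,
                                  fraction = 0.5) {
  stopifnot(inherits(events, "head_events"))
  if (!is.numeric(reference_mean_duration) || reference_mean_duration <= 0) {
    stop("reference_mean_duration must be > 0")
  }
  if (!nrow(events)) return(events)
  dur <- events$offset - events$onset
  cutoff <- fraction * reference_mean_duration
  out <- events[dur > cutoff - 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("head_events", "data.frame")
  out
}
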