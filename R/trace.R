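# Orientation traces: time-stamped unit-quaternion head orientations with
# optional trial markers (trial_start / target_on / response).

#' Construct a head orientation trace
#'
#' The fundamental container of the package: a time series of head
#' orientations as unit quaternions, with optional per-trial event markers.
#' Orientations may be supplied as quaternions or as engine Euler angles
#' (degrees), which are converted via [euler_to_quat()].
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing.
#' @param quat n x 4 matrix of quaternions (w, x, y, z); normalized on input.
#' @param euler alternatively, an n x 3 matrix of (pitch, yaw, roll) degrees.
#' @param markers optional data frame with columns `time` (s) and `kind`
#'   (one of `"trial_start"`, `"target_on"`, `"response"`).
#' @param rate nominal sample rate in Hz; if `NULL` it is estimated as the
#'   reciprocal median timestamp step.
#' @return an object of class `head_trace`: a list with elements `time`,
#'   `quat`, `rate`, `markers`, and `uniform` (logical, whether timestamps sit
#'   on an exact uniform grid).
#' @seealso [resample_uniform()], [head_kinematics()], [read_trace()]
#' @examples
#' tr <- head_trace(seq(0, 1, by = 1/90),
#'                  euler = cbind(0, seq(0, 20, length.out = 91), 0))
#' tr
#' @export
head_trace <- function(time, quat = NULL, euler = NULL, markers = NULL,
                       rate = NULL) {
  time <- as.numeric(time)
  if (length(time) < 1L) stop("trace needs at least one sample")
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    stop(sprintf("timestamps must be strictly increasing; first violation at index %d (t[%d]=%.6f >= t[%d]=%.6f)",
                 bad[1] + 1L, bad[1], time[bad[1]], bad[1] + 1L, time[bad[1] + 1L]))
  }
  if (is.null(quat)) {
    if (is.null(euler)) stop("supply either quat or euler orientations")
    quat <- euler_to_quat(euler)
  }
  quat <- quat_normalize(as.matrix(quat))
  if (nrow(quat) != length(time)) stop("time and orientation lengths differ")
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    stopifnot(all(c("time", "kind") %in% names(markers)))
    markers$time <- as.numeric(markers$time)
    markers$kind <- as.character(markers$kind)
    ok <- c("trial_start", "target_on", "response")
    if (!all(markers$kind %in% ok)) {
      stop("marker kind must be one of: ", paste(ok, collapse = ", "))
    }
    markers <- markers[order(markers$time), , drop = FALSE]
    rownames(markers) <- NULL
  }
  dt <- diff(time)
  if (is.null(rate)) rate <- if (length(dt)) 1 / stats::median(dt) else NA_real_
  uniform <- length(dt) == 0L ||
    max(abs(time - (time[1] + (seq_along(time) - 1) / rate))) < 1e-9
  structure(list(time = time, quat = quat, rate = rate,
                 markers = markers, uniform = uniform),
            class = "head_trace")
}

#' @export
print.head_trace <- function(x, ...) {
  cat(sprintf("<head_trace> %d samples, %.3f-%.3f s, rate %.2f Hz%s\n",
              length(x$time), x$time[1], x$time[length(x$time)], x$rate,
              if (x$uniform) " (uniform)" else " (non-uniform)"))
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %d (%s)\n", nrow(x$markers),
                paste(names(table(x$markers$kind)), collapse = ", ")))
  }
  invisible(x)
}

#' Resample a trace onto a uniform time grid
#'
#' Spherical linear interpolation of orientations onto a grid of spacing
#' `1/rate` starting at the first timestamp and spanning the original time
#' range. HMD streams typically carry small timestamp jitter; all kinematic
#' derivations assume a uniform grid. A trace already on the target grid is
#' returned unchanged. Markers are carried over untouched.
#'
#' @param trace a [head_trace()].
#' @param rate target sample rate in Hz (default: the trace's nominal rate).
#' @return a uniform `head_trace` at `rate` Hz.
#' @examples
#' t_jit <- cumsum(rep(1/90, 50)) + stats::rnorm(50, 0, 1e-3)
#' tr <- head_trace(sort(t_jit), euler = cbind(0, seq(0, 10, length.out = 50), 0))
#' resample_uniform(tr, 90)
#' @export
resample_uniform <- function(trace, rate = trace$rate) {
  stopifnot(inherits(trace, "head_trace"))
  if (length(trace$time) < 2L) stop("resampling needs at least 2 samples")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  t0 <- trace$time[1]
  span <- trace$time[length(trace$time)] - t0
  n <- floor(span * rate + 1e-9) + 1L
  grid <- t0 + (seq_len(n) - 1L) / rate
  if (length(grid) == length(trace$time) &&
      max(abs(grid - trace$time)) < 1e-12) {
    out <- trace
    out$uniform <- TRUE
    out$rate <- rate
    return(out)
  }
  q <- quat_align_signs(trace$quat)
  idx <- findInterval(grid, trace$time, rightmost.closed = TRUE)
  idx <- pmax(1L, pmin(idx, length(trace$time) - 1L))
  tl <- trace$time[idx]
  tr_ <- trace$time[idx + 1L]
  frac <- (grid - tl) / (tr_ - tl)
  frac <- pmax(0, pmin(1, frac))
  qi <- quat_slerp(q[idx, , drop = FALSE], q[idx + 1L, , drop = FALSE], frac)
  head_trace(grid, quat = qi, markers = trace$markers, rate = rate)
}

#' Per-sample mask of within-trial samples
#'
#' Raters and agreement scoring operate between the start of a trial and the
#' participant's response; this returns the corresponding logical mask over
#' the trace's samples. Each `trial_start` marker opens a window closed by
#' the next `response` marker (or the end of the trace).
#'
#' @param time numeric vector of sample timestamps (s).
#' @param markers marker data frame (`time`, `kind`).
#' @return logical vector, `TRUE` for samples inside a trial window.
#' @export
trial_mask <- function(time, markers) {
  mask <- rep(FALSE, length(time))
  if (is.null(markers) || !nrow(markers)) return(mask)
  starts <- markers$time[markers$kind == "trial_start"]
  resps <- markers$time[markers$kind == "response"]
  for (s in starts) {
    e <- resps[resps > s]
    e <- if (length(e)) min(e) else max(time)
    mask <- mask | (time >= s & time <= e)
  }
  mask
}
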