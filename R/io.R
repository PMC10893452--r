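# Delimited-text readers/writers for traces, markers and event tables, plus
# the run manifest. Times are serialized in seconds with 6 decimal places;
# angles in degrees.

#' Read an orientation trace from delimited text
#'
#' The header decides the orientation encoding: quaternion files carry
#' columns `time_s, qw, qx, qy, qz`; Euler files carry
#' `time_s, rx_deg, ry_deg, rz_deg` (pitch, yaw, roll about the engine x,
#' y, z axes), converted to quaternions on read.
#'
#' @param path trace file path.
#' @param markers_path optional marker file (`time_s, kind`).
#' @param sep field separator.
#' @return a [head_trace()].
#' @export
read_trace <- function(path, markers_path = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("trace file lacks a time_s column")
  quat_cols <- c("qw", "qx", "qy", "qz")
  euler_cols <- c("rx_deg", "ry_deg", "rz_deg")
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("non-numeric value in column %s at data row %d", cn, bad))
    }
  }
  markers <- if (!is.null(markers_path)) read_markers(markers_path, sep)
  if (all(quat_cols %in% names(df))) {
    head_trace(df$time_s, quat = as.matrix(df[quat_cols]), markers = markers)
  } else if (all(euler_cols %in% names(df))) {
    head_trace(df$time_s, euler = as.matrix(df[euler_cols]),
               markers = markers)
  } else {
    stop("trace file must have columns qw,qx,qy,qz or rx_deg,ry_deg,rz_deg")
  }
}

#' @rdname read_trace
#' @param trace a [head_trace()].
#' @param quaternion write quaternion columns (default) or Euler angles.
#' @export
write_trace <- function(trace, path, quaternion = TRUE, sep = ",") {
  stopifnot(inherits(trace, "head_trace"))
  if (quaternion) {
    df <- data.frame(time_s = sprintf("%.6f", trace$time),
                     qw = sprintf("%.12f", trace$quat[, 1]),
                     qx = sprintf("%.12f", trace$quat[, 2]),
                     qy = sprintf("%.12f", trace$quat[, 3]),
                     qz = sprintf("%.12f", trace$quat[, 4]))
  } else {
    eul <- quat_to_euler(trace$quat)
    df <- data.frame(time_s = sprintf("%.6f", trace$time),
                     rx_deg = sprintf("%.9f", eul[, "pitch"]),
                     ry_deg = sprintf("%.9f", eul[, "yaw"]),
                     rz_deg = sprintf("%.9f", eul[, "roll"]))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trial-marker file
#'
#' @param path marker file with columns `time_s, kind`.
#' @param sep field separator.
#' @return data frame with columns `time`, `kind`.
#' @export
read_markers <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "kind") %in% names(df)))
  data.frame(time = as.numeric(df$time_s), kind = as.character(df$kind))
}

#' @rdname read_markers
#' @param markers marker data frame (`time`, `kind`).
#' @export
write_markers <- function(markers, path, sep = ",") {
  utils::write.table(data.frame(time_s = sprintf("%.6f", markers$time),
                                kind = markers$kind),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a movement-event table
#'
#' The interchange schema shared by classifier output and human-rater
#' annotations: one record per event with fields `subject`, `block`,
#' `algorithm`, `onset_s`, `offset_s`, `direction`, `amplitude_deg`,
#' `peak_velocity_deg_s`. Absent metadata columns are written as `NA`.
#'
#' @param path events file path.
#' @param sep field separator.
#' @return `read_events`: a [head_events()] (metadata columns preserved).
#' @export
read_events <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("onset_s", "offset_s") %in% names(df)))
  head_events(onset = df$onset_s, offset = df$offset_s,
              direction = df$direction %||% NA_character_,
              amplitude = df$amplitude_deg %||% NA_real_,
              peak_velocity = df$peak_velocity_deg_s %||% NA_real_,
              subject = df$subject %||% NA_character_,
              block = df$block %||% NA_character_,
              algorithm = df$algorithm %||% NA_character_)
}

#' @rdname read_events
#' @param events a [head_events()].
#' @export
write_events <- function(events, path, sep = ",") {
  stopifnot(inherits(events, "head_events"))
  get_col <- function(nm, default) {
    if (nm %in% names(events)) events[[nm]] else rep(default, nrow(events))
  }
  df <- data.frame(subject = get_col("subject", NA_character_),
                   block = get_col("block", NA_character_),
                   algorithm = get_col("algorithm", NA_character_),
                   onset_s = sprintf("%.6f", events$onset),
                   offset_s = sprintf("%.6f", events$offset),
                   direction = events$direction,
                   amplitude_deg = events$amplitude,
                   peak_velocity_deg_s = events$peak_velocity)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-sample label series
#'
#' @param labels a [label_series()].
#' @param path file path.
#' @param sep field separator.
#' @export
write_labels <- function(labels, path, sep = ",") {
  df <- data.frame(time_s = sprintf("%.6f", labels$time),
                   moving = as.integer(labels$moving))
  if (!is.null(labels$mask)) df$mask <- as.integer(labels$mask)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  label_series(df$time_s, df$moving > 0,
               if ("mask" %in% names(df)) df$mask > 0)
}

#' Build a reproducibility manifest
#'
#' Records the package version, a hash of the configuration, digests of the
#' input files and the seed, so a pipeline run can be reproduced and
#' verified byte-for-byte (the timestamp is excluded from the hash).
#'
#' @param config any serializable configuration object.
#' @param inputs character vector of input file paths.
#' @param seed integer seed used for the run.
#' @return list of class `hm_manifest` with a stable `hash` field.
#' @export
run_manifest <- function(config, inputs = character(), seed = NA_integer_) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    sprintf("size:%d", file.info(p)$size)
  }
  cfg_str <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  core <- list(version = as.character(utils::packageVersion("headmov")),
               config = cfg_str,
               inputs = stats::setNames(vapply(inputs, digest_file, ""),
                                        inputs),
               seed = seed)
  hash <- sum(utf8ToInt(paste(unlist(core), collapse = "|")) *
                seq_along(utf8ToInt(paste(unlist(core), collapse = "|")))) %% 2147483647
  structure(c(core, list(hash = hash, timestamp = format(Sys.time()))),
            class = "hm_manifest")
}
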