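# Agreement and bias metrics between any two labelers (human or algorithm),
# and the amplitude / peak-velocity main-sequence correlation.

#' Cohen's kappa for sample-by-sample agreement
#'
#' Chance-corrected agreement between two binary moving/stationary label
#' series, K = (Po - Pe) / (1 - Pe), where Po is the observed per-sample
#' agreement and Pe the agreement expected by chance from the marginal
#' label frequencies. Only samples masked-in by *both* series' masks (where
#' present, intersected with `mask`) are scored; pass no masks to score the
#' full series. When Pe = 1 (both labelers constant with identical
#' marginals) kappa is undefined and reported as `NA`.
#'
#' @param a,b [label_series()] of equal length.
#' @param mask optional additional logical mask.
#' @return object of class `hm_agreement`: list with `kappa`, `po`, `pe`,
#'   `n_samples`.
#' @examples
#' t <- 0:3
#' cohens_kappa(label_series(t, c(1, 1, 0, 0)), label_series(t, c(1, 0, 0, 0)))
#' @export
cohens_kappa <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "label_series"), inherits(b, "label_series"))
  if (length(a$moving) != length(b$moving)) {
    stop("label series have different lengths")
  }
  keep <- rep(TRUE, length(a$moving))
  if (!is.null(a$mask)) keep <- keep & a$mask
  if (!is.null(b$mask)) keep <- keep & b$mask
  if (!is.null(mask)) keep <- keep & mask
  x <- a$moving[keep]
  y <- b$moving[keep]
  n <- length(x)
  if (n == 0L) {
    return(structure(list(kappa = NA_real_, po = NA_real_, pe = NA_real_,
                          n_samples = 0L), class = "hm_agreement"))
  }
  po <- mean(x == y)
  px <- mean(x); py <- mean(y)
  pe <- px * py + (1 - px) * (1 - py)
  kappa <- if (pe >= 1 - 1e-15) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, po = po, pe = pe, n_samples = n),
            class = "hm_agreement")
}

#' @export
print.hm_agreement <- function(x, ...) {
  cat(sprintf("<hm_agreement> kappa = %s (Po = %.4f, Pe = %.4f, n = %d)\n",
              if (is.na(x$kappa)) "undefined (Pe = 1)" else sprintf("%.4f", x$kappa),
              x$po, x$pe, x$n_samples))
  invisible(x)
}

#' Union of rater labelings (ground truth)
#'
#' Per-sample logical OR across raters: a sample counts as moving if any
#' rater classified it as moving. Maximal runs of the union form the
#' ground-truth events used for event matching.
#'
#' @param raters list of aligned [label_series()].
#' @return a [label_series()] (mask = intersection of the raters' masks).
#' @export
merge_raters <- function(raters) {
  stopifnot(length(raters) >= 1L)
  n <- length(raters[[1]]$moving)
  moving <- rep(FALSE, n)
  mask <- NULL
  for (r in raters) {
    stopifnot(inherits(r, "label_series"))
    if (length(r$moving) != n) stop("rater label series have different lengths")
    moving <- moving | r$moving
    if (!is.null(r$mask)) mask <- if (is.null(mask)) r$mask else mask & r$mask
  }
  label_series(raters[[1]]$time, moving, mask)
}

#' Match ground-truth events to classifier events by midpoint containment
#'
#' A ground-truth event and a classifier event are the same movement iff
#' the truth event's midpoint, (onset + offset) / 2 in continuous time,
#' lies in the classifier event's half-open `[onset, offset)` window. Any
#' classifier event containing two or more truth midpoints has no
#' one-to-one pairing and is removed together with all its pairings;
#' unmatched events on either side are excluded.
#'
#' @param truth,pred [head_events()] tables (sorted, disjoint).
#' @return data frame with one row per kept pair: `truth_idx`, `pred_idx`,
#'   and the paired events' `truth_onset`, `truth_offset`,
#'   `truth_amplitude`, `pred_onset`, `pred_offset`, `pred_amplitude`.
#' @export
match_events <- function(truth, pred) {
  stopifnot(inherits(truth, "head_events"), inherits(pred, "head_events"))
  empty <- data.frame(truth_idx = integer(), pred_idx = integer(),
                      truth_onset = numeric(), truth_offset = numeric(),
                      truth_amplitude = numeric(), pred_onset = numeric(),
                      pred_offset = numeric(), pred_amplitude = numeric())
  if (!nrow(truth) || !nrow(pred)) return(empty)
  mid <- (truth$onset + truth$offset) / 2
  # preds are disjoint and sorted: locate each midpoint by interval search
  pred_idx <- rep(NA_integer_, nrow(truth))
  j <- findInterval(mid, pred$onset)
  ok <- j >= 1L
  ok[ok] <- mid[ok] < pred$offset[j[ok]]   # half-open right bound
  pred_idx[ok] <- j[ok]
  counts <- table(pred_idx)
  dup <- as.integer(names(counts)[counts >= 2L])
  keep <- !is.na(pred_idx) & !(pred_idx %in% dup)
  if (!any(keep)) return(empty)
  ti <- which(keep)
  pj <- pred_idx[keep]
  data.frame(truth_idx = ti, pred_idx = pj,
             truth_onset = truth$onset[ti], truth_offset = truth$offset[ti],
             truth_amplitude = truth$amplitude[ti],
             pred_onset = pred$onset[pj], pred_offset = pred$offset[pj],
             pred_amplitude = pred$amplitude[pj])
}

#' Onset / offset / duration / amplitude bias over matched pairs
#'
#' Bias is the (human-rated) truth value minus the classifier value: a
#' positive onset bias means raters placed the movement start *after* the
#' classifier did. Times are reported in milliseconds, amplitude in
#' degrees; each with its across-pair standard error.
#'
#' @param pairs matched pairs from [match_events()].
#' @return object of class `hm_bias`: list with `onset_bias`, `offset_bias`,
#'   `duration_bias` (ms), `amplitude_bias` (deg), matching `*_se` fields,
#'   and `n_pairs`. With zero pairs the metrics are `NA`.
#' @export
bias_metrics <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    return(structure(list(onset_bias = NA_real_, offset_bias = NA_real_,
                          duration_bias = NA_real_, amplitude_bias = NA_real_,
                          onset_se = NA_real_, offset_se = NA_real_,
                          duration_se = NA_real_, amplitude_se = NA_real_,
                          n_pairs = 0L), class = "hm_bias"))
  }
  d_on <- (pairs$truth_onset - pairs$pred_onset) * 1000
  d_off <- (pairs$truth_offset - pairs$pred_offset) * 1000
  d_dur <- d_off - d_on
  d_amp <- pairs$truth_amplitude - pairs$pred_amplitude
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(onset_bias = mean(d_on), offset_bias = mean(d_off),
                 duration_bias = mean(d_dur), amplitude_bias = mean(d_amp),
                 onset_se = se(d_on), offset_se = se(d_off),
                 duration_se = se(d_dur), amplitude_se = se(d_amp),
                 n_pairs = n), class = "hm_bias")
}

#' @export
print.hm_bias <- function(x, ...) {
  cat(sprintf("<hm_bias> %d pairs\n", x$n_pairs))
  if (x$n_pairs > 0L) {
    cat(sprintf("  onset    %+8.2f ms (SE %.2f)\n", x$onset_bias, x$onset_se))
    cat(sprintf("  offset   %+8.2f ms (SE %.2f)\n", x$offset_bias, x$offset_se))
    cat(sprintf("  duration %+8.2f ms (SE %.2f)\n", x$duration_bias, x$duration_se))
    cat(sprintf("  amplitude%+8.2f deg (SE %.2f)\n", x$amplitude_bias, x$amplitude_se))
  }
  invisible(x)
}

#' Main-sequence correlation
#'
#' Pearson correlation between movement amplitude and peak velocity across
#' events — the stereotyped positive relation borrowed from saccade
#' research. Requires at least 3 events with finite values in both
#' variables; zero variance in either variable yields `r = NA` with a
#' degenerate flag.
#'
#' @param events a [head_events()] with `amplitude` and `peak_velocity`
#'   filled (see [annotate_events()]).
#' @return object of class `hm_main_sequence`: list with `r`, `p_value`,
#'   `n`, `degenerate`.
#' @export
main_sequence <- function(events) {
  stopifnot(inherits(events, "head_events"))
  ok <- is.finite(events$amplitude) & is.finite(events$peak_velocity)
  a <- events$amplitude[ok]
  v <- events$peak_velocity[ok]
  if (length(a) < 3L) stop("main sequence needs at least 3 annotated events")
  if (stats::sd(a) == 0 || stats::sd(v) == 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = length(a),
                          degenerate = TRUE), class = "hm_main_sequence"))
  }
  ct <- stats::cor.test(a, v, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(a), degenerate = FALSE),
            class = "hm_main_sequence")
}

#' @export
print.hm_main_sequence <- function(x, ...) {
  cat(sprintf("<hm_main_sequence> r = %s, p = %.3g, n = %d%s\n",
              if (is.na(x$r)) "NA" else sprintf("%.3f", x$r),
              x$p_value, x$n,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
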