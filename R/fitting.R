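# Threshold grid search with leave-one-subject-out selection.
#
# A "subject" is a list with elements `kin` (head_kinematics) and `raters`
# (list of label_series); the simulator's simulate_study() produces this
# shape directly.

#' Default threshold grids
#'
#' BMAT's grid spans the fitted range of the baseline-SD multiplier, 0.2 to
#' 4.0 in steps of 0.1; SVT and Chen & Walton grids span plausible
#' angular-speed thresholds.
#'
#' @param algo one of `"bmat"`, `"svt"`, `"cw"`.
#' @return numeric threshold grid.
#' @export
default_grid <- function(algo = c("bmat", "svt", "cw")) {
  switch(match.arg(algo),
         bmat = seq(0.2, 4.0, by = 0.1),
         svt = seq(2, 40, by = 0.5),
         cw = seq(1, 15, by = 0.25))
}

#' Run a thresholding classifier at a given threshold, as per-sample labels
#'
#' Dispatch helper used by the fitting routines: the threshold is the BMAT
#' SD multiplier `n_sd`, or the angular-speed threshold for SVT and
#' Chen & Walton. Event-producing classifiers are converted to labels on the
#' kinematic grid.
#'
#' @param kin a [head_kinematics()].
#' @param algo `"bmat"`, `"svt"` or `"cw"`.
#' @param threshold threshold value.
#' @param baseline optional explicit BMAT baseline (else pre-trial windows).
#' @return a [label_series()].
#' @export
classify_labels <- function(kin, algo = c("bmat", "svt", "cw"), threshold,
                            baseline = NULL) {
  algo <- match.arg(algo)
  switch(algo,
         bmat = classify_bmat(kin, baseline,
                              bmat_config(n_sd = threshold)),
         svt = events_to_labels(
           classify_svt(kin, svt_config(speed_threshold = threshold)),
           kin$time),
         cw = events_to_labels(
           classify_cw(kin, cw_config(speed_threshold = threshold)),
           kin$time))
}

#' Per-subject kappa across a threshold grid
#'
#' For every threshold: run the classifier on each subject, score Cohen's
#' kappa against each of the subject's raters within the trial windows,
#' average within subject, giving a subjects x thresholds kappa matrix and
#' its across-subject column means. A classifier failure on one subject
#' leaves that cell `NA` (with a warning) and it is excluded from means.
#'
#' @param subjects list of subjects (each: list with `kin`, `raters`).
#' @param algo `"bmat"`, `"svt"` or `"cw"`.
#' @param grid numeric threshold grid (default [default_grid()]).
#' @param use_mask score within trial windows only (default `TRUE`; the
#'   mask comes from the trace's trial markers).
#' @return list with `grid`, `kappa` (subjects x thresholds matrix),
#'   `mean_kappa` (named numeric, one entry per threshold).
#' @export
grid_search <- function(subjects, algo, grid = default_grid(algo),
                        use_mask = TRUE) {
  stopifnot(length(subjects) >= 1L, length(grid) >= 1L)
  km <- matrix(NA_real_, length(subjects), length(grid))
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    mask <- if (use_mask) trial_mask(sub$kin$time, sub$kin$markers) else NULL
    for (gi in seq_along(grid)) {
      labs <- tryCatch(classify_labels(sub$kin, algo, grid[gi]),
                       error = function(e) {
                         warning(sprintf("%s failed on subject %d at threshold %g: %s",
                                         algo, si, grid[gi], conditionMessage(e)))
                         NULL
                       })
      if (is.null(labs)) next
      kk <- vapply(sub$raters, function(r) {
        cohens_kappa(labs, r, mask = mask)$kappa
      }, numeric(1))
      km[si, gi] <- mean(kk)
    }
  }
  mean_kappa <- colMeans(km, na.rm = TRUE)
  names(mean_kappa) <- format(grid)
  list(grid = grid, kappa = km, mean_kappa = mean_kappa)
}

#' Leave-one-subject-out threshold fit
#'
#' For each held-out subject the threshold maximizing the mean
#' within-subject kappa over the remaining subjects is selected (ties break
#' toward the smallest threshold, favoring sensitivity) and evaluated on
#' the held-out subject. Selection is fully deterministic given the data
#' and grid.
#'
#' @param subjects list of >= 3 subjects (each: list with `kin`, `raters`).
#' @param algo `"bmat"`, `"svt"` or `"cw"`.
#' @param grid numeric threshold grid.
#' @param use_mask score within trial windows only.
#' @return an object of class `hm_loo_fit` with components `per_fold`
#'   (data frame: `held_out`, `threshold`, `kappa`), `mean_kappa`,
#'   `kappa_se`, `mean_threshold`, `threshold_se`, `grid`, `algo`.
#'   Standard errors are SD / sqrt(n_folds).
#' @examples
#' \donttest{
#' study <- simulate_study(n_subjects = 3, cfg = sim_config(n_trials = 4, seed = 1))
#' fit <- fit_loo(study, "svt", grid = seq(5, 20, 5))
#' summary(fit)
#' }
#' @export
fit_loo <- function(subjects, algo, grid = default_grid(algo),
                    use_mask = TRUE) {
  if (length(subjects) < 3L) stop("leave-one-out needs at least 3 subjects")
  gs <- grid_search(subjects, algo, grid, use_mask)
  nsub <- length(subjects)
  sel <- numeric(nsub)
  held <- numeric(nsub)
  for (i in seq_len(nsub)) {
    mk <- colMeans(gs$kappa[-i, , drop = FALSE], na.rm = TRUE)
    best <- which(mk >= max(mk, na.rm = TRUE) - 1e-12)[1]  # smallest-threshold tie-break
    sel[i] <- grid[best]
    held[i] <- gs$kappa[i, best]
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(per_fold = data.frame(held_out = seq_len(nsub),
                                       threshold = sel, kappa = held),
                 mean_kappa = mean(held), kappa_se = se(held),
                 mean_threshold = mean(sel), threshold_se = se(sel),
                 grid = grid, algo = algo, grid_kappa = gs),
            class = "hm_loo_fit")
}

#' @export
print.hm_loo_fit <- function(x, ...) {
  cat(sprintf("<hm_loo_fit> %s: kappa %.3f (SE %.3g), threshold %.3g (SE %.3g), %d folds\n",
              x$algo, x$mean_kappa, x$kappa_se, x$mean_threshold,
              x$threshold_se, nrow(x$per_fold)))
  invisible(x)
}

#' @export
summary.hm_loo_fit <- function(object, ...) {
  print(object)
  cat("per-fold results:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' @export
coef.hm_loo_fit <- function(object, ...) {
  c(threshold = object$mean_threshold, kappa = object$mean_kappa)
}

#' Assemble a fit-report table across algorithms and conditions
#'
#' One row per (condition, algorithm): held-out kappa and selected
#' threshold, each with its standard error.
#'
#' @param fits named list (condition -> named list (algorithm ->
#'   `hm_loo_fit`)).
#' @return data frame with columns `condition`, `algorithm`, `kappa`,
#'   `kappa_se`, `threshold`, `threshold_se`.
#' @export
fit_report <- function(fits) {
  rows <- list()
  for (cond in names(fits)) {
    for (algo in names(fits[[cond]])) {
      f <- fits[[cond]][[algo]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, algorithm = algo,
        kappa = f$mean_kappa, kappa_se = f$kappa_se,
        threshold = f$mean_threshold, threshold_se = f$threshold_se)
    }
  }
  do.call(rbind, rows)
}
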