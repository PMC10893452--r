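# Decision-tree labeler: a supervised per-sample classifier trained on
# rater labels, using the smoothed head speed and head-angle magnitude at
# the current time step as features.

#' Feature table for the decision-tree labeler
#'
#' @param kin a [head_kinematics()].
#' @return data frame with columns `speed` (Savitzky-Golay smoothed angular
#'   speed, deg/s) and `angle` (head-angle magnitude, deg).
#' @export
tree_features <- function(kin) {
  stopifnot(inherits(kin, "head_kinematics"))
  data.frame(speed = kin$speed_smooth, angle = kin$head_angle)
}

#' Train the decision-tree labeler
#'
#' Fits an axis-aligned binary classification tree (Gini impurity splits,
#' depth capped at `max_depth`) predicting the per-sample moving/stationary
#' label from the feature table. Training pools all supplied samples; both
#' classes must be present.
#'
#' @param features data frame of per-sample features (see [tree_features()]).
#' @param labels a [label_series()] (or logical vector) aligned with
#'   `features`.
#' @param config a [tree_config()].
#' @return an object of class `hm_tree` wrapping the fitted [rpart::rpart]
#'   model (serializable with [saveRDS()]).
#' @export
tree_train <- function(features, labels, config = tree_config()) {
  stopifnot(inherits(config, "tree_config"))
  moving <- if (inherits(labels, "label_series")) labels$moving else as.logical(labels)
  if (nrow(features) != length(moving)) stop("features and labels are not aligned")
  if (length(unique(moving)) < 2L) {
    stop("training labels contain a single class; cannot fit a tree")
  }
  dat <- cbind(features, .moving = factor(moving, levels = c(FALSE, TRUE)))
  fit <- rpart::rpart(.moving ~ ., data = dat, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = config$max_depth, cp = 0,
                        minsplit = 20, xval = 0))
  structure(list(fit = fit, feature_names = names(features), config = config),
            class = "hm_tree")
}

#' @export
print.hm_tree <- function(x, ...) {
  cat(sprintf("<hm_tree> depth %d, %d leaves, features: %s\n",
              tree_depth(x), sum(x$fit$frame$var == "<leaf>"),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Depth of a fitted tree
#'
#' @param model an `hm_tree`.
#' @return integer depth (0 for a stump with no splits).
#' @export
tree_depth <- function(model) {
  nodes <- as.integer(rownames(model$fit$frame))
  max(floor(log2(nodes)))
}

#' Label samples with a trained tree
#'
#' @param model an `hm_tree` from [tree_train()].
#' @param features feature table with the training feature columns.
#' @param time optional timestamps for the returned series (defaults to the
#'   0-based sample index).
#' @return a [label_series()].
#' @export
tree_classify <- function(model, features, time = NULL) {
  stopifnot(inherits(model, "hm_tree"))
  if (!all(model$feature_names %in% names(features))) {
    stop("feature columns do not match the trained model: expected ",
         paste(model$feature_names, collapse = ", "))
  }
  p <- stats::predict(model$fit, newdata = features, type = "class")
  if (is.null(time)) time <- seq_len(nrow(features)) - 1
  label_series(time, p == "TRUE")
}

#' Contiguous-block k-fold cross-validation of the tree labeler
#'
#' Folds are contiguous blocks of samples (not random shuffles), so that
#' the strong temporal autocorrelation of head-tracking data cannot leak
#' between training and validation sets.
#'
#' @param features feature table.
#' @param labels a [label_series()] or logical vector.
#' @param k number of folds.
#' @param config a [tree_config()].
#' @return list with `accuracy` (mean held-out accuracy), `fold_accuracy`.
#' @export
tree_cv <- function(features, labels, k = 5L, config = tree_config()) {
  moving <- if (inherits(labels, "label_series")) labels$moving else as.logical(labels)
  n <- length(moving)
  fold <- cut(seq_len(n), breaks = k, labels = FALSE)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- tree_train(features[tr, , drop = FALSE], moving[tr], config)
    pred <- tree_classify(model, features[!tr, , drop = FALSE])
    acc[f] <- mean(pred$moving == moving[!tr])
  }
  list(accuracy = mean(acc), fold_accuracy = acc)
}
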