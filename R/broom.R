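#' Tidy a trained model bundle
#'
#' One row per feature with its impurity importance, most important first.
#'
#' @param x An `exocargo_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`.
#' @method tidy exocargo_model
#' @export
tidy.exocargo_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) %>%
    arrange(dplyr::desc(.data$importance))
}

#' Glance at a trained model bundle
#'
#' @param x An `exocargo_model`.
#' @param ... Unused.
#' @return One-row tibble: scheme, tree count, seed, class sizes,
#'   out-of-bag prediction error, decision threshold.
#' @method glance exocargo_model
#' @export
glance.exocargo_model <- function(x, ...) {
  tibble(
    scheme = x$scheme %||% NA_character_,
    n_trees = x$n_trees,
    seed = x$seed,
    n_train_pos = x$n_train_pos,
    n_train_neg = x$n_train_neg,
    oob_error = x$forest$prediction.error,
    decision_threshold = x$decision_threshold
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `exocargo_cv`.
#' @param ... Unused.
#' @return The aggregate tibble: one row per (scheme, n_trees) with
#'   mean/sd of accuracy, AUC and MCC over all fold cells.
#' @method tidy exocargo_cv
#' @export
tidy.exocargo_cv <- function(x, ...) x$aggregate

#' Glance at a cross-validation result
#'
#' @param x An `exocargo_cv`.
#' @param criterion Selection criterion passed to [grid_select()].
#' @param ... Unused.
#' @return One-row tibble: the winning cell plus the sweep dimensions.
#' @method glance exocargo_cv
#' @export
glance.exocargo_cv <- function(x, criterion = "ACC", ...) {
  best <- grid_select(x, criterion)
  best$n_schemes <- length(unique(x$folds$scheme))
  best$n_tree_values <- length(unique(x$folds$n_trees))
  best$n_repeats <- x$config$n_repeats
  best$n_folds <- x$config$n_folds
  best
}

#' @export
print.exocargo_model <- function(x, ...) {
  cat("<exocargo_model> scheme:", x$scheme %||% "?",
      " trees:", x$n_trees, " seed:", x$seed, "\n",
      "trained on", x$n_train_pos, "positive /", x$n_train_neg,
      "negative records\n")
  invisible(x)
}

#' @export
print.exocargo_cv <- function(x, ...) {
  cat("<exocargo_cv>", x$config$n_repeats, "x", x$config$n_folds,
      "-fold CV;", nrow(x$aggregate), "aggregate cells\n")
  print(x$aggregate, n = 10)
  invisible(x)
}

#' Plot a cross-validation sweep
#'
#' Mean cross-validated accuracy against the number of trees, one line per
#' feature scheme — the standard view for judging where the forest
#' stabilizes.
#'
#' @param object An `exocargo_cv`.
#' @param metric Aggregate column to plot (`"acc_mean"`, `"auc_mean"`,
#'   `"mcc_mean"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exocargo_cv
#' @export
autoplot.exocargo_cv <- function(object, metric = "acc_mean", ...) {
  ggplot2::ggplot(object$aggregate,
                  ggplot2::aes(x = .data$n_trees, y = .data[[metric]],
                               colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of trees", y = metric, colour = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @inheritParams roc_auc
#' @return A ggplot object of SE against 1 - SP with the chance diagonal.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
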