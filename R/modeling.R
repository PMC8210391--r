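#' Training configuration
#'
#' Bundles the knobs of the cross-validation sweep. The default tree-count
#' grid is the 31-value grid 100, 150, ..., 1000, then 1500, 2000, ...,
#' 6000, then 8000 and 10000 — accuracy typically stabilizes around 1500
#' trees, so sweeps on small data can pass a much shorter grid.
#'
#' @param scheme Feature scheme name (see [encode()]).
#' @param tree_grid Strictly increasing positive integer vector.
#' @param n_folds Folds per repeat (>= 2); 10 by default.
#' @param n_repeats Repeats of the whole CV (>= 1); 10 by default.
#' @param seed Integer master seed; every downstream random draw derives
#'   from it.
#' @param decision_threshold Score threshold for the Y/N call, in (0, 1).
#' @return A list of class `exocargo_config`.
#' @export
train_config <- function(scheme = "DP", tree_grid = default_tree_grid(),
                         n_folds = 10, n_repeats = 10, seed = 1,
                         decision_threshold = 0.5) {
  scheme <- match_scheme(scheme)
  if (any(tree_grid <= 0) || is.unsorted(tree_grid, strictly = TRUE)) {
    abort("tree_grid must be positive and strictly increasing")
  }
  if (n_folds < 2) abort("n_folds must be >= 2")
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("decision_threshold must be in (0, 1)")
  }
  structure(list(scheme = scheme, tree_grid = as.integer(tree_grid),
                 n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "exocargo_config")
}

#' @rdname train_config
#' @export
default_tree_grid <- function() {
  c(seq(100L, 1000L, by = 50L), seq(1500L, 6000L, by = 500L), 8000L, 10000L)
}

#' Train a random forest on an encoded dataset
#'
#' Fits a probability forest (ranger) with `mtry = sqrt(p)` and unlimited
#' depth; the score of a record is the forest's class-probability estimate
#' for the positive class, in \[0, 1\]. Training is deterministic for a
#' fixed (features, labels, n_trees, seed) — two fits produce identical
#' scores on any probe set.
#'
#' @param features Wide feature tibble from [encode_dataset()] (its `label`
#'   column is ignored) or a plain numeric matrix.
#' @param labels True labels, one per row; both classes required.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param scheme Feature scheme name recorded in the bundle (taken from the
#'   feature tibble's attribute when present).
#' @param scale_set Scale set to record for prediction-time encoding.
#' @param decision_threshold Default Y/N threshold carried by the bundle.
#' @return A model bundle of class `exocargo_model`.
#' @export
train_forest <- function(features, labels, n_trees = 500, seed = 1,
                         scheme = NULL, scale_set = NULL,
                         decision_threshold = 0.5) {
  scheme <- scheme %||% attr(features, "scheme")
  if (is.data.frame(features)) features <- feature_matrix(features)
  labels <- as_binary_labels(labels)
  if (nrow(features) != length(labels)) abort("feature rows and labels differ in length")
  if (anyNA(features)) abort("feature matrix contains missing values")
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("need at least 2 examples of each class")
  }
  y <- factor(ifelse(labels, "positive", "negative"),
              levels = c("negative", "positive"))
  df <- as.data.frame(features)
  fit <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                        probability = TRUE, importance = "impurity",
                        seed = seed, num.threads = 1)
  structure(list(
    forest = fit,
    scheme = scheme,
    n_trees = as.integer(n_trees),
    seed = as.integer(seed),
    feature_names = colnames(features),
    scale_set = scale_set,
    scale_set_version = if (is.null(scale_set)) "builtin" else "custom",
    decision_threshold = decision_threshold,
    n_train_pos = sum(labels), n_train_neg = sum(!labels),
    package_version = as.character(packageVersion("exocargo"))
  ), class = "exocargo_model")
}

# score a feature matrix with a bundle -> positive-class probability
score_matrix <- function(bundle, features) {
  if (is.data.frame(features)) features <- feature_matrix(features)
  if (!identical(colnames(features), bundle$feature_names)) {
    abort("feature columns do not match the model's feature space")
  }
  p <- stats::predict(bundle$forest, data = as.data.frame(features),
                      num.threads = 1)$predictions
  unname(p[, "positive"])
}

#' Score protein records with a trained model
#'
#' Encodes each record under the bundle's feature scheme and returns the
#' forest's positive-class score plus the Y/N call at the decision
#' threshold (Y iff score >= threshold). Scores do not depend on record
#' order.
#'
#' @param bundle `exocargo_model` from [train_forest()] or [load_model()].
#' @param records Record tibble (`id`, `sequence`).
#' @param threshold Decision threshold; defaults to the bundle's.
#' @param scale_set Scale set for encoding; defaults to the bundle's, else
#'   the built-in set.
#' @return Tibble `id`, `score`, `call` (`"Y"`/`"N"`), in record order.
#' @export
predict_scores <- function(bundle, records, threshold = NULL, scale_set = NULL) {
  if (!inherits(bundle, "exocargo_model")) abort("bundle is not an exocargo_model")
  if (anyDuplicated(records$id)) abort("duplicate record ids in prediction batch")
  threshold <- threshold %||% bundle$decision_threshold
  scale_set <- scale_set %||% bundle$scale_set %||% aa_scale_set()
  feats <- encode_dataset(records, bundle$scheme, scale_set)
  score <- score_matrix(bundle, feats)
  tibble(id = records$id, score = score,
         call = ifelse(score >= threshold, "Y", "N"))
}

#' Repeated stratified k-fold cross-validation over a tree grid
#'
#' Encodes the dataset once (encodings are per-sequence, so no information
#' leaks across folds), then for each repeat draws a seeded stratified
#' partition into `n_folds` folds (class ratio preserved to within one
#' record per fold) and, for every tree count in the grid, trains on k-1
#' folds and evaluates SE, SP, ACC, MCC and AUC on the held-out fold.
#' Aggregates are the mean and standard deviation over the
#' `n_repeats * n_folds` fold-level values.
#'
#' @param records Labeled record tibble (`label` in positive/negative form).
#' @param config `exocargo_config` from [train_config()].
#' @param scale_set Scale set for encoding.
#' @return An `exocargo_cv` object: list with `folds` (per-cell metrics),
#'   `aggregate` (per scheme x n_trees mean/sd), `assignments` (repeat,
#'   fold, id) and `config`.
#' @export
cross_validate <- function(records, config = train_config(),
                           scale_set = aa_scale_set()) {
  if (!inherits(config, "exocargo_config")) abort("config must be an exocargo_config")
  labels <- as_binary_labels(records$label)
  if (min(sum(labels), sum(!labels)) < config$n_folds) {
    abort("each class needs at least n_folds members for stratified CV")
  }
  feats <- encode_dataset(records, config$scheme, scale_set)
  mat <- feature_matrix(feats)

  cells <- list(); assigns <- list()
  for (r in seq_len(config$n_repeats)) {
    fold_of <- stratified_folds(labels, config$n_folds,
                                seed = config$seed + 7919L * r)
    assigns[[r]] <- tibble(repeat_id = r, fold_id = fold_of, id = records$id)
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      for (ti in seq_along(config$tree_grid)) {
        nt <- config$tree_grid[ti]
        bundle <- train_forest(mat[train_idx, , drop = FALSE], labels[train_idx],
                               n_trees = nt,
                               seed = config$seed + 1000L * r + 10L * f + ti,
                               scheme = config$scheme)
        sc <- score_matrix(bundle, mat[test_idx, , drop = FALSE])
        cm <- confusion_counts(sc, labels[test_idx],
                               threshold = config$decision_threshold)
        met <- confusion_metrics(cm)
        cells[[length(cells) + 1]] <- dplyr::bind_cols(
          tibble(scheme = config$scheme, n_trees = nt,
                 repeat_id = r, fold_id = f),
          cm, met[, c("se", "sp", "acc_percent", "mcc")],
          tibble(auc = roc_auc(sc, labels[test_idx]),
                 n_test = length(test_idx)))
      }
    }
  }
  folds <- bind_rows(cells)
  structure(list(folds = folds, aggregate = aggregate_cv(folds),
                 assignments = bind_rows(assigns), config = config),
            class = "exocargo_cv")
}

stratified_folds <- function(labels, n_folds, seed) {
  fold_of <- integer(length(labels))
  withr_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cls))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold_of
}

aggregate_cv <- function(folds) {
  folds %>%
    group_by(.data$scheme, .data$n_trees) %>%
    summarise(
      acc_mean = mean(.data$acc_percent, na.rm = TRUE),
      acc_sd = sd(.data$acc_percent, na.rm = TRUE),
      auc_mean = mean(.data$auc, na.rm = TRUE),
      auc_sd = sd(.data$auc, na.rm = TRUE),
      mcc_mean = mean(.data$mcc, na.rm = TRUE),
      mcc_sd = sd(.data$mcc, na.rm = TRUE),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Sweep several feature schemes through cross-validation
#'
#' Runs [cross_validate()] once per scheme with otherwise identical
#' configuration and row-binds the results, mirroring the experiment layout
#' in which each encoding is swept over the tree grid.
#'
#' @param records Labeled record tibble.
#' @param schemes Character vector of scheme names.
#' @param config Base `exocargo_config`; its `scheme` field is overridden.
#' @param scale_set Scale set for encoding.
#' @return An `exocargo_cv` covering all schemes.
#' @export
cv_sweep <- function(records, schemes = FEATURE_SCHEMES,
                     config = train_config(), scale_set = aa_scale_set()) {
  runs <- lapply(schemes, function(s) {
    cfg <- config; cfg$scheme <- match_scheme(s)
    cross_validate(records, cfg, scale_set)
  })
  folds <- bind_rows(lapply(runs, `[[`, "folds"))
  structure(list(folds = folds, aggregate = aggregate_cv(folds),
                 assignments = runs[[1]]$assignments, config = config),
            class = "exocargo_cv")
}

#' Select the winning (scheme, tree count) cell from a CV result
#'
#' Returns the cell with the highest aggregate mean of the chosen
#' criterion. Ties break toward fewer trees, then toward the earlier scheme
#' in the fixed order PCP < AA < PCP_AA < DP < PCP_AA_DP.
#'
#' @param cv `exocargo_cv` object.
#' @param criterion `"ACC"`, `"AUC"` or `"MCC"`.
#' @return One-row tibble from the aggregate table.
#' @export
grid_select <- function(cv, criterion = c("ACC", "AUC", "MCC")) {
  criterion <- match.arg(criterion)
  agg <- cv$aggregate
  if (nrow(agg) == 0) abort("empty cross-validation result")
  col <- c(ACC = "acc_mean", AUC = "auc_mean", MCC = "mcc_mean")[[criterion]]
  agg %>%
    mutate(.scheme_rank = match(.data$scheme, FEATURE_SCHEMES)) %>%
    arrange(dplyr::desc(.data[[col]]), .data$n_trees, .data$.scheme_rank) %>%
    slice(1) %>%
    select(-".scheme_rank")
}

#' Persist / restore a trained model bundle
#'
#' The bundle is written as a single versioned RDS archive; loading
#' validates the format tag and version, so a truncated or foreign file is
#' an error rather than a silently broken model. A round-tripped bundle
#' produces scores identical to the original on any input.
#'
#' @param bundle `exocargo_model`.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly (save); the restored bundle (load).
#' @export
save_model <- function(bundle, path) {
  if (!inherits(bundle, "exocargo_model")) abort("bundle is not an exocargo_model")
  saveRDS(list(format = "exocargo_model", format_version = 1L,
               bundle = unclass(bundle)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort(paste0("cannot read model file: ",
                                                   conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "exocargo_model")) {
    abort("file is not an exocargo model bundle")
  }
  if (!identical(obj$format_version, 1L)) {
    abort(paste0("unsupported model bundle version: ", obj$format_version))
  }
  structure(obj$bundle, class = "exocargo_model")
}
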