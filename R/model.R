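#' Model configuration
#'
#' Settings for the nested cross-validated random-forest classifier of
#' ordinal impairment scores. Outer folds estimate generalization; an inner
#' cross-validation grid search on each outer training set picks the forest
#' hyperparameters, so the held-out fold never influences tuning.
#'
#' @param outer_folds,inner_folds Number of folds (both default 5).
#' @param num_trees,max_depth,min_node Hyperparameter grid vectors. A
#'   `max_depth` of 0 means unlimited depth.
#' @param seed Master seed; fixes fold assignment, tuning and forest fits.
#' @param grouping `"by_participant"` keeps all trials of a participant in
#'   one fold (no identity leakage across folds, the default since each
#'   participant contributes two trials); `"by_trial"` assigns trials
#'   independently.
#'
#' @return A list of class `model_config`.
#' @export
model_config <- function(outer_folds = 5, inner_folds = 5,
                         num_trees = c(100, 300, 500),
                         max_depth = c(0, 5, 10),
                         min_node = c(1, 3, 5),
                         seed = 1,
                         grouping = c("by_participant", "by_trial")) {
  stopifnot(outer_folds >= 2, inner_folds >= 2,
            length(num_trees) >= 1)
  structure(
    list(outer_folds = as.integer(outer_folds),
         inner_folds = as.integer(inner_folds),
         grid = expand.grid(num_trees = num_trees, max_depth = max_depth,
                            min_node = min_node, KEEP.OUT.ATTRS = FALSE),
         seed = as.integer(seed),
         grouping = match.arg(grouping)),
    class = "model_config"
  )
}

# Evaluate expr with a locally-set RNG seed, restoring global state after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Standardizer: per-feature mean and scale, fitted on training rows only.
# Zero-variance features get scale 1 so standardization is a no-op there.
fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sc <- apply(X, 2L, sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  list(mean = mu, scale = sc)
}

apply_standardizer <- function(std, X) {
  scale(X, center = std$mean, scale = std$scale)
}

# Deterministic fold assignment; with by_participant grouping, whole
# participants are dealt round-robin in shuffled order to balance fold sizes.
assign_folds <- function(ids, k, seed) {
  u <- unique(ids)
  with_local_seed(seed, {
    shuffled <- sample(u)
  })
  fold_of <- setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  unname(fold_of[ids])
}

rf_fit <- function(X, y, params, seed, importance = "none") {
  ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = params$num_trees,
    max.depth = if (params$max_depth == 0) NULL else params$max_depth,
    min.node.size = params$min_node,
    seed = seed, num.threads = 1,
    importance = importance,
    classification = TRUE
  )
}

rf_predict <- function(fit, X) {
  as.integer(as.character(
    predict(fit, data = as.data.frame(X), num.threads = 1)$predictions))
}

# Factor over the observed classes only (ranger rejects empty levels);
# predictions are mapped back to integers via their labels.
score_levels <- function(y) factor(y, levels = sort(unique(y)))

# Inner grid search: mean inner-CV accuracy per grid row; ties broken by
# grid order so selection is deterministic.
tune_inner <- function(X, y, groups, config, seed) {
  folds <- assign_folds(groups, config$inner_folds, seed)
  grid <- config$grid
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- 0L
    total <- 0L
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      std <- fit_standardizer(X[tr, , drop = FALSE])
      fit <- rf_fit(apply_standardizer(std, X[tr, , drop = FALSE]),
                    score_levels(y[tr]), grid[g, ], seed = seed + g)
      pred <- rf_predict(fit, apply_standardizer(std, X[!tr, , drop = FALSE]))
      hits <- hits + sum(pred == y[!tr])
      total <- total + sum(!tr)
    }
    acc[g] <- if (total > 0L) hits / total else 0
  }
  best <- which.max(acc)
  list(params = grid[best, , drop = FALSE], inner_accuracy = acc[best])
}

feature_matrix <- function(table) {
  cols <- feature_names()
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L) {
    abort(paste0("feature table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  as.matrix(table[, cols])
}

#' Nested cross-validated evaluation
#'
#' Splits the labelled feature table into `outer_folds` equal folds. For each
#' outer fold the remaining folds form the training set: an inner
#' cross-validation grid search there selects hyperparameters by accuracy,
#' the feature standardizer (remove mean, scale to unit variance) is fitted
#' on the training rows only, and a random forest refit on the whole training
#' set predicts the held-out fold. Every trial therefore receives exactly one
#' out-of-fold prediction.
#'
#' @param table Labelled feature table from [build_feature_table()]
#'   (24 feature columns plus `median_score`).
#' @param config A [model_config()].
#' @return An object of class `nested_cv` with elements `predictions`
#'   (tibble: `trial_id`, `participant_id`, `fold`, `predicted`,
#'   `median_score`), `fold_accuracy` (per-fold tibble with the chosen
#'   hyperparameters), `mean_accuracy`, and `instrumentation` (per fold: the
#'   training row indices and the fitted standardizer means, so leakage can
#'   be audited).
#' @export
nested_cv_evaluate <- function(table, config = model_config()) {
  stopifnot(nrow(table) >= config$outer_folds * 2)
  y <- table$median_score
  if (length(unique(y)) < 2L) abort("need at least two distinct labels")
  X <- feature_matrix(table)
  groups <- if (config$grouping == "by_participant") {
    table$participant_id
  } else {
    table$trial_id
  }
  folds <- assign_folds(groups, config$outer_folds, config$seed)

  pred <- integer(nrow(table))
  fold_rows <- list()
  instr <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) {
      warn(sprintf("outer fold %d: training set has a single class", f))
    }
    tuned <- tune_inner(X[tr, , drop = FALSE], y[tr], groups[tr], config,
                        seed = config$seed * 1000L + f)
    std <- fit_standardizer(X[tr, , drop = FALSE])
    fit <- rf_fit(apply_standardizer(std, X[tr, , drop = FALSE]),
                  score_levels(y[tr]), tuned$params,
                  seed = config$seed * 1000L + f)
    pred[!tr] <- rf_predict(fit, apply_standardizer(std, X[!tr, , drop = FALSE]))
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n_test = sum(!tr),
      accuracy = mean(pred[!tr] == y[!tr]),
      num_trees = tuned$params$num_trees,
      max_depth = tuned$params$max_depth,
      min_node = tuned$params$min_node,
      inner_accuracy = tuned$inner_accuracy
    )
    instr[[f]] <- list(fold = f, train_rows = which(tr),
                       standardizer_mean = std$mean,
                       standardizer_scale = std$scale)
  }
  fold_accuracy <- dplyr::bind_rows(fold_rows)
  structure(
    list(
      predictions = tibble::tibble(
        trial_id = table$trial_id,
        participant_id = table$participant_id,
        fold = folds,
        predicted = pred,
        median_score = y
      ),
      fold_accuracy = fold_accuracy,
      mean_accuracy = mean(fold_accuracy$accuracy),
      instrumentation = instr,
      config = config
    ),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf("<nested_cv> %d trials, %d outer folds, mean accuracy %.3f\n",
              nrow(x$predictions), nrow(x$fold_accuracy), x$mean_accuracy))
  print(x$fold_accuracy)
  invisible(x)
}

#' @method tidy nested_cv
#' @export
tidy.nested_cv <- function(x, ...) x$fold_accuracy

#' @method glance nested_cv
#' @export
glance.nested_cv <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$predictions),
    outer_folds = nrow(x$fold_accuracy),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = sd(x$fold_accuracy$accuracy)
  )
}

#' Fit the final model on all labelled trials
#'
#' Hyperparameters are chosen by an inner cross-validation over the full
#' table, then the standardizer and a random forest (with impurity variable
#' importance) are fitted on every row.
#'
#' @inheritParams nested_cv_evaluate
#' @return An object of class `arm_rf` with the fitted standardizer, forest,
#'   chosen hyperparameters and normalized feature importances.
#' @export
fit_final <- function(table, config = model_config()) {
  y <- table$median_score
  X <- feature_matrix(table)
  groups <- if (config$grouping == "by_participant") {
    table$participant_id
  } else {
    table$trial_id
  }
  tuned <- tune_inner(X, y, groups, config, seed = config$seed * 1000L)
  std <- fit_standardizer(X)
  fit <- rf_fit(apply_standardizer(std, X), score_levels(y), tuned$params,
                seed = config$seed, importance = "impurity")
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  structure(
    list(standardizer = std, forest = fit, params = tuned$params,
         features = feature_names(), importance = imp,
         version = "arm_rf/1"),
    class = "arm_rf"
  )
}

#' Predict ordinal scores with a fitted model
#'
#' @param object An `arm_rf` model from [fit_final()].
#' @param newdata Feature table containing the 24 feature columns.
#' @param ... Unused.
#' @return Tibble with `trial_id`, `participant_id` (when present in
#'   `newdata`) and integer `predicted` in 0-4.
#' @export
predict.arm_rf <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  out <- tibble::tibble(
    predicted = rf_predict(object$forest,
                           apply_standardizer(object$standardizer, X))
  )
  for (col in c("participant_id", "trial_id")) {
    if (col %in% names(newdata)) {
      out[[col]] <- newdata[[col]]
      out <- dplyr::relocate(out, dplyr::all_of(col), .before = 1L)
    }
  }
  out
}

#' @export
print.arm_rf <- function(x, ...) {
  cat(sprintf(
    "<arm_rf> %d trees, max depth %s, min node %d (%d features)\n",
    x$params$num_trees,
    if (x$params$max_depth == 0) "unlimited" else x$params$max_depth,
    x$params$min_node, length(x$features)))
  invisible(x)
}

#' @method tidy arm_rf
#' @export
tidy.arm_rf <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @method glance arm_rf
#' @export
glance.arm_rf <- function(x, ...) {
  tibble::tibble(
    num_trees = x$params$num_trees,
    max_depth = x$params$max_depth,
    min_node = x$params$min_node,
    oob_error = x$forest$prediction.error
  )
}

#' Save / load a fitted model
#'
#' The model file is a self-describing RDS carrying a format version tag.
#'
#' @param model An `arm_rf` object.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "arm_rf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "arm_rf") || !identical(model$version, "arm_rf/1")) {
    abort("not a recognised model file")
  }
  model
}

#' Monte-Carlo permutation null for classification accuracy
#'
#' Distribution of the accuracy between a fixed prediction vector and random
#' permutations of the reference labels -- the chance level implied by the
#' two marginal label distributions.
#'
#' @param pred,ref Integer score vectors of equal length.
#' @param n_perm Number of permutations (default 2000).
#' @param seed RNG seed.
#' @return List with `mean`, `sd` and the vector of permuted accuracies.
#' @export
permutation_null_accuracy <- function(pred, ref, n_perm = 2000, seed = 1) {
  stopifnot(length(pred) == length(ref))
  accs <- with_local_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(pred == sample(ref)), numeric(1))
  })
  list(mean = mean(accs), sd = sd(accs), samples = accs)
}
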