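#' Evaluation protocol configuration
#'
#' Settings for the repeated train-test evaluation protocol: by default 20
#' rounds of fresh 80:20 splits, the 6 top-ranked features, and a random
#' forest, with PD as the positive class.
#'
#' Splits are stratified by default: with a small imbalanced cohort an
#' unstratified 20% test set can easily contain a single class. Set
#' `stratified = FALSE` to restore plain random splits.
#'
#' @param n_runs Number of evaluation rounds (>= 1).
#' @param test_fraction Held-out fraction per round (in (0, 1)).
#' @param top_k Number of top-ranked features kept by default (<= 28).
#' @param model_family One of `"random_forest"`, `"decision_tree_regression"`,
#'   `"support_vector"`, `"multilayer_perceptron"`.
#' @param seed Integer seed; every round uses a seed derived from it.
#' @param stratified Stratify splits by class.
#' @param num_trees Trees per forest (ranking and random-forest fits).
#' @return A `pd_eval_config` object.
#' @export
eval_config <- function(n_runs = 20, test_fraction = 0.2, top_k = 6,
                        model_family = c("random_forest",
                                         "decision_tree_regression",
                                         "support_vector",
                                         "multilayer_perceptron"),
                        seed = 1, stratified = TRUE, num_trees = 500) {
  model_family <- rlang::arg_match(model_family)
  if (n_runs < 1) rlang::abort("`n_runs` must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("`test_fraction` must be in (0, 1)")
  }
  if (top_k < 1 || top_k > 28) rlang::abort("`top_k` must be in 1..28")
  structure(
    list(
      n_runs = as.integer(n_runs), test_fraction = test_fraction,
      top_k = as.integer(top_k), model_family = model_family,
      seed = as.integer(seed), stratified = isTRUE(stratified),
      num_trees = as.integer(num_trees), positive = "pd"
    ),
    class = "pd_eval_config"
  )
}

label_factor <- function(pd_status) {
  factor(ifelse(pd_status == 1, "pd", "control"), levels = c("control", "pd"))
}

feature_cols <- function(features) {
  setdiff(names(features), c("session_id", "pd_status"))
}

# median imputation; medians taken from `ref` (train set) if given
impute_median <- function(X, ref = NULL) {
  ref <- ref %||% X
  for (j in names(X)) {
    nas <- is.na(X[[j]])
    if (any(nas)) {
      med <- stats::median(ref[[j]], na.rm = TRUE)
      if (is.na(med)) rlang::abort(sprintf("feature '%s' is entirely missing", j))
      X[[j]][nas] <- med
    }
  }
  X
}

#' Rank features by extra-trees importance
#'
#' Fits an extremely randomized trees ensemble (random split thresholds, no
#' bootstrap) on the full feature matrix after median imputation, and ranks
#' features by impurity importance, normalized to sum to 1. Ties are broken
#' by registry order. By default the ranking uses all sessions, mirroring
#' the screening protocol; for a leakage-safe variant, rank inside each
#' train split yourself before calling [evaluate_features()].
#'
#' @param features Feature matrix from [features_to_matrix()] (must include
#'   `pd_status` with both classes, at least 2 sessions per class).
#' @param seed Integer seed for the ensemble.
#' @param num_trees Number of trees.
#' @return A `pd_feature_ranking`: tibble with `rank`, `feature`,
#'   `importance` (descending, sums to 1).
#' @export
rank_features <- function(features, seed = 1, num_trees = 500) {
  y <- label_factor(features$pd_status)
  if (length(unique(y)) < 2L) rlang::abort("both classes must be present to rank features")
  if (min(table(y)) < 2L) rlang::abort("need at least 2 sessions per class")
  X <- impute_median(dplyr::select(
    tibble::as_tibble(features), dplyr::all_of(feature_cols(features))
  ))
  fit <- ranger::ranger(
    x = as.data.frame(X), y = y,
    splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1,
    importance = "impurity", num.trees = num_trees, seed = seed
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(-imp, seq_along(imp))
  out <- tibble::tibble(
    rank = seq_along(imp),
    feature = names(imp)[ord],
    importance = unname(imp[ord])
  )
  class(out) <- c("pd_feature_ranking", class(out))
  out
}

#' Keep the top-k ranked features
#'
#' @param ranking A `pd_feature_ranking` from [rank_features()].
#' @param k Number of features to keep (1 <= k <= length of ranking).
#' @return Character vector of feature ids, ranking order preserved.
#' @export
select_top_k <- function(ranking, k = 6) {
  if (!inherits(ranking, "pd_feature_ranking")) {
    rlang::abort("`ranking` must come from rank_features()")
  }
  if (k < 1) rlang::abort("`k` must be at least 1 (an empty model is forbidden)")
  if (k > nrow(ranking)) {
    rlang::abort(sprintf("`k` = %d exceeds the %d ranked features", k, nrow(ranking)))
  }
  ranking$feature[seq_len(k)]
}

# classification metrics at threshold 0.5, PD positive
compute_metrics <- function(y, score) {
  pred <- factor(ifelse(score >= 0.5, "pd", "control"), levels = c("control", "pd"))
  tp <- sum(pred == "pd" & y == "pd")
  fp <- sum(pred == "pd" & y == "control")
  fn <- sum(pred == "control" & y == "pd")
  recalls <- c(
    pd = if (any(y == "pd")) tp / sum(y == "pd") else NA_real_,
    control = if (any(y == "control")) sum(pred == "control" & y == "control") / sum(y == "control") else NA_real_
  )
  bal_acc <- mean(recalls, na.rm = TRUE)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(y)) == 2L) {
    as.numeric(pROC::auc(
      response = y, predictor = score,
      levels = c("control", "pd"), direction = "<", quiet = TRUE
    ))
  } else {
    rlang::warn("test split contains a single class; AUC recorded as NA")
    NA_real_
  }
  c(auc = auc, balanced_accuracy = bal_acc, f1 = f1)
}

fit_and_score <- function(family, X_train, y_train, X_test, seed, num_trees) {
  set.seed(seed)
  switch(family,
    random_forest = {
      fit <- ranger::ranger(
        x = as.data.frame(X_train), y = y_train, probability = TRUE,
        num.trees = num_trees, seed = seed
      )
      stats::predict(fit, as.data.frame(X_test))$predictions[, "pd"]
    },
    decision_tree_regression = {
      df <- data.frame(.y = as.numeric(y_train == "pd"), X_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "anova")
      as.numeric(stats::predict(fit, data.frame(X_test)))
    },
    support_vector = {
      keep <- vapply(X_train, function(v) stats::sd(v) > 0, logical(1))
      if (!any(keep)) keep[1] <- TRUE
      fit <- suppressWarnings(e1071::svm(
        x = as.data.frame(X_train[keep]), y = y_train, probability = TRUE
      ))
      pr <- stats::predict(fit, as.data.frame(X_test[keep]), probability = TRUE)
      attr(pr, "probabilities")[, "pd"]
    },
    multilayer_perceptron = {
      mu <- vapply(X_train, mean, numeric(1))
      sg <- vapply(X_train, stats::sd, numeric(1))
      sg[sg == 0] <- 1
      scl <- function(X) sweep(sweep(as.matrix(X), 2, mu), 2, sg, "/")
      fit <- nnet::nnet(
        x = scl(X_train), y = as.numeric(y_train == "pd"),
        size = 8, decay = 0.01, maxit = 300, entropy = TRUE, trace = FALSE
      )
      as.numeric(stats::predict(fit, scl(X_test)))
    }
  )
}

stratified_split <- function(y, test_fraction, stratified) {
  n <- length(y)
  if (stratified) {
    unlist(lapply(split(seq_len(n), y), function(idx) {
      sample(idx, max(1L, round(length(idx) * test_fraction)))
    }), use.names = FALSE)
  } else {
    sample(n, max(1L, round(n * test_fraction)))
  }
}

#' Repeated train-test evaluation of a feature subset
#'
#' For each round: draw a fresh (stratified) 80:20 split from a
#' round-specific derived seed, impute missing values by train-set medians,
#' fit the configured model family, and score the held-out set. Records AUC
#' (from continuous scores), balanced accuracy and F1 (PD positive,
#' threshold 0.5; the regression tree's continuous output is thresholded the
#' same way), then aggregates mean and SD across rounds. A single-class
#' test split (possible when unstratified) records an NA AUC with a warning,
#' never a crash.
#'
#' @param features Feature matrix from [features_to_matrix()] (or any tibble
#'   with `pd_status` and feature columns).
#' @param feature_subset Character vector of feature columns to use;
#'   `NULL` uses all feature columns.
#' @param config An [eval_config()].
#' @return A `pd_eval_report` with per-run metrics (`$runs`), aggregates
#'   (`$summary`), the feature subset and a config echo. See
#'   [tidy.pd_eval_report()] and [glance.pd_eval_report()].
#' @export
evaluate_features <- function(features, feature_subset = NULL,
                              config = eval_config()) {
  stopifnot(inherits(config, "pd_eval_config"))
  feature_subset <- feature_subset %||% feature_cols(features)
  if (length(feature_subset) == 0) rlang::abort("`feature_subset` must be non-empty")
  miss <- setdiff(feature_subset, names(features))
  if (length(miss) > 0) {
    rlang::abort(paste0("feature(s) not in matrix: ", paste(miss, collapse = ", ")))
  }
  y <- label_factor(features$pd_status)
  if (length(unique(y)) < 2L) rlang::abort("both classes must be present")
  X <- dplyr::select(tibble::as_tibble(features), dplyr::all_of(feature_subset))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$n_runs)

  runs <- purrr::map_dfr(seq_len(config$n_runs), function(r) {
    set.seed(run_seeds[r])
    test_idx <- stratified_split(y, config$test_fraction, config$stratified)
    X_train <- impute_median(X[-test_idx, , drop = FALSE])
    X_test <- impute_median(X[test_idx, , drop = FALSE], ref = X[-test_idx, , drop = FALSE])
    y_train <- y[-test_idx]
    score <- if (length(unique(y_train)) < 2L) {
      rlang::warn("train split contains a single class; scoring constantly")
      rep(as.numeric(y_train[1] == "pd"), length(test_idx))
    } else {
      fit_and_score(
        config$model_family, X_train, y_train, X_test,
        seed = run_seeds[r], num_trees = config$num_trees
      )
    }
    m <- compute_metrics(y[test_idx], score)
    tibble::tibble(
      run = r, n_test = length(test_idx),
      auc = m[["auc"]], balanced_accuracy = m[["balanced_accuracy"]],
      f1 = m[["f1"]]
    )
  })
  summary <- tidyr::pivot_longer(
    runs, c("auc", "balanced_accuracy", "f1"),
    names_to = "metric", values_to = "value"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(summary, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  structure(
    list(runs = runs, summary = summary, features = feature_subset,
         config = config),
    class = "pd_eval_report"
  )
}

#' @export
print.pd_eval_report <- function(x, ...) {
  cat(sprintf("<pd_eval_report> %s | %d features | %d runs (%.0f:%.0f split%s)\n",
              x$config$model_family, length(x$features), x$config$n_runs,
              100 * (1 - x$config$test_fraction), 100 * x$config$test_fraction,
              if (x$config$stratified) ", stratified" else ""))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-18s %.4f (SD %.4f)\n",
                x$summary$metric[i], x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Tidy per-run metrics of an evaluation report
#'
#' @param x A `pd_eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per run: `run`, `n_test`, `auc`,
#'   `balanced_accuracy`, `f1`.
#' @method tidy pd_eval_report
#' @export
tidy.pd_eval_report <- function(x, ...) {
  x$runs
}

#' One-row summary of an evaluation report
#'
#' @param x A `pd_eval_report`.
#' @param ... Unused.
#' @return One-row tibble with the model family, run count, feature count,
#'   and mean/SD of AUC, balanced accuracy and F1.
#' @method glance pd_eval_report
#' @export
glance.pd_eval_report <- function(x, ...) {
  s <- x$summary
  g <- function(m, col) s[[col]][s$metric == m]
  tibble::tibble(
    model_family = x$config$model_family,
    n_features = length(x$features),
    n_runs = x$config$n_runs,
    mean_auc = g("auc", "mean"), sd_auc = g("auc", "sd"),
    mean_balanced_accuracy = g("balanced_accuracy", "mean"),
    sd_balanced_accuracy = g("balanced_accuracy", "sd"),
    mean_f1 = g("f1", "mean"), sd_f1 = g("f1", "sd")
  )
}

#' Evaluate every feature on its own
#'
#' Runs the repeated-split protocol once per single-feature model and
#' returns one summary row per feature, in registry order — the shape of a
#' single-feature comparison table.
#'
#' @inheritParams evaluate_features
#' @return Tibble with `feature`, `label`, and mean/SD of AUC, balanced
#'   accuracy and F1 per feature.
#' @export
single_feature_sweep <- function(features, config = eval_config()) {
  reg <- feature_registry()
  ids <- intersect(reg$id, feature_cols(features))
  purrr::map_dfr(ids, function(id) {
    rep <- evaluate_features(features, feature_subset = id, config = config)
    dplyr::bind_cols(
      tibble::tibble(feature = id, label = reg$label[reg$id == id]),
      dplyr::select(glance(rep), -"model_family", -"n_features", -"n_runs")
    )
  })
}

#' Run the full screening protocol
#'
#' Rank all features by extra-trees importance, keep the top `config$top_k`,
#' and evaluate them with the repeated-split protocol.
#'
#' @inheritParams evaluate_features
#' @return List with `ranking` (from [rank_features()]), `selected`
#'   (character vector) and `report` (a `pd_eval_report`).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(default_cohort_config(n_pd = 10, n_control = 10, seed = 1))
#' res <- screening_protocol(features_to_matrix(cohort),
#'                           config = eval_config(n_runs = 5))
#' glance(res$report)
#' }
screening_protocol <- function(features, config = eval_config()) {
  ranking <- rank_features(features, seed = config$seed,
                           num_trees = config$num_trees)
  selected <- select_top_k(ranking, config$top_k)
  report <- evaluate_features(features, feature_subset = selected,
                              config = config)
  list(ranking = ranking, selected = selected, report = report)
}
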