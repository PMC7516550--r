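#' Boosted-tree classifier configuration
#'
#' Defaults: 200 boosting rounds, learning rate 0.1, maximum depth 6, L2
#' regularization 1, gain importance normalized to sum 1, single-threaded for
#' determinism. The objective is chosen from the number of classes at fit
#' time unless forced.
#'
#' @param n_trees Number of boosting rounds (K).
#' @param learning_rate Shrinkage per round.
#' @param max_depth Maximum tree depth.
#' @param reg_lambda L2 regularization on leaf weights.
#' @param max_leaves Leaf-count cap per tree (0 = no cap).
#' @param seed Integer seed passed to the booster.
#' @param objective `"auto"`, `"binary"` or `"multiclass"`.
#' @param nthread Threads used by the booster (1 keeps fits reproducible).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 200L, learning_rate = 0.1,
                              max_depth = 6L, reg_lambda = 1,
                              max_leaves = 0L, seed = 1L,
                              objective = c("auto", "binary", "multiclass"),
                              nthread = 1L) {
  stopifnot(n_trees >= 1, reg_lambda >= 0, learning_rate > 0, max_depth >= 1)
  objective <- arg_match(objective)
  structure(
    list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
         max_depth = as.integer(max_depth), reg_lambda = reg_lambda,
         max_leaves = as.integer(max_leaves), seed = as.integer(seed),
         objective = objective, nthread = as.integer(nthread)),
    class = "classifier_config"
  )
}

feature_matrix <- function(table) {
  meta <- intersect(c("segment_id", "label"), names(table))
  feats <- setdiff(names(table), meta)
  m <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit the gradient-boosted seizure classifier
#'
#' Trains an XGBoost model on a feature table (rows = segments, columns =
#' features, plus a `label` column). Training is deterministic under a fixed
#' seed and single-threaded booster. Non-finite feature values are left to
#' the booster's native missing-value handling.
#'
#' @param table Feature-table tibble with a `label` column.
#' @param cfg A [classifier_config()].
#' @return A `seizure_model`: list with the fitted booster, feature names,
#'   class levels, and config.
#' @export
fit_classifier <- function(table, cfg = classifier_config()) {
  labels <- factor(table$label)
  if (nlevels(labels) < 2) abort("training data must contain at least 2 classes.")
  m <- feature_matrix(table)
  m[!is.finite(m)] <- NA
  y <- as.integer(labels) - 1L
  n_class <- nlevels(labels)
  objective <- switch(cfg$objective,
    auto = if (n_class == 2) "binary" else "multiclass",
    cfg$objective
  )
  params <- list(
    max_depth = cfg$max_depth, eta = cfg$learning_rate,
    lambda = cfg$reg_lambda, nthread = cfg$nthread, seed = cfg$seed
  )
  if (cfg$max_leaves > 0) params$max_leaves <- cfg$max_leaves
  if (objective == "binary") {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softmax"
    params$num_class <- n_class
  }
  dtrain <- xgboost::xgb.DMatrix(m, label = y, nthread = cfg$nthread)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = cfg$n_trees, verbose = 0)
  structure(
    list(booster = booster, features = colnames(m), classes = levels(labels),
         objective = objective, config = cfg),
    class = "seizure_model"
  )
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("<seizure_model: %s, %d features, classes: %s>\n",
              x$objective, length(x$features), paste(x$classes, collapse = " / ")))
  invisible(x)
}

#' Predict class labels for a feature table
#'
#' @param object A `seizure_model`.
#' @param newdata Feature-table tibble (extra columns beyond the model's
#'   features are ignored; the model's feature order is enforced).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.seizure_model <- function(object, newdata, ...) {
  m <- feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("newdata lacks %d model features (first: %s)",
                  length(missing), missing[1]))
  }
  m <- m[, object$features, drop = FALSE]
  m[!is.finite(m)] <- NA
  p <- predict(object$booster, xgboost::xgb.DMatrix(m, nthread = object$config$nthread))
  if (object$objective == "binary") {
    object$classes[as.integer(p > 0.5) + 1L]
  } else {
    object$classes[as.integer(p) + 1L]
  }
}

#' Per-feature importance ranking
#'
#' Gain importance (total loss reduction attributed to splits on each
#' feature) normalized to sum 1 across all features; features the booster
#' never used score 0. Ties are broken lexicographically so the ordering is
#' stable across runs.
#'
#' @param model A `seizure_model`.
#' @return A tibble `(feature, score)` in descending score order.
#' @export
importance_ranking <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  scores <- setNames(rep(0, length(model$features)), model$features)
  scores[imp$Feature] <- imp$Gain
  total <- sum(scores)
  if (total > 0) scores <- scores / total
  tb <- tibble(feature = names(scores), score = unname(scores))
  arrange(tb, desc(.data$score), .data$feature)
}

#' Threshold-prune features by importance score
#'
#' Keeps features whose normalized importance score is at least `threshold`
#' (default 0.001), in descending-score order. Raising the threshold never
#' adds a feature.
#'
#' @param ranking Importance tibble from [importance_ranking()].
#' @param threshold Minimum normalized score to keep (inclusive).
#' @return Character vector of retained feature names.
#' @export
select_features <- function(ranking, threshold = 0.001) {
  keep <- ranking$feature[ranking$score >= threshold]
  if (length(keep) == 0) {
    abort(sprintf(
      "no feature reaches importance %g; lower the selection threshold.",
      threshold
    ))
  }
  keep
}

#' The n most important features, annotated
#'
#' @param ranking Importance tibble from [importance_ranking()].
#' @param n Number of rows (default 20).
#' @return A tibble `(name, score, component, feature, domain)` in descending
#'   score order, ties lexicographic.
#' @export
top_features <- function(ranking, n = 20) {
  if (n > nrow(ranking)) abort("`n` exceeds the number of ranked features.")
  top <- head(ranking, n)
  parsed <- parse_feature_names(top$feature)
  tibble(name = top$feature, score = top$score,
         component = parsed$component, feature = parsed$feature,
         domain = parsed$domain)
}

#' Confusion counts
#'
#' @param labels True class labels.
#' @param predictions Predicted class labels (classes must all appear in the
#'   label set).
#' @param positive The positive class (default `"seizure"` when present,
#'   otherwise the first label level).
#' @return A named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion <- function(labels, predictions, positive = NULL) {
  if (length(labels) != length(predictions)) {
    abort("labels and predictions must have equal length.")
  }
  lv <- unique(as.character(labels))
  bad <- setdiff(unique(as.character(predictions)), lv)
  if (length(bad) > 0) {
    abort(sprintf("predictions contain unseen class '%s'.", bad[1]))
  }
  if (is.null(positive)) positive <- if ("seizure" %in% lv) "seizure" else lv[1]
  lp <- labels == positive
  pp <- predictions == positive
  c(TP = sum(lp & pp), FP = sum(!lp & pp), TN = sum(!lp & !pp), FN = sum(lp & !pp))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `ACC = (TP+TN)/total`, each as a
#' percentage on `[0, 100]`. A metric with a zero denominator is returned as
#' `NA`.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN` (as from
#'   [confusion()]).
#' @return Named numeric vector `c(SEN, SPE, ACC)` in percent.
#' @export
sen_spe_acc <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(
    SEN = pct(tp, tp + fn),
    SPE = pct(tn, tn + fp),
    ACC = pct(tp + tn, tp + tn + fp + fn)
  )
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      if (length(ix) < k) {
        abort(sprintf("class '%s' has fewer members (%d) than folds (%d).",
                      cl, length(ix), k))
      }
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
  })
  fold
}

#' Cross-validated evaluation with importance-based feature selection
#'
#' Stratified k-fold cross-validation of the full
#' fit-rank-select-refit-predict cycle. By default feature selection is
#' refit inside each training fold (no information leaks from the test
#' fold); `global_selection = TRUE` instead selects once on the full table
#' before splitting, the optimistic reading some studies use. Within a fold,
#' if no feature reaches the threshold the fold falls back to all features
#' (with a warning) rather than failing the whole evaluation.
#'
#' For two-class problems SEN/SPE/ACC are reported per fold; for three or
#' more classes ACC is the headline metric and SEN/SPE are `NA` in the fold
#' table, with one-vs-rest per-class values in `$per_class`.
#'
#' @param table Feature-table tibble with a `label` column.
#' @param cfg A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the stratified fold shuffle.
#' @param threshold Importance-selection threshold (see [select_features()]).
#' @param global_selection Select once on the whole table instead of per
#'   fold.
#' @param positive Positive class for SEN/SPE (default `"seizure"` when
#'   present).
#' @return A `seizure_cv` object: `folds` tibble (per-fold SEN/SPE/ACC in %,
#'   n_selected), `summary` tibble (mean, sd per metric), `per_class`
#'   one-vs-rest metrics, `k`, `wall_time_s`, and the final all-data
#'   importance ranking.
#' @export
cross_validate <- function(table, cfg = classifier_config(), k = 10,
                           seed = 1L, threshold = 0.001,
                           global_selection = FALSE, positive = NULL) {
  t0 <- proc.time()[["elapsed"]]
  labels <- as.character(table$label)
  classes <- sort(unique(labels))
  if (is.null(positive)) positive <- if ("seizure" %in% classes) "seizure" else classes[1]
  fold <- stratified_folds(labels, k, seed)
  feats <- setdiff(names(table), c("segment_id", "label"))

  global_keep <- NULL
  if (global_selection) {
    full_rank <- importance_ranking(fit_classifier(table, cfg))
    global_keep <- tryCatch(select_features(full_rank, threshold),
                            error = function(e) feats)
  }

  fold_rows <- vector("list", k)
  all_true <- all_pred <- character(0)
  for (f in seq_len(k)) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    keep <- if (global_selection) {
      global_keep
    } else {
      ranker <- fit_classifier(train, cfg)
      rank_f <- importance_ranking(ranker)
      rm(ranker)
      tryCatch(select_features(rank_f, threshold), error = function(e) {
        warn(sprintf("fold %d: no feature reached the threshold; using all features.", f))
        feats
      })
    }
    model <- fit_classifier(train[, c("label", keep)], cfg)
    pred <- predict(model, test)
    rm(model)
    gc(verbose = FALSE) # release booster handles eagerly across many folds
    truth <- as.character(test$label)
    all_true <- c(all_true, truth)
    all_pred <- c(all_pred, pred)
    acc <- 100 * mean(pred == truth)
    if (length(classes) == 2) {
      met <- sen_spe_acc(confusion(truth, pred, positive = positive))
    } else {
      met <- c(SEN = NA_real_, SPE = NA_real_, ACC = acc)
    }
    fold_rows[[f]] <- tibble(fold = f, SEN = met[["SEN"]], SPE = met[["SPE"]],
                             ACC = met[["ACC"]], n_selected = length(keep))
  }
  folds <- bind_rows(fold_rows)
  summary <- tidyr::pivot_longer(folds, c("SEN", "SPE", "ACC"),
                                 names_to = "metric", values_to = "value")
  summary <- summarise(group_by(summary, .data$metric),
                       mean = mean(.data$value), sd = sd(.data$value),
                       .groups = "drop")
  summary <- summary[match(c("SEN", "SPE", "ACC"), summary$metric), ]

  per_class <- bind_rows(lapply(classes, function(cl) {
    met <- sen_spe_acc(confusion(all_true, all_pred, positive = cl))
    tibble(class = cl, SEN = met[["SEN"]], SPE = met[["SPE"]], ACC = met[["ACC"]])
  }))

  structure(
    list(folds = folds, summary = summary, per_class = per_class, k = k,
         positive = positive, threshold = threshold,
         global_selection = global_selection, seed = seed,
         wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "seizure_cv"
  )
}

#' @export
print.seizure_cv <- function(x, ...) {
  cat(sprintf("<seizure_cv: %d-fold stratified cross-validation (%.1f s)>\n",
              x$k, x$wall_time_s))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %s\n", s$metric[i],
                if (is.na(s$mean[i])) "-" else
                  sprintf("%.2f +/- %.2f", s$mean[i], s$sd[i])))
  }
  invisible(x)
}

#' @export
tidy.seizure_cv <- function(x, ...) x$folds

#' @export
glance.seizure_cv <- function(x, ...) {
  s <- x$summary
  tibble(
    k = x$k,
    sen_mean = s$mean[s$metric == "SEN"], sen_sd = s$sd[s$metric == "SEN"],
    spe_mean = s$mean[s$metric == "SPE"], spe_sd = s$sd[s$metric == "SPE"],
    acc_mean = s$mean[s$metric == "ACC"], acc_sd = s$sd[s$metric == "ACC"],
    wall_time_s = x$wall_time_s
  )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `seizure_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seizure_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("SEN", "SPE", "ACC"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   group = .data$metric, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold", y = "percent",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to JSON and a text table
#'
#' @param cv A `seizure_cv`.
#' @param path Output path; `.json` holds the machine-readable report and a
#'   sibling `.txt` a human-readable table (SEN, SPE, ACC, Time).
#' @export
write_report <- function(cv, path) {
  obj <- list(
    k = cv$k, positive = cv$positive, threshold = cv$threshold,
    folds = cv$folds, summary = cv$summary, per_class = cv$per_class,
    wall_time_s = cv$wall_time_s
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  txt <- sub("\\.json$", ".txt", path)
  s <- cv$summary
  fmt <- function(metric) {
    i <- which(s$metric == metric)
    if (is.na(s$mean[i])) "-" else sprintf("%.2f +/- %.2f", s$mean[i], s$sd[i])
  }
  writeLines(c(
    sprintf("%-6s %-20s %-20s %-20s %s", "k", "SEN", "SPE", "ACC", "Time"),
    sprintf("%-6d %-20s %-20s %-20s %.1fs", cv$k, fmt("SEN"), fmt("SPE"),
            fmt("ACC"), cv$wall_time_s)
  ), txt)
  invisible(path)
}
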