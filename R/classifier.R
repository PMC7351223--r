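#' Classifier protocol parameters
#'
#' The repeated-shuffle protocol: 50 random full-data shuffles, each split
#' 75:25 into train and test (no stratification), standardization fitted on
#' the training split only, one-vs-rest L1-regularized logistic regression
#' with the regularization strength chosen by internal 3-fold
#' cross-validation, and a 1000-tree random forest. Important features must
#' be used (nonzero L1 coefficient) in at least 40 of the 50 L1-LR models
#' and have mean normalized RF importance above 0.005.
#'
#' @param n_shuffles number of repeated shuffles.
#' @param train_frac training fraction of day-samples.
#' @param rf_trees trees per random forest.
#' @param cv_folds internal CV folds for the L1-LR regularization path.
#' @param lambda_grid decreasing L1 penalty grid searched by the internal CV.
#' @param importance_min_models L1-LR persistence threshold (at least).
#' @param rf_importance_min mean RF importance threshold (strictly greater).
#' @param seed master seed; per-shuffle seeds derive from it.
#' @return List of class `ml_params`.
#' @export
ml_params <- function(n_shuffles = 50, train_frac = 0.75, rf_trees = 1000,
                      cv_folds = 3,
                      lambda_grid = 10^seq(1, -4, length.out = 40),
                      importance_min_models = 40, rf_importance_min = 0.005,
                      seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1,
            importance_min_models <= n_shuffles)
  structure(list(n_shuffles = n_shuffles, train_frac = train_frac,
                 rf_trees = rf_trees, cv_folds = cv_folds,
                 lambda_grid = lambda_grid,
                 importance_min_models = importance_min_models,
                 rf_importance_min = rf_importance_min, seed = seed),
            class = "ml_params")
}

#' Assemble single-day feature profiles from per-building tables
#'
#' Each day-sample becomes one observation vector of all feature log2
#' intensities, labeled by building.
#'
#' @param tables named list of per-building log2 `feature_table`s
#'   (replicates averaged; identical feature universe).
#' @return List: `x` (day-samples x features matrix), `y` (building labels),
#'   `day` (dates), `weekday` (logical).
#' @export
build_day_profiles <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- tables[[1]]$features$feature_id
  parts <- lapply(names(tables), function(b) {
    t <- tables[[b]]
    if (!identical(t$features$feature_id, ids)) {
      stop("feature universes differ across buildings")
    }
    m <- day_matrix(t)
    list(x = t(m), y = rep(b, ncol(m)), day = as.Date(colnames(m)))
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  day <- as.Date(unlist(lapply(parts, function(p) as.character(p$day))))
  list(x = x, y = unlist(lapply(parts, `[[`, "y")), day = day,
       weekday = is_weekday(day))
}

standardize_fit <- function(xtr) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, function(v) sqrt(mean((v - mean(v))^2)))
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mean, "-"), 2, sc$sd, "/")
}

ovr_auc <- function(y_true, class, score) {
  is_pos <- y_true == class
  if (!any(is_pos) || all(is_pos)) return(NA_real_)
  r <- pROC::roc(response = is_pos, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Train and evaluate building classifiers on single-day profiles
#'
#' For each shuffle: permute the day-samples, split `train_frac`:rest,
#' standardize on the training split, fit one-vs-rest L1-LR (regularization
#' chosen by internal cross-validation on the training split) and a random
#' forest, and compute the held-out one-vs-rest ROC AUC per class. A class
#' absent from a test split gives a missing (not zero) AUC for that shuffle.
#'
#' @param x day-samples x features matrix (log2 intensities).
#' @param y class label per row (>= 2 classes).
#' @param params an [ml_params()].
#' @return List of class `classifier_report`: `lr_auc` and `rf_auc`
#'   (shuffle x class matrices), `lr_auc_mean`, `lr_auc_sd`, `rf_auc_mean`,
#'   `rf_auc_sd` (across shuffles of the per-shuffle class-mean AUC),
#'   `importance` data.frame (feature, lr_nonzero_count,
#'   rf_mean_importance), `params`.
#' @export
train_evaluate <- function(x, y, params = ml_params()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 label classes")
  n <- nrow(x)
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(p))
  lr_auc <- matrix(NA_real_, params$n_shuffles, length(classes),
                   dimnames = list(NULL, classes))
  rf_auc <- lr_auc
  lr_used <- matrix(FALSE, params$n_shuffles, p)
  rf_imp <- matrix(NA_real_, params$n_shuffles, p)
  for (s in seq_len(params$n_shuffles)) {
    set.seed((params$seed + 1000003L * s) %% .Machine$integer.max)
    idx <- sample.int(n)
    n_tr <- round(params$train_frac * n)
    tr <- idx[seq_len(n_tr)]
    te <- idx[(n_tr + 1):n]
    if (length(unique(y[tr])) < 2) next
    sc <- standardize_fit(x[tr, , drop = FALSE])
    xtr <- standardize_apply(x[tr, , drop = FALSE], sc)
    xte <- standardize_apply(x[te, , drop = FALSE], sc)
    used_s <- rep(FALSE, p)
    for (cl in classes) {
      ytr <- as.numeric(y[tr] == cl)
      if (length(unique(ytr)) < 2) next
      nf <- min(params$cv_folds, min(table(ytr)))
      fit <- tryCatch(
        suppressWarnings(
          glmnet::cv.glmnet(xtr, ytr, family = "binomial", alpha = 1,
                            nfolds = max(nf, 3), lambda = params$lambda_grid,
                            standardize = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      score <- as.numeric(stats::predict(fit, newx = xte, s = "lambda.min",
                                         type = "response"))
      lr_auc[s, cl] <- ovr_auc(y[te], cl, score)
      cf <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
      used_s <- used_s | (cf != 0)
    }
    lr_used[s, ] <- used_s
    rf <- randomForest::randomForest(xtr, factor(y[tr], levels = classes),
                                     ntree = params$rf_trees,
                                     importance = FALSE)
    prob <- stats::predict(rf, xte, type = "prob")
    for (cl in intersect(classes, colnames(prob))) {
      rf_auc[s, cl] <- ovr_auc(y[te], cl, prob[, cl])
    }
    gi <- randomForest::importance(rf, type = 2)[, 1]
    rf_imp[s, ] <- if (sum(gi) > 0) gi / sum(gi) else gi
  }
  shuffle_mean <- function(m) rowMeans(m, na.rm = TRUE)
  lr_overall <- shuffle_mean(lr_auc)
  rf_overall <- shuffle_mean(rf_auc)
  structure(list(
    classes = classes,
    lr_auc = lr_auc, rf_auc = rf_auc,
    lr_auc_mean = mean(lr_overall, na.rm = TRUE),
    lr_auc_sd = stats::sd(lr_overall[!is.na(lr_overall)]),
    rf_auc_mean = mean(rf_overall, na.rm = TRUE),
    rf_auc_sd = stats::sd(rf_overall[!is.na(rf_overall)]),
    importance = data.frame(
      feature = feats,
      lr_nonzero_count = colSums(lr_used),
      rf_mean_importance = colMeans(rf_imp, na.rm = TRUE)),
    params = params), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: %d shuffles, classes: %s\n",
              nrow(x$lr_auc), paste(x$classes, collapse = ", ")))
  cat(sprintf("  L1-LR AUC %.3f +/- %.3f; RF AUC %.3f +/- %.3f\n",
              x$lr_auc_mean, x$lr_auc_sd, x$rf_auc_mean, x$rf_auc_sd))
  invisible(x)
}

#' Extract important features from a classifier report
#'
#' Dual criterion: nonzero L1-LR coefficient in at least
#' `importance_min_models` of the shuffled models AND mean normalized RF
#' importance strictly greater than `rf_importance_min`.
#'
#' @param report a `classifier_report`.
#' @param params an [ml_params()] (thresholds).
#' @return Character vector of selected feature ids; the report's
#'   `importance` table with a `selected` column as attribute `"table"`.
#' @export
extract_important_features <- function(report, params = report$params) {
  imp <- report$importance
  imp$selected <- imp$lr_nonzero_count >= params$importance_min_models &
    imp$rf_mean_importance > params$rf_importance_min
  out <- imp$feature[imp$selected]
  attr(out, "table") <- imp
  out
}

#' Weekday/weekend classification for one building
#'
#' Same shuffled-split protocol with binary weekday/weekend labels built
#' from the day-of-week of each day-sample.
#'
#' @param table a single-building log2 `feature_table`, replicates averaged.
#' @param params an [ml_params()].
#' @return A `classifier_report` with classes `weekday`/`weekend`.
#' @export
weekday_weekend_classifier <- function(table, params = ml_params()) {
  stopifnot(inherits(table, "feature_table"))
  m <- day_matrix(table)
  y <- ifelse(is_weekday(as.Date(colnames(m))), "weekday", "weekend")
  if (length(unique(y)) < 2) stop("need both weekday and weekend samples")
  train_evaluate(t(m), y, params)
}
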