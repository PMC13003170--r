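# Grouped cross-validation, per-fold preprocessing hygiene, the four
# learners with seeded hyperparameter search, and evaluation metrics.

ALGORITHMS <- c("decision_tree", "regularized_lr", "random_forest",
                "boosted_trees")

#' Model specification
#'
#' @param algorithm One of `"decision_tree"`, `"regularized_lr"`,
#'   `"random_forest"`, `"boosted_trees"`.
#' @param task `"classification"` or `"regression"`.
#' @param params Optional named list of fixed hyperparameters; when
#'   `NULL` the search starts from the algorithm's defaults.
#' @param budget Number of hyperparameter configurations to evaluate
#'   (default 25; `1` evaluates the defaults only).
#' @param seed Integer seed controlling the search and all stochastic
#'   fits.
#' @return A `model_spec` list.
#' @export
model_spec <- function(algorithm, task = c("classification", "regression"),
                       params = NULL, budget = 25, seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  task <- match.arg(task)
  stopifnot(budget >= 1)
  structure(list(algorithm = algorithm, task = task, params = params,
                 budget = budget, seed = seed),
            class = "model_spec")
}

#' Homoeolog-grouped cross-validation plan
#'
#' Validation folds are the homoeolog groups of the layout (nine
#' genome-wide) or single chromosomes for a one-subgenome model.  Row
#' order is shuffled within chromosomes under the seed so models cannot
#' exploit positional ordering; fold membership itself is deterministic.
#'
#' @param table A `feature_table` (rows carry `chrom`).
#' @param layout A [genome_layout()].
#' @param subgenome Optional `"A"` or `"C"`: one fold per chromosome of
#'   that subgenome (the table must already be restricted to it).
#' @param seed Integer seed for the within-chromosome shuffle.
#' @return A `cv_plan` tibble with columns `row` (row index into the
#'   table, shuffled within chromosome), `chrom`, `fold`.
#' @export
make_cv_plan <- function(table, layout, subgenome = NULL, seed = 1) {
  folds <- homoeolog_folds(layout, subgenome)
  fold_of <- folds$fold[match(table$chrom, folds$chrom)]
  if (anyNA(fold_of))
    stop("table chromosome(s) without a fold: ",
         paste(unique(table$chrom[is.na(fold_of)]), collapse = ", "))
  rows <- with_seed(stage_seed(seed, "cv_shuffle"), {
    unlist(lapply(split(seq_len(nrow(table)),
                        factor(table$chrom, levels = unique(table$chrom))),
                  function(i) if (length(i) == 1) i else sample(i)),
           use.names = FALSE)
  })
  out <- tibble::tibble(row = rows, chrom = table$chrom[rows],
                        fold = fold_of[rows])
  attr(out, "n_folds") <- length(unique(folds$fold))
  class(out) <- c("cv_plan", class(out))
  out
}

#' Fit / apply the per-fold preprocessor
#'
#' Fitted on the training fold only: categorical predictors are
#' dummy-encoded (training levels), zero-variance columns are dropped,
#' and remaining columns are z-scored by training mean and SD.  The
#' fitted transform is applied unchanged to validation rows (values
#' outside the training range are transformed, never clipped).
#'
#' @param df Data frame of training rows.
#' @param predictors Character vector of predictor columns.
#' @return A `preprocessor` list with `$apply(newdata)` semantics via
#'   [apply_preprocessor()].
#' @export
fit_preprocessor <- function(df, predictors) {
  stopifnot(nrow(df) > 0)
  levels_map <- list()
  for (col in predictors) {
    if (is.character(df[[col]]) || is.factor(df[[col]]))
      levels_map[[col]] <- levels(factor(df[[col]]))
  }
  x <- expand_dummies(df, predictors, levels_map)
  ctr <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  keep <- sdev > 0
  if (!any(keep)) stop("all predictors are constant on the training fold")
  structure(list(predictors = predictors, levels_map = levels_map,
                 source = attr(x, "source")[keep],
                 keep = colnames(x)[keep],
                 center = ctr[keep], scale = sdev[keep]),
            class = "preprocessor")
}

expand_dummies <- function(df, predictors, levels_map) {
  cols <- list()
  source <- character(0)
  for (col in predictors) {
    if (col %in% names(levels_map)) {
      lv <- levels_map[[col]]
      for (l in lv[-1]) {
        nm <- paste(col, l, sep = "..")
        cols[[nm]] <- as.numeric(as.character(df[[col]]) == l)
        source[nm] <- col
      }
    } else {
      cols[[col]] <- as.numeric(df[[col]])
      source[col] <- col
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  attr(x, "source") <- source
  x
}

#' @rdname fit_preprocessor
#' @param prep A fitted `preprocessor`.
#' @param newdata Data frame with the raw predictor columns.
#' @return Numeric matrix of transformed predictors.
#' @export
apply_preprocessor <- function(prep, newdata) {
  x <- expand_dummies(newdata, prep$predictors, prep$levels_map)
  x <- x[, prep$keep, drop = FALSE]
  sweep(sweep(x, 2, prep$center, "-"), 2, prep$scale, "/")
}

default_params <- function(algorithm, task, p) {
  switch(algorithm,
    decision_tree = list(cp = 0.01, maxdepth = 10, minsplit = 10),
    regularized_lr = list(penalty = 1e-3, mixture = 0.5),
    random_forest = list(
      mtry = max(1, if (task == "classification") floor(sqrt(p))
                 else floor(p / 3)),
      trees = 500, min_n = 5),
    boosted_trees = list(mtry_frac = 0.8, trees = 200, learn_rate = 0.1,
                         tree_depth = 4, loss_reduction = 0,
                         min_n = 3))
}

param_space <- function(algorithm, p) {
  switch(algorithm,
    decision_tree = list(
      cp = list(lo = -4, hi = -1, log10 = TRUE),
      maxdepth = list(lo = 2, hi = 20, int = TRUE),
      minsplit = list(lo = 2, hi = 40, int = TRUE)),
    regularized_lr = list(
      penalty = list(lo = -4, hi = 0, log10 = TRUE),
      mixture = list(lo = 0, hi = 1)),
    random_forest = list(
      mtry = list(lo = 1, hi = p, int = TRUE),
      trees = list(lo = 200, hi = 800, int = TRUE),
      min_n = list(lo = 1, hi = 15, int = TRUE)),
    boosted_trees = list(
      mtry_frac = list(lo = 0.3, hi = 1),
      trees = list(lo = 100, hi = 500, int = TRUE),
      learn_rate = list(lo = -2, hi = -0.5, log10 = TRUE),
      tree_depth = list(lo = 2, hi = 8, int = TRUE),
      loss_reduction = list(lo = 0, hi = 5),
      min_n = list(lo = 1, hi = 10, int = TRUE)))
}

# Seeded space-filling (Latin hypercube) candidate draw over the tunable
# ranges; the algorithm defaults are always candidate 1.
sample_params <- function(algorithm, task, p, budget, seed) {
  cands <- list(default_params(algorithm, task, p))
  if (budget > 1) {
    space <- param_space(algorithm, p)
    u <- with_seed(stage_seed(seed, paste0("tune_", algorithm)),
                   lhs::randomLHS(budget - 1, length(space)))
    for (i in seq_len(nrow(u))) {
      cand <- list()
      for (j in seq_along(space)) {
        s <- space[[j]]
        v <- s$lo + u[i, j] * (s$hi - s$lo)
        if (isTRUE(s$log10)) v <- 10^v
        if (isTRUE(s$int)) v <- as.integer(round(v))
        cand[[names(space)[j]]] <- v
      }
      cands[[i + 1]] <- cand
    }
  }
  cands
}

fit_learner <- function(algorithm, task, params, x, y, seed = 1) {
  cls <- task == "classification"
  fit <- switch(algorithm,
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- if (cls) factor(y, levels = c(0, 1)) else y
      rpart::rpart(.y ~ ., data = df,
                   method = if (cls) "class" else "anova",
                   control = rpart::rpart.control(
                     cp = params$cp, maxdepth = params$maxdepth,
                     minsplit = params$minsplit, xval = 0))
    },
    regularized_lr = {
      xm <- x
      if (ncol(xm) < 2) xm <- cbind(xm, .pad = 0)
      glmnet::glmnet(xm, if (cls) factor(y, levels = c(0, 1)) else y,
                     family = if (cls) "binomial" else "gaussian",
                     alpha = params$mixture, lambda = params$penalty,
                     standardize = FALSE)
    },
    random_forest = {
      ranger::ranger(
        x = data.frame(x, check.names = FALSE),
        y = if (cls) factor(y, levels = c(0, 1)) else y,
        num.trees = params$trees,
        mtry = min(ncol(x), max(1, params$mtry)),
        min.node.size = params$min_n,
        probability = cls,
        importance = "impurity",
        num.threads = 1,
        seed = stage_seed(seed, "ranger"))
    },
    boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y))
      xgboost::xgb.train(
        params = list(
          objective = if (cls) "binary:logistic" else "reg:squarederror",
          eta = params$learn_rate, max_depth = params$tree_depth,
          gamma = params$loss_reduction,
          min_child_weight = params$min_n,
          colsample_bytree = params$mtry_frac,
          nthread = 1, seed = stage_seed(seed, "xgb")),
        data = dtrain, nrounds = params$trees, verbose = 0)
    })
  structure(list(algorithm = algorithm, task = task, fit = fit,
                 params = params, features = colnames(x)),
            class = "learner_fit")
}

predict_learner <- function(object, x) {
  fit <- object$fit
  cls <- object$task == "classification"
  switch(object$algorithm,
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      if (cls) stats::predict(fit, df, type = "prob")[, "1"]
      else as.numeric(stats::predict(fit, df))
    },
    regularized_lr = {
      xm <- x
      if (ncol(xm) < 2) xm <- cbind(xm, .pad = 0)
      as.numeric(stats::predict(fit, xm, type = "response"))
    },
    random_forest = {
      pr <- stats::predict(fit, data = data.frame(x, check.names = FALSE),
                           num.threads = 1)$predictions
      if (cls) pr[, "1"] else as.numeric(pr)
    },
    boosted_trees =
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x))))
}

#' Fitted model bundle with a uniform predict contract
#'
#' `predict(model, newdata)` on a `recland_model` applies the stored
#' preprocessor to the raw predictor columns of `newdata` and returns
#' numeric predictions (hotspot probability for classification, rate for
#' regression).
#'
#' @param object A `recland_model`.
#' @param newdata Data frame containing the raw predictor columns.
#' @param ... Ignored.
#' @export
predict.recland_model <- function(object, newdata, ...) {
  x <- apply_preprocessor(object$prep, newdata)
  predict_learner(object$learner, x)
}

fit_model <- function(algorithm, task, params, table, predictors,
                      seed = 1) {
  prep <- fit_preprocessor(table, predictors)
  x <- apply_preprocessor(prep, table)
  learner <- fit_learner(algorithm, task, params, x, table$target, seed)
  structure(list(algorithm = algorithm, task = task, learner = learner,
                 prep = prep, predictors = predictors, params = params),
            class = "recland_model")
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counting one half (computed from average
#' ranks, equivalent to exhaustive pair counting).
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination on pooled predictions
#'
#' `1 - SSE/SST`; can be negative when predictions are worse than the
#' mean.
#'
#' @param obs,pred Numeric vectors.
#' @return R-squared.
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("zero-variance observations")
  1 - sum((obs - pred)^2) / sst
}

#' Per-chromosome Pearson correlation of predicted vs observed
#'
#' @param obs,pred Numeric vectors.
#' @param chrom Chromosome label per element.
#' @return Named numeric vector of Pearson r per chromosome (`NA` for
#'   chromosomes with degenerate values).
#' @export
per_chromosome_pearson <- function(obs, pred, chrom) {
  vapply(split(seq_along(obs), factor(chrom, levels = unique(chrom))),
         function(i) {
           if (stats::sd(obs[i]) == 0 || stats::sd(pred[i]) == 0)
             return(NA_real_)
           stats::cor(obs[i], pred[i])
         }, numeric(1))
}

fold_metric <- function(task, obs, pred) {
  if (task == "classification") {
    if (length(unique(obs)) < 2) return(NA_real_)
    auroc(obs, pred)
  } else r_squared(obs, pred)
}

# Out-of-fold predictions for one hyperparameter configuration: each
# fold's rows are predicted by a model trained strictly on the other
# folds, with the preprocessor refitted per fold.
cv_oof <- function(algorithm, task, params, plan, table, predictors,
                   seed = 1) {
  folds <- sort(unique(plan$fold))
  res <- lapply(folds, function(k) {
    tr <- plan$row[plan$fold != k]
    va <- plan$row[plan$fold == k]
    prep <- fit_preprocessor(table[tr, , drop = FALSE], predictors)
    xtr <- apply_preprocessor(prep, table[tr, , drop = FALSE])
    xva <- apply_preprocessor(prep, table[va, , drop = FALSE])
    fit <- with_seed(stage_seed(seed, paste0("fold", k)),
                     fit_learner(algorithm, task, params, xtr,
                                 table$target[tr], seed = seed + k))
    tibble::tibble(row = va, fold = k,
                   observed = table$target[va],
                   predicted = predict_learner(fit, xva))
  })
  dplyr::bind_rows(res)
}

#' Tune hyperparameters and evaluate under grouped cross-validation
#'
#' Evaluates `budget` hyperparameter configurations (the algorithm
#' defaults plus a seeded Latin-hypercube draw over the tunable ranges)
#' by mean fold AUROC (classification) or mean fold R-squared
#' (regression), keeps the best configuration's out-of-fold predictions,
#' and refits a final model on the full table for downstream importance
#' and interpretation.
#'
#' @param spec A [model_spec()].
#' @param plan A [make_cv_plan()].
#' @param table A `feature_table`.
#' @return A `cv_report` list: `algorithm`, `task`, `best_params`,
#'   `fold_metrics`, `mean_fold_metric`, `overall_metric` (pooled
#'   out-of-fold), `per_chrom_pearson`, `predictions` (tibble with
#'   `chrom`, `start`, `end`, `fold`, `observed`, `predicted`),
#'   `model` (a `recland_model`), `search` (per-candidate mean metric).
#' @export
tune_and_fit <- function(spec, plan, table) {
  stopifnot(inherits(spec, "model_spec"))
  predictors <- attr(table, "predictors") %||%
    setdiff(names(table), c("chrom", "start", "end", "target", "snp_count"))
  p <- length(predictors)
  cands <- if (!is.null(spec$params)) list(spec$params)
           else sample_params(spec$algorithm, spec$task, p, spec$budget,
                              spec$seed)
  search <- vector("list", length(cands))
  best <- NULL
  for (i in seq_along(cands)) {
    oof <- cv_oof(spec$algorithm, spec$task, cands[[i]], plan, table,
                  predictors, seed = stage_seed(spec$seed, paste0("cand", i)))
    fm <- vapply(split(oof, oof$fold),
                 function(d) fold_metric(spec$task, d$observed,
                                         d$predicted), numeric(1))
    m <- mean(fm, na.rm = TRUE)
    search[[i]] <- tibble::tibble(candidate = i, mean_fold_metric = m)
    if (is.null(best) || (is.finite(m) && m > best$metric))
      best <- list(i = i, metric = m, oof = oof, fold_metrics = fm)
  }
  if (is.null(best)) stop("no candidate produced a successful fit")
  params <- cands[[best$i]]
  oof <- best$oof
  preds <- dplyr::bind_cols(table[oof$row, c("chrom", "start", "end")],
                            oof[, c("fold", "observed", "predicted")])
  overall <- fold_metric(spec$task, preds$observed, preds$predicted)
  model <- with_seed(stage_seed(spec$seed, "final_fit"),
                     fit_model(spec$algorithm, spec$task, params, table,
                               predictors, seed = spec$seed))
  structure(list(
    algorithm = spec$algorithm, task = spec$task, best_params = params,
    fold_metrics = tibble::tibble(fold = as.integer(names(best$fold_metrics)),
                                  metric = unname(best$fold_metrics)),
    mean_fold_metric = best$metric,
    overall_metric = overall,
    per_chrom_pearson = per_chromosome_pearson(preds$observed,
                                               preds$predicted,
                                               preds$chrom),
    predictions = preds,
    model = model,
    search = dplyr::bind_rows(search)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s %s | folds: %d | mean fold %s = %.3f | pooled = %.3f\n",
              x$algorithm, x$task, nrow(x$fold_metrics),
              if (x$task == "classification") "AUROC" else "R2",
              x$mean_fold_metric, x$overall_metric))
  invisible(x)
}
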