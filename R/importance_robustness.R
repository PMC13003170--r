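# Model-specific feature importance, direction inference, and the
# multicollinearity-robustness model-selection protocol.

#' Extract model-specific feature importance
#'
#' Decision tree and random forest: summed impurity reduction per
#' feature (Gini for classification, residual sum of squares for
#' regression).  Boosted trees: total gain across all trees.
#' Regularized regression: absolute standardized coefficient (inputs are
#' z-scored by the preprocessor, so coefficients are on SD scale).
#' Importance of dummy-expanded categorical columns is summed back to
#' the source feature.  Features unused by the model score 0.
#'
#' @param model A `recland_model` (from [tune_and_fit()] or
#'   [fit_model()]).
#' @return Tibble `feature`, `score` (>= 0), `rank` (1 = most important;
#'   average ranks on ties).
#' @export
extract_importance <- function(model) {
  stopifnot(inherits(model, "recland_model"))
  fit <- model$learner$fit
  cols <- model$learner$features
  raw <- switch(model$algorithm,
    decision_tree = {
      vi <- fit$variable.importance
      if (is.null(vi)) stats::setNames(numeric(length(cols)), cols) else vi
    },
    regularized_lr = {
      b <- as.matrix(stats::coef(fit))[-1, 1]
      abs(b[names(b) != ".pad"])
    },
    random_forest = ranger::importance(fit),
    boosted_trees = {
      imp <- xgboost::xgb.importance(model = fit)
      stats::setNames(imp$Gain, imp$Feature)
    })
  score <- stats::setNames(numeric(length(cols)), cols)
  common <- intersect(names(raw), cols)
  score[common] <- raw[common]
  src <- model$prep$source[names(score)]
  agg <- tapply(score, src, sum)
  out <- tibble::tibble(feature = names(agg), score = as.numeric(agg))
  # predictors dropped as zero-variance still belong in the ranking
  missing <- setdiff(model$predictors, out$feature)
  if (length(missing) > 0)
    out <- dplyr::bind_rows(out, tibble::tibble(feature = missing,
                                                score = 0))
  out$rank <- rank(-out$score, ties.method = "average")
  out[order(out$rank), ]
}

#' Infer the direction of each feature's association
#'
#' Regularized regression: the sign of the coefficient.  Tree-based
#' models, classification: whether the mean feature value is greater in
#' predicted-hotspot bins (prediction > 0.5) than in predicted
#' non-hotspot bins.  Tree-based models, regression: the sign of the
#' Spearman correlation between feature values and predicted rates.
#' Constant predictions leave the direction `NA` with a warning.
#'
#' @param model A `recland_model`.
#' @param table The feature table to evaluate predictions on.
#' @return Tibble `feature`, `direction` (`"positive"`/`"negative"`).
#' @export
infer_direction <- function(model, table) {
  stopifnot(inherits(model, "recland_model"))
  feats <- model$predictors
  if (model$algorithm == "regularized_lr") {
    b <- as.matrix(stats::coef(model$learner$fit))[-1, 1]
    src <- model$prep$source[names(b)[names(b) != ".pad"]]
    agg <- tapply(b[names(b) != ".pad"], src, sum)
    dir <- ifelse(as.numeric(agg) >= 0, "positive", "negative")
    out <- tibble::tibble(feature = names(agg), direction = dir)
    missing <- setdiff(feats, out$feature)
    if (length(missing) > 0)
      out <- dplyr::bind_rows(out, tibble::tibble(feature = missing,
                                                  direction = NA))
    return(out)
  }
  pred <- stats::predict(model, table)
  if (stats::sd(pred) == 0) {
    warning("constant predictions: directions undefined")
    return(tibble::tibble(feature = feats, direction = NA_character_))
  }
  dir <- vapply(feats, function(f) {
    x <- as.numeric(table[[f]])
    if (model$task == "classification") {
      hot <- pred > 0.5
      if (all(hot) || !any(hot)) return(NA_character_)
      if (mean(x[hot]) > mean(x[!hot])) "positive" else "negative"
    } else {
      rho <- suppressWarnings(stats::cor(x, pred, method = "spearman"))
      if (is.na(rho)) NA_character_
      else if (rho >= 0) "positive" else "negative"
    }
  }, character(1))
  tibble::tibble(feature = feats, direction = unname(dir))
}

#' Cluster highly correlated features
#'
#' Features are clustered as the connected components of the graph whose
#' edges join feature pairs with `|Pearson r| > threshold` (transitive:
#' a chain a-b, b-c joins a and c even if r(a, c) is low); only
#' components with at least two members are kept.  The representative of
#' each cluster is either user-fixed or the member with the highest mean
#' `|r|` to the rest of its cluster.
#'
#' @param table A `feature_table` (or any tibble of numeric features).
#' @param threshold Absolute-correlation threshold in (0, 1); default
#'   0.80.
#' @param representatives Optional character vector of preferred
#'   representatives (one per cluster at most).
#' @param features Optional character vector restricting the columns
#'   considered.
#' @return A `cluster_set` list: `clusters` (list of feature-name
#'   vectors), `representatives` (one per cluster), `reduced_features`
#'   (representatives plus all unclustered features).
#' @export
build_clusters <- function(table, threshold = 0.80,
                           representatives = NULL, features = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  feats <- features %||% attr(table, "predictors") %||%
    setdiff(names(table), c("chrom", "start", "end", "target", "snp_count"))
  feats <- feats[vapply(feats, function(f)
    is.numeric(table[[f]]) && stats::sd(table[[f]]) > 0, logical(1))]
  if (length(feats) < 2) stop("need at least two variable features")
  cm <- abs(stats::cor(as.data.frame(table[, feats])))
  adj <- cm > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- list(); reps <- character(0)
  for (k in seq_len(comp$no)) {
    members <- feats[comp$membership == k]
    if (length(members) < 2) next
    rep_k <- intersect(representatives, members)
    if (length(rep_k) == 0) {
      mean_r <- vapply(members, function(f)
        mean(cm[f, setdiff(members, f)]), numeric(1))
      rep_k <- members[which.max(mean_r)]
    } else rep_k <- rep_k[1]
    clusters[[length(clusters) + 1]] <- members
    reps <- c(reps, rep_k)
  }
  clustered <- unlist(clusters)
  structure(list(clusters = clusters, representatives = reps,
                 reduced_features = c(reps, setdiff(feats, clustered))),
            class = "cluster_set")
}

#' Importance-ranking robustness under multicollinearity
#'
#' Trains the model twice -- once on all features, once on the reduced
#' set keeping a single representative per correlated cluster -- and
#' quantifies (1) the Spearman rank correlation between the two
#' importance rankings over the reduced set's features and (2) how
#' evenly importance is spread inside clusters: the mean within-cluster
#' SD of full-model importance scores divided by the overall SD across
#' all features.
#'
#' @param spec A [model_spec()] (its `params`/`budget` drive both fits).
#' @param plan A [make_cv_plan()] for the table.
#' @param table A `feature_table`.
#' @param clusters A [build_clusters()] result.
#' @param refit `"full"` (default): importances from a full-data refit;
#'   `"cv"`: importances averaged over per-fold refits.
#' @return A `robustness_report` list: `algorithm`, `task`, `spearman`,
#'   `within_sd`, `overall_sd`, `sd_ratio`, `ranking_full`,
#'   `ranking_reduced`, `cv_metric`.
#' @export
robustness_protocol <- function(spec, plan, table, clusters,
                                refit = c("full", "cv")) {
  refit <- match.arg(refit)
  stopifnot(inherits(clusters, "cluster_set"))
  reduced <- clusters$reduced_features
  if (length(reduced) < 3)
    warning("reduced feature set has fewer than 3 features; ",
            "Spearman is unstable")
  imp_for <- function(feats, tag) {
    tab <- table
    attr(tab, "predictors") <- feats
    if (refit == "full") {
      rep <- tune_and_fit(spec, plan, tab)
      list(imp = extract_importance(rep$model), metric = rep$mean_fold_metric)
    } else {
      rep <- tune_and_fit(spec, plan, tab)
      per_fold <- lapply(sort(unique(plan$fold)), function(k) {
        tr <- plan$row[plan$fold != k]
        m <- with_seed(stage_seed(spec$seed, paste0(tag, "_imp", k)),
                       fit_model(spec$algorithm, spec$task,
                                 rep$best_params,
                                 tab[tr, , drop = FALSE], feats,
                                 seed = spec$seed + k))
        extract_importance(m)
      })
      sc <- Reduce(`+`, lapply(per_fold, function(d)
        d$score[match(feats, d$feature)])) / length(per_fold)
      imp <- tibble::tibble(feature = feats, score = sc,
                            rank = rank(-sc, ties.method = "average"))
      list(imp = imp, metric = rep$mean_fold_metric)
    }
  }
  full <- imp_for(attr(table, "predictors") %||%
                    setdiff(names(table),
                            c("chrom", "start", "end", "target",
                              "snp_count")), "full")
  red <- imp_for(reduced, "reduced")
  rank_full <- full$imp$rank[match(reduced, full$imp$feature)]
  rank_red <- red$imp$rank[match(reduced, red$imp$feature)]
  spearman <- suppressWarnings(
    stats::cor(rank_full, rank_red, method = "spearman"))
  within <- vapply(clusters$clusters, function(m)
    stats::sd(full$imp$score[match(m, full$imp$feature)]), numeric(1))
  within_sd <- mean(within)
  overall_sd <- stats::sd(full$imp$score)
  structure(list(
    algorithm = spec$algorithm, task = spec$task,
    spearman = spearman, within_sd = within_sd, overall_sd = overall_sd,
    sd_ratio = if (overall_sd > 0) within_sd / overall_sd else NA_real_,
    ranking_full = full$imp, ranking_reduced = red$imp,
    cv_metric = full$metric
  ), class = "robustness_report")
}

#' Select the reference model
#'
#' Deterministic lexicographic choice over candidate models: highest
#' robustness Spearman first, ties broken by cross-validation metric,
#' then by lowest within/overall SD ratio.
#'
#' @param reports List of `robustness_report`s (one per candidate).
#' @return The chosen report, with attribute `rationale`.
#' @export
select_model <- function(reports) {
  if (length(reports) == 0) stop("empty candidate list")
  key <- vapply(reports, function(r)
    c(r$spearman, r$cv_metric, -r$sd_ratio), numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ], decreasing = TRUE)
  chosen <- reports[[ord[1]]]
  attr(chosen, "rationale") <- sprintf(
    "chosen %s: Spearman %.3f, CV metric %.3f, SD ratio %.3f",
    chosen$algorithm, chosen$spearman, chosen$cv_metric, chosen$sd_ratio)
  chosen
}
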