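# Model-agnostic interpretation: accumulated local effects (ALE) and
# Friedman H-statistics, implemented from first principles against the
# uniform predict contract of `recland_model`.

#' Accumulated local effect curve for one feature
#'
#' Interval edges are placed at empirical quantiles of the feature
#' (duplicates merged).  For each interval, the local effect is the mean
#' over its observations of the prediction difference when the feature
#' is substituted by the interval's upper versus lower edge; effects are
#' accumulated by a cumulative sum along the intervals and centered by
#' subtracting the count-weighted mean of the interval mid-curve, so the
#' curve averages to zero over the data distribution.  A two-level
#' feature (e.g. the subgenome dummy) yields a single interval whose
#' effect is the mean prediction difference between the two levels.
#'
#' @param model A `recland_model` (or any object with a numeric
#'   `predict(model, newdata)` method).
#' @param table Data frame with the model's raw predictor columns.
#' @param feature Feature name (numeric, >= 2 distinct values).
#' @param K Number of quantile intervals (default 20).
#' @return An `ale_curve` list: `feature`, `edges` (length K'+1), `ale`
#'   (centered accumulated effect at each edge), `counts` (observations
#'   per interval).
#' @export
ale_curve <- function(model, table, feature, K = 20) {
  x <- as.numeric(table[[feature]])
  if (length(unique(x)) < 2) stop("constant feature: ", feature)
  edges <- unique(as.numeric(stats::quantile(
    x, probs = seq(0, 1, length.out = K + 1), type = 7)))
  n_int <- length(edges) - 1
  idx <- as.integer(cut(x, edges, include.lowest = TRUE))
  counts <- tabulate(idx, nbins = n_int)
  lo_tab <- hi_tab <- table
  lo_tab[[feature]] <- edges[idx]
  hi_tab[[feature]] <- edges[idx + 1]
  diff <- stats::predict(model, hi_tab) - stats::predict(model, lo_tab)
  delta <- rep(0, n_int)
  agg <- tapply(diff, idx, mean)
  delta[as.integer(names(agg))] <- as.numeric(agg)
  acc <- c(0, cumsum(delta))
  mid <- (acc[-1] + acc[-length(acc)]) / 2
  centered <- acc - sum(counts * mid) / sum(counts)
  structure(list(feature = feature, edges = edges, ale = centered,
                 counts = counts),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat(sprintf("<ale_curve> %s: %d intervals, range [%.4g, %.4g]\n",
              x$feature, length(x$counts), min(x$ale), max(x$ale)))
  invisible(x)
}

#' Feature value at which an ALE curve attains its maximum
#'
#' @param curve An [ale_curve()].
#' @return The edge value with the largest centered effect.
#' @export
ale_peak <- function(curve) curve$edges[which.max(curve$ale)]

# Centered Monte-Carlo partial dependence of feature set `J`, evaluated
# at the subsample's own J-values: PD_J(x_J,i) = mean_m f(x_J,i, x_-J,m).
partial_dependence <- function(model, S, J) {
  n <- nrow(S)
  big <- S[rep(seq_len(n), times = n), , drop = FALSE]
  for (col in J)
    big[[col]] <- rep(S[[col]], each = n)
  pred <- stats::predict(model, big)
  pd <- colMeans(matrix(pred, nrow = n))
  pd - mean(pd)
}

h_subsample <- function(table, n_sample, seed) {
  n <- min(n_sample, nrow(table))
  rows <- with_seed(stage_seed(seed, "h_sample"),
                    sample(nrow(table), n))
  table[rows, , drop = FALSE]
}

#' Pairwise Friedman H-statistic
#'
#' Fraction of the joint two-feature partial-dependence variance not
#' explained by the two one-feature partial dependences:
#' `H^2 = sum((PD_jk - PD_j - PD_k)^2) / sum(PD_jk^2)` with all terms
#' centered, evaluated by Monte Carlo over a seeded subsample.  H = 0
#' means the pair acts additively; H = 1 means its signal is pure
#' interaction.  Negative numerical values are clipped to 0.
#'
#' @param model A `recland_model`.
#' @param table Data frame of raw predictor columns.
#' @param j,k Feature names.
#' @param n_sample Subsample size (default 500).
#' @param seed Integer seed for the subsample.
#' @return H in `[0, 1]`.
#' @export
h_pairwise <- function(model, table, j, k, n_sample = 500, seed = 1) {
  S <- h_subsample(table, n_sample, seed)
  pd_j <- partial_dependence(model, S, j)
  pd_k <- partial_dependence(model, S, k)
  pd_jk <- partial_dependence(model, S, c(j, k))
  denom <- sum(pd_jk^2)
  if (denom == 0) stop("degenerate joint partial dependence for ",
                       j, ", ", k)
  h2 <- sum((pd_jk - pd_j - pd_k)^2) / denom
  sqrt(clamp01(h2))
}

#' Overall Friedman H-statistic of one feature
#'
#' Fraction of the (centered) prediction variance not explained by the
#' sum of the feature's partial dependence and the partial dependence of
#' all remaining features:
#' `H^2 = sum((f - PD_j - PD_-j)^2) / sum(f^2)`.
#'
#' @inheritParams h_pairwise
#' @param feature Feature name.
#' @return H in `[0, 1]`.
#' @export
h_overall <- function(model, table, feature, n_sample = 500, seed = 1) {
  S <- h_subsample(table, n_sample, seed)
  feats <- if (!is.null(attr(table, "predictors")))
    attr(table, "predictors") else model$predictors
  f <- stats::predict(model, S)
  f <- f - mean(f)
  pd_j <- partial_dependence(model, S, feature)
  pd_rest <- partial_dependence(model, S, setdiff(feats, feature))
  denom <- sum(f^2)
  if (denom == 0) stop("constant predictions")
  sqrt(clamp01(sum((f - pd_j - pd_rest)^2) / denom))
}

#' All pairwise H-statistics
#'
#' Computes [h_pairwise()] for every feature pair, caching the
#' one-feature partial dependences over a single shared subsample.
#'
#' @inheritParams h_pairwise
#' @param features Character vector of features (default: the table's
#'   predictors).
#' @return Tibble `feature_1`, `feature_2`, `h`, sorted by decreasing
#'   `h`, with attribute `n` (subsample size).
#' @export
h_pairwise_all <- function(model, table, features = NULL, n_sample = 500,
                           seed = 1) {
  feats <- features %||% attr(table, "predictors") %||% model$predictors
  S <- h_subsample(table, n_sample, seed)
  pd1 <- lapply(stats::setNames(feats, feats), function(f)
    partial_dependence(model, S, f))
  pairs <- utils::combn(feats, 2)
  h <- vapply(seq_len(ncol(pairs)), function(i) {
    j <- pairs[1, i]; k <- pairs[2, i]
    pd_jk <- partial_dependence(model, S, c(j, k))
    denom <- sum(pd_jk^2)
    if (denom == 0) return(0)
    sqrt(clamp01(sum((pd_jk - pd1[[j]] - pd1[[k]])^2) / denom))
  }, numeric(1))
  out <- tibble::tibble(feature_1 = pairs[1, ], feature_2 = pairs[2, ],
                        h = h)
  out <- out[order(-out$h), ]
  attr(out, "n") <- nrow(S)
  out
}
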