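lin_table <- function(n = 300, p = 4, seed = 2, target_fun = NULL) {
  withr::with_seed(seed, {
    tab <- uniform_table(n, p, seed = seed)
    tab$chrom <- rep(c("A01", "C01"), length.out = n)
    tab$start <- seq_len(n) * 100
    tab$end <- tab$start + 99
    tab$snp_count <- 1L
    tab$target <- if (is.null(target_fun)) rnorm(n) else target_fun(tab)
    attr(tab, "predictors") <- paste0("x", seq_len(p))
    tab
  })
}

test_that("regularized-model importance is the absolute standardized coefficient", {
  tab <- lin_table(500, 3, seed = 4,
                   target_fun = function(t) 2 * t$x1 - 1 * t$x2 + 0)
  attr(tab, "task") <- "regression"
  m <- recland:::fit_model("regularized_lr", "regression",
                           list(penalty = 1e-4, mixture = 0),
                           tab, c("x1", "x2", "x3"))
  imp <- extract_importance(m)
  expect_equal(imp$feature[1:2], c("x1", "x2"))
  expect_gt(imp$score[1], imp$score[2])
  expect_equal(imp$score[imp$feature == "x3"], 0, tolerance = 0.05)
  dir <- infer_direction(m, tab)
  expect_equal(dir$direction[dir$feature == "x1"], "positive")
  expect_equal(dir$direction[dir$feature == "x2"], "negative")
})

test_that("a single planted signal ranks first in a random forest", {
  tab <- lin_table(400, 5, seed = 6,
                   target_fun = function(t) 3 * t$x3 + rnorm(nrow(t), 0, 0.3))
  attr(tab, "task") <- "regression"
  m <- recland:::fit_model("random_forest", "regression",
                           list(mtry = 2, trees = 300, min_n = 5),
                           tab, paste0("x", 1:5), seed = 1)
  imp <- extract_importance(m)
  expect_equal(imp$feature[1], "x3")
  dir <- infer_direction(m, tab)
  expect_equal(dir$direction[dir$feature == "x3"], "positive")
})

test_that("duplicated predictors split importance but keep the pair total", {
  tab <- lin_table(500, 2, seed = 8,
                   target_fun = function(t) 2 * t$x1 + rnorm(nrow(t), 0, 0.2))
  attr(tab, "task") <- "regression"
  tab$x1_copy <- tab$x1
  tab_dup <- tab
  attr(tab_dup, "predictors") <- c("x1", "x2", "x1_copy")
  prm <- list(mtry = 2, trees = 500, min_n = 5)
  m_single <- recland:::fit_model("random_forest", "regression", prm,
                                  tab, c("x1", "x2"), seed = 1)
  m_dup <- recland:::fit_model("random_forest", "regression", prm,
                               tab_dup, c("x1", "x2", "x1_copy"), seed = 1)
  i_s <- extract_importance(m_single)
  i_d <- extract_importance(m_dup)
  solo <- i_s$score[i_s$feature == "x1"]
  pair <- sum(i_d$score[i_d$feature %in% c("x1", "x1_copy")])
  expect_lt(abs(pair - solo) / solo, 0.25)
  shares <- i_d$score[i_d$feature %in% c("x1", "x1_copy")]
  expect_gt(min(shares) / max(shares), 0.25)  # roughly split
})

test_that("clusters are connected components of the high-correlation graph", {
  n <- 400
  base <- withr::with_seed(3, rnorm(n))
  tab <- tibble::tibble(
    a = base + rnorm(n, 0, 0.2),
    b = base + rnorm(n, 0, 0.2),
    c = -base + rnorm(n, 0, 0.2),
    d = rnorm(n), e = rnorm(n))
  cl <- build_clusters(tab, threshold = 0.8,
                       features = c("a", "b", "c", "d", "e"))
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters[[1]], c("a", "b", "c"))
  expect_true(cl$representatives %in% c("a", "b", "c"))
  expect_setequal(cl$reduced_features, c(cl$representatives, "d", "e"))

  none <- build_clusters(tibble::tibble(d = rnorm(n), e = rnorm(n),
                                        f = rnorm(n)),
                         features = c("d", "e", "f"))
  expect_length(none$clusters, 0)
  expect_setequal(none$reduced_features, c("d", "e", "f"))

  # chain a-b, b-c strong, a-c below threshold: one transitive component
  m <- withr::with_seed(4, rnorm(n))
  chain <- withr::with_seed(5, tibble::tibble(
    a = m + rnorm(n, 0, 0.6), b = m, c = m + rnorm(n, 0, 0.6)))
  cm <- abs(cor(chain))
  expect_gt(cm["a", "b"], 0.8)
  expect_gt(cm["b", "c"], 0.8)
  expect_lt(cm["a", "c"], 0.8)
  cl3 <- build_clusters(chain, features = c("a", "b", "c"))
  expect_setequal(cl3$clusters[[1]], c("a", "b", "c"))

  expect_error(build_clusters(tab, threshold = 1.2,
                              features = c("a", "b")), "threshold")
  # user-fixed representative wins
  cl_rep <- build_clusters(tab, representatives = "b",
                           features = c("a", "b", "c", "d", "e"))
  expect_equal(cl_rep$representatives, "b")
})

test_that("robustness statistics behave on constructed rankings", {
  # identical rankings give Spearman exactly 1; reversal gives -1
  r1 <- tibble::tibble(feature = letters[1:5], score = 5:1,
                       rank = 1:5)
  expect_equal(cor(r1$rank, r1$rank, method = "spearman"), 1)
  expect_equal(cor(r1$rank, rev(r1$rank), method = "spearman"), -1)

  # equal within-cluster importances give SD ratio 0 (scale-invariant)
  scores <- c(a = 2, b = 2, c = 2, d = 7, e = 1)
  within_sd <- sd(scores[c("a", "b", "c")])
  expect_equal(within_sd, 0)
  for (k in c(1, 10)) {
    sc <- scores * k
    expect_equal(sd(sc[c("a", "b", "c")]) / sd(sc), 0)
  }
})

test_that("the full robustness protocol reports consistent statistics", {
  n <- 500
  base <- withr::with_seed(11, rnorm(n))
  tab <- tibble::tibble(
    chrom = rep(c("A01", "C01", "A02", "C02"), each = n / 4),
    start = seq_len(n) * 100, end = seq_len(n) * 100 + 99,
    f1 = base + rnorm(n, 0, 0.25),
    f2 = base + rnorm(n, 0, 0.25),
    f3 = base + rnorm(n, 0, 0.25),
    g1 = withr::with_seed(12, rnorm(n)),
    g2 = withr::with_seed(13, rnorm(n)),
    snp_count = 1L)
  tab$target <- 2 * base + 0.5 * tab$g1 + rnorm(n, 0, 0.3)
  attr(tab, "predictors") <- c("f1", "f2", "f3", "g1", "g2")
  attr(tab, "task") <- "regression"
  layout <- toy_layout(4, len = 1e7)
  plan <- make_cv_plan(tab, layout, seed = 1)
  expect_equal(length(unique(plan$fold)), 2)
  clusters <- build_clusters(tab)
  expect_setequal(clusters$clusters[[1]], c("f1", "f2", "f3"))
  spec <- model_spec("random_forest", "regression",
                     params = list(mtry = 2, trees = 200, min_n = 5),
                     seed = 2)
  rob <- robustness_protocol(spec, plan, tab, clusters)
  expect_true(rob$spearman >= -1 && rob$spearman <= 1)
  expect_gte(rob$sd_ratio, 0)
  expect_equal(nrow(rob$ranking_full), 5)
  expect_setequal(rob$ranking_reduced$feature, clusters$reduced_features)
  # the cluster's signal should keep its representative highly ranked in
  # both fits, so the protocol yields a high Spearman for RF
  expect_gt(rob$spearman, 0.5)
})

test_that("model selection is lexicographic on Spearman, metric, SD ratio", {
  mk <- function(alg, sp, cv, ratio)
    structure(list(algorithm = alg, task = "classification",
                   spearman = sp, cv_metric = cv, sd_ratio = ratio),
              class = "robustness_report")
  a <- mk("random_forest", 1.0, 0.85, 0.4)
  b <- mk("regularized_lr", 0.55, 0.9, 0.2)
  expect_equal(select_model(list(a, b))$algorithm, "random_forest")
  c1 <- mk("boosted_trees", 1.0, 0.80, 0.4)
  expect_equal(select_model(list(c1, a))$algorithm, "random_forest")
  d <- mk("decision_tree", 1.0, 0.85, 0.1)
  expect_equal(select_model(list(a, d))$algorithm, "decision_tree")
  expect_equal(select_model(list(b))$algorithm, "regularized_lr")
  expect_error(select_model(list()), "empty")
})
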