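# End-to-end orchestration: simulate/ingest -> map -> feature tables ->
# univariate stats -> model training -> robustness -> interpretation,
# with per-stage seeds derived from one master seed and a provenance
# record alongside every run.

#' Pipeline run configuration
#'
#' Inputs are either a [synth_config()] (synthetic study) or file paths
#' to crossover, layout and SNP tables.  All stage seeds are derived
#' from `seed` via [stage_seed()].
#'
#' @param output_dir Directory to write stage outputs into.
#' @param seed Master seed.
#' @param synth A [synth_config()]; set `NULL` when supplying paths.
#' @param co_path,layout_path,snp_path Input files for an ingested run
#'   (CO TSV read with [read_co_tsv()], which also needs `meioses`).
#' @param meioses Named informative-meiosis counts (ingested runs).
#' @param bin_width,max_co_per_individual,max_interval_len Map-stage
#'   parameters.
#' @param smoothing_alpha SES smoothing parameter.
#' @param algorithms Algorithms to train (default all four).
#' @param budget Hyperparameter search budget for the training stage.
#' @param robustness_budget Budget for the robustness fits (default 1:
#'   algorithm defaults, since the protocol compares rankings rather
#'   than tuning).
#' @param h_sample Subsample size for H-statistics.
#' @return A `run_config` list (validated).
#' @export
run_config <- function(output_dir, seed = 1, synth = synth_config(seed),
                       co_path = NULL, layout_path = NULL, snp_path = NULL,
                       meioses = NULL,
                       bin_width = 3e5, max_co_per_individual = 100,
                       max_interval_len = 2e6, smoothing_alpha = 0.1,
                       algorithms = ALGORITHMS, budget = 3,
                       robustness_budget = 1, h_sample = 200) {
  if (is.null(synth)) {
    for (p in c(co_path, layout_path, snp_path))
      if (!file.exists(p)) stop("missing input path: ", p)
    if (is.null(meioses)) stop("ingested runs need meiosis counts")
  }
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  structure(list(output_dir = output_dir, seed = seed, synth = synth,
                 co_path = co_path, layout_path = layout_path,
                 snp_path = snp_path, meioses = meioses,
                 bin_width = bin_width,
                 max_co_per_individual = max_co_per_individual,
                 max_interval_len = max_interval_len,
                 smoothing_alpha = smoothing_alpha,
                 algorithms = algorithms, budget = budget,
                 robustness_budget = robustness_budget,
                 h_sample = h_sample),
            class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and writes all stage outputs plus a
#' `provenance.json` (configuration hash, seeds, package version,
#' filter accounting) into `config$output_dir`.  Re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results:
#'   `map`, `tables`, `tests`, `glm`, `cv` (per algorithm x task),
#'   `robustness`, `selected`, `ale`, `h_pairs`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  seed <- config$seed

  study <- pipeline_stage("simulate|ingest", {
    if (!is.null(config$synth)) {
      cfg <- config$synth
      cfg$seed <- seed
      cfg$bin_width <- config$bin_width
      simulate_study(cfg)
    } else {
      layout <- read_layout(config$layout_path)
      bins <- build_bins(layout, config$bin_width)
      list(layout = layout, bins = bins,
           cos = read_co_tsv(config$co_path, config$meioses),
           snps = read_snp_tsv(config$snp_path),
           features = NULL, truth = NULL)
    }
  })
  n_raw <- nrow(study$cos$records)

  map <- pipeline_stage("map", {
    m <- build_recomb_map(study$cos, study$bins, study$snps,
                          seed = stage_seed(seed, "hotspots"),
                          max_co_per_individual = config$max_co_per_individual,
                          max_interval_len = config$max_interval_len)
    readr::write_tsv(as.data.frame(m), out("recomb_map.tsv"))
    m
  })

  tables <- pipeline_stage("features", {
    if (is.null(study$features))
      stop("ingested feature tracks are assembled upstream; ",
           "supply a synthetic config or a prebuilt feature table")
    tabs <- list(
      classification = assemble_table(map, study$features,
                                      "classification",
                                      alpha = config$smoothing_alpha),
      regression = assemble_table(map, study$features, "regression",
                                  alpha = config$smoothing_alpha))
    write_feature_table(tabs$classification, out("table_classification.tsv"))
    write_feature_table(tabs$regression, out("table_regression.tsv"))
    tabs
  })

  tests <- pipeline_stage("stats", {
    tt <- hotspot_tests(tables$classification, map = map,
                        layout = study$layout)
    readr::write_tsv(tt, out("hotspot_tests.tsv"))
    tt
  })
  glm_fit <- pipeline_stage("stats_glm", {
    g <- hotspot_glm(map, study$layout)
    readr::write_tsv(g$coefficients, out("hotspot_glm.tsv"))
    g
  })

  cv <- pipeline_stage("train", {
    res <- list()
    for (task in c("classification", "regression")) {
      plan <- make_cv_plan(tables[[task]], study$layout,
                           seed = stage_seed(seed, paste0("plan_", task)))
      for (alg in config$algorithms) {
        spec <- model_spec(alg, task, budget = config$budget,
                           seed = stage_seed(seed, paste0(alg, "_", task)))
        rep <- tune_and_fit(spec, plan, tables[[task]])
        readr::write_tsv(rep$predictions,
                         out(sprintf("oof_%s_%s.tsv", alg, task)))
        res[[paste(alg, task, sep = ".")]] <- rep
      }
    }
    res
  })

  robustness <- pipeline_stage("robustness", {
    res <- list()
    rows <- list()
    for (task in c("classification", "regression")) {
      plan <- make_cv_plan(tables[[task]], study$layout,
                           seed = stage_seed(seed, paste0("plan_", task)))
      clusters <- build_clusters(tables[[task]])
      for (alg in config$algorithms) {
        spec <- model_spec(alg, task, budget = config$robustness_budget,
                           seed = stage_seed(seed,
                                             paste0("rob_", alg, "_", task)))
        r <- robustness_protocol(spec, plan, tables[[task]], clusters)
        res[[paste(alg, task, sep = ".")]] <- r
        rows[[length(rows) + 1]] <- tibble::tibble(
          task = task, model = alg, spearman = r$spearman,
          within_cluster_sd = r$within_sd, overall_sd = r$overall_sd,
          sd_ratio = r$sd_ratio)
      }
    }
    readr::write_tsv(dplyr::bind_rows(rows), out("robustness.tsv"))
    res
  })

  selected <- pipeline_stage("select", {
    reg <- robustness[grepl("\\.regression$", names(robustness))]
    select_model(unname(reg))
  })

  interp <- pipeline_stage("interpret", {
    key <- paste(selected$algorithm, "regression", sep = ".")
    model <- cv[[key]]$model
    tab <- tables$regression
    curves <- lapply(model$predictors, function(f)
      if (length(unique(tab[[f]])) >= 2) ale_curve(model, tab, f)
      else NULL)
    curves <- Filter(Negate(is.null), curves)
    ale_tsv <- dplyr::bind_rows(lapply(curves, function(cv_)
      tibble::tibble(feature = cv_$feature, edge = cv_$edges,
                     ale = cv_$ale,
                     count = c(NA, cv_$counts))))
    readr::write_tsv(ale_tsv, out("ale_curves.tsv"))
    hp <- h_pairwise_all(model, tab, n_sample = config$h_sample,
                         seed = stage_seed(seed, "h_stats"))
    readr::write_tsv(hp, out("h_pairwise.tsv"))
    list(ale = curves, h_pairs = hp)
  })

  prov <- list(
    package_version = as.character(utils::packageVersion("recland")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    n_raw_cos = n_raw,
    n_filtered_cos = attr(map, "n_filtered_cos"),
    removed_individuals = length(attr(map, "removed_individuals")),
    meioses_total = attr(map, "meioses_total"),
    selected_model = selected$algorithm
  )
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(study = study, map = map, tables = tables, tests = tests,
                 glm = glm_fit, cv = cv, robustness = robustness,
                 selected = selected, ale = interp$ale,
                 h_pairs = interp$h_pairs))
}
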