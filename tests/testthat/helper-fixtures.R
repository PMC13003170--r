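# Shared fixtures, built in code.  The default-size synthetic study is
# expensive, so it is simulated once per test run and cached.

toy_layout <- function(n = 2, len = 1e7, cen_frac = 0.4) {
  genome_layout(
    chrom = c(paste0("A0", seq_len(ceiling(n / 2))),
              paste0("C0", seq_len(floor(n / 2))))[seq_len(n)],
    length = rep(len, n),
    subgenome = rep(c("A", "C"), length.out = n),
    centromere = rep(len * cen_frac, n),
    homoeolog_group = rep(seq_len(ceiling(n / 2)), length.out = n)
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default-condition synthetic study plus its recombination map.
shared_study <- function() cached("study", {
  study <- simulate_study(synth_config(seed = 2024))
  study$map <- build_recomb_map(study$cos, study$bins, study$snps,
                                seed = 11)
  study
})

# A small, fast study (reduced populations) for modelling tests where
# per-bin precision is not the point.
small_study <- function() cached("small_study", {
  cfg <- synth_config(seed = 7, n_individuals = c(pop1 = 250, pop2 = 260))
  study <- simulate_study(cfg)
  study$map <- build_recomb_map(study$cos, study$bins, study$snps,
                                seed = 11)
  study
})

# A custom-predict model for the interpretation module: `fun` maps a
# data frame of predictor columns to numeric predictions.  Registered
# against the stats generic so S3 dispatch finds it from inside the
# package namespace.
toy_model <- function(fun) structure(list(fun = fun), class = "toy_model")
predict.toy_model <- function(object, newdata, ...) object$fun(newdata)
registerS3method("predict", "toy_model", predict.toy_model,
                 envir = asNamespace("stats"))

# Uncorrelated uniform predictor table for analytic ALE / H cases.
uniform_table <- function(n, p = 2, seed = 1, min = -1, max = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(stats::runif(n * p, min, max), ncol = p))
    names(df) <- paste0("x", seq_len(p))
    tibble::as_tibble(df)
  })
}
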