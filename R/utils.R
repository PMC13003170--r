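# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp01 <- function(x) clamp(x, 0, 1)

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from a single master seed; each
#' stochastic stage draws its own seed through this pure function so that
#' re-running one stage cannot perturb another.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(master) %% 2147480009 * 31 + h) %% 2147480009)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Centred moving average with window `2*bw + 1`, edges shrunk to the
# available bins.  Used to make spatially autocorrelated synthetic tracks.
moving_average <- function(x, bw) {
  if (bw <= 0 || length(x) < 2) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - bw, 1)
  hi <- pmin(seq_len(n) + bw, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
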