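# Univariate hotspot-vs-non-hotspot statistics and the
# hotspot ~ SNP + subgenome logistic model.

#' Two-sample feature tests between hotspot and non-hotspot bins
#'
#' Each numeric feature is z-scored (jointly over both classes, which
#' leaves the t statistic unchanged) and compared between hotspot and
#' non-hotspot bins with a pooled-variance two-sample Student's t-test.
#' The binary subgenome feature is tested with a chi-square test on the
#' 2x2 hotspot-by-subgenome count table.  P-values are adjusted with the
#' Benjamini-Hochberg step-up procedure to control the false discovery
#' rate (`method = "bonferroni"` gives a strict Bonferroni sensitivity
#' analysis); adjusted p below `alpha` is flagged significant.
#'
#' Because non-hotspots are sampled per chromosome in equal numbers to
#' hotspots, label and subgenome are independent by construction inside
#' the balanced sample; the subgenome chi-square is therefore computed
#' on genome-wide hotspot counts (all non-SNP-empty bins) when `map` is
#' supplied, which is what the sampling design leaves free to vary.
#'
#' @param table A classification `feature_table` (binary `target`).
#' @param alpha Significance threshold on adjusted p (default 0.1).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @param map Optional `recomb_map` with a `C_subgenome` column or
#'   accompanied by `layout`; genome-wide counts for the subgenome
#'   chi-square.
#' @param layout Optional [genome_layout()] to derive subgenomes from
#'   `map` chromosomes.
#' @return Tibble: `feature`, `test`, `statistic`, `p`, `p_adj`,
#'   `significant`, `direction` (`"enriched"`/`"depleted"` in hotspots).
#' @export
hotspot_tests <- function(table, alpha = 0.1,
                          method = c("BH", "bonferroni"),
                          map = NULL, layout = NULL) {
  method <- match.arg(method)
  stopifnot(attr(table, "task") == "classification" ||
              all(table$target %in% c(0, 1)))
  y <- table$target
  if (length(unique(y)) < 2) stop("both classes must be non-empty")
  predictors <- attr(table, "predictors") %||%
    setdiff(names(table), c("chrom", "start", "end", "target", "snp_count"))
  rows <- lapply(predictors, function(f) {
    x <- table[[f]]
    if (f == "C_subgenome") {
      if (!is.null(map)) {
        if (!"C_subgenome" %in% names(map)) {
          if (is.null(layout))
            stop("supply layout to derive subgenomes from the map")
          map$C_subgenome <-
            as.integer(layout$subgenome[match(map$chrom,
                                              layout$chrom)] == "C")
        }
        mm <- map[!map$snp_empty, , drop = FALSE]
        yy <- as.integer(mm$hotspot_label == "hotspot")
        xx <- mm$C_subgenome
      } else {
        yy <- y; xx <- x
      }
      tab2 <- table(factor(yy, levels = c(0, 1)),
                    factor(xx, levels = sort(unique(xx))))
      ct <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE))
      dir <- if (mean(xx[yy == 1]) > mean(xx[yy == 0]))
        "enriched" else "depleted"
      tibble::tibble(feature = f, test = "chi_square",
                     statistic = unname(ct$statistic),
                     p = ct$p.value, direction = dir)
    } else {
      z <- (x - mean(x)) / stats::sd(x)
      if (!is.finite(z[1]) || stats::sd(x) == 0) {
        return(tibble::tibble(feature = f, test = "t_zero_variance",
                              statistic = 0, p = 1,
                              direction = "depleted"))
      }
      tt <- stats::t.test(z[y == 1], z[y == 0], var.equal = TRUE)
      tibble::tibble(feature = f, test = "t",
                     statistic = unname(tt$statistic), p = tt$p.value,
                     direction = if (mean(x[y == 1]) > mean(x[y == 0]))
                       "enriched" else "depleted")
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = method)
  out$significant <- out$p_adj < alpha
  out[, c("feature", "test", "statistic", "p", "p_adj", "significant",
          "direction")]
}

#' Logistic model of hotspot occurrence on SNP density and subgenome
#'
#' Fits `hotspot ~ snp_count + C_subgenome` by maximum likelihood
#' (binomial GLM, logit link) on all non-SNP-empty bins, where the
#' response marks membership in the top recombination-rate percentile.
#' Wald z statistics and two-sided normal p-values are reported per
#' term.  Perfect separation is reported, never silently returned.
#'
#' @param map A `recomb_map` (needs `hotspot_label`, `snp_count`,
#'   `snp_empty`) plus a `C_subgenome` indicator per bin (either a `map`
#'   column or supplied via `layout`).
#' @param layout Optional [genome_layout()] used to derive the subgenome
#'   flag from bin chromosomes.
#' @param zscore Z-score the SNP counts before fitting (default `FALSE`,
#'   i.e. raw counts).
#' @return A `hotspot_glm` list: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `z`, `p`), `converged`, `separation`, `fit`.
#' @export
hotspot_glm <- function(map, layout = NULL, zscore = FALSE) {
  assert_cols(map, c("hotspot_label", "snp_count", "snp_empty"))
  if (!"C_subgenome" %in% names(map)) {
    if (is.null(layout)) stop("supply a layout or a C_subgenome column")
    map$C_subgenome <-
      as.integer(layout$subgenome[match(map$chrom, layout$chrom)] == "C")
  }
  df <- map[!map$snp_empty, , drop = FALSE]
  df$hotspot <- as.integer(df$hotspot_label == "hotspot")
  if (length(unique(df$hotspot)) < 2)
    stop("need at least one hotspot and one non-hotspot bin")
  snp <- if (zscore) as.numeric(scale(df$snp_count)) else df$snp_count
  dat <- data.frame(hotspot = df$hotspot, snp = snp,
                    C_subgenome = df$C_subgenome)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(hotspot ~ snp + C_subgenome, family = stats::binomial(),
               data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(sm),
      estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p = sm[, 4]),
    converged = fit$converged,
    separation = warned,
    fit = fit
  ), class = "hotspot_glm")
}

#' @export
print.hotspot_glm <- function(x, ...) {
  cat("<hotspot_glm> hotspot ~ snp + C_subgenome\n")
  print(as.data.frame(x$coefficients), digits = 5)
  if (!x$converged) cat("WARNING: IRLS did not converge\n")
  if (x$separation) cat("WARNING: (quasi-)separation detected\n")
  invisible(x)
}
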