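# Per-bin multi-omic feature computation and feature-table assembly.

intervals_to_granges <- function(intervals, chr_levels) {
  GenomicRanges::GRanges(
    factor(intervals$chrom, levels = chr_levels),
    IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
}

#' Fraction of each bin covered by an annotation
#'
#' Within-type overlaps are merged (union semantics) before coverage, so
#' duplicated or overlapping annotation records never double-count.
#' When `trim_against` is supplied, regions overlapping any
#' higher-priority interval set are removed from this set first
#' (cross-type trimming, e.g. gene > TE).  Intervals extending beyond
#' chromosome bounds are clipped with a warning.
#'
#' @param intervals Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param bins A `bin_grid`.
#' @param trim_against Optional list of higher-priority interval tibbles.
#' @param layout Optional [genome_layout()] used to clip out-of-bounds
#'   intervals.
#' @return Numeric vector in `[0, 1]`, one covered fraction per bin.
#' @export
coverage_fraction <- function(intervals, bins, trim_against = NULL,
                              layout = NULL) {
  assert_cols(intervals, c("chrom", "start", "end"))
  chr_levels <- unique(bins$chrom)
  if (!is.null(layout)) {
    len <- layout$length[match(intervals$chrom, layout$chrom)]
    if (any(intervals$start < 0 | intervals$end > len, na.rm = TRUE)) {
      warning("interval(s) outside chromosome bounds were clipped")
      intervals$start <- pmax(intervals$start, 0)
      intervals$end <- pmin(intervals$end, len)
      intervals <- intervals[intervals$end > intervals$start, , drop = FALSE]
    }
  }
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals, chr_levels))
  if (!is.null(trim_against)) {
    for (higher in trim_against) {
      hg <- GenomicRanges::reduce(intervals_to_granges(higher, chr_levels))
      gr <- GenomicRanges::setdiff(gr, hg)
    }
  }
  bin_gr <- intervals_to_granges(bins, chr_levels)
  ov <- GenomicRanges::findOverlaps(gr, bin_gr)
  covered <- numeric(nrow(bins))
  if (length(ov) > 0) {
    w <- GenomicRanges::width(
      GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                bin_gr[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::subjectHits(ov), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  covered / (bins$end - bins$start)
}

bin_index_of <- function(chrom, pos, bins) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    b <- which(bins$chrom == ch)
    if (length(b) == 0) next
    sel <- which(chrom == ch)
    edges <- c(bins$start[b], bins$end[b][length(b)])
    k <- findInterval(pos[sel], edges)
    inside <- k >= 1 & k <= length(b) & pos[sel] < bins$end[b][length(b)]
    idx[sel[inside]] <- b[k[inside]]
  }
  idx
}

# Averaging cascade shared by single-base methylation features:
# per replicate rate -> mean over the tissue's replicates (cytosines not
# called in every replicate of a tissue are excluded from that tissue)
# -> mean over tissues -> unweighted mean over a bin's cytosines.
cytosine_rates <- function(calls) {
  calls$site <- paste(calls$chrom, calls$pos, sep = ":")
  reps_per_tissue <- tapply(calls$replicate, calls$tissue,
                            function(r) length(unique(r)))
  calls$rate <- calls$methylated / calls$total
  per_tissue <- dplyr::summarise(
    dplyr::group_by(calls, .data$site, .data$chrom, .data$pos,
                    .data$tissue),
    n_rep = dplyr::n_distinct(.data$replicate),
    rate = mean(.data$rate), .groups = "drop")
  per_tissue <- per_tissue[per_tissue$n_rep ==
                             reps_per_tissue[per_tissue$tissue], ]
  dplyr::summarise(dplyr::group_by(per_tissue, .data$site, .data$chrom,
                                   .data$pos),
                   rate = mean(.data$rate), .groups = "drop")
}

#' Single-base methylation rate per bin
#'
#' For each cytosine the methylation rate is methylated / total calls per
#' replicate; cytosines not called in all replicates of a tissue are
#' excluded from that tissue; rates are averaged across replicates, then
#' across tissues; the bin value is the unweighted mean over retained
#' cytosines.  Bins without a retained cytosine are `NA` (imputed at
#' table assembly).
#'
#' @param calls Cytosine call tibble (`chrom`, `pos` 0-based, `context`,
#'   `tissue`, `replicate`, `methylated`, `total`).
#' @param bins A `bin_grid`.
#' @param context `"CpG"`, `"CHG"` or `"CHH"`.
#' @return Numeric vector per bin (`NA` where undefined).
#' @export
methylation_rate <- function(calls, bins, context) {
  calls <- calls[calls$context == context, , drop = FALSE]
  if (nrow(calls) == 0) stop("no calls for context ", context)
  site <- cytosine_rates(calls)
  idx <- bin_index_of(site$chrom, site$pos, bins)
  out <- rep(NA_real_, nrow(bins))
  agg <- tapply(site$rate, idx, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Weighted methylation rate per bin
#'
#' Total methylated calls divided by total calls per bin, pooled over all
#' tissues and replicates (coverage-weighted, in contrast to the
#' single-base average of [methylation_rate()]).
#'
#' @inheritParams methylation_rate
#' @return Numeric vector per bin (`NA` for bins with zero total calls).
#' @export
weighted_methylation <- function(calls, bins, context) {
  calls <- calls[calls$context == context, , drop = FALSE]
  if (nrow(calls) == 0) stop("no calls for context ", context)
  idx <- bin_index_of(calls$chrom, calls$pos, bins)
  meth <- tapply(calls$methylated, idx, sum)
  tot <- tapply(calls$total, idx, sum)
  out <- rep(NA_real_, nrow(bins))
  out[as.integer(names(meth))] <- as.numeric(meth) / as.numeric(tot)
  out
}

#' TE-body CHH methylation per bin
#'
#' The single-base CHH methylation cascade restricted to cytosines whose
#' position falls inside an annotated transposable element.
#'
#' @inheritParams methylation_rate
#' @param te_intervals TE annotation tibble (`chrom`, `start`, `end`).
#' @return Numeric vector per bin (`NA` where no TE-resident CHH
#'   cytosine is retained).
#' @export
te_body_chh <- function(calls, te_intervals, bins) {
  calls <- calls[calls$context == "CHH", , drop = FALSE]
  if (nrow(calls) == 0) stop("no CHH calls")
  chr_levels <- unique(c(bins$chrom, te_intervals$chrom))
  pos_gr <- GenomicRanges::GRanges(
    factor(calls$chrom, levels = chr_levels),
    IRanges::IRanges(start = calls$pos + 1, width = 1))
  te_gr <- GenomicRanges::reduce(
    intervals_to_granges(te_intervals, chr_levels))
  inside <- IRanges::overlapsAny(pos_gr, te_gr)
  if (!any(inside)) return(rep(NA_real_, nrow(bins)))
  methylation_rate(calls[inside, , drop = FALSE], bins, context = "CHH")
}

#' GC content per bin
#'
#' Proportion of G and C bases per bin, case-insensitive; ambiguity codes
#' count as non-GC; the denominator is the true bin length.
#'
#' @param seqs A [Biostrings::DNAStringSet] named by chromosome.
#' @param bins A `bin_grid`.
#' @return Numeric vector in `[0, 1]` per bin.
#' @export
gc_content <- function(seqs, bins) {
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    if (!ch %in% names(seqs)) stop("sequence missing for ", ch)
    b <- which(bins$chrom == ch)
    if (max(bins$end[b]) > Biostrings::width(seqs[ch]))
      stop("sequence shorter than layout for ", ch)
    v <- Biostrings::Views(seqs[[ch]], start = bins$start[b] + 1,
                           end = bins$end[b])
    gc <- Biostrings::letterFrequency(v, letters = "GC")
    out[b] <- as.numeric(gc) / (bins$end[b] - bins$start[b])
  }
  out
}

#' Dinucleotide coverage per bin
#'
#' Fraction of bin positions covered by at least one occurrence of the
#' 2-mer; overlapping matches are union-covered (e.g. `"ATAT"` is fully
#' covered by `AT`).
#'
#' @inheritParams gc_content
#' @param dinuc Two-letter string, e.g. `"AT"`.
#' @return Numeric vector in `[0, 1]` per bin.
#' @export
dinucleotide_fraction <- function(seqs, bins, dinuc = "AT") {
  stopifnot(nchar(dinuc) == 2)
  out <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    if (!ch %in% names(seqs)) stop("sequence missing for ", ch)
    b <- which(bins$chrom == ch)
    m <- Biostrings::matchPattern(dinuc, seqs[[ch]])
    covered <- IRanges::reduce(IRanges::ranges(m))
    bin_ir <- IRanges::IRanges(start = bins$start[b] + 1, end = bins$end[b])
    ov <- IRanges::findOverlaps(covered, bin_ir)
    w <- IRanges::width(IRanges::pintersect(
      covered[S4Vectors::queryHits(ov)], bin_ir[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::subjectHits(ov), sum)
    frac <- numeric(length(b))
    frac[as.integer(names(agg))] <- as.numeric(agg)
    out[b] <- frac / (bins$end[b] - bins$start[b])
  }
  out
}

#' Chromatin-accessibility score per bin
#'
#' Per tissue, open-chromatin regions are merged and the accessible
#' length within the bin is transformed as
#' `log10(accessible_length + 1) / log10(bin_length)`, capped at 1; the
#' final score is the mean over tissues.  The log transform compresses
#' large tissue-specific peaks while keeping 0 = fully inaccessible and
#' 1 = fully accessible.
#'
#' @param ocr_by_tissue Named list of interval tibbles, one per tissue.
#' @param bins A `bin_grid`.
#' @return Numeric vector in `[0, 1]` per bin.
#' @export
accessibility_score <- function(ocr_by_tissue, bins) {
  stopifnot(length(ocr_by_tissue) > 0)
  len <- bins$end - bins$start
  scores <- vapply(ocr_by_tissue, function(ocr) {
    acc_len <- coverage_fraction(ocr, bins) * len
    clamp01(log10(acc_len + 1) / log10(len))
  }, numeric(nrow(bins)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(bins))
  rowMeans(scores)
}

#' Gene-expression score per bin
#'
#' Per gene: TPM averaged across replicates of each tissue, transformed
#' as `log10(mean_tpm + 0.1)`, then averaged across tissues.  Genes are
#' assigned to the bin containing their midpoint; the bin score is the
#' mean over its genes.  Gene-less bins take the transform floor
#' `log10(0.1) = -1`.  Genes without an expression record are treated as
#' TPM 0 with a warning.
#'
#' @param tpm Tibble `gene_id`, `tissue`, `replicate`, `tpm`.
#' @param gene_pos Tibble `chrom`, `start`, `end`, `gene_id`.
#' @param bins A `bin_grid`.
#' @return Numeric vector per bin.
#' @export
expression_score <- function(tpm, gene_pos, bins) {
  assert_cols(gene_pos, c("chrom", "start", "end", "gene_id"))
  missing <- setdiff(gene_pos$gene_id, unique(tpm$gene_id))
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) without expression record; TPM 0")
    pad <- tibble::tibble(gene_id = missing, tissue = tpm$tissue[1],
                          replicate = tpm$replicate[1], tpm = 0)
    tpm <- dplyr::bind_rows(tpm, pad)
  }
  per_tissue <- dplyr::summarise(
    dplyr::group_by(tpm, .data$gene_id, .data$tissue),
    tpm = mean(.data$tpm), .groups = "drop")
  per_tissue$val <- log10(per_tissue$tpm + 0.1)
  per_gene <- dplyr::summarise(dplyr::group_by(per_tissue, .data$gene_id),
                               val = mean(.data$val), .groups = "drop")
  mid <- floor((gene_pos$start + gene_pos$end) / 2)
  idx <- bin_index_of(gene_pos$chrom, mid, bins)
  val <- per_gene$val[match(gene_pos$gene_id, per_gene$gene_id)]
  out <- rep(log10(0.1), nrow(bins))
  agg <- tapply(val, idx, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Simple exponential smoothing
#'
#' `s_1 = x_1; s_t = alpha * x_t + (1 - alpha) * s_{t-1}`.  The initial
#' level is pinned at the first observation for reproducibility.  Apply
#' per chromosome, in bin order.
#'
#' @param x Numeric series (one chromosome).
#' @param alpha Smoothing parameter in `(0, 1]` (default 0.1).
#' @return Smoothed series of the same length.
#' @export
ses_smooth <- function(x, alpha = 0.1) {
  if (length(x) == 0) stop("empty series")
  stopifnot(alpha > 0, alpha <= 1)
  if (length(x) == 1) return(x)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = x[1]))
}

smooth_by_chrom <- function(x, chrom, alpha) {
  f <- factor(chrom, levels = unique(chrom))
  unsplit(lapply(split(x, f), ses_smooth, alpha = alpha), f)
}

#' Assemble a modelling feature table
#'
#' Joins the recombination map with per-bin feature tracks and builds the
#' table for one task.  Classification rows are the sampled hotspot /
#' non-hotspot bins with a binary target; regression rows are all
#' non-SNP-empty bins with the SNP-normalized rate as target.  SNP count
#' is kept as metadata but excluded from predictors.  Missing feature
#' values are imputed with the column median (counts logged).  When
#' `smooth = TRUE`, simple exponential smoothing is applied per
#' chromosome to the smoothable feature columns and to the regression
#' target, immediately before modelling; the binary classification
#' target, telomere distance and the subgenome flag are never smoothed.
#'
#' @param map A `recomb_map` from [build_recomb_map()].
#' @param features Per-bin feature tibble (same bin order as `map`).
#' @param task `"classification"` or `"regression"`.
#' @param smooth Apply SES smoothing (default `TRUE`).
#' @param alpha SES smoothing parameter (default 0.1).
#' @return A `feature_table` tibble with columns `chrom`, `start`, `end`,
#'   `target`, `snp_count` and the predictor columns; attributes `task`,
#'   `predictors`, `smoothable`, `imputation_log`.
#' @export
assemble_table <- function(map, features,
                           task = c("classification", "regression"),
                           smooth = TRUE, alpha = 0.1) {
  task <- match.arg(task)
  stopifnot(nrow(map) == nrow(features))
  unsmoothable <- c("telomere_distance", "C_subgenome")
  predictors <- setdiff(names(features), "snp_count")
  tab <- dplyr::bind_cols(
    map[, c("chrom", "start", "end")],
    features[, predictors, drop = FALSE])
  tab$snp_count <- if ("snp_count" %in% names(features))
    features$snp_count else map$snp_count
  # impute undefined feature values (e.g. bins with no retained cytosine)
  imputation_log <- list()
  for (col in predictors) {
    nas <- is.na(tab[[col]])
    if (any(nas)) {
      tab[[col]][nas] <- stats::median(tab[[col]], na.rm = TRUE)
      imputation_log[[col]] <- sum(nas)
    }
  }
  # smooth along the full contiguous bin grid, before any row subsetting,
  # so adjacent-bin noise is what gets averaged out
  smoothable <- setdiff(predictors, unsmoothable)
  if (smooth) {
    for (col in smoothable)
      tab[[col]] <- smooth_by_chrom(tab[[col]], tab$chrom, alpha)
  }
  if (task == "classification") {
    keep <- map$hotspot_label %in% c("hotspot", "non_hotspot_sampled")
    tab <- tab[keep, , drop = FALSE]
    tab$target <- as.integer(map$hotspot_label[keep] == "hotspot")
  } else {
    keep <- !map$snp_empty
    tab <- tab[keep, , drop = FALSE]
    tab$target <- map$normalized_rate[keep]
    if (smooth)
      tab$target <- smooth_by_chrom(tab$target, tab$chrom, alpha)
  }
  attr(tab, "task") <- task
  attr(tab, "predictors") <- predictors
  attr(tab, "smoothable") <- smoothable
  attr(tab, "smoothing_alpha") <- if (smooth) alpha else NULL
  attr(tab, "imputation_log") <- imputation_log
  class(tab) <- c("feature_table", class(tab))
  tab
}
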