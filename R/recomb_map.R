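#' Crossover interval set
#'
#' Container for crossover (CO) intervals detected across informative
#' meioses, together with the informative-meiosis count of each
#' population (two meioses per informative individual).
#'
#' @param records Tibble with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `individual`, `population` and optionally `generation`
#'   and the latent simulation coordinate `point`.
#' @param meioses Named numeric vector: informative meioses per
#'   population (all > 0).
#' @return A `co_set` list with elements `records` and `meioses`.
#' @export
co_set <- function(records, meioses) {
  assert_cols(records, c("chrom", "start", "end", "individual",
                         "population"), "CO records")
  if (nrow(records) > 0 && any(records$start >= records$end))
    stop("every CO interval must satisfy start < end")
  if (is.null(names(meioses)) || any(meioses <= 0))
    stop("meioses must be a named vector of positive counts")
  structure(list(records = tibble::as_tibble(records),
                 meioses = meioses),
            class = "co_set")
}

#' @export
print.co_set <- function(x, ...) {
  cat(sprintf("<co_set> %d CO intervals, %d individuals, %s meioses (%s)\n",
              nrow(x$records),
              length(unique(x$records$individual)),
              format(sum(x$meioses), big.mark = ","),
              paste(sprintf("%s: %s", names(x$meioses), x$meioses),
                    collapse = ", ")))
  invisible(x)
}

#' Remove COs from outlier individuals
#'
#' Drops every record of any individual whose total CO count over all
#' meiotic events and chromosomes *exceeds* `max_total` (an individual
#' with exactly `max_total` COs is retained).  Such individuals are
#' treated as genotyping artifacts; each removed individual also
#' subtracts two informative meioses from its population's count.
#'
#' @param cos A [co_set()].
#' @param max_total Maximum tolerated CO count per individual (default 100).
#' @return A filtered [co_set()] with attribute `removed_individuals`.
#' @export
filter_individuals <- function(cos, max_total = 100) {
  stopifnot(inherits(cos, "co_set"))
  if (nrow(cos$records) == 0) {
    out <- cos
    attr(out, "removed_individuals") <- character(0)
    return(out)
  }
  totals <- table(cos$records$individual)
  bad <- names(totals)[totals > max_total]
  keep <- !(cos$records$individual %in% bad)
  pop_of <- cos$records$population[match(bad, cos$records$individual)]
  meioses <- cos$meioses
  if (length(bad) > 0) {
    drop <- table(factor(pop_of, levels = names(meioses)))
    meioses <- meioses - 2 * as.numeric(drop)
    if (any(meioses <= 0))
      stop("individual filter removed an entire population")
  }
  out <- co_set(cos$records[keep, , drop = FALSE], meioses)
  attr(out, "removed_individuals") <- bad
  out
}

#' Discard overlong CO intervals
#'
#' Removes CO intervals strictly longer than `max_len` bp (an interval of
#' exactly `max_len` is retained); record order is preserved.  Long
#' intervals reflect sparse marker coverage rather than confident CO
#' placement.
#'
#' @param cos A [co_set()].
#' @param max_len Maximum interval length in bp (default 2,000,000).
#' @return A filtered [co_set()].
#' @export
filter_intervals <- function(cos, max_len = 2e6) {
  stopifnot(inherits(cos, "co_set"))
  keep <- (cos$records$end - cos$records$start) <= max_len
  out <- co_set(cos$records[keep, , drop = FALSE], cos$meioses)
  attr(out, "removed_individuals") <- attr(cos, "removed_individuals")
  out
}

#' Proportionally assign CO intervals to bins
#'
#' Each CO interval contributes weight `overlap(CO, bin) / length(CO)` to
#' every bin it overlaps, so the weights of one CO sum to one and total
#' CO mass is conserved across the grid.
#'
#' @param cos A [co_set()].
#' @param bins A `bin_grid` from [build_bins()].
#' @return Numeric vector of fractional CO counts, one per bin.
#' @export
assign_cos_to_bins <- function(cos, bins) {
  stopifnot(inherits(cos, "co_set"))
  rec <- cos$records
  counts <- numeric(nrow(bins))
  if (nrow(rec) == 0) return(counts)
  unknown <- setdiff(unique(rec$chrom), unique(bins$chrom))
  if (length(unknown) > 0)
    stop("CO on chromosome(s) absent from grid: ",
         paste(unknown, collapse = ", "))
  chr_levels <- unique(bins$chrom)
  co_gr <- GenomicRanges::GRanges(
    factor(rec$chrom, levels = chr_levels),
    IRanges::IRanges(start = rec$start + 1, end = rec$end))
  bin_gr <- GenomicRanges::GRanges(
    factor(bins$chrom, levels = chr_levels),
    IRanges::IRanges(start = bins$start + 1, end = bins$end))
  ov <- GenomicRanges::findOverlaps(co_gr, bin_gr)
  inter <- GenomicRanges::pintersect(co_gr[S4Vectors::queryHits(ov)],
                                     bin_gr[S4Vectors::subjectHits(ov)])
  w <- GenomicRanges::width(inter) /
    GenomicRanges::width(co_gr)[S4Vectors::queryHits(ov)]
  agg <- tapply(w, S4Vectors::subjectHits(ov), sum)
  counts[as.integer(names(agg))] <- as.numeric(agg)
  counts
}

#' Per-bin recombination rate in cM/Mbp
#'
#' `rate_i = 100 * (crossovers_i / meioses) / bin_length_Mbp_i`, using the
#' actual (possibly truncated) length of each bin.
#'
#' @param counts Fractional CO counts per bin ([assign_cos_to_bins()]).
#' @param meioses_total Total informative meioses (> 0).
#' @param bins The `bin_grid` the counts were computed on.
#' @return Numeric vector of rates in cM/Mbp.
#' @export
recombination_rate <- function(counts, meioses_total, bins) {
  if (!is.numeric(meioses_total) || meioses_total <= 0)
    stop("meioses_total must be positive")
  stopifnot(length(counts) == nrow(bins))
  len_mbp <- (bins$end - bins$start) / 1e6
  100 * (counts / meioses_total) / len_mbp
}

count_snps_per_bin <- function(bins, snps) {
  assert_cols(snps, c("chrom", "pos"))
  counts <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    b <- which(bins$chrom == ch)
    pos <- snps$pos[snps$chrom == ch]
    if (length(pos) == 0) next
    edges <- c(bins$start[b], bins$end[b][length(b)])
    h <- findInterval(pos, edges, left.open = FALSE)
    h <- h[h >= 1 & h <= length(b)]
    tab <- tabulate(h, nbins = length(b))
    counts[b] <- tab
  }
  counts
}

#' Build a binned recombination map
#'
#' Runs the map stage end to end: individual and interval quality
#' filters, proportional CO-to-bin assignment, the cM/Mbp rate formula,
#' SNP counting and SNP normalization, and hotspot / non-hotspot
#' labelling.
#'
#' @param cos A [co_set()] (raw; filters are applied internally).
#' @param bins A `bin_grid`.
#' @param snps Tibble of marker positions (`chrom`, `pos`).
#' @param seed Integer seed for non-hotspot sampling.
#' @param max_co_per_individual Individual filter threshold (default 100).
#' @param max_interval_len Interval filter threshold in bp (default 2 Mbp).
#' @param hotspot_top Genome-wide quantile above which a bin is a hotspot
#'   (default 0.95).
#' @param nonhotspot_below Quantile below which non-hotspots are sampled
#'   (default 0.75).
#' @param filter Apply the two quality filters (default `TRUE`).
#' @param population Optional population name: restrict the map to that
#'   population's COs and meioses (for cross-population correlation
#'   checks); default uses all populations, summing fractional counts
#'   and meiosis counts.
#' @return A `recomb_map` tibble: `chrom`, `start`, `end`, `midpoint`,
#'   `co_count`, `rate`, `snp_count`, `normalized_rate`, `snp_empty`,
#'   `hotspot_label`; attributes `meioses_total`, `n_filtered_cos`,
#'   `removed_individuals`.
#' @export
build_recomb_map <- function(cos, bins, snps, seed = 1,
                             max_co_per_individual = 100,
                             max_interval_len = 2e6,
                             hotspot_top = 0.95,
                             nonhotspot_below = 0.75,
                             filter = TRUE, population = NULL) {
  if (!is.null(population)) {
    if (!population %in% names(cos$meioses))
      stop("unknown population: ", population)
    cos <- co_set(cos$records[cos$records$population == population, ,
                              drop = FALSE],
                  cos$meioses[population])
  }
  if (filter) {
    cos <- filter_individuals(cos, max_co_per_individual)
    cos <- filter_intervals(cos, max_interval_len)
  }
  counts <- assign_cos_to_bins(cos, bins)
  meioses_total <- sum(cos$meioses)
  map <- tibble::as_tibble(bins)
  map$co_count <- counts
  map$rate <- recombination_rate(counts, meioses_total, bins)
  map$snp_count <- count_snps_per_bin(bins, snps)
  map$snp_empty <- map$snp_count == 0
  map$normalized_rate <- ifelse(map$snp_empty, NA_real_,
                                map$rate / map$snp_count)
  map$hotspot_label <- sample_hotspots(map, seed = seed,
                                       hotspot_top = hotspot_top,
                                       nonhotspot_below = nonhotspot_below)
  attr(map, "width") <- attr(bins, "width")
  attr(map, "meioses_total") <- meioses_total
  attr(map, "n_filtered_cos") <- nrow(cos$records)
  attr(map, "removed_individuals") <- attr(cos, "removed_individuals")
  class(map) <- c("recomb_map", class(map))
  map
}

#' Label hotspot and sampled non-hotspot bins
#'
#' Hotspots are bins whose (un-normalized) recombination rate is strictly
#' above the genome-wide 95th percentile; SNP-empty bins are excluded
#' from both the percentile computation and labelling.  For each
#' chromosome, the same number of non-hotspot bins as hotspot bins is
#' drawn uniformly without replacement from that chromosome's bins with
#' rate below the genome-wide 75th percentile.  If a chromosome has
#' fewer eligible bins than hotspots, the sample is truncated with a
#' warning.
#'
#' @param map Tibble with `chrom`, `rate`, `snp_empty`.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param hotspot_top,nonhotspot_below Genome-wide quantiles (defaults
#'   0.95 and 0.75).
#' @param on Column used for the percentiles (default `"rate"`).
#' @return Character vector: `"hotspot"`, `"non_hotspot_sampled"` or
#'   `"unlabelled"` per bin.
#' @export
sample_hotspots <- function(map, seed = 1, hotspot_top = 0.95,
                            nonhotspot_below = 0.75, on = "rate") {
  assert_cols(map, c("chrom", on, "snp_empty"))
  rate <- map[[on]]
  ok <- !map$snp_empty
  q_hot <- stats::quantile(rate[ok], hotspot_top, names = FALSE, type = 7)
  q_low <- stats::quantile(rate[ok], nonhotspot_below, names = FALSE,
                           type = 7)
  label <- rep("unlabelled", nrow(map))
  hot <- ok & rate > q_hot
  label[hot] <- "hotspot"
  eligible <- ok & !hot & rate < q_low
  with_seed(seed, {
    for (ch in unique(map$chrom)) {
      n_hot <- sum(hot & map$chrom == ch)
      if (n_hot == 0) next
      pool <- which(eligible & map$chrom == ch)
      if (length(pool) < n_hot) {
        warning(sprintf(
          "chromosome %s: only %d eligible non-hotspot bins for %d hotspots",
          ch, length(pool), n_hot))
        n_hot <- length(pool)
      }
      if (n_hot > 0) {
        pick <- if (length(pool) == 1) pool
                else sample(pool, n_hot, replace = FALSE)
        label[pick] <- "non_hotspot_sampled"
      }
    }
  })
  label
}
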