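make_cos <- function(df, meioses = c(pop1 = 100)) {
  if (!"individual" %in% names(df)) df$individual <- "i1"
  if (!"population" %in% names(df)) df$population <- "pop1"
  co_set(df, meioses)
}

test_that("the individual filter removes strictly-above-threshold individuals and their meioses", {
  rec <- tibble::tibble(
    chrom = "A01",
    start = rep(0, 201), end = rep(1000, 201),
    individual = c(rep("keep100", 100), rep("drop101", 101)),
    population = "pop1")
  cos <- co_set(rec, c(pop1 = 50))
  out <- filter_individuals(cos, max_total = 100)
  expect_setequal(unique(out$records$individual), "keep100")
  expect_equal(nrow(out$records), 100)
  expect_equal(attr(out, "removed_individuals"), "drop101")
  expect_equal(unname(out$meioses), 48)  # two meioses per removed individual

  empty <- co_set(rec[0, ], c(pop1 = 50))
  expect_equal(nrow(filter_individuals(empty)$records), 0)
})

test_that("the interval filter is strict on 'longer than' and preserves order", {
  rec <- tibble::tibble(
    chrom = "A01", start = c(0, 10, 20),
    end = c(2e6, 2e6 + 11, 120),
    individual = "i1", population = "pop1")
  cos <- co_set(rec, c(pop1 = 10))
  out <- filter_intervals(cos, max_len = 2e6)
  expect_equal(out$records$end - out$records$start, c(2e6, 100))
  expect_equal(out$records$start, c(0, 20))
  # identity on an all-short set
  short <- co_set(rec[3, ], c(pop1 = 10))
  expect_identical(filter_intervals(short)$records, short$records)
})

test_that("individual and interval filters commute on raw totals", {
  study <- small_study()
  cos <- study$cos
  a <- filter_intervals(filter_individuals(cos))
  b <- filter_individuals(filter_intervals(cos))
  # the individual threshold is evaluated on the raw set in path (a);
  # path (b) can only differ if interval removal changes who exceeds it
  ord <- function(d) d[order(d$chrom, d$start, d$individual), ]
  expect_equal(ord(a$records), ord(b$records), ignore_attr = TRUE)
})

test_that("proportional CO assignment splits weight by overlap and conserves mass", {
  lay <- genome_layout("A01", 1.2e6, "A", 5e5, 1L)
  bins <- build_bins(lay, 3e5)
  cos <- make_cos(tibble::tibble(chrom = "A01", start = 250e3, end = 550e3))
  w <- assign_cos_to_bins(cos, bins)
  expect_equal(w[1], 50e3 / 300e3)
  expect_equal(w[2], 250e3 / 300e3)
  expect_equal(sum(w), 1)

  inside <- make_cos(tibble::tibble(chrom = "A01", start = 310e3,
                                    end = 320e3))
  expect_equal(assign_cos_to_bins(inside, bins), c(0, 1, 0, 0))

  expect_error(assign_cos_to_bins(
    make_cos(tibble::tibble(chrom = "Z1", start = 0, end = 10)), bins),
    "absent")
})

test_that("vectorized assignment equals a per-CO loop oracle", {
  lay <- toy_layout(3, len = 4e6)
  bins <- build_bins(lay, 3e5)
  set.seed(99)
  n <- 1000
  chrom <- sample(lay$chrom, n, replace = TRUE)
  start <- floor(runif(n, 0, 3.5e6))
  len <- pmax(1, floor(rexp(n, 1 / 2e5)))
  end <- pmin(start + len, 4e6)
  cos <- make_cos(tibble::tibble(chrom = chrom, start = start, end = end))
  fast <- assign_cos_to_bins(cos, bins)
  # oracle: loop over COs, loop over bins, accumulate overlap fractions
  slow <- numeric(nrow(bins))
  for (i in seq_len(n)) {
    for (b in which(bins$chrom == chrom[i])) {
      ov <- max(0, min(end[i], bins$end[b]) - max(start[i], bins$start[b]))
      slow[b] <- slow[b] + ov / (end[i] - start[i])
    }
  }
  expect_equal(fast, slow, tolerance = 1e-9)
  expect_equal(sum(fast), n, tolerance = 1e-9)
})

test_that("the recombination-rate formula and its whole-genome identity hold", {
  lay <- genome_layout("A01", 3e5, "A", 1e5, 1L)
  bins <- build_bins(lay, 3e5)
  expect_equal(recombination_rate(3, 1000, bins), 1.0)
  expect_equal(recombination_rate(0, 1000, bins), 0.0)
  expect_error(recombination_rate(3, 0, bins), "positive")

  study <- small_study()
  map <- study$map
  len_mbp <- (map$end - map$start) / 1e6
  expect_equal(sum(map$rate * len_mbp),
               100 * attr(map, "n_filtered_cos") / attr(map, "meioses_total"),
               tolerance = 1e-9)
  expect_equal(sum(map$co_count), attr(map, "n_filtered_cos"),
               tolerance = 1e-9)
})

test_that("SNP normalization divides by counts and flags empty bins", {
  lay <- genome_layout("A01", 9e5, "A", 4e5, 1L)
  bins <- build_bins(lay, 3e5)
  snps <- tibble::tibble(chrom = "A01", pos = c(1e5, 1.1e5, 2e5, 2.5e5,
                                                4e5, 4.5e5))
  cos <- make_cos(tibble::tibble(chrom = "A01",
                                 start = c(0, 3.5e5), end = c(1e5, 4.5e5)),
                  meioses = c(pop1 = 10))
  map <- build_recomb_map(cos, bins, snps, seed = 1, filter = FALSE)
  expect_equal(map$snp_count, c(4L, 2L, 0L))
  expect_equal(map$snp_empty, c(FALSE, FALSE, TRUE))
  expect_equal(map$normalized_rate[1], map$rate[1] / 4)
  expect_true(is.na(map$normalized_rate[3]))

  # uniform SNP density: normalized profile rank-identical to raw
  study <- small_study()
  m <- study$map[!study$map$snp_empty, ]
  expect_equal(cor(rank(m$rate / mean(m$snp_count)), rank(m$rate)), 1)
})

test_that("hotspot sampling takes the top 5% and balances non-hotspots per chromosome", {
  set.seed(5)
  map1 <- tibble::tibble(chrom = "A01", rate = sample(1:100),
                         snp_empty = FALSE)
  lab <- sample_hotspots(map1, seed = 3)
  expect_equal(sum(lab == "hotspot"), 5)
  expect_equal(sum(lab == "non_hotspot_sampled"), 5)
  expect_equal(sum(lab == "hotspot" & lab == "non_hotspot_sampled"), 0)
  expect_true(all(map1$rate[lab == "hotspot"] > 95))
  expect_true(all(map1$rate[lab == "non_hotspot_sampled"] < 75.25))

  # all hotspots on chromosome 1: chromosome 2 contributes nothing
  map2 <- tibble::tibble(
    chrom = rep(c("A01", "C01"), each = 50),
    rate = c(51:100, 1:50), snp_empty = FALSE)
  lab2 <- sample_hotspots(map2, seed = 3)
  expect_true(all(which(lab2 == "hotspot") <= 50))
  expect_true(all(which(lab2 == "non_hotspot_sampled") <= 50))
  expect_equal(sum(lab2 == "hotspot"), sum(lab2 == "non_hotspot_sampled"))

  # determinism: same seed identical; other seed keeps the hotspot set
  expect_identical(lab, sample_hotspots(map1, seed = 3))
  lab_b <- sample_hotspots(map1, seed = 4)
  expect_identical(which(lab == "hotspot"), which(lab_b == "hotspot"))

  # SNP-empty bins are excluded from percentiles and labelling
  map3 <- map1
  map3$snp_empty <- map1$rate > 90
  lab3 <- sample_hotspots(map3, seed = 3)
  expect_true(all(!map3$snp_empty[lab3 == "hotspot"]))
})

test_that("per-population maps partition the pooled CO mass", {
  study <- small_study()
  pooled <- study$map
  m1 <- build_recomb_map(study$cos, study$bins, study$snps, seed = 11,
                         population = "pop1")
  m2 <- build_recomb_map(study$cos, study$bins, study$snps, seed = 11,
                         population = "pop2")
  expect_equal(m1$co_count + m2$co_count, pooled$co_count,
               tolerance = 1e-9)
  expect_equal(attr(m1, "meioses_total") + attr(m2, "meioses_total"),
               attr(pooled, "meioses_total"))
  # the two populations see the same landscape (strong rank agreement)
  ok <- !pooled$snp_empty
  expect_gt(cor(m1$rate[ok], m2$rate[ok], method = "spearman"), 0.6)
  expect_error(build_recomb_map(study$cos, study$bins, study$snps,
                                population = "nope"), "unknown")
})
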