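tiny_bins <- function(len = 1e4, width = 1e3, chrom = "A01") {
  build_bins(genome_layout(chrom, len, "A", len * 0.4, 1L), width)
}

test_that("coverage uses union semantics and splits across bin boundaries", {
  bins <- tiny_bins()
  dup <- tibble::tibble(chrom = "A01", start = c(0, 0), end = c(500, 500))
  expect_equal(coverage_fraction(dup, bins)[1], 0.5)
  span <- tibble::tibble(chrom = "A01", start = 900, end = 1200)
  cov <- coverage_fraction(span, bins)
  expect_equal(cov[1:2], c(0.1, 0.2))

  # cross-type trimming removes higher-priority regions first
  te <- tibble::tibble(chrom = "A01", start = 0, end = 1000)
  gene <- tibble::tibble(chrom = "A01", start = 0, end = 400)
  expect_equal(coverage_fraction(te, bins, trim_against = list(gene))[1],
               0.6)
})

test_that("coverage equals a per-base boolean-mask oracle on a toy genome", {
  len <- 1e4
  bins <- tiny_bins(len, 700)
  set.seed(42)
  n <- 60
  start <- sample(0:(len - 10), n, replace = TRUE)
  iv <- tibble::tibble(chrom = "A01", start = start,
                       end = pmin(start + sample(1:800, n, TRUE), len))
  fast <- coverage_fraction(iv, bins)
  mask <- logical(len)
  for (i in seq_len(n)) mask[(iv$start[i] + 1):iv$end[i]] <- TRUE
  slow <- vapply(seq_len(nrow(bins)), function(b)
    mean(mask[(bins$start[b] + 1):bins$end[b]]), numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
  expect_true(all(fast >= 0 & fast <= 1))
})

calls_fixture <- function() {
  tibble::tibble(
    chrom = "A01",
    pos = c(100, 100, 250, 250, 500),
    context = "CpG",
    tissue = c("leaf", "leaf", "leaf", "leaf", "leaf"),
    replicate = c("r1", "r2", "r1", "r2", "r1"),
    methylated = c(2, 1, 4, 4, 1),
    total = c(4, 1, 4, 4, 1))
}

test_that("single-base methylation applies the replicate/tissue averaging cascade", {
  bins <- tiny_bins(1e3, 1e3)
  # one cytosine, replicates 2/4 and 1/1 -> (0.5 + 1.0)/2 = 0.75
  one <- calls_fixture()[1:2, ]
  expect_equal(methylation_rate(one, bins, "CpG"), 0.75)
  # cytosine called in only one of two replicates is excluded
  partial <- calls_fixture()
  r <- methylation_rate(partial, bins, "CpG")
  expect_equal(r, mean(c(0.75, 1.0)))  # pos 500 (r1 only) excluded
  # all methylated -> 1
  all_m <- tibble::tibble(chrom = "A01", pos = c(10, 20), context = "CHH",
                          tissue = "leaf", replicate = "r1",
                          methylated = c(3, 5), total = c(3, 5))
  expect_equal(methylation_rate(all_m, bins, "CHH"), 1.0)
  expect_error(methylation_rate(all_m, bins, "CpG"), "no calls")
})

test_that("weighted methylation pools counts and matches single-base under uniform coverage", {
  bins <- tiny_bins(1e3, 1e3)
  two <- tibble::tibble(chrom = "A01", pos = c(100, 200), context = "CpG",
                        tissue = "leaf", replicate = "r1",
                        methylated = c(2, 1), total = c(4, 1))
  expect_equal(weighted_methylation(two, bins, "CpG"), 3 / 5)
  expect_equal(methylation_rate(two, bins, "CpG"), 0.75)
  uniform <- tibble::tibble(chrom = "A01", pos = c(100, 200),
                            context = "CpG", tissue = "leaf",
                            replicate = "r1",
                            methylated = c(2, 3), total = c(4, 4))
  expect_equal(weighted_methylation(uniform, bins, "CpG"),
               methylation_rate(uniform, bins, "CpG"))
})

test_that("TE-body CHH restricts the cascade to TE-resident cytosines", {
  bins <- tiny_bins(1e3, 1e3)
  calls <- tibble::tibble(chrom = "A01", pos = c(100, 200, 300),
                          context = "CHH", tissue = "leaf",
                          replicate = "r1",
                          methylated = c(1, 0, 1), total = c(1, 1, 2))
  te_none <- tibble::tibble(chrom = "A01", start = 800, end = 900)
  expect_true(is.na(te_body_chh(calls, te_none, bins)))
  te_all <- tibble::tibble(chrom = "A01", start = 0, end = 1000)
  expect_equal(te_body_chh(calls, te_all, bins),
               methylation_rate(calls, bins, "CHH"))
  # positional-membership oracle on random placements
  set.seed(3)
  pos <- sample(0:999, 60)
  rcalls <- tibble::tibble(chrom = "A01", pos = pos, context = "CHH",
                           tissue = "leaf", replicate = "r1",
                           methylated = rbinom(60, 5, 0.4), total = 5)
  te <- tibble::tibble(chrom = "A01", start = c(100, 600),
                       end = c(300, 950))
  member <- (pos >= 100 & pos < 300) | (pos >= 600 & pos < 950)
  expect_equal(te_body_chh(rcalls, te, bins),
               mean(rcalls$methylated[member] / rcalls$total[member]))
})

test_that("GC content and dinucleotide coverage follow base-level definitions", {
  seqs <- Biostrings::DNAStringSet(c(A01 = "ATGC", A02 = "ATAT",
                                     A03 = "AATT"))
  lay <- genome_layout(c("A01", "A02", "A03"), c(4, 4, 4),
                       rep("A", 3), c(2, 2, 2), 1:3)
  bins <- build_bins(lay, 4)
  expect_equal(gc_content(seqs, bins)[1], 0.5)
  at <- dinucleotide_fraction(seqs, bins, "AT")
  expect_equal(at[2], 1.0)   # overlapping matches union-covered
  expect_equal(at[3], 0.5)   # single central match covers 2 of 4 bases
})

test_that("accessibility transform is log-compressed, tissue-averaged and capped", {
  lay <- genome_layout("A01", 3e5, "A", 1e5, 1L)
  bins <- build_bins(lay, 3e5)
  none <- list(leaf = tibble::tibble(chrom = "A01", start = 1,
                                     end = 1)[0, ])
  expect_equal(accessibility_score(none, bins), 0)
  almost <- list(leaf = tibble::tibble(chrom = "A01", start = 0,
                                       end = 3e5 - 1))
  expect_equal(accessibility_score(almost, bins), 1)
  full <- list(leaf = tibble::tibble(chrom = "A01", start = 0, end = 3e5))
  expect_equal(accessibility_score(full, bins), 1)  # capped
  # mean over tissues
  half <- list(
    leaf = tibble::tibble(chrom = "A01", start = 0, end = 3e5 - 1),
    root = tibble::tibble(chrom = "A01", start = 1, end = 1)[0, ])
  expect_equal(accessibility_score(half, bins), 0.5)
})

test_that("expression score transforms, averages and floors gene-less bins", {
  lay <- genome_layout("A01", 6e5, "A", 2e5, 1L)
  bins <- build_bins(lay, 3e5)
  genes <- tibble::tibble(chrom = "A01", start = c(1e3, 2e3),
                          end = c(2e3, 3e3), gene_id = c("g1", "g2"))
  tpm <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"), tissue = c("leaf", "leaf", "leaf"),
    replicate = c("r1", "r2", "r1"), tpm = c(0.8, 1.0, 0))
  sc <- expression_score(tpm, genes, bins)
  expect_equal(sc[1], mean(c(log10(0.9 + 0.1), log10(0 + 0.1))))
  expect_equal(sc[1], mean(c(0, -1)))
  expect_equal(sc[2], -1)  # gene-less bin at the transform floor
  # missing expression record treated as TPM 0 with warning
  expect_warning(
    sc2 <- expression_score(tpm[tpm$gene_id == "g1", ], genes, bins),
    "without expression")
  expect_equal(sc2[1], mean(c(0, -1)))
})

test_that("exponential smoothing follows the pinned-init recursion", {
  expect_equal(ses_smooth(rep(3, 10)), rep(3, 10))
  expect_equal(ses_smooth(c(0, 10), alpha = 0.1), c(0, 1.0))
  x <- rnorm(50)
  expect_equal(ses_smooth(x, alpha = 1), x)
  expect_error(ses_smooth(numeric(0)), "empty")
  # recursion by hand
  y <- c(2, 4, 8, 1)
  s <- y[1]
  for (t in 2:4) s[t] <- 0.1 * y[t] + 0.9 * s[t - 1]
  expect_equal(ses_smooth(y, 0.1), s)
  # linear, shift-equivariant, range-bounded
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(ses_smooth(a + b), ses_smooth(a) + ses_smooth(b))
  expect_equal(ses_smooth(a + 5), ses_smooth(a) + 5)
  expect_true(all(ses_smooth(a) >= min(a) & ses_smooth(a) <= max(a)))
})

test_that("feature tables have the right rows, targets and round-trip exactly", {
  study <- small_study()
  tc <- assemble_table(study$map, study$features, "classification")
  expect_equal(nrow(tc),
               2 * sum(study$map$hotspot_label == "hotspot"))
  expect_setequal(unique(tc$target), c(0, 1))
  tr <- assemble_table(study$map, study$features, "regression")
  expect_equal(nrow(tr), sum(!study$map$snp_empty))
  expect_false(any(is.na(tr$target)))
  expect_false("snp_count" %in% attr(tr, "predictors"))
  expect_false(any(vapply(attr(tr, "predictors"), function(f)
    any(is.na(tr[[f]])), logical(1))))
  # unsmoothable columns pass through untouched
  tr0 <- assemble_table(study$map, study$features, "regression",
                        smooth = FALSE)
  expect_equal(tr$telomere_distance, tr0$telomere_distance)
  expect_equal(tr$C_subgenome, tr0$C_subgenome)
  expect_false(isTRUE(all.equal(tr$CpG, tr0$CpG)))

  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(tr, tmp)
  back <- read_feature_table(tmp)
  expect_equal(back$target, tr$target)
  expect_equal(back$CpG, tr$CpG)
  expect_equal(attr(back, "predictors"), attr(tr, "predictors"))
  unlink(c(tmp, paste0(tmp, ".meta.json")))
})
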