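#' Configuration for the synthetic two-subgenome recombination study
#'
#' The defaults emulate the statistical structure of a large rapeseed
#' recombination study: two multiparental populations (1243 and 1323
#' informative individuals, two meioses each), an expectation of 1.2 COs
#' per chromosome per meiosis, marker-resolution CO intervals from a
#' moderate-density genotyping array (~3.5 markers per 0.3-Mbp bin on
#' average, denser in gene-rich regions), centromere-suppressed CO
#' intensity, a subtelomeric positional CO preference in the A subgenome
#' (peak near relative telomere distance 0.25) versus an interior
#' preference in the C subgenome (peak near 0.75), bimodal
#' subgenome-shifted feature tracks (C more methylated and TE-rich, A
#' more gene-rich and expressed), and a small fraction of
#' genotyping-artifact individuals with inflated CO counts.
#'
#' @param seed Master seed; every stage derives its own via [stage_seed()].
#' @param bin_width Bin width in bp.
#' @param n_individuals Named vector of individuals per population.
#' @param meioses_per_individual Informative meioses per individual.
#' @param mean_co_per_chromosome Expected COs per chromosome per meiosis.
#' @param beta Named log-intensity coefficients of the planted feature
#'   effect (applied to the generated per-bin feature values).
#' @param pos_effect_A,pos_effect_C Positional log-intensity shapes as
#'   `list(peak, trough, width, height)` in relative telomere distance
#'   (0 = telomere, 1 = centromere): a Gaussian bump at `peak` minus an
#'   equal-height bump at `trough` (omit `trough` for a plain bump), so
#'   the default subgenome preferences are antisymmetric.
#' @param subgenome_co_offset Log-scale offset on the per-chromosome CO
#'   expectation of C-subgenome chromosomes (default -0.3): the
#'   intrinsic recombination deficit of the C subgenome beyond what
#'   features and position carry.
#' @param centromere_exclusion Half-width (bp) of the zero-CO window
#'   around each centromere.
#' @param snp_mean_per_bin Genome-wide mean marker count per full bin.
#' @param artifact_fraction Proportion of individuals with inflated CO
#'   counts (genotyping artifacts).
#' @param artifact_multiplier CO-intensity multiplier for artifact
#'   individuals.
#' @param noise_sd Scale of the smoothed per-track noise fields.
#' @param subgenome_offsets Named list overriding the default additive
#'   C-subgenome offsets per feature track.
#' @param state_shape Per-subgenome sigmoid parameters (`slope`, `mid`)
#'   of the latent chromatin-state baseline as a function of telomere
#'   distance; the steeper, earlier C default extends heterochromatin
#'   further along the C arms.
#' @param smooth_bandwidth Moving-average half-window (in bins) used to
#'   spatially autocorrelate the noise fields.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         bin_width = 3e5,
                         n_individuals = c(pop1 = 1243, pop2 = 1323),
                         meioses_per_individual = 2,
                         mean_co_per_chromosome = 1.2,
                         beta = c(CpG = -3.0, TE = -1.8, gene = 2.2),
                         pos_effect_A = list(peak = 0.25, trough = 0.75,
                                             width = 0.15, height = 1.6),
                         pos_effect_C = list(peak = 0.75, trough = 0.25,
                                             width = 0.15, height = 1.6),
                         subgenome_co_offset = -0.5,
                         centromere_exclusion = 2.5e6,
                         snp_mean_per_bin = 3.5,
                         artifact_fraction = 0.02,
                         artifact_multiplier = 4,
                         noise_sd = 1,
                         smooth_bandwidth = 4,
                         subgenome_offsets = NULL,
                         state_shape = list(A = c(slope = 6, mid = 0.55),
                                            C = c(slope = 12, mid = 0.15))) {
  stopifnot(mean_co_per_chromosome > 0,
            artifact_fraction >= 0, artifact_fraction < 1,
            noise_sd >= 0, bin_width > 0,
            all(n_individuals > 0))
  offsets <- list(CpG = 0.10, CHG = 0.08, CHH = 0.015, TE = 0.12,
                  retrotransposon = 0.10, transposon = 0.03,
                  gene = -0.08, expression = -0.05,
                  accessibility = -0.05, CHH_TEs = -0.01)
  if (!is.null(subgenome_offsets))
    offsets[names(subgenome_offsets)] <- subgenome_offsets
  structure(list(
    seed = seed, bin_width = bin_width,
    n_individuals = n_individuals,
    meioses_per_individual = meioses_per_individual,
    mean_co_per_chromosome = mean_co_per_chromosome,
    beta = beta, pos_effect_A = pos_effect_A, pos_effect_C = pos_effect_C,
    subgenome_co_offset = subgenome_co_offset,
    centromere_exclusion = centromere_exclusion,
    snp_mean_per_bin = snp_mean_per_bin,
    artifact_fraction = artifact_fraction,
    artifact_multiplier = artifact_multiplier,
    noise_sd = noise_sd, smooth_bandwidth = smooth_bandwidth,
    subgenome_offsets = offsets, state_shape = state_shape
  ), class = "synth_config")
}

# Smoothed noise field with ~unit marginal SD, one value per bin,
# independent per chromosome so tracks do not bleed across chromosome
# ends.  The moving average induces the spatial autocorrelation that
# makes exponential smoothing of the resulting tracks meaningful; the
# sqrt-window rescale keeps the per-bin SD at the configured scale.
noise_field <- function(bins, bw) {
  z <- stats::rnorm(nrow(bins))
  sm <- unlist(lapply(split(z, factor(bins$chrom,
                                      levels = unique(bins$chrom))),
                      moving_average, bw = bw), use.names = FALSE)
  sm * sqrt(2 * bw + 1)
}

#' Generate per-bin multi-omic feature tracks
#'
#' Builds a latent chromatin-state field per bin (low in gene-rich distal
#' euchromatin, high around centromeres; in the C subgenome the
#' heterochromatic state extends further along the arms) and derives all
#' feature tracks from it: methylation in the three contexts, TE /
#' transposon / retrotransposon coverage and CpG methylation rise with
#' the state, while gene coverage, expression and accessibility fall;
#' C-subgenome bins receive positive offsets on methylation/TE tracks
#' and negative offsets on gene/expression tracks (producing the bimodal
#' pooled distributions); TE-body CHH methylation is constructed to
#' covary positively with gene coverage; marker counts are drawn with
#' intensity increasing in gene coverage.
#'
#' @param layout A [genome_layout()].
#' @param bins A `bin_grid` on that layout.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with `features` (tibble of per-bin tracks incl.
#'   `telomere_distance`, `C_subgenome`, `snp_count`) and `truth`
#'   (latent chromatin state and generator snapshot).
#' @export
generate_features <- function(layout, bins, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(bins) == 0) stop("zero bins")
  d <- telomere_distance(bins, layout)
  isC <- layout$subgenome[match(bins$chrom, layout$chrom)] == "C"
  off <- config$subgenome_offsets
  bw <- config$smooth_bandwidth
  ns <- config$noise_sd
  with_seed(stage_seed(seed, "features"), {
    # chromatin state: sigmoidal rise toward the centromere; steeper and
    # earlier in C so heterochromatin reaches further into the arms
    shp <- config$state_shape
    c_base <- ifelse(isC,
                     stats::plogis(shp$C["slope"] * (d - shp$C["mid"])),
                     stats::plogis(shp$A["slope"] * (d - shp$A["mid"])))
    state <- clamp01(c_base + 0.22 * ns * noise_field(bins, bw))
    nuc <- noise_field(bins, bw)
    e <- function(s) s * ns * noise_field(bins, bw)
    gene <- clamp01(0.70 - 0.55 * state + off$gene * isC + e(0.045))
    feats <- tibble::tibble(
      CpG = clamp01(0.12 + 0.55 * state + off$CpG * isC + e(0.04)),
      CHG = clamp01(0.06 + 0.40 * state + off$CHG * isC + e(0.09)),
      CHH = clamp01(0.01 + 0.05 * state + off$CHH * isC + e(0.025)),
      CHH_TEs = clamp01(0.075 + 0.08 * gene + off$CHH_TEs * isC + e(0.020)),
      gene = gene,
      TE = clamp01(0.10 + 0.65 * state + off$TE * isC + e(0.045)),
      transposon = clamp01(0.04 + 0.18 * state + off$transposon * isC +
                             e(0.06)),
      retrotransposon = clamp01(0.05 + 0.50 * state +
                                  off$retrotransposon * isC + e(0.12)),
      accessibility = clamp01(0.15 + 0.55 * gene + off$accessibility * isC +
                                e(0.09)),
      expression = clamp(-1 + 1.8 * gene + off$expression * isC + e(0.35),
                         -1, 2),
      # nucleotide composition rides its own latent field: GC and AT are
      # tightly (anti-)correlated with each other but only weakly coupled
      # to chromatin state, so they form a correlated cluster without
      # being informative proxies for recombination
      GC = clamp01(0.365 + 0.008 * state + 0.035 * nuc + e(0.004)),
      AT = clamp01(0.23 - 0.006 * state - 0.028 * nuc + e(0.003)),
      telomere_distance = d,
      C_subgenome = as.integer(isC)
    )
    # marker density couples to gene content (ascertainment on polymorphic,
    # gene-rich regions); truncated terminal bins scale with true length
    len_frac <- (bins$end - bins$start) / config$bin_width
    lam <- 0.6 + 0.8 * feats$gene
    lam <- config$snp_mean_per_bin * lam / mean(lam) * len_frac
    feats$snp_count <- stats::rpois(nrow(bins), lam)
  })
  list(features = feats,
       truth = list(chromatin_state = state,
                    telomere_distance = d,
                    config = config))
}

# Gaussian bump at `peak`, optionally mirrored by an equal-height trough,
# so the two subgenomes' positional preferences can be antisymmetric.
pos_effect_value <- function(d, eff) {
  v <- eff$height * exp(-((d - eff$peak) / eff$width)^2)
  if (!is.null(eff$trough))
    v <- v - eff$height * exp(-((d - eff$trough) / eff$width)^2)
  v
}

#' Generate CO intervals and the SNP marker map
#'
#' Per-bin CO intensity is `exp(beta . x(b) + s_subgenome(d_tel(b)))`
#' scaled by bin length and clamped to zero inside the centromere
#' exclusion window.  Per individual, meiosis and chromosome, the CO
#' count is Poisson with the configured per-chromosome mean (inflated
#' for artifact individuals); CO point positions are sampled
#' proportionally to intensity and reported as the interval between the
#' two flanking markers, emulating array resolution.  COs falling
#' outside the marker range of a chromosome are undetectable and
#' dropped.
#'
#' @param layout,bins,config As in [generate_features()].
#' @param features The `features` tibble from [generate_features()].
#' @param truth The `truth` list from [generate_features()].
#' @param seed Integer seed.
#' @return List with `cos` (a [co_set()]; records carry the latent
#'   `point`), `snps` (tibble `chrom`, `pos`) and `truth` extended with
#'   `lambda` (per-bin intensity) and `artifact_individuals`.
#' @export
generate_recombination <- function(layout, bins, features, truth, config,
                                   seed = config$seed) {
  stopifnot(inherits(config, "synth_config"),
            nrow(features) == nrow(bins))
  d <- truth$telomere_distance
  isC <- layout$subgenome[match(bins$chrom, layout$chrom)] == "C"
  beta <- config$beta
  eta <- numeric(nrow(bins))
  for (nm in names(beta)) {
    if (!nm %in% names(features))
      stop("beta names a feature absent from the table: ", nm)
    eta <- eta + beta[[nm]] * features[[nm]]
  }
  eta <- eta + ifelse(isC, pos_effect_value(d, config$pos_effect_C),
                      pos_effect_value(d, config$pos_effect_A))
  cen <- layout$centromere[match(bins$chrom, layout$chrom)]
  excl <- abs(bins$midpoint - cen) < config$centromere_exclusion
  lambda <- exp(eta) * (bins$end - bins$start)
  lambda[excl] <- 0
  bychrom <- split(seq_len(nrow(bins)),
                   factor(bins$chrom, levels = layout$chrom))
  if (any(vapply(bychrom, function(i) sum(lambda[i]), 0) == 0))
    stop("all-zero CO intensity on at least one chromosome")

  with_seed(stage_seed(seed, "recombination"), {
    # marker map first: positions uniform within bins, counts from the
    # feature stage's ascertainment model
    nsnp <- features$snp_count
    snps <- tibble::tibble(
      chrom = rep(bins$chrom, nsnp),
      pos = floor(rep(bins$start, nsnp) +
                    stats::runif(sum(nsnp)) * rep(bins$end - bins$start,
                                                  nsnp))
    )
    snps <- dplyr::arrange(snps, .data$chrom, .data$pos)

    pops <- names(config$n_individuals)
    ind <- unlist(lapply(pops, function(p)
      sprintf("%s_ind%04d", p, seq_len(config$n_individuals[[p]]))))
    pop_of <- rep(pops, config$n_individuals)
    n_ind <- length(ind)
    artifact <- stats::runif(n_ind) < config$artifact_fraction
    generation <- sample(c("G2", "G3", "G4"), n_ind, replace = TRUE,
                         prob = c(0.25, 0.35, 0.40))
    n_chr <- nrow(layout)
    n_mei <- config$meioses_per_individual
    mult <- ifelse(artifact, config$artifact_multiplier, 1)
    # CO counts per individual x meiosis x chromosome; the C subgenome
    # carries an intrinsic deficit beyond features and position
    chr_mean <- config$mean_co_per_chromosome *
      exp((config$subgenome_co_offset %||% 0) *
            (layout$subgenome == "C"))
    mu <- rep_len(chr_mean, n_chr * n_mei * length(ind)) *
      rep(mult, each = n_chr * n_mei)
    n_co <- stats::rpois(n_ind * n_mei * n_chr, mu)
    chr_idx <- rep_len(rep(seq_len(n_chr), n_mei), n_ind * n_mei * n_chr)
    ind_idx <- rep(seq_len(n_ind), each = n_chr * n_mei)
    co_chr <- rep(chr_idx, n_co)
    co_ind <- rep(ind_idx, n_co)
    # sample a bin for every CO, per chromosome, proportional to lambda
    ord <- order(co_chr)
    co_chr <- co_chr[ord]; co_ind <- co_ind[ord]
    co_bin <- integer(length(co_chr))
    for (ci in seq_len(n_chr)) {
      sel <- which(co_chr == ci)
      if (length(sel) == 0) next
      idx <- bychrom[[ci]]
      co_bin[sel] <- idx[sample.int(length(idx), length(sel),
                                    replace = TRUE,
                                    prob = lambda[idx])]
    }
    point <- floor(bins$start[co_bin] +
                     stats::runif(length(co_bin)) *
                       (bins$end[co_bin] - bins$start[co_bin]))
    co_chrom <- bins$chrom[co_bin]
    # resolve each CO point to its flanking-marker interval
    start <- end <- rep(NA_real_, length(point))
    for (ch in layout$chrom) {
      sel <- which(co_chrom == ch)
      if (length(sel) == 0) next
      mpos <- snps$pos[snps$chrom == ch]
      if (length(mpos) < 2) next
      k <- findInterval(point[sel], mpos)
      inside <- k >= 1 & k < length(mpos)
      start[sel[inside]] <- mpos[k[inside]]
      end[sel[inside]] <- mpos[k[inside] + 1]
    }
    keep <- !is.na(start) & end > start
    records <- tibble::tibble(
      chrom = co_chrom[keep],
      start = start[keep],
      end = end[keep],
      individual = ind[co_ind[keep]],
      population = pop_of[co_ind[keep]],
      generation = generation[co_ind[keep]],
      point = point[keep]
    )
    meioses <- stats::setNames(
      config$n_individuals * n_mei, pops)
    truth$lambda <- lambda
    truth$artifact_individuals <- ind[artifact]
    list(cos = co_set(records, meioses), snps = snps, truth = truth)
  })
}

#' Simulate a complete synthetic recombination study
#'
#' Convenience wrapper chaining [generate_features()] and
#' [generate_recombination()] on a layout (default: the packaged
#' rapeseed-like layout).
#'
#' @param config A [synth_config()].
#' @param layout A [genome_layout()] (default [default_layout()]).
#' @return List with `layout`, `bins`, `features`, `cos`, `snps`,
#'   `truth`.
#' @export
simulate_study <- function(config = synth_config(),
                           layout = default_layout()) {
  bins <- build_bins(layout, config$bin_width)
  f <- generate_features(layout, bins, config)
  r <- generate_recombination(layout, bins, f$features, f$truth, config)
  list(layout = layout, bins = bins, features = f$features,
       cos = r$cos, snps = r$snps, truth = r$truth)
}
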