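#' Genome layout: chromosomes, subgenomes, centromeres, homoeolog groups
#'
#' A genome layout is a tibble with one row per chromosome and columns
#' `chrom`, `length` (bp), `subgenome` (`"A"` or `"C"`), `centromere`
#' (bp, a single representative position strictly inside the chromosome)
#' and `homoeolog_group` (integer id shared by homoeologous chromosomes).
#'
#' @param chrom Character chromosome labels.
#' @param length Chromosome lengths in base pairs (> 0).
#' @param subgenome `"A"` or `"C"` per chromosome.
#' @param centromere Centromere position in bp, `0 < centromere < length`.
#' @param homoeolog_group Integer group ids; homoeologs share an id.
#' @return A `genome_layout` tibble.
#' @export
genome_layout <- function(chrom, length, subgenome, centromere,
                          homoeolog_group) {
  stopifnot(length(chrom) == length(length),
            length(chrom) == length(subgenome),
            length(chrom) == length(centromere),
            length(chrom) == length(homoeolog_group))
  if (anyDuplicated(chrom)) stop("duplicated chromosome labels")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (!all(subgenome %in% c("A", "C")))
    stop("subgenome must be 'A' or 'C'")
  if (any(centromere <= 0 | centromere >= length))
    stop("every centromere must satisfy 0 < centromere < length")
  out <- tibble::tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    subgenome = as.character(subgenome),
    centromere = as.numeric(centromere),
    homoeolog_group = as.integer(homoeolog_group)
  )
  class(out) <- c("genome_layout", class(out))
  out
}

#' Default 19-chromosome rapeseed-like layout
#'
#' Ten A-subgenome chromosomes (A01-A10) and nine C-subgenome chromosomes
#' (C01-C09) with lengths and single-point centromere positions emulating
#' the *Brassica napus* genome (~293 Mbp A, ~435 Mbp C).  Homoeolog groups
#' pair A0k with C0k for k = 1..8; A09, A10 and C09 form the ninth group.
#'
#' @return A [genome_layout()] tibble with 19 rows.
#' @export
default_layout <- function() {
  path <- system.file("extdata", "rapeseed_layout.tsv", package = "recland",
                      mustWork = TRUE)
  read_layout(path)
}

#' Build a fixed-width bin grid over a genome layout
#'
#' Partitions every chromosome into non-overlapping, contiguous bins of
#' `width` bp (0-based half-open).  The final bin of a chromosome is
#' truncated at the chromosome end and keeps its true, shorter length.
#'
#' @param layout A [genome_layout()].
#' @param width Bin width in bp (default 300,000).
#' @return A `bin_grid` tibble with columns `chrom`, `start`, `end`,
#'   `midpoint` and attribute `width`.
#' @export
build_bins <- function(layout, width = 3e5) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("width must be a single positive number")
  if (nrow(layout) == 0) stop("empty layout")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(
      chrom = layout$chrom[i],
      start = starts,
      end = pmin(starts + width, len)
    )
  })
  out <- dplyr::bind_rows(pieces)
  out$midpoint <- (out$start + out$end) / 2
  attr(out, "width") <- width
  class(out) <- c("bin_grid", class(out))
  out
}

#' Relative telomere distance of bin midpoints
#'
#' For each bin midpoint, the position along its chromosome arm expressed
#' as a ratio: 0 at the telomere of the arm containing the midpoint and 1
#' at the centromere.  `orientation = "centromere"` returns the reflected
#' ratio (0 at the centromere, 1 at the telomere), the form in which the
#' quantity is sometimes written as distance-from-centromere over arm
#' length.
#'
#' @param bins A `bin_grid` (or any tibble with `chrom` and `midpoint`).
#' @param layout A [genome_layout()] containing every bin chromosome.
#' @param orientation `"telomere"` (default; 0 = telomere, 1 = centromere)
#'   or `"centromere"` for the reflection.
#' @return Numeric vector in `[0, 1]`, one value per bin.
#' @export
telomere_distance <- function(bins, layout,
                              orientation = c("telomere", "centromere")) {
  orientation <- match.arg(orientation)
  assert_cols(bins, c("chrom", "midpoint"))
  idx <- match(bins$chrom, layout$chrom)
  if (anyNA(idx))
    stop("bin chromosome(s) absent from layout: ",
         paste(unique(bins$chrom[is.na(idx)]), collapse = ", "))
  cen <- layout$centromere[idx]
  len <- layout$length[idx]
  m <- bins$midpoint
  d <- ifelse(m <= cen, m / cen, (len - m) / (len - cen))
  d <- clamp01(d)
  if (orientation == "centromere") d <- 1 - d
  d
}

#' Homoeolog-grouped fold assignment for cross-validation
#'
#' With no subgenome filter, folds are the homoeolog groups of the layout
#' (nine in the default rapeseed layout).  When models are built from a
#' single subgenome, homoeolog groups are replaced by chromosomes: one
#' fold per chromosome of that subgenome.
#'
#' @param layout A [genome_layout()].
#' @param subgenome Optional `"A"` or `"C"` filter.
#' @return Tibble with columns `chrom` and `fold` (integer fold id);
#'   every retained chromosome appears in exactly one fold.
#' @export
homoeolog_folds <- function(layout, subgenome = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(subgenome)) {
    fold <- match(layout$homoeolog_group,
                  sort(unique(layout$homoeolog_group)))
    return(tibble::tibble(chrom = layout$chrom, fold = fold))
  }
  if (!subgenome %in% c("A", "C"))
    stop("unknown subgenome filter: ", subgenome)
  keep <- layout[layout$subgenome == subgenome, ]
  tibble::tibble(chrom = keep$chrom, fold = seq_len(nrow(keep)))
}
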