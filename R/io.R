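# File-format boundary.  All internal intervals are 0-based half-open;
# readers convert 1-based closed dialects (GFF3, cytosine reports) on the
# way in and writers convert back where a dialect requires it.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read / write a genome layout TSV
#'
#' Columns: `chrom`, `length`, `subgenome`, `centromere`,
#' `homoeolog_group`.
#'
#' @param path File path.
#' @return [read_layout()] returns a [genome_layout()].
#' @export
read_layout <- function(path) {
  df <- read_tsv_quiet(path)
  assert_cols(df, c("chrom", "length", "subgenome", "centromere",
                    "homoeolog_group"), "layout file")
  genome_layout(df$chrom, df$length, df$subgenome, df$centromere,
                df$homoeolog_group)
}

#' @rdname read_layout
#' @param layout A [genome_layout()].
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(as.data.frame(layout), path)
  invisible(path)
}

#' Read a BED(-like) interval file
#'
#' BED intervals are 0-based half-open and are kept as such internally.
#' Headerless files get columns `chrom`, `start`, `end` (extra columns are
#' named `V4`, `V5`, ...).
#'
#' @param path File path.
#' @param col_names Optional column names for columns beyond the third.
#' @return Tibble with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, col_names = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  nm <- c("chrom", "start", "end")
  extra <- ncol(df) - 3
  if (extra > 0) {
    more <- if (!is.null(col_names)) col_names else paste0("V", 3 + seq_len(extra))
    nm <- c(nm, more[seq_len(extra)])
  }
  names(df) <- nm
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("malformed BED coordinates in ", path)
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad) > 0)
    stop("malformed BED record(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (+ extras).
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(as.data.frame(intervals), path, col_names = FALSE)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Uses the standard GFF3 parser and converts the 1-based closed
#' coordinates to the internal 0-based half-open convention.
#'
#' @param path GFF3 file path.
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @return Tibble `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
        else paste0("gene", seq_along(gr))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    gene_id = id
  )
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read / write crossover interval tables
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `individual`,
#' `population`, `generation` (0-based half-open coordinates).  The
#' meiosis counts per population travel in a two-column sidecar-style
#' header comment when written by [write_co_tsv()]; [read_co_tsv()]
#' accepts them via the `meioses` argument instead.
#'
#' @param path File path.
#' @param meioses Named numeric vector: informative meioses per population.
#' @return A [co_set()].
#' @export
read_co_tsv <- function(path, meioses) {
  df <- read_tsv_quiet(path)
  assert_cols(df, c("chrom", "start", "end", "individual", "population"),
              "CO file")
  if (!"generation" %in% names(df)) df$generation <- NA_character_
  co_set(df, meioses)
}

#' @rdname read_co_tsv
#' @param cos A [co_set()].
#' @export
write_co_tsv <- function(cos, path) {
  df <- cos$records
  df$point <- NULL  # latent simulation coordinate, not part of the contract
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write SNP marker positions
#'
#' TSV with columns `chrom`, `pos` (0-based).
#'
#' @param path File path.
#' @return Tibble `chrom`, `pos`.
#' @export
read_snp_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_cols(df, c("chrom", "pos"), "SNP file")
  df
}

#' @rdname read_snp_tsv
#' @param snps Tibble with `chrom`, `pos`.
#' @export
write_snp_tsv <- function(snps, path) {
  readr::write_tsv(as.data.frame(snps), path)
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' TSV with columns `chrom`, `pos` (1-based, converted to 0-based
#' internally), `context` (CpG/CHG/CHH), `tissue`, `replicate`,
#' `methylated`, `total`.
#'
#' @param path File path.
#' @return Tibble of cytosine calls with 0-based `pos`.
#' @export
read_cytosine_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_cols(df, c("chrom", "pos", "context", "tissue", "replicate",
                    "methylated", "total"), "cytosine report")
  if (any(df$methylated > df$total | df$methylated < 0))
    stop("methylated calls must satisfy 0 <= methylated <= total")
  df$pos <- df$pos - 1
  df
}

#' Read a per-gene TPM matrix
#'
#' Long TSV with columns `gene_id`, `tissue`, `replicate`, `tpm`.
#'
#' @param path File path.
#' @return Tibble of TPM records.
#' @export
read_tpm_tsv <- function(path) {
  df <- read_tsv_quiet(path)
  assert_cols(df, c("gene_id", "tissue", "replicate", "tpm"), "TPM table")
  df
}

#' Write a feature table with a sidecar metadata file
#'
#' The table itself is plain TSV; `<path>.meta.json` records the target
#' column, predictor columns, smoothable flags and the imputation log.
#'
#' @param table A feature table from [assemble_table()].
#' @param path Output TSV path.
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(as.data.frame(table), path)
  meta <- list(
    task = attr(table, "task"),
    predictors = attr(table, "predictors"),
    smoothable = attr(table, "smoothable"),
    smoothing_alpha = attr(table, "smoothing_alpha"),
    imputation_log = attr(table, "imputation_log")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_quiet(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "task") <- meta$task
    attr(df, "predictors") <- meta$predictors
    attr(df, "smoothable") <- meta$smoothable
    attr(df, "smoothing_alpha") <- meta$smoothing_alpha
  }
  df
}
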