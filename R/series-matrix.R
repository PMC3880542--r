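# Minimal GEO series-matrix reader for the optional real-data mode.
# Only the expression table and the `!Sample_*` metadata lines are
# parsed; probe-level records are collapsed to gene symbols by median.

#' Read a GEO series-matrix file
#'
#' Parses the tab-delimited table between `!series_matrix_table_begin`
#' and `!series_matrix_table_end` plus the `!Sample_*` metadata lines.
#' Intended for accession-based checks of the screen on deposited array
#' data; tests run entirely on synthetic files in the same format.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return list with `intensities` (numeric matrix, rows = IDs, columns =
#'   samples) and `sample_info` (data.frame of `!Sample_*` fields, one row
#'   per sample).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("no series-matrix table found in ", path, call. = FALSE)
  }
  tab <- read.table(
    text = lines[(begin + 1L):(end - 1L)],
    header = TRUE, sep = "\t", quote = "\"", check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = ""
  )
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- as.character(tab[[1L]])
  storage.mode(mat) <- "double"

  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  sample_info <- NULL
  if (length(meta_lines) > 0L) {
    fields <- lapply(strsplit(meta_lines, "\t"), function(x) {
      gsub("^\"|\"$", "", x)
    })
    keys <- sub("^!Sample_", "", vapply(fields, `[[`, "", 1L))
    vals <- lapply(fields, function(x) x[-1L])
    n <- max(lengths(vals))
    sample_info <- as.data.frame(
      lapply(vals, function(v) c(v, rep(NA_character_, n - length(v)))),
      col.names = make.unique(keys), stringsAsFactors = FALSE
    )
  }
  list(intensities = mat, sample_info = sample_info)
}

#' Collapse probe-level rows to gene symbols
#'
#' Median of probes per gene symbol (robust, order-independent). Rows with
#' an empty or missing symbol are dropped.
#'
#' @param intensities numeric matrix with probe rownames.
#' @param symbols character vector mapping each row to a gene symbol.
#' @return numeric matrix with one row per gene symbol.
#' @export
collapse_probes <- function(intensities, symbols) {
  if (length(symbols) != nrow(intensities)) {
    stop("`symbols` must have one entry per probe row", call. = FALSE)
  }
  keep <- !is.na(symbols) & symbols != ""
  intensities <- intensities[keep, , drop = FALSE]
  symbols <- symbols[keep]
  genes <- sort(unique(symbols))
  out <- vapply(genes, function(g) {
    apply(intensities[symbols == g, , drop = FALSE], 2L, median)
  }, numeric(ncol(intensities)))
  out <- matrix(out,
    nrow = ncol(intensities),
    dimnames = list(colnames(intensities), genes)
  )
  t(out)
}

#' Screen a series-matrix file for differential expression
#'
#' The real-data path of the screen: read the series matrix, optionally
#' collapse probes to genes, build an [expression_matrix()] from the
#' supplied condition labels, normalize per chip and classify by the
#' fold-change cutoff.
#'
#' @param path series-matrix file.
#' @param condition character vector (`"control"`/`"treated"`), named by
#'   sample column or in column order.
#' @param symbols optional probe-to-symbol map for collapsing.
#' @param cutoff,percentile screen parameters as in [de_table()] and
#'   [normalize_percentile()].
#' @return list with `de` (the full table) and `partition` (per
#'   [partition_by_cutoff()]).
#' @export
screen_series_matrix <- function(path, condition, symbols = NULL,
                                 cutoff = 1.3, percentile = 50) {
  sm <- read_series_matrix(path)
  mat <- sm$intensities
  if (!is.null(symbols)) mat <- collapse_probes(mat, symbols)
  em <- expression_matrix(mat, condition)
  norm <- normalize_percentile(em, percentile)
  de <- de_table(fold_change(norm), cutoff)
  list(de = de, partition = partition_by_cutoff(de, cutoff))
}
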