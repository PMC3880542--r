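# Light container for gene-level one-colour array intensities.

#' Construct an expression matrix with condition labels
#'
#' @param intensities numeric matrix, genes x samples, non-negative, with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#' @param condition character vector, one of `"control"`/`"treated"` per
#'   sample (named or in column order).
#' @return object of class `"expression_matrix"`: a list with elements
#'   `intensities` and `condition`.
#' @export
expression_matrix <- function(intensities, condition) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities))) {
    stop("gene identifiers (rownames) must be present and unique",
      call. = FALSE
    )
  }
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities))) {
    stop("sample identifiers (colnames) must be present and unique",
      call. = FALSE
    )
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.null(names(condition))) {
    if (!setequal(names(condition), colnames(intensities))) {
      stop("names of `condition` do not match sample identifiers",
        call. = FALSE
      )
    }
    condition <- condition[colnames(intensities)]
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(intensities)) {
    stop("`condition` must have one label per sample", call. = FALSE)
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'", call. = FALSE)
  }
  if (!all(table(factor(condition, c("control", "treated"))) >= 0L) ||
    length(unique(condition)) < 1L) {
    stop("at least one sample required", call. = FALSE)
  }
  structure(
    list(
      intensities = intensities,
      condition = setNames(condition, colnames(intensities))
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(
    "expression_matrix:", nrow(x$intensities), "genes x",
    ncol(x$intensities), "samples (",
    paste(names(tab), tab, sep = "=", collapse = ", "), ")\n"
  )
  invisible(x)
}

#' Write / read a tab-delimited expression matrix with a condition sidecar
#'
#' The matrix file has a `gene` column followed by one column per sample;
#' the sidecar (default `<path>.conditions`) maps sample id to condition.
#'
#' @param x an [expression_matrix()].
#' @param path output path for the matrix TSV.
#' @param condition_path sidecar path (default `paste0(path, ".conditions")`).
#' @return `write_expression_matrix()`: `path`, invisibly.
#'   `read_expression_matrix()`: an [expression_matrix()].
#' @export
write_expression_matrix <- function(x, path,
                                    condition_path = paste0(
                                      path, ".conditions"
                                    )) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(
    gene = rownames(x$intensities), x$intensities,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(
    data.frame(
      sample = names(x$condition), condition = unname(x$condition),
      stringsAsFactors = FALSE
    ),
    condition_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path,
                                   condition_path = paste0(
                                     path, ".conditions"
                                   )) {
  df <- read.table(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  cond <- read.table(condition_path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  expression_matrix(mat, setNames(cond$condition, cond$sample))
}
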