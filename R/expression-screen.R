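# Per-chip percentile normalization, signed fold changes and the
# |FC| >= cutoff partition.

#' Per-chip percentile normalization
#'
#' Divides every array (column) by its own `percentile`-th intensity, the
#' GeneSpring-style per-chip 50th-percentile method by default: after
#' normalization the median of every array is 1.
#'
#' @param x an [expression_matrix()] or bare numeric matrix (genes x
#'   samples).
#' @param percentile percentile in `(0, 100]`; default 50 (the median).
#' @return same class as `x`, intensities rescaled per array.
#' @examples
#' normalize_percentile(
#'   expression_matrix(
#'     matrix(c(1, 2, 3, 10, 20, 30), 3,
#'       dimnames = list(c("a", "b", "c"), c("s1", "s2"))
#'     ),
#'     c(s1 = "control", s2 = "treated")
#'   )
#' )
#' @export
normalize_percentile <- function(x, percentile = 50) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
    percentile <= 0 || percentile > 100) {
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  }
  mat <- if (inherits(x, "expression_matrix")) x$intensities else x
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`x` must be an expression_matrix or numeric matrix", call. = FALSE)
  }
  if (any(colSums(mat > 0) == 0L)) {
    bad <- colnames(mat)[colSums(mat > 0) == 0L]
    stop(
      "array(s) without any positive intensity cannot be normalized: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  divisors <- apply(mat, 2L, quantile, probs = percentile / 100,
    names = FALSE, type = 7
  )
  if (any(divisors <= 0)) {
    stop(
      "percentile intensity is zero for array(s): ",
      paste(colnames(mat)[divisors <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  norm <- sweep(mat, 2L, divisors, `/`)
  if (inherits(x, "expression_matrix")) {
    out <- expression_matrix(norm, x$condition)
    attr(out, "normalization") <- list(
      method = "per-chip percentile", percentile = percentile,
      divisors = setNames(divisors, colnames(mat))
    )
    out
  } else {
    norm
  }
}

#' Signed fold change per gene between conditions
#'
#' For each gene, `r = mean(treated) / mean(control)` over normalized
#' linear intensities; reported in the signed convention
#' `fc = r` if `r >= 1` else `-1/r`, so magnitudes are always `>= 1` and
#' the sign is the direction of change in the treated condition.
#'
#' Genes with a zero control mean cannot be given a ratio: they are
#' reported with `fc_signed = NA` and listed in the `"diagnostics"`
#' attribute (with a warning), never silently dropped.
#'
#' @param x a normalized [expression_matrix()] containing both conditions.
#' @return data.frame with columns `gene`, `mean_control`, `mean_treated`,
#'   `fc_signed`; attribute `"diagnostics"` is a character vector of
#'   messages for non-computable genes.
#' @export
fold_change <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!all(c("control", "treated") %in% x$condition)) {
    stop("both conditions must be present to compute fold changes",
      call. = FALSE
    )
  }
  mat <- x$intensities
  m_ctrl <- rowMeans(mat[, x$condition == "control", drop = FALSE])
  m_trt <- rowMeans(mat[, x$condition == "treated", drop = FALSE])
  r <- m_trt / m_ctrl
  fc <- ifelse(r >= 1, r, -1 / r)
  bad <- m_ctrl == 0
  diagnostics <- character(0)
  if (any(bad)) {
    fc[bad] <- NA_real_
    diagnostics <- sprintf(
      "gene %s: control mean is zero, fold change undefined",
      rownames(mat)[bad]
    )
    warning(
      sum(bad), " gene(s) with zero control mean reported as NA ",
      "(see attr(, 'diagnostics'))",
      call. = FALSE
    )
  }
  out <- data.frame(
    gene = rownames(mat),
    mean_control = unname(m_ctrl),
    mean_treated = unname(m_trt),
    fc_signed = unname(fc),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diagnostics
  out
}

# Coerce partition/de input (named numeric or data.frame) to a
# data.frame(gene, fc_signed).
as_fc_frame <- function(fc) {
  if (is.data.frame(fc)) {
    if (!all(c("gene", "fc_signed") %in% names(fc))) {
      stop("fold-change data.frame needs columns `gene` and `fc_signed`",
        call. = FALSE
      )
    }
    fc[, intersect(c("gene", "fc_signed"), names(fc)), drop = FALSE]
  } else if (is.numeric(fc)) {
    if (is.null(names(fc))) {
      stop("a bare fold-change vector must be named by gene", call. = FALSE)
    }
    data.frame(
      gene = names(fc), fc_signed = unname(fc), stringsAsFactors = FALSE
    )
  } else {
    stop("`fc` must be a data.frame or named numeric vector", call. = FALSE)
  }
}

#' Classify genes against an absolute fold-change cutoff
#'
#' @param fc data.frame with columns `gene`, `fc_signed` (e.g. from
#'   [fold_change()]) or a named numeric vector of signed fold changes.
#' @param cutoff absolute fold-change threshold `tau >= 1`; comparison is
#'   inclusive (`fc >= tau` is up, `fc <= -tau` is down). Default 1.3.
#' @return data.frame with columns `gene`, `fc_signed`, `direction`
#'   (`up`/`down`/`unchanged`), `passes_cutoff`; ordered by `|fc|`
#'   descending, ties by gene identifier. Genes with `NA` fold change are
#'   kept with `direction = "unchanged"` and `passes_cutoff = FALSE`.
#' @examples
#' de_table(c(a = 1.31, b = -1.30, c = 1.29))
#' @export
de_table <- function(fc, cutoff = 1.3) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 1) {
    stop("`cutoff` must be a single number >= 1", call. = FALSE)
  }
  df <- as_fc_frame(fc)
  f <- df$fc_signed
  direction <- ifelse(is.na(f), "unchanged",
    ifelse(f >= cutoff, "up", ifelse(f <= -cutoff, "down", "unchanged"))
  )
  out <- data.frame(
    gene = df$gene, fc_signed = f, direction = direction,
    passes_cutoff = direction != "unchanged",
    stringsAsFactors = FALSE
  )
  ord <- order(-abs(ifelse(is.na(out$fc_signed), 0, out$fc_signed)), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Partition genes into up / down / unchanged lists
#'
#' @inheritParams de_table
#' @return list with data.frame elements `up`, `down`, `unchanged`
#'   (disjoint, jointly covering all input genes, each ordered by `|fc|`
#'   descending then gene id) and integer vector `counts`.
#' @examples
#' partition_by_cutoff(c(a = 1.31, b = -1.30, c = 1.29))$counts
#' @export
partition_by_cutoff <- function(fc, cutoff = 1.3) {
  tab <- de_table(fc, cutoff)
  split_dir <- function(d) {
    out <- tab[tab$direction == d, c("gene", "fc_signed"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  parts <- list(
    up = split_dir("up"),
    down = split_dir("down"),
    unchanged = split_dir("unchanged")
  )
  parts$counts <- c(
    up = nrow(parts$up), down = nrow(parts$down),
    unchanged = nrow(parts$unchanged)
  )
  parts
}

#' Write a differential-expression table
#'
#' @param de a [de_table()] result.
#' @param path tab-delimited output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
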