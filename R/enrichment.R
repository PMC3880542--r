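# Hypergeometric GO over-representation with Benjamini-Hochberg control.

#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing an overlap of at least `k` between a
#' term of size `K` and a query of size `n` drawn from a universe of size
#' `N`:
#' `p = sum_{i = k..min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`.
#'
#' @param k observed overlap (`0 <= k <= min(K, n)`).
#' @param K term size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return the exact upper-tail probability; vectorized over its
#'   arguments.
#' @examples
#' hypergeom_tail(4, 5, 8, 20) # 7280 / 125970
#' @export
hypergeom_tail <- function(k, K, n, N) {
  args <- cbind(k = k, K = K, n = n, N = N)
  if (anyNA(args) || any(args < 0) || any(args != floor(args))) {
    stop("k, K, n, N must be non-negative integers", call. = FALSE)
  }
  k <- unname(args[, "k"])
  K <- unname(args[, "K"])
  n <- unname(args[, "n"])
  N <- unname(args[, "N"])
  if (any(K > N) || any(n > N)) {
    stop("term size K and query size n cannot exceed the universe N",
      call. = FALSE
    )
  }
  if (any(k > pmin(K, n))) {
    stop("overlap k cannot exceed min(K, n)", call. = FALSE)
  }
  # P(X >= k) for X ~ Hypergeometric(N, K, n); phyper is exact
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj(i) = min_{j: rank(j) >= rank(i)} (m / rank(j)) p(j)`, capped at
#' 1, with the input order preserved in the output.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric GO term over-representation test
#'
#' Tests every annotated term with at least one query gene for
#' over-representation in `query` against the universe, adjusts with
#' Benjamini-Hochberg across the tested (k >= 1) terms, and flags
#' significance at `alpha`. Query genes outside the universe are dropped
#' with a warning.
#'
#' @param query character vector of gene identifiers (e.g. the upregulated
#'   list).
#' @param annotation data.frame with columns `gene`, `term`; pairs are
#'   deduplicated.
#' @param alpha significance level for the adjusted p-value (default 0.05).
#' @param universe reference gene set; defaults to all genes in
#'   `annotation`.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p_raw`,
#'   `p_adj`, `significant`, sorted by `p_adj` ascending with ties broken
#'   by term id. Terms with zero overlap are excluded (and do not count in
#'   the adjustment family).
#' @export
enrich <- function(query, annotation, alpha = 0.05, universe = NULL) {
  if (!is.data.frame(annotation) ||
    !all(c("gene", "term") %in% names(annotation))) {
    stop("`annotation` needs columns `gene` and `term`", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  annotation <- unique(annotation[, c("gene", "term")])
  if (is.null(universe)) universe <- unique(annotation$gene)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]

  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(
      length(outside), " query gene(s) outside the universe dropped: ",
      paste(utils::head(outside, 5L), collapse = ", "),
      if (length(outside) > 5L) ", ..." else "",
      call. = FALSE
    )
    query <- intersect(query, universe)
  }

  N <- length(universe)
  n <- length(query)
  term_sets <- split(annotation$gene, annotation$term)
  K <- lengths(term_sets)
  k <- vapply(term_sets, function(g) length(intersect(g, query)), 0L)

  keep <- k >= 1L
  if (!any(keep)) {
    out <- data.frame(
      term = character(), k = integer(), K = integer(), n = integer(),
      N = integer(), p_raw = numeric(), p_adj = numeric(),
      significant = logical(), stringsAsFactors = FALSE
    )
    attr(out, "alpha") <- alpha
    return(out)
  }
  out <- data.frame(
    term = names(term_sets)[keep],
    k = unname(k[keep]), K = unname(K[keep]), n = n, N = N,
    stringsAsFactors = FALSE
  )
  out$p_raw <- hypergeom_tail(out$k, out$K, out$n, out$N)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Write an enrichment result table
#'
#' @param res an [enrich()] result.
#' @param path tab-delimited output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
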