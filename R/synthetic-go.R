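# Synthetic gene -> GO-term annotation with one planted enriched term.

#' Generate a GO annotation table with a planted enriched term
#'
#' Produces a two-column (gene, term) annotation over `genes`. Background
#' terms annotate genes drawn uniformly; the planted term
#' (`truth$enriched_term`) annotates `enriched_overlap` planted-upregulated
#' genes plus `enriched_size - enriched_overlap` other genes, so its
#' overlap with any upregulated query exceeds random expectation by
#' construction.
#'
#' @param truth a [ground_truth()]; genes with planted `fc > 0` form the
#'   upregulated set the enriched term is seeded from.
#' @param genes character vector: the gene universe (must contain the
#'   planted genes).
#' @param n_terms number of background terms (>= 0); `0` with no planted
#'   overlap gives an empty table.
#' @param term_size_range integer range of background term sizes.
#' @param enriched_size number of genes annotated to the planted term.
#' @param enriched_overlap how many of those are planted-upregulated genes;
#'   must not exceed `enriched_size` nor the number available.
#' @param seed integer seed (defaults to `truth$seed`).
#' @return data.frame with columns `gene`, `term` (deduplicated pairs).
#' @export
generate_go_annotation <- function(truth, genes,
                                   n_terms = 50L,
                                   term_size_range = c(10L, 40L),
                                   enriched_size = 10L,
                                   enriched_overlap = 8L,
                                   seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_terms < 0L) stop("`n_terms` must be >= 0", call. = FALSE)
  if (enriched_overlap > enriched_size) {
    stop("planted overlap (", enriched_overlap,
      ") exceeds the enriched term size (", enriched_size, ")",
      call. = FALSE
    )
  }
  up_genes <- intersect(
    names(truth$planted_fc)[truth$planted_fc > 0], genes
  )
  if (enriched_overlap > length(up_genes)) {
    stop("planted overlap exceeds the number of planted upregulated genes",
      call. = FALSE
    )
  }
  if (enriched_size > length(genes)) {
    stop("enriched term larger than the gene universe", call. = FALSE)
  }
  if (n_terms == 0L) {
    return(data.frame(
      gene = character(), term = character(), stringsAsFactors = FALSE
    ))
  }

  with_seed(seed, {
    terms <- sprintf("GO:%07d", seq_len(max(0L, n_terms - 1L)))
    pieces <- lapply(terms, function(tm) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      data.frame(
        gene = sample(genes, min(size, length(genes))), term = tm,
        stringsAsFactors = FALSE
      )
    })
    planted_members <- c(
      sample(up_genes, enriched_overlap),
      sample(setdiff(genes, up_genes), enriched_size - enriched_overlap)
    )
    pieces[[length(pieces) + 1L]] <- data.frame(
      gene = planted_members, term = truth$enriched_term,
      stringsAsFactors = FALSE
    )
    out <- do.call(rbind, pieces)
    out <- unique(out)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a two-column gene-to-GO-term table
#'
#' @param annotation data.frame with columns `gene`, `term`.
#' @param path file path (tab-delimited, header `gene  term`).
#' @return `write_go_annotation()`: `path` invisibly;
#'   `read_go_annotation()`: the annotation data.frame.
#' @export
write_go_annotation <- function(annotation, path) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  write.table(annotation[, c("gene", "term")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_go_annotation
#' @export
read_go_annotation <- function(path) {
  read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = "character"
  )
}
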