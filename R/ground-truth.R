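# Ground truth container for the synthetic-data generators.

#' Construct a ground truth for synthetic data generation
#'
#' Bundles everything the generators need to plant recoverable signal:
#' signed fold changes per gene, the identity of the enriched GO term, and
#' the promoter motif placements per (gene, motif, species).
#'
#' @param planted_fc named numeric; signed fold changes (GeneSpring
#'   convention, so every `|fc| >= 1`), names are gene identifiers.
#' @param enriched_term GO-term identifier planted as over-represented
#'   among the upregulated genes.
#' @param planted_motifs data.frame with columns `gene`, `motif`,
#'   `species`, `offset` (TSS-relative position of the site's 5'-most
#'   base; negative = upstream, no position 0), `strand` (`"+"`/`"-"`);
#'   or `NULL` for none.
#' @param seed integer RNG seed; the default seed used by the generators.
#' @return object of class `"ground_truth"`.
#' @examples
#' gt <- ground_truth(c(Hes5 = -56.83, Dll1 = 2.26), seed = 1)
#' gt$planted_fc
#' @export
ground_truth <- function(planted_fc = numeric(), enriched_term = "GO:0007399",
                         planted_motifs = NULL, seed = 1L) {
  if (length(planted_fc) > 0L) {
    if (is.null(names(planted_fc)) || anyNA(names(planted_fc)) ||
      any(names(planted_fc) == "")) {
      stop("`planted_fc` must be a named numeric vector", call. = FALSE)
    }
    if (anyDuplicated(names(planted_fc))) {
      stop("duplicated gene names in `planted_fc`", call. = FALSE)
    }
    if (anyNA(planted_fc) || any(abs(planted_fc) < 1)) {
      stop(
        "all planted fold changes must satisfy |fc| >= 1 ",
        "(signed convention leaves no values in (-1, 1))",
        call. = FALSE
      )
    }
  }
  if (!is.null(planted_motifs)) {
    need <- c("gene", "motif", "species", "offset", "strand")
    if (!is.data.frame(planted_motifs) ||
      !all(need %in% names(planted_motifs))) {
      stop(
        "`planted_motifs` needs columns ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(planted_motifs$offset == 0L)) {
      stop("TSS-relative offsets use a no-zero convention (+1 is the TSS)",
        call. = FALSE
      )
    }
    if (!all(planted_motifs$strand %in% c("+", "-"))) {
      stop("`strand` must be '+' or '-'", call. = FALSE)
    }
  }
  structure(
    list(
      planted_fc = planted_fc,
      enriched_term = enriched_term,
      planted_motifs = planted_motifs,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

#' Default ground truth mirroring the published screen
#'
#' Plants the full reference fold-change table ([notch_screen_table()])
#' and the conserved-motif plan ([conserved_motif_plan()]) replicated
#' across all requested species, so the default pipeline run recovers the
#' published effect sizes and conservation calls.
#'
#' @param seed integer RNG seed.
#' @param species character vector of species carrying the ortholog
#'   promoters.
#' @return a [ground_truth()] object.
#' @export
default_ground_truth <- function(seed = 1L,
                                 species = c(
                                   "chick", "mouse", "human", "zebrafish"
                                 )) {
  tab <- notch_screen_table()
  plan <- conserved_motif_plan()
  motifs <- do.call(rbind, lapply(species, function(sp) {
    cbind(plan[, c("gene", "motif")],
      species = sp,
      plan[, c("offset", "strand")]
    )
  }))
  rownames(motifs) <- NULL
  ground_truth(
    planted_fc = setNames(tab$fc, tab$gene),
    enriched_term = "GO:0007399",
    planted_motifs = motifs,
    seed = seed
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$planted_fc), "planted fold changes,",
    if (is.null(x$planted_motifs)) 0L else nrow(x$planted_motifs),
    "planted motif sites, enriched term", x$enriched_term,
    "(seed", paste0(x$seed, ")"), "\n"
  )
  invisible(x)
}
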