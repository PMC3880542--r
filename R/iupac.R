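# IUPAC nucleotide code machinery shared by the motif scanner, the
# consensus deriver and the promoter generator.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base-set -> code, keyed by the sorted, concatenated base set
IUPAC_CODE_OF <- local({
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  setNames(names(IUPAC_SETS), keys)
})

#' Validate an IUPAC consensus string
#'
#' @param x character scalar; a nucleotide consensus such as `"CANNTG"`.
#' @param min_len minimum accepted length.
#' @return `x`, upper-cased, invisibly usable; errors on characters outside
#'   the 15-letter IUPAC alphabet.
#' @keywords internal
check_iupac <- function(x, min_len = 1L) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("consensus must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(
      "invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  if (nchar(x) < min_len) {
    stop("consensus shorter than ", min_len, " nt", call. = FALSE)
  }
  x
}

# IUPAC string -> regex of character classes, e.g. CANNTG -> CA[ACGT][ACGT]TG
iupac_regex <- function(consensus) {
  chars <- strsplit(check_iupac(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

# Reverse complement preserving ambiguity codes (delegates to Biostrings,
# which complements R<->Y, B<->V, etc. correctly).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Draw one concrete ACGT realization of an IUPAC string (used when
# planting a degenerate motif into a synthetic promoter).
sample_from_iupac <- function(consensus) {
  chars <- strsplit(check_iupac(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, ""), collapse = "")
}

#' Binding-site motif definitions
#'
#' The four motif classes used throughout the screen: the degenerate E-box
#' (`CANNTG`, bound by activator-type bHLH factors such as ASCL1/NHLH1) and
#' N-box (`CACNAG`, bound by repressor-type HES/HEY factors), plus the two
#' strict 7-mer antagonist signatures: MHAM (`CACCTGC`, ASCL1/HEY) and MNAM
#' (`GCAGCTG`, ASCL1/NHLH1). Strict 7-mers give a more stringent scan than
#' the degenerate boxes alone.
#'
#' @param ids optional character vector restricting which motifs to return.
#' @return data.frame with columns `motif`, `consensus`, `description`.
#' @examples
#' motif_defs()
#' motif_defs(c("MHAM", "MNAM"))
#' @export
motif_defs <- function(ids = NULL) {
  defs <- data.frame(
    motif = c("EBOX", "NBOX", "MHAM", "MNAM"),
    consensus = c("CANNTG", "CACNAG", "CACCTGC", "GCAGCTG"),
    description = c(
      "degenerate E-box, activator bHLH (ASCL1/NHLH1) site",
      "degenerate N-box, repressor bHLH (HES/HEY) site",
      "strict 7-mer ASCL1/HEY antagonist site",
      "strict 7-mer ASCL1/NHLH1 antagonist site"
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(ids)) {
    missing <- setdiff(ids, defs$motif)
    if (length(missing) > 0L) {
      stop("unknown motif id(s): ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    defs <- defs[match(ids, defs$motif), , drop = FALSE]
    rownames(defs) <- NULL
  }
  defs
}

# Normalize a `motif` argument (data.frame from motif_defs(), a named or
# bare IUPAC string) into a one-row-per-motif data.frame(motif, consensus).
as_motif_frame <- function(motif) {
  if (is.data.frame(motif)) {
    if (!all(c("motif", "consensus") %in% names(motif))) {
      stop("motif data.frame needs columns `motif` and `consensus`",
        call. = FALSE
      )
    }
    out <- motif[, c("motif", "consensus"), drop = FALSE]
  } else if (is.character(motif)) {
    ids <- if (is.null(names(motif))) motif else names(motif)
    out <- data.frame(motif = ids, consensus = unname(motif),
      stringsAsFactors = FALSE
    )
  } else {
    stop("`motif` must be a data.frame or character vector", call. = FALSE)
  }
  out$consensus <- vapply(out$consensus, check_iupac, "", min_len = 4L)
  rownames(out) <- NULL
  out
}

#' Derive an IUPAC consensus from aligned binding sites
#'
#' Each column of the (gap-free, equal-length) site set is reduced to the
#' IUPAC code denoting exactly the set of bases observed in that column.
#' Input sites may themselves contain ambiguity codes; their base sets are
#' unioned.
#'
#' @param sites character vector of aligned, equal-length sequences.
#' @return single IUPAC string of the common length.
#' @examples
#' derive_iupac_consensus(c("CAACTG", "CAGCTG", "CATCTG", "CACCTG")) # CANCTG
#' @export
derive_iupac_consensus <- function(sites) {
  if (length(sites) < 1L) stop("need at least one site", call. = FALSE)
  sites <- vapply(sites, check_iupac, "", USE.NAMES = FALSE)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop("sites have ragged lengths: ",
      paste(sort(unique(lens)), collapse = ", "),
      call. = FALSE
    )
  }
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    bases <- sort(unique(unlist(IUPAC_SETS[unique(col)], use.names = FALSE)))
    IUPAC_CODE_OF[[paste(bases, collapse = "")]]
  }), collapse = "")
}
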