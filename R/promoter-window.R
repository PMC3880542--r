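# TSS-anchored promoter windows and the +1 coordinate convention.
#
# TSS-relative coordinates follow the "+1" convention: the base pairs
# immediately upstream of the transcription start are ..., -2, -1; the
# start itself is +1; there is no position 0. A window with `upstream` bp
# before and `downstream` bp after the TSS covers positions
# -upstream..-1, +1, +2..+(downstream+1) and has length
# upstream + downstream + 1 (601 nt for the default 500/100).
#
# Internally positions are linearized (no gap at zero) via tss_to_lin();
# all arithmetic (window indexing, positional spread) happens on the
# linear scale and is converted back for reporting.

# +1-convention position -> integer line with no gap (-1 -> -1, +1 -> 0)
tss_to_lin <- function(p) {
  p <- as.integer(p)
  if (any(p == 0L)) {
    stop("TSS-relative position 0 does not exist (+1 convention)",
      call. = FALSE
    )
  }
  ifelse(p < 0L, p, p - 1L)
}

# inverse of tss_to_lin
lin_to_tss <- function(l) {
  l <- as.integer(l)
  ifelse(l < 0L, l, l + 1L)
}

#' Specify a TSS-anchored promoter window
#'
#' @param upstream bases before the TSS (default 500).
#' @param downstream bases after the TSS (default 100).
#' @return object of class `"promoter_window_spec"`. The window covers
#'   TSS-relative positions `-upstream..-1, +1..+(downstream+1)` (the TSS
#'   is `+1`; there is no position 0) and has length
#'   `upstream + downstream + 1`.
#' @examples
#' window_length(promoter_window_spec()) # 601
#' @export
promoter_window_spec <- function(upstream = 500L, downstream = 100L) {
  if (upstream < 0L || downstream < 0L) {
    stop("`upstream` and `downstream` must be >= 0", call. = FALSE)
  }
  structure(
    list(upstream = as.integer(upstream), downstream = as.integer(downstream)),
    class = "promoter_window_spec"
  )
}

#' @rdname promoter_window_spec
#' @param spec a `promoter_window_spec`.
#' @export
window_length <- function(spec) {
  stopifnot(inherits(spec, "promoter_window_spec"))
  spec$upstream + spec$downstream + 1L
}

# TSS-relative position -> 1-based index into a window whose first base
# sits at TSS-relative `first_pos` (default -upstream for a full window)
tss_to_index <- function(p, spec, first_pos = -spec$upstream) {
  tss_to_lin(p) - tss_to_lin(first_pos) + 1L
}

index_to_tss <- function(i, spec, first_pos = -spec$upstream) {
  lin_to_tss(tss_to_lin(first_pos) + i - 1L)
}

#' Extract a TSS-anchored promoter window from a sequence record
#'
#' Slices the window around `tss` and returns it reading 5'->3' on the
#' gene's coding strand (minus-strand genes are reverse-complemented). If
#' the window extends past either end of the record it is truncated with a
#' warning; a TSS outside the record is an error.
#'
#' @param sequence a character scalar or `Biostrings::DNAString`; the
#'   source record (chromosome or pre-cut promoter).
#' @param tss 1-based position of the transcription start within `sequence`.
#' @param strand gene strand, `"+"` or `"-"`.
#' @param spec a [promoter_window_spec()].
#' @param gene,species optional identifiers carried into reports.
#' @return object of class `"promoter_window"`: list with `seq` (character),
#'   `gene`, `species`, `spec`, `first_pos` (TSS-relative position of the
#'   first base of `seq`).
#' @examples
#' w <- extract_window("AAACGTTT", tss = 4, spec = promoter_window_spec(3, 2))
#' w$seq # "AACGTT"
#' @export
extract_window <- function(sequence, tss, strand = "+", spec = promoter_window_spec(),
                           gene = NA_character_, species = NA_character_) {
  stopifnot(inherits(spec, "promoter_window_spec"))
  seq_chr <- toupper(as.character(sequence))
  len <- nchar(seq_chr)
  tss <- as.integer(tss)
  if (tss < 1L || tss > len) {
    stop("TSS position ", tss, " outside the record (length ", len, ")",
      call. = FALSE
    )
  }
  if (!strand %in% c("+", "-")) stop("`strand` must be '+' or '-'",
    call. = FALSE
  )

  if (strand == "+") {
    lo <- tss - spec$upstream
    hi <- tss + spec$downstream
  } else {
    lo <- tss - spec$downstream
    hi <- tss + spec$upstream
  }
  lo_cl <- max(lo, 1L)
  hi_cl <- min(hi, len)
  if (lo_cl > lo || hi_cl < hi) {
    warning(
      "window truncated to fit the record (",
      hi_cl - lo_cl + 1L, " of ", hi - lo + 1L, " nt retained)",
      call. = FALSE
    )
  }
  win <- substr(seq_chr, lo_cl, hi_cl)
  if (strand == "-") win <- revcomp(win)

  # TSS-relative position of the first retained base, on the coding strand
  first_lin <- if (strand == "+") lo_cl - tss else tss - hi_cl
  structure(
    list(
      seq = win, gene = gene, species = species, spec = spec,
      first_pos = lin_to_tss(first_lin)
    ),
    class = "promoter_window"
  )
}

#' @export
print.promoter_window <- function(x, ...) {
  last <- index_to_tss(nchar(x$seq), x$spec, x$first_pos)
  cat(
    "promoter_window", if (!is.na(x$gene)) paste0("[", x$gene, "]") else "",
    nchar(x$seq), "nt,", sprintf("%+d..%+d", x$first_pos, last), "\n"
  )
  invisible(x)
}
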