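# Both-strand IUPAC motif scanning over promoter windows.

#' Scan a promoter window for an IUPAC motif
#'
#' Tests every position of the window against the consensus under IUPAC
#' wildcard semantics (N matches any base, R = A/G, ...). Overlapping
#' occurrences are all reported. With `both_strands = TRUE` the reverse
#' complement of the consensus is also scanned; minus-strand hits are
#' reported at the leftmost (5'-most on the window's plus strand) base of
#' the matched region, with strand `"-"`. Hits are ordered by position,
#' then strand (`+` before `-`).
#'
#' @param window a [promoter_window()][extract_window] object or a bare
#'   character sequence.
#' @param motif a row of [motif_defs()], a named character vector
#'   (`c(MHAM = "CACCTGC")`), or a bare IUPAC string. Several motifs may
#'   be supplied; hits are concatenated.
#' @param both_strands scan both strands (default `TRUE`).
#' @return data.frame with columns `gene`, `species`, `motif`, `start`
#'   (1-based position in the window), `start_tss` (TSS-relative, no-zero
#'   convention; `NA` for bare sequences), `strand`, `match` (the
#'   plus-strand sequence of the matched region).
#' @examples
#' scan_motif("TTCACCTGCTT", c(MHAM = "CACCTGC"))
#' scan_motif("CAGCTG", c(EBOX = "CANNTG")) # hits on both strands at 1
#' @export
scan_motif <- function(window, motif, both_strands = TRUE) {
  if (inherits(window, "promoter_window")) {
    seq_chr <- window$seq
    gene <- window$gene
    species <- window$species
    to_tss <- function(i) index_to_tss(i, window$spec, window$first_pos)
  } else if (is.character(window) && length(window) == 1L) {
    seq_chr <- toupper(window)
    gene <- NA_character_
    species <- NA_character_
    to_tss <- function(i) rep(NA_integer_, length(i))
  } else {
    stop("`window` must be a promoter_window or a single character string",
      call. = FALSE
    )
  }
  if (nchar(seq_chr) == 0L) stop("empty window", call. = FALSE)
  motifs <- as_motif_frame(motif)

  one_strand <- function(consensus, strand, id) {
    pat <- paste0("(?=", iupac_regex(consensus), ")")
    m <- gregexpr(pat, seq_chr, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    if (length(starts) == 0L) return(NULL)
    data.frame(
      gene = gene, species = species, motif = id,
      start = starts, start_tss = to_tss(starts), strand = strand,
      match = substring(seq_chr, starts, starts + nchar(consensus) - 1L),
      stringsAsFactors = FALSE
    )
  }

  pieces <- list()
  for (r in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[r]
    id <- motifs$motif[r]
    pieces[[length(pieces) + 1L]] <- one_strand(cons, "+", id)
    if (both_strands) {
      pieces[[length(pieces) + 1L]] <- one_strand(revcomp(cons), "-", id)
    }
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(), species = character(), motif = character(),
      start = integer(), start_tss = integer(), strand = character(),
      match = character(), stringsAsFactors = FALSE
    )
  } else {
    out <- out[
      order(out$motif, out$start, match(out$strand, c("+", "-"))), ,
      drop = FALSE
    ]
    rownames(out) <- NULL
  }
  out
}

#' Call cross-species conservation of motif hits
#'
#' Presence-based call: a (gene, motif) pair is conserved when hits exist
#' in at least `m` distinct species of the universe. The positional spread
#' (largest pairwise distance, in nt, between supporting hit positions
#' across species) is reported so stricter positional post-filters are
#' possible, but it is not used as a filter here.
#'
#' @param hits data.frame of motif hits (columns `gene`, `species`,
#'   `motif`, `start_tss` or `start`) as produced by [scan_motif()] /
#'   [annotate_promoter_map()].
#' @param species_universe character vector of all species screened.
#' @param m minimum number of species required (default: all species in
#'   the universe).
#' @return data.frame with columns `gene`, `motif`, `n_species`,
#'   `species_with_hit` (comma-collapsed), `conserved`,
#'   `positional_spread`. Only (gene, motif) pairs with at least one hit
#'   appear.
#' @export
call_conservation <- function(hits, species_universe,
                              m = length(species_universe)) {
  if (length(species_universe) == 0L) {
    stop("empty species universe", call. = FALSE)
  }
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (m > length(species_universe)) {
    stop("`m` (", m, ") exceeds the species universe size (",
      length(species_universe), ")",
      call. = FALSE
    )
  }
  need <- c("gene", "species", "motif")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    stop("`hits` needs columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  hits <- hits[hits$species %in% species_universe, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(
      gene = character(), motif = character(), n_species = integer(),
      species_with_hit = character(), conserved = logical(),
      positional_spread = integer(), stringsAsFactors = FALSE
    ))
  }
  pos <- if ("start_tss" %in% names(hits) && !all(is.na(hits$start_tss))) {
    tss_to_lin(hits$start_tss)
  } else {
    hits$start
  }
  key <- interaction(hits$gene, hits$motif, drop = TRUE)
  groups <- split(seq_len(nrow(hits)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    sp <- sort(unique(hits$species[idx]))
    p <- pos[idx]
    data.frame(
      gene = hits$gene[idx[1]], motif = hits$motif[idx[1]],
      n_species = length(sp),
      species_with_hit = paste(sp, collapse = ","),
      conserved = length(sp) >= m,
      positional_spread = if (all(is.na(p))) NA_integer_ else
        as.integer(max(p, na.rm = TRUE) - min(p, na.rm = TRUE)),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$gene, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "species_universe") <- species_universe
  out
}

#' Scan all motifs across ortholog promoter windows and call conservation
#'
#' The per-gene promoter report behind a motif-track figure: every motif
#' of `motifs` is scanned in every species' window of every gene, hits are
#' pooled, conservation is called at threshold `m`, and E-box hits that
#' subsume a strict MHAM hit at the same position/strand are annotated
#' (CACCTGC contains CACCTG, so every plus-strand MHAM hit co-occurs with
#' an E-box hit at its start).
#'
#' @param promoters named character vector in the
#'   `gene|species|start..end|strand` header convention (e.g. from
#'   [generate_ortholog_promoters()] or [read_promoters()]), or a list of
#'   [extract_window()] windows.
#' @param motifs motif definitions (default [motif_defs()]).
#' @param spec window spec used to interpret headers (default 500/100).
#' @param species_universe species screened; defaults to those present.
#' @param m conservation threshold (default: all species).
#' @param both_strands scan both strands (default `TRUE`).
#' @return list with elements `hits` (all motif hits; column `subsumes`
#'   names a strict motif contained at the same start, `NA` otherwise),
#'   `conservation` (the [call_conservation()] table), and `genes` (every
#'   input gene, including those with no hits).
#' @export
annotate_promoter_map <- function(promoters, motifs = motif_defs(),
                                  spec = promoter_window_spec(),
                                  species_universe = NULL, m = NULL,
                                  both_strands = TRUE) {
  windows <- if (is.list(promoters) &&
    all(vapply(promoters, inherits, TRUE, "promoter_window"))) {
    promoters
  } else {
    promoters_as_windows(promoters, spec)
  }
  motifs <- as_motif_frame(motifs)
  if (is.null(species_universe)) {
    species_universe <- unique(
      vapply(windows, function(w) w$species, "")
    )
  }
  if (is.null(m)) m <- length(species_universe)

  hits <- do.call(rbind, lapply(windows, function(w) {
    scan_motif(w, motifs, both_strands = both_strands)
  }))
  if (is.null(hits)) {
    hits <- scan_motif("A", motifs, both_strands = FALSE)[0, ]
  }

  # annotate degenerate hits subsuming a strict hit at the same position
  hits$subsumes <- NA_character_
  if (nrow(hits) > 0L) {
    # pairs (broad, tight): a longer strict consensus whose prefix
    # matches the broader pattern, e.g. EBOX CANNTG starts MHAM CACCTGC
    strict <- merge(motifs, motifs, by = NULL,
      suffixes = c(".x", ".y")
    )
    names(strict) <- c("motif.x", "consensus.x", "motif.y", "consensus.y")
    keep <- strict$motif.x != strict$motif.y &
      nchar(strict$consensus.y) > nchar(strict$consensus.x) &
      vapply(seq_len(nrow(strict)), function(i) {
        grepl(
          paste0("^", iupac_regex(strict$consensus.x[i])),
          strict$consensus.y[i]
        )
      }, TRUE)
    strict <- strict[keep, , drop = FALSE]
    for (i in seq_len(nrow(strict))) {
      broad <- strict$motif.x[i]
      tight <- strict$motif.y[i]
      key_b <- hits$motif == broad
      key_t <- hits$motif == tight
      if (!any(key_b) || !any(key_t)) next
      id_b <- paste(hits$gene, hits$species, hits$start, hits$strand)[key_b]
      id_t <- paste(hits$gene, hits$species, hits$start, hits$strand)[key_t]
      hits$subsumes[key_b][id_b %in% id_t] <- tight
    }
  }

  conservation <- call_conservation(hits, species_universe, m)
  genes <- unique(vapply(windows, function(w) w$gene, ""))
  list(hits = hits, conservation = conservation, genes = genes)
}
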