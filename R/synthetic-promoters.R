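# Synthetic orthologous promoter sets with planted conserved motifs.

#' Generate orthologous promoter windows with planted motifs
#'
#' One TSS-anchored window per (gene, species): background drawn i.i.d.
#' from a configurable base composition, with the planted motif strings
#' from `truth$planted_motifs` overwritten at their stated TSS-relative
#' offsets on the stated strands (minus-strand sites are written as the
#' reverse complement on the stored plus strand). Degenerate planted
#' consensi are realized by sampling one concrete matching sequence.
#'
#' @param truth a [ground_truth()]; `truth$planted_motifs` gives the
#'   placements. Motif ids must resolve via `motifs`.
#' @param genes genes to emit promoters for; defaults to all genes named in
#'   `truth` (fold changes and motif plan combined).
#' @param species species set; defaults to the species named in the plan,
#'   or a 4-species panel when none are planted.
#' @param spec a [promoter_window_spec()].
#' @param motifs motif definitions resolving planted motif ids
#'   (default [motif_defs()]).
#' @param gc background GC content in `[0, 1]` (default 0.5: uniform ACGT).
#' @param seed integer seed (defaults to `truth$seed`).
#' @return named character vector of window sequences, names in the FASTA
#'   header convention `gene|species|start..end|strand` with TSS-relative,
#'   no-zero coordinates (e.g. `Chga|mouse|-500..+101|+`).
#' @export
generate_ortholog_promoters <- function(truth, genes = NULL, species = NULL,
                                        spec = promoter_window_spec(),
                                        motifs = motif_defs(),
                                        gc = 0.5, seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"),
    inherits(spec, "promoter_window_spec")
  )
  if (gc < 0 || gc > 1) stop("`gc` must be in [0, 1]", call. = FALSE)
  plan <- truth$planted_motifs
  if (is.null(genes)) {
    genes <- union(names(truth$planted_fc), if (!is.null(plan)) plan$gene)
    if (length(genes) == 0L) stop("no genes to generate", call. = FALSE)
  }
  if (is.null(species)) {
    species <- if (!is.null(plan)) unique(plan$species) else
      c("chick", "mouse", "human", "zebrafish")
  }
  motifs <- as_motif_frame(motifs)
  wl <- window_length(spec)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  if (!is.null(plan)) {
    unknown <- setdiff(plan$motif, motifs$motif)
    if (length(unknown) > 0L) {
      stop("planted motif id(s) not in `motifs`: ",
        paste(unique(unknown), collapse = ", "),
        call. = FALSE
      )
    }
  }

  with_seed(seed, {
    hdr_last <- lin_to_tss(tss_to_lin(-spec$upstream) + wl - 1L)
    out <- character(0)
    for (g in genes) {
      for (sp in species) {
        seq_chars <- sample(names(probs), wl, replace = TRUE, prob = probs)
        if (!is.null(plan)) {
          rows <- plan[plan$gene == g & plan$species == sp, , drop = FALSE]
          for (r in seq_len(nrow(rows))) {
            cons <- motifs$consensus[motifs$motif == rows$motif[r]]
            site <- sample_from_iupac(cons)
            if (rows$strand[r] == "-") site <- revcomp(site)
            i <- tss_to_index(rows$offset[r], spec)
            j <- i + nchar(site) - 1L
            if (i < 1L || j > wl) {
              stop(
                "planted site for ", g, "/", rows$motif[r], " at offset ",
                rows$offset[r], " does not fit the ", wl, " nt window",
                call. = FALSE
              )
            }
            seq_chars[i:j] <- strsplit(site, "", fixed = TRUE)[[1]]
          }
        }
        nm <- sprintf(
          "%s|%s|%+d..%+d|+", g, sp, -spec$upstream, hdr_last
        )
        out[nm] <- paste(seq_chars, collapse = "")
      }
    }
    out
  })
}

#' Write / read promoter windows as multi-FASTA
#'
#' Headers follow `gene|species|start..end|strand` with TSS-relative,
#' no-zero coordinates.
#'
#' @param promoters named character vector as returned by
#'   [generate_ortholog_promoters()].
#' @param path FASTA file path.
#' @return `write_promoters()`: `path` invisibly; `read_promoters()`: a
#'   named character vector of sequences.
#' @export
write_promoters <- function(promoters, path) {
  dna <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}

#' Parse a promoter FASTA header
#'
#' @param header character vector of `gene|species|start..end|strand`
#'   headers.
#' @return data.frame with columns `gene`, `species`, `start`, `end`,
#'   `strand`.
#' @export
parse_promoter_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed promoter header(s): ",
      paste(header[bad], collapse = ", "),
      call. = FALSE
    )
  }
  coords <- vapply(parts, `[[`, "", 3L)
  m <- regmatches(coords, regexec("^([+-]?\\d+)\\.\\.([+-]?\\d+)$", coords))
  if (any(lengths(m) != 3L)) {
    stop("malformed coordinate range in promoter header", call. = FALSE)
  }
  data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    species = vapply(parts, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 2L)),
    end = as.integer(vapply(m, `[[`, "", 3L)),
    strand = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# Turn a named promoter vector into a list of promoter_window objects.
promoters_as_windows <- function(promoters, spec = promoter_window_spec()) {
  info <- parse_promoter_header(names(promoters))
  lapply(seq_along(promoters), function(i) {
    structure(
      list(
        seq = toupper(unname(promoters[i])), gene = info$gene[i],
        species = info$species[i], spec = spec, first_pos = info$start[i]
      ),
      class = "promoter_window"
    )
  })
}
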