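# End-to-end orchestration: synthesize -> DE screen -> enrichment ->
# motif/conservation report -> summary join.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end screen with validated
#' defaults. All randomness derives from `seed`.
#'
#' @param seed integer RNG seed.
#' @param n_genes genes on the synthetic array.
#' @param n_control,n_treated replicate arrays per condition.
#' @param noise_sd log-scale intensity noise SD.
#' @param scale_factor_range per-array global scale factor range.
#' @param cutoff absolute fold-change threshold (>= 1).
#' @param percentile normalization percentile in (0, 100].
#' @param alpha enrichment significance level.
#' @param n_terms background GO terms in the synthetic annotation.
#' @param enriched_size,enriched_overlap size and planted-up overlap of
#'   the planted enriched term.
#' @param window a [promoter_window_spec()].
#' @param motifs motif definitions (default [motif_defs()]).
#' @param species species panel for the ortholog promoters.
#' @param min_species conservation threshold `m`; `NULL` means all
#'   species.
#' @param out_dir optional directory to write tab-delimited stage outputs
#'   into; `NULL` keeps everything in memory.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, n_genes = 2000L,
                            n_control = 4L, n_treated = 4L,
                            noise_sd = 0.1,
                            scale_factor_range = c(0.5, 2),
                            cutoff = 1.3, percentile = 50, alpha = 0.05,
                            n_terms = 50L, enriched_size = 10L,
                            enriched_overlap = 8L,
                            window = promoter_window_spec(),
                            motifs = motif_defs(),
                            species = c(
                              "chick", "mouse", "human", "zebrafish"
                            ),
                            min_species = NULL, out_dir = NULL) {
  if (cutoff < 1) stop("`cutoff` must be >= 1", call. = FALSE)
  if (percentile <= 0 || percentile > 100) {
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]",
    call. = FALSE
  )
  stopifnot(inherits(window, "promoter_window_spec"))
  if (is.null(min_species)) min_species <- length(species)
  if (min_species < 1L || min_species > length(species)) {
    stop("`min_species` must be between 1 and the number of species",
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      n_control = as.integer(n_control), n_treated = as.integer(n_treated),
      noise_sd = noise_sd, scale_factor_range = scale_factor_range,
      cutoff = cutoff, percentile = percentile, alpha = alpha,
      n_terms = as.integer(n_terms),
      enriched_size = as.integer(enriched_size),
      enriched_overlap = as.integer(enriched_overlap),
      window = window, motifs = as_motif_frame(motifs),
      species = species, min_species = as.integer(min_species),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

# serializable key=value lines describing a config (written above outputs)
config_header <- function(config) {
  c(
    sprintf("# notchscreen %s", as.character(utils::packageVersion("notchscreen"))),
    sprintf("# seed=%d", config$seed),
    sprintf("# n_genes=%d n_control=%d n_treated=%d noise_sd=%g",
      config$n_genes, config$n_control, config$n_treated, config$noise_sd
    ),
    sprintf("# cutoff=%g percentile=%g alpha=%g", config$cutoff,
      config$percentile, config$alpha
    ),
    sprintf("# window=-%d..+%d min_species=%d species=%s",
      config$window$upstream, config$window$downstream + 1L,
      config$min_species, paste(config$species, collapse = ",")
    )
  )
}

write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_log <- function(...) message("[notchscreen] ", ...)

#' Run the full synthetic screen end to end
#'
#' Generates ground-truth inputs, normalizes, computes the signed
#' fold-change table and cutoff partition, tests GO enrichment of the
#' upregulated list, scans ortholog promoters for the motif set, calls
#' cross-species conservation, joins upregulated genes to their conserved
#' motifs, and checks the observed fold-change signs against the expected
#' Notch-inhibition response. Stage progress is logged to stderr; results
#' are returned (and optionally written) separately from the log.
#'
#' @param config a [pipeline_config()].
#' @param truth optional [ground_truth()]; default
#'   `default_ground_truth(config$seed, config$species)`.
#' @return list with elements `truth`, `expression` (raw), `normalized`,
#'   `de` (full [de_table()]), `partition`, `enrichment`, `hits`,
#'   `conservation`, `summary` (upregulated genes joined to conserved
#'   motifs), `consistency`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(truth)) {
    truth <- default_ground_truth(config$seed, config$species)
  }

  stage_log("expression: generating ", config$n_genes, " genes x ",
    config$n_control + config$n_treated, " arrays (seed ", config$seed, ")"
  )
  expr <- generate_expression(
    truth,
    n_control = config$n_control, n_treated = config$n_treated,
    n_genes = config$n_genes, noise_sd = config$noise_sd,
    scale_factor_range = config$scale_factor_range,
    seed = config$seed
  )
  normalized <- normalize_percentile(expr, config$percentile)
  de <- de_table(fold_change(normalized), config$cutoff)
  parts <- partition_by_cutoff(de, config$cutoff)
  stage_log("de screen: ", parts$counts[["up"]], " up / ",
    parts$counts[["down"]], " down / ", parts$counts[["unchanged"]],
    " unchanged at |FC| >= ", config$cutoff
  )

  annotation <- generate_go_annotation(
    truth,
    genes = rownames(expr$intensities),
    n_terms = config$n_terms, enriched_size = config$enriched_size,
    enriched_overlap = config$enriched_overlap,
    seed = config$seed + 1L
  )
  enrichment <- enrich(parts$up$gene, annotation,
    alpha = config$alpha, universe = rownames(expr$intensities)
  )
  stage_log("enrichment: ", sum(enrichment$significant), " of ",
    nrow(enrichment), " tested terms significant at alpha = ", config$alpha
  )

  promoters <- generate_ortholog_promoters(
    truth,
    species = config$species, spec = config$window,
    motifs = config$motifs, seed = config$seed + 2L
  )
  report <- annotate_promoter_map(
    promoters,
    motifs = config$motifs, spec = config$window,
    species_universe = config$species, m = config$min_species
  )
  stage_log("motifs: ", nrow(report$hits), " hits, ",
    sum(report$conservation$conserved), " conserved (gene, motif) pairs at m = ",
    config$min_species
  )

  conserved <- report$conservation[report$conservation$conserved, ,
    drop = FALSE
  ]
  summary_tab <- merge(
    parts$up[, c("gene", "fc_signed")],
    conserved[, c("gene", "motif", "n_species", "positional_spread")],
    by = "gene"
  )
  summary_tab <- summary_tab[
    order(-abs(summary_tab$fc_signed), summary_tab$gene, summary_tab$motif), ,
    drop = FALSE
  ]
  rownames(summary_tab) <- NULL

  consistency <- consistency_check(de)

  out <- list(
    truth = truth, expression = expr, normalized = normalized, de = de,
    partition = parts, enrichment = enrichment, hits = report$hits,
    conservation = report$conservation, summary = summary_tab,
    consistency = consistency, config = config
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      write_stage_table(df, file.path(config$out_dir, name), config)
    }
    w(de, "de_table.tsv")
    w(enrichment, "enrichment.tsv")
    w(report$hits, "motif_hits.tsv")
    w(report$conservation, "conservation.tsv")
    w(summary_tab, "summary.tsv")
    w(consistency, "consistency.tsv")
    stage_log("outputs written to ", config$out_dir)
  }
  out
}

#' Check fold-change signs against the expected Notch-inhibition response
#'
#' Compares observed fold-change directions with the expected sign pattern
#' under Notch inhibition (by default the signs of the published screen
#' table: Hes5, Hey1, Nrarp, Jag1, Numb, Lfng, Notch1, Notch2 down; Dll1,
#' Mfng, Aph1a and the proneural/neuronal battery up). Genes absent from
#' the DE table are reported as untestable, not errors.
#'
#' @param de a [de_table()] / [fold_change()] result or named numeric of
#'   signed fold changes.
#' @param expected named numeric of expected signed fold changes (only
#'   the signs are used); default from [notch_screen_table()].
#' @return data.frame with columns `gene`, `expected_direction`,
#'   `observed_fc`, `observed_direction`, `status`
#'   (`consistent`/`violation`/`untestable`); attribute `"n_violations"`.
#' @export
consistency_check <- function(de, expected = NULL) {
  if (is.null(expected)) {
    tab <- notch_screen_table()
    expected <- setNames(tab$fc, tab$gene)
  }
  df <- as_fc_frame(de)
  obs <- setNames(df$fc_signed, df$gene)
  dir_of <- function(fc) {
    ifelse(is.na(fc), NA_character_, ifelse(fc > 1, "up",
      ifelse(fc < -1, "down", "unchanged")
    ))
  }
  exp_dir <- dir_of(expected)
  observed_fc <- obs[names(expected)]
  obs_dir <- dir_of(observed_fc)
  status <- ifelse(is.na(obs_dir), "untestable",
    ifelse(obs_dir == exp_dir, "consistent", "violation")
  )
  out <- data.frame(
    gene = names(expected),
    expected_direction = unname(exp_dir),
    observed_fc = unname(observed_fc),
    observed_direction = unname(obs_dir),
    status = unname(status),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_violations") <- sum(out$status == "violation")
  out
}
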