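# End-to-end pipeline, consistency check and the series-matrix path.

test_that("default pipeline joins upregulated genes to conserved motifs", {
  res <- suppressMessages(run_pipeline(pipeline_config(seed = 101)))

  strict <- res$summary[res$summary$motif %in% c("MHAM", "MNAM"), ]
  mham <- strict$gene[strict$motif == "MHAM"]
  mnam <- strict$gene[strict$motif == "MNAM"]
  # Hes5 is planted down so of the four MHAM promoters only Chga, Chrdl1
  # and Dll1 can surface in the upregulated join
  expect_true(all(c("Chga", "Chrdl1") %in% mham))
  expect_true(all(c("Robo2", "Tagln3") %in% mnam))
  expect_false("Hes5" %in% strict$gene)

  expect_identical(attr(res$consistency, "n_violations"), 0L)
  expect_identical(res$enrichment$term[1], res$truth$enriched_term)
  expect_true(res$enrichment$significant[1])
})

test_that("an unreachable cutoff empties the lists but completes", {
  cfg <- pipeline_config(seed = 3, cutoff = 1e6, n_genes = 400)
  res <- suppressMessages(run_pipeline(cfg))
  expect_identical(res$partition$counts[["up"]], 0L)
  expect_identical(res$partition$counts[["down"]], 0L)
  expect_identical(nrow(res$summary), 0L)
})

test_that("same seed and config give byte-identical outputs", {
  d1 <- file.path(tempdir(), "run1")
  d2 <- file.path(tempdir(), "run2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  suppressMessages(run_pipeline(
    pipeline_config(seed = 55, n_genes = 400, out_dir = d1)
  ))
  suppressMessages(run_pipeline(
    pipeline_config(seed = 55, n_genes = 400, out_dir = d2)
  ))
  for (f in list.files(d1)) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
      label = f
    )
  }
})

test_that("consistency check counts sign flips and flags absent genes", {
  tab <- notch_screen_table()
  direct <- consistency_check(setNames(tab$fc, tab$gene))
  expect_identical(attr(direct, "n_violations"), 0L)

  flipped <- setNames(tab$fc, tab$gene)
  flipped[c("Hes5", "Dll1", "Chga")] <- -flipped[c("Hes5", "Dll1", "Chga")]
  res <- consistency_check(flipped)
  expect_identical(attr(res, "n_violations"), 3L)
  expect_setequal(
    res$gene[res$status == "violation"], c("Hes5", "Dll1", "Chga")
  )

  partial <- consistency_check(c(Hes5 = -10))
  expect_identical(
    unique(partial$status[partial$gene != "Hes5"]), "untestable"
  )
  expect_identical(partial$status[partial$gene == "Hes5"], "consistent")
})

test_that("series-matrix files feed the screen unchanged", {
  gt <- ground_truth(c(Hes5 = -56.83, Dll1 = 2.26), seed = 9)
  em <- generate_expression(gt, n_genes = 120, noise_sd = 0)

  path <- tempfile(fileext = ".txt")
  con <- file(path, "w")
  writeLines(c(
    "!Series_title\t\"synthetic screen\"",
    paste(
      c("!Sample_title", sprintf("\"%s\"", colnames(em$intensities))),
      collapse = "\t"
    ),
    "!series_matrix_table_begin",
    paste(c("ID_REF", colnames(em$intensities)), collapse = "\t")
  ), con)
  write.table(em$intensities, con,
    sep = "\t", quote = FALSE, col.names = FALSE
  )
  writeLines("!series_matrix_table_end", con)
  close(con)

  res <- screen_series_matrix(path, em$condition)
  expect_identical(res$partition$counts[["up"]], 1L)
  expect_identical(res$partition$counts[["down"]], 1L)
  expect_equal(
    res$de$fc_signed[res$de$gene == "Hes5"], -56.83,
    tolerance = 1e-9
  )

  # probe collapsing: median across probes of a symbol
  mat <- rbind(p1 = c(1, 2), p2 = c(3, 4), p3 = c(100, 100))
  colnames(mat) <- c("s1", "s2")
  coll <- collapse_probes(mat, c("g", "g", "h"))
  expect_equal(coll["g", ], c(s1 = 2, s2 = 3))
})
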