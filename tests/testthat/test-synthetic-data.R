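# Synthetic-data generators: planted signal, reproducibility, rejection
# of inconsistent requests.

test_that("noise-free generation reproduces planted ratios exactly", {
  gt <- ground_truth(
    c(Hes5 = -56.83, Dll1 = 2.26, Neurog1 = 8.85),
    seed = 11
  )
  em <- generate_expression(gt,
    n_genes = 200, noise_sd = 0,
    scale_factor_range = c(1, 1)
  )
  ratio <- rowMeans(em$intensities[, em$condition == "treated"]) /
    rowMeans(em$intensities[, em$condition == "control"])
  expect_equal(ratio[["Hes5"]], 1 / 56.83, tolerance = 1e-12)
  expect_equal(ratio[["Dll1"]], 2.26, tolerance = 1e-12)
  expect_equal(ratio[["Neurog1"]], 8.85, tolerance = 1e-12)
})

test_that("no planted genes, no noise, unit factors: conditions identical", {
  gt <- ground_truth(seed = 3)
  em <- generate_expression(gt,
    n_genes = 50, noise_sd = 0,
    scale_factor_range = c(1, 1)
  )
  expect_identical(
    em$intensities[, em$condition == "control", drop = FALSE][, 1],
    em$intensities[, em$condition == "treated", drop = FALSE][, 1]
  )
})

test_that("generators are bit-reproducible under a fixed seed", {
  gt <- default_ground_truth(seed = 42)
  a <- generate_expression(gt, n_genes = 300)
  b <- generate_expression(gt, n_genes = 300)
  expect_identical(a$intensities, b$intensities)

  pa <- generate_ortholog_promoters(gt)
  pb <- generate_ortholog_promoters(gt)
  expect_identical(pa, pb)

  fa <- tempfile(fileext = ".fa")
  fb <- tempfile(fileext = ".fa")
  write_promoters(pa, fa)
  write_promoters(pb, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
    readBin(fb, "raw", file.size(fb))
  )

  ga <- generate_go_annotation(gt, genes = names(gt$planted_fc))
  gb <- generate_go_annotation(gt, genes = names(gt$planted_fc))
  expect_identical(ga, gb)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_expression(ground_truth(seed = 5), n_genes = 20))
  expect_identical(runif(1), before)
})

test_that("invalid generation requests are rejected", {
  gt <- ground_truth(c(A = 2), seed = 1)
  expect_error(generate_expression(gt, noise_sd = -0.1), "noise_sd")
  expect_error(generate_expression(gt, n_control = 0), "replicate")
  expect_error(ground_truth(c(A = 0.5)), "\\|fc\\| >= 1")
  expect_error(
    generate_go_annotation(gt, genes = LETTERS,
      enriched_size = 5, enriched_overlap = 6
    ),
    "overlap"
  )
  # planted site must fit inside the window
  bad <- ground_truth(
    c(Chga = 1.74),
    planted_motifs = data.frame(
      gene = "Chga", motif = "MHAM", species = "mouse",
      offset = 99L, strand = "+"
    ),
    seed = 1
  )
  expect_error(
    generate_ortholog_promoters(bad, spec = promoter_window_spec(50, 100)),
    "does not fit"
  )
  expect_error(
    ground_truth(c(A = 2), planted_motifs = data.frame(
      gene = "A", motif = "MHAM", species = "m", offset = 0L, strand = "+"
    )),
    "no-zero"
  )
})

test_that("GO generator plants the requested overlap and sizes", {
  fc <- setNames(rep(2, 30), sprintf("up%02d", 1:30))
  gt <- ground_truth(fc, enriched_term = "GO:TEST", seed = 8)
  genes <- c(names(fc), sprintf("bg%02d", 1:70))
  ann <- generate_go_annotation(gt,
    genes = genes, n_terms = 5,
    enriched_size = 10, enriched_overlap = 8
  )
  planted <- ann$gene[ann$term == "GO:TEST"]
  expect_length(planted, 10)
  expect_identical(sum(planted %in% names(fc)), 8L)

  empty <- generate_go_annotation(gt, genes = genes, n_terms = 0)
  expect_identical(nrow(empty), 0L)
})

test_that("planted promoter motifs are written at the stated coordinates", {
  plan <- data.frame(
    gene = c("Chga", "Chga", "Robo2"),
    motif = c("MHAM", "MHAM", "MNAM"),
    species = c("chick", "mouse", "mouse"),
    offset = c(-120L, -120L, 40L),
    strand = c("+", "-", "+")
  )
  gt <- ground_truth(c(Chga = 1.74, Robo2 = 1.46),
    planted_motifs = plan, seed = 21
  )
  prom <- generate_ortholog_promoters(gt, species = c("chick", "mouse"))
  spec <- promoter_window_spec()

  # plus-strand site: literal motif at the offset
  chick <- prom[grepl("^Chga\\|chick", names(prom))]
  i <- notchscreen:::tss_to_index(-120L, spec)
  expect_identical(unname(substr(chick, i, i + 6L)), "CACCTGC")

  # minus-strand site: reverse complement written on the plus strand
  mouse <- prom[grepl("^Chga\\|mouse", names(prom))]
  expect_identical(unname(substr(mouse, i, i + 6L)), "GCAGGTG")

  # downstream (positive offset) planting
  robo <- prom[grepl("^Robo2\\|mouse", names(prom))]
  j <- notchscreen:::tss_to_index(40L, spec)
  expect_identical(unname(substr(robo, j, j + 6L)), "GCAGCTG")

  # headers carry the window coordinates and round-trip through FASTA
  info <- parse_promoter_header(names(prom))
  expect_true(all(info$start == -500L & info$end == 101L))
  fa <- tempfile(fileext = ".fa")
  write_promoters(prom, fa)
  expect_identical(read_promoters(fa), prom)
})

test_that("expression matrix round-trips through its TSV form", {
  gt <- ground_truth(c(Hes5 = -56.83), seed = 13)
  em <- generate_expression(gt, n_genes = 30)
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path)
  expect_equal(back$intensities, em$intensities, tolerance = 1e-12)
  expect_identical(back$condition, em$condition)
})

test_that("background motif hit counts match the Bernoulli expectation", {
  # strict 7-mer on unplanted uniform sequence: per window of length L
  # there are (L - 6) positions x 2 strands, each matching with prob 4^-7
  gt <- ground_truth(seed = 1)
  spec <- promoter_window_spec()
  L <- window_length(spec)
  n_win <- 120
  p <- (1 / 4)^7
  n_pos <- (L - 6) * 2 * n_win
  expected <- n_pos * p

  hits <- 0
  for (s in seq_len(n_win)) {
    gt_s <- ground_truth(c(G1 = 2), seed = s)
    prom <- generate_ortholog_promoters(gt_s,
      genes = "G1", species = "only",
      spec = spec
    )
    hits <- hits + nrow(scan_motif(unname(prom[1]), c(MHAM = "CACCTGC")))
  }
  sigma <- sqrt(n_pos * p * (1 - p))
  expect_lt(abs(hits - expected), 3 * sigma + 1)
})
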