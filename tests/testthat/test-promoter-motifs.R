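# Window extraction, IUPAC scanning, consensus derivation and
# conservation calling.

test_that("window extraction slices around the TSS on either strand", {
  spec <- promoter_window_spec(3, 2)
  w <- extract_window("AAACGTTT", tss = 5, spec = spec)
  expect_identical(w$seq, "AACGTT")
  expect_identical(w$first_pos, -3L)
  expect_identical(notchscreen:::index_to_tss(4L, spec, w$first_pos), 1L)

  # minus-strand gene: reverse complement of the mirrored slice
  wm <- extract_window("AAACGTTT", tss = 5, strand = "-", spec = spec)
  expect_identical(wm$seq, revcomp_chr(substr("AAACGTTT", 3, 8)))

  expect_identical(window_length(promoter_window_spec()), 601L)

  expect_warning(
    trunc <- extract_window("ACGTACGT", tss = 2, spec = spec),
    "truncated"
  )
  expect_identical(trunc$seq, "ACGT")
  expect_identical(trunc$first_pos, -1L)

  expect_error(extract_window("ACGT", tss = 9, spec = spec), "outside")
})

test_that("motif scanning matches the worked examples", {
  hit <- scan_motif("TTCACCTGCTT", c(MHAM = "CACCTGC"))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 3L)
  expect_identical(hit$strand, "+")

  # CANNTG as a pattern class is reverse-complement symmetric
  eb <- scan_motif("CAGCTG", c(EBOX = "CANNTG"))
  expect_identical(eb$start, c(1L, 1L))
  expect_identical(eb$strand, c("+", "-"))

  expect_identical(
    nrow(scan_motif(strrep("A", 50), motif_defs())), 0L
  )
  expect_error(scan_motif("ACGT", c(BAD = "CAXXTG")), "invalid IUPAC")

  # overlapping occurrences are all reported
  ov <- scan_motif("CACACACAG", c(M = "CACA"), both_strands = FALSE)
  expect_identical(ov$start, c(1L, 3L, 5L))
})

test_that("scanner agrees with the naive position-by-position oracle", {
  set.seed(77)
  motifs <- c(
    EBOX = "CANNTG", NBOX = "CACNAG", MHAM = "CACCTGC", MNAM = "GCAGCTG",
    MIX = "RYSWKM"
  )
  for (i in 1:150) {
    sq <- random_dna(sample(20:200, 1))
    id <- sample(names(motifs), 1)
    got <- scan_motif(sq, motifs[id])
    want <- naive_scan(sq, motifs[[id]])
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- want[order(want$start, match(want$strand, c("+", "-"))), ]
      expect_identical(got$start, want$start)
      expect_identical(got$strand, want$strand)
    }
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  set.seed(31)
  for (i in 1:25) {
    sq <- random_dna(80)
    cons <- c(X = sample(c("CANNTG", "CACCTGC", "GCAGCTG"), 1))
    fwd <- scan_motif(sq, cons)
    rev <- scan_motif(revcomp_chr(sq), cons)
    L <- nchar(cons[[1]])
    mirrored <- sort(nchar(sq) - (fwd$start + L - 1L) + 1L)
    expect_identical(sort(rev$start), mirrored)
    expect_identical(nrow(rev), nrow(fwd))
  }
})

test_that("every plus-strand MHAM hit contains an E-box at its start", {
  set.seed(13)
  for (i in 1:20) {
    sq <- paste0(random_dna(40), "CACCTGC", random_dna(40))
    mham <- scan_motif(sq, c(MHAM = "CACCTGC"), both_strands = FALSE)
    ebox <- scan_motif(sq, c(EBOX = "CANNTG"), both_strands = FALSE)
    expect_true(all(mham$start %in% ebox$start))
  }
})

test_that("IUPAC consensus derivation is exact, order-invariant and round-trips", {
  expect_identical(derive_iupac_consensus("CACCTGC"), "CACCTGC")
  expect_identical(
    derive_iupac_consensus(c("CACCTGC", "CACCTGC")), "CACCTGC"
  )
  sites <- c("CAACTG", "CAGCTG", "CATCTG", "CACCTG")
  expect_identical(derive_iupac_consensus(sites), "CANCTG")
  expect_identical(
    derive_iupac_consensus(rev(sites)), derive_iupac_consensus(sites)
  )
  expect_error(derive_iupac_consensus(c("CAT", "CATG")), "ragged")

  # round-trip: every input site matches the derived consensus
  set.seed(5)
  for (i in 1:20) {
    sites <- vapply(1:4, function(j) random_dna(8), "")
    cons <- derive_iupac_consensus(sites)
    for (s in sites) {
      expect_identical(
        scan_motif(s, c(C = cons), both_strands = FALSE)$start, 1L
      )
    }
  }
})

test_that("conservation calls are presence-based at threshold m", {
  hits <- data.frame(
    gene = c("Chga", "Chga", "Robo2"),
    species = c("mouse", "chick", "mouse"),
    motif = c("MHAM", "MHAM", "MNAM"),
    start_tss = c(-120L, -118L, -150L)
  )
  sp4 <- c("mouse", "chick", "human", "zebrafish")
  calls <- call_conservation(hits, sp4, m = 2)
  chga <- calls[calls$gene == "Chga", ]
  expect_true(chga$conserved)
  expect_identical(chga$positional_spread, 2L)
  expect_false(calls$conserved[calls$gene == "Robo2"])

  expect_error(call_conservation(hits, sp4, m = 5), "exceeds")
  expect_error(call_conservation(hits, sp4, m = 0), ">= 1")
})

test_that("promoter map recovers planted motifs and keeps empty genes", {
  plan <- rbind(
    data.frame(
      gene = "Chga", motif = "MHAM",
      species = c("chick", "mouse", "human", "zebrafish"),
      offset = -120L, strand = "+"
    ),
    data.frame(
      gene = "Tagln3", motif = "MNAM", species = "mouse",
      offset = -65L, strand = "+"
    )
  )
  gt <- ground_truth(c(Chga = 1.74, Tagln3 = 3.69, Bare = 2),
    planted_motifs = plan, seed = 14
  )
  sp <- c("chick", "mouse", "human", "zebrafish")
  prom <- generate_ortholog_promoters(gt, species = sp)
  rep <- annotate_promoter_map(prom, species_universe = sp, m = 3)

  cons <- rep$conservation
  expect_true(cons$conserved[cons$gene == "Chga" & cons$motif == "MHAM"])
  mham_chga <- rep$hits[
    rep$hits$gene == "Chga" & rep$hits$motif == "MHAM" &
      rep$hits$strand == "+",
  ]
  # the planted site is found at its offset in every species (chance
  # background hits elsewhere in the window are allowed)
  expect_setequal(
    mham_chga$species[mham_chga$start_tss == -120L], sp
  )

  # MNAM present in only 1 of 4 species: below threshold, not conserved
  mnam <- cons[cons$gene == "Tagln3" & cons$motif == "MNAM", ]
  expect_true(nrow(mnam) == 0L || !mnam$conserved)

  # genes with no hits still appear in the report's gene list
  expect_true("Bare" %in% rep$genes)

  # EBOX annotated as subsuming the planted MHAM at the same start
  sub <- rep$hits[
    rep$hits$gene == "Chga" & rep$hits$motif == "EBOX" &
      !is.na(rep$hits$subsumes),
  ]
  expect_true(any(sub$start_tss == -120L & sub$subsumes == "MHAM"))
})
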