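---
title: "Methods: fold-change screening, GO enrichment and promoter motif conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fold-change screening, GO enrichment and promoter motif conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchscreen)
```

`notchscreen` rebuilds a Notch-target discovery screen as a pipeline of
four stages. This vignette explains the model behind each stage, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open.

## The biological screen being modelled

During early neurogenesis, Notch signalling keeps progenitors
undifferentiated by lateral inhibition: DLL1 on a differentiating cell
activates NOTCH in its neighbours; NOTCH induces the repressor bHLH
genes *Hes5* and *Hey1*; HES5/HEY1 silence the proneural activator
*Ascl1*, which otherwise drives *Dll1*, *Nhlh1* and a battery of
neuronal genes. Chemically blocking Notch (DAPT, a γ-secretase
inhibitor) collapses this loop: *Hes5*/*Hey1* fall, the proneural
programme rises. A one-colour microarray comparison of treated versus
control embryonic forebrain tissue reads the programme out as fold
changes; GO over-representation summarizes the affected processes; and
a cross-species promoter scan asks whether candidate targets carry the
binding-site signatures of the circuit's own transcription factors —
the degenerate E-box (`CANNTG`, activator bHLH) and N-box (`CACNAG`,
repressor bHLH), and two strict 7-mers offering better stringency than
the degenerate boxes: MHAM (`CACCTGC`, an ASCL1/HEY antagonist site)
and MNAM (`GCAGCTG`, an ASCL1/NHLH1 antagonist site).
`regulatory_model()` records the static interaction table of this
circuit; `notch_screen_table()` records the published signed fold
changes that the package treats as reference inputs.

## Expression screen

**Normalization.** Each array is divided by its own 50th-percentile
intensity (`normalize_percentile()`, `percentile = 50`). This per-chip
method makes arrays comparable without any between-array model; after
it, every array's median is exactly 1. The operation is idempotent and
invariant to global array scale factors. Arrays with no positive
intensity, or whose chosen percentile is zero, are rejected outright
rather than propagating division by zero.

**Fold change.** For each gene, `r = mean(treated) / mean(control)`
over the normalized *linear* intensities, reported in the signed
magnitude-≥1 convention: `fc = r` when `r ≥ 1`, else `−1/r`. The choice
of arithmetic means on the linear scale (rather than means of logs) is
a design decision: it matches how ratio-style fold changes are
conventionally reported for one-colour arrays, and it makes the
noise-free recovery property exact. Genes whose control mean is zero
have no defined ratio; they are reported with `NA` and a diagnostic
message, never dropped silently.

**Cutoff.** `partition_by_cutoff()` classifies genes at an *inclusive*
absolute threshold (default 1.3): `fc ≥ 1.3` is up, `fc ≤ −1.3` down,
everything else unchanged. The three lists are disjoint, jointly
exhaustive, and deterministically ordered (|fc| descending, ties by
gene identifier). A fold change of exactly 1.30 is upregulated — the
boundary gene *Chrdl1* (1.30) in the reference table is the canonical
check. No variance filter or moderated statistic is applied: the screen
is fold-change-only by design, and p-value-based testing is explicitly
out of scope.

## GO enrichment

`enrich()` performs the standard over-representation test: for a query
of `n` genes from a universe of `N`, a term annotating `K` genes and
overlapping the query in `k`, the raw p-value is the exact upper tail

p = Σ_{i = k}^{min(K, n)} C(K, i) C(N−K, n−i) / C(N, n),

computed via the hypergeometric distribution function (no normal
approximation). Benjamini–Hochberg is applied across the *tested*
terms, where tested means overlap ≥ 1; terms with zero overlap are
suppressed, which deliberately makes the BH family the set of
reportable terms — this matters, because including empty terms would
shrink every adjusted p-value. The universe defaults to all annotated
genes but is configurable; the pipeline passes the full array gene list
so the term sizes `K` are measured against everything that could have
been detected. One-sidedness is fixed at "at least k" (the observed
overlap is included in the tail). Significance is `p_adj ≤ α` with
α = 0.05. No GO-graph propagation is performed: the annotation is taken
as given.

## Promoter windows and motif conservation

**Coordinates.** Promoter windows are anchored at the transcription
start site with the "+1" convention: the TSS is position +1, the base
before it −1, and there is *no position 0*. A window of
`upstream = 500` and `downstream = 100` therefore covers
−500…−1, +1, +2…+101 — 601 nt in total (`window_length()`), i.e. 500
bases before the start, the start itself, and 100 bases after it.
Internally all arithmetic happens on a gapless integer line
(−1 ↔ −1, +1 ↔ 0) with converters at the interfaces, so off-by-one
errors around the missing zero cannot accumulate; FASTA headers and all
reports use the +1 convention. `extract_window()` takes a 1-based TSS
position within its source record, returns the window reading 5'→3' on
the gene's coding strand (minus-strand genes are
reverse-complemented), truncates with a warning when the record is too
short, and rejects a TSS outside the record.

**Scanning.** `scan_motif()` tests every window position against the
consensus under IUPAC semantics, compiled to character-class regular
expressions with a lookahead so overlapping occurrences are all found.
Both strands are scanned by default — a deliberate choice the E-box
class justifies (as a pattern class `CANNTG` is its own reverse
complement, and TF binding is double-stranded); the reported strand
disambiguates. Minus-strand hits are reported at the leftmost base of
the matched region on the window's plus strand, so plus- and
minus-strand hits at the same site share a coordinate. Scanning is
strict string matching, not PSSM scoring: the strict 7-mers are the
point of the screen precisely because they are more stringent than the
degenerate boxes, and matrix scoring is out of scope.

**Consensus derivation.** `derive_iupac_consensus()` reduces each
column of a gap-free alignment of sites to the IUPAC code denoting
exactly the set of observed bases. Note this is set-exact, not
generalizing: `{CAACTG, CAGCTG, CATCTG, CACCTG}` yields `CANCTG`, not
the looser `CANNTG`, because the third column saw all four bases but
the fourth saw only `C`.

**Conservation.** `call_conservation()` is presence-based: a
(gene, motif) pair is conserved when hits exist in at least `m`
distinct species (default: all species provided). The largest pairwise
distance between supporting hit positions (`positional_spread`, in nt
on the gapless line) is reported but not filtered on — the source
analyses used multiple alignments without stating a positional
tolerance, so the package reports the quantity a stricter post-filter
would need rather than inventing a threshold. `annotate_promoter_map()`
pools hits over all motifs, species and genes, calls conservation, and
annotates degenerate hits that subsume a strict hit at the same
position (every plus-strand MHAM occurrence contains an E-box at its
start, since `CACCTGC` begins with a `CANNTG` match).

## The synthetic-data generator

The generator exists so that every downstream stage can be tested
against known truth, offline. Its defaults are the study conditions:

* **Design:** 4 control + 4 treated arrays (`n_control`, `n_treated`),
  mirroring four independent pooled-replicate culture sets per
  condition. Pooling variance is not modelled separately from array
  noise; both are absorbed into the single `noise_sd` knob.
* **Effect sizes:** `default_ground_truth()` plants the full published
  fold-change table (34 genes, from *Hes5* at −56.83 to *Chrdl1* at
  +1.30) via the ratio `fc` (up) or `1/|fc|` (down).
* **Noise:** multiplicative log-normal on intensities, `noise_sd = 0.1`
  (natural-log scale), the calibrated noisy study condition. The
  log-normal choice is standard for one-colour arrays and preserves
  positivity.
* **Array effects:** each array is multiplied by a global scale factor
  drawn log-uniformly from [0.5, 2], so the normalization stage has
  real work to do and is actually exercised by every test.
* **Baselines:** per-gene log-normal (meanlog `log(500)`, sdlog 1).
  Planted genes are seated outside the central quartile band of the
  unplanted baselines — upregulated above Q3, downregulated below Q1.
  This is the one non-obvious numerical choice in the generator:
  because planting then never moves any gene across the array median,
  the 50th-percentile divisors are pinned by unplanted genes, and with
  `noise_sd = 0` the normalize → fold-change path returns every planted
  value to machine precision (the package asserts ≤ 1e-9 relative
  error). Without this placement, a strongly downregulated gene
  crossing the median would perturb the divisor and exactness would be
  unattainable.
* **Annotation:** background terms annotate uniformly sampled genes;
  the planted term annotates 8 planted-upregulated genes out of 10
  (`enriched_overlap`/`enriched_size`), an overlap far above random
  expectation by construction.
* **Promoters:** uniform ACGT background (configurable GC), one window
  per gene per species, with planted motif strings overwritten at their
  stated TSS-relative offsets and strands; the default plan places MHAM
  in the *Hes5*, *Dll1*, *Chga* and *Chrdl1* windows and MNAM in
  *Robo2* and *Tagln3*, in all four default species (chick, mouse,
  human, zebrafish — a panel choice; the original comparison spanned
  "numerous organisms" without listing them). Planted offsets are a
  fixture choice within the proximal window, not published coordinates.

Seeds are explicit function arguments, never global state: generation
is bit-reproducible and leaves the caller's RNG stream untouched.

**What passing tests do and do not show.** The generator emulates
gene-level intensities with independent log-normal noise, uniform
promoter background and a clean planted signal. Real arrays have
probe-level structure, correlated noise, intensity-dependent variance,
background hybridization and flagging, and real promoters have
composition bias, repeats and alignable orthology — none of which is
modelled. Recovery on synthetic data therefore validates the *code
path and its mathematics* (normalization exactness, sign conventions,
tail probabilities, coordinate handling, conservation logic), not the
biological error rate of the screen on deposited data. The real-data
mode (`read_series_matrix()`, `screen_series_matrix()`,
`collapse_probes()` — median per gene symbol, robust and
order-independent) runs the identical stages on a deposited
series-matrix file; reproducing the original up/down totals exactly
would additionally require the original unstated probe filtering, so
totals from that path should be read as approximations, and the
published database-dependent enrichment p-values are not reproduction
targets at all.

## Problem sizes and determinism

Default runs use 2,000 genes × 8 arrays, 50 GO terms, and
34 genes × 4 species × 601 nt of promoter sequence — sizes at which the
full pipeline completes in about a second and the repeated-seed
studies (100 seeds for direction recovery, 20 for conservation
recovery, 200 null enrichment queries) complete in well under a minute
each. Two runs with the same seed and configuration produce
byte-identical output files; every output table carries its
configuration in commented header lines.

## Known limitations

* Fold-change-only screening has no error model; a gene's membership in
  the up/down lists is sensitive to noise exactly at the cutoff
  boundary (a planted |FC| = 1.30 gene sits on the threshold and falls
  below it in roughly half of noisy replicates — its *direction* is
  still recovered).
* Conservation is presence-in-window, not positional orthology;
  `positional_spread` is reported so users can post-filter.
* The strict 7-mers are matched literally; true binding affinity
  differences between sites are invisible to string matching.
* The GEO reader parses only the series-matrix table and `!Sample_*`
  lines; supplementary raw files are out of scope.
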