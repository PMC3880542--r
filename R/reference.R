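# Published reference values used as inputs: the fold-change table from
# the DAPT-vs-DMSO forebrain screen and the static regulatory interaction
# model of the Notch/proneural circuit.

#' Reference fold changes of the Notch-inhibition screen
#'
#' Signed fold changes (GeneSpring convention: magnitude >= 1, sign =
#' direction in DAPT-treated vs DMSO control forebrain) for the Notch
#' signalling pathway components and for the 23 upregulated genes of the
#' enriched *nervous system development* GO term. These printed values are
#' inputs to the package: the synthetic-data generator plants them as
#' ground-truth effect sizes and [consistency_check()] uses their signs as
#' the expected response to Notch inhibition.
#'
#' @param category optional filter: `"notch_pathway"`,
#'   `"nervous_system_development"`, or both (default).
#' @return data.frame with columns `gene`, `category`, `fc` (signed fold
#'   change, `|fc| >= 1`).
#' @examples
#' head(notch_screen_table())
#' nrow(notch_screen_table("nervous_system_development")) # 23
#' @export
notch_screen_table <- function(category = c(
                                 "notch_pathway",
                                 "nervous_system_development"
                               )) {
  category <- match.arg(category, several.ok = TRUE)
  notch <- data.frame(
    gene = c(
      "Hes5", "Hey1", "Nrarp", "Jag1", "Numb", "Lfng", "Notch1",
      "Notch2", "Aph1a", "Dll1", "Mfng"
    ),
    category = "notch_pathway",
    fc = c(
      -56.83, -2.89, -2.02, -1.58, -1.49, -1.46, -1.31,
      -1.30, 1.34, 2.26, 3.15
    ),
    stringsAsFactors = FALSE
  )
  nsd <- data.frame(
    gene = c(
      "Neurog1", "Nhlh2", "Nefm", "Tagln3", "Nhlh1", "Stmn2", "Nr5a1",
      "Nrg1", "Chga", "Sim1", "Bsx", "Ascl1", "Nr5a2", "Gap43",
      "Neurog2", "Sox14", "Robo2", "Cntn2", "Slit1", "Hes6", "Bdnf",
      "Foxn4", "Chrdl1"
    ),
    category = "nervous_system_development",
    fc = c(
      8.85, 4.18, 4.05, 3.69, 3.47, 2.49, 1.87,
      1.77, 1.74, 1.74, 1.68, 1.67, 1.59, 1.57,
      1.57, 1.51, 1.46, 1.39, 1.37, 1.36, 1.34,
      1.31, 1.30
    ),
    stringsAsFactors = FALSE
  )
  out <- rbind(notch, nsd)
  out <- out[out$category %in% category, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Static regulatory interaction model of the Notch/proneural circuit
#'
#' Directed, signed edges of the lateral-inhibition circuit: DLL1 on a
#' neighbouring cell activates NOTCH; activated NOTCH induces the
#' repressor-type bHLH effectors HES5 and HEY1; these repress the proneural
#' activator ASCL1; ASCL1 activates DLL1, NHLH1 and the downstream neuronal
#' target battery (Tagln3, Chga, Chrdl1, Robo2, Stmn2, ...), as does NHLH1.
#'
#' @return data.frame with columns `regulator`, `target`, `effect`
#'   (`"activates"` or `"represses"`).
#' @export
regulatory_model <- function() {
  data.frame(
    regulator = c(
      "DLL1", "NOTCH", "NOTCH", "HES5", "HEY1",
      "ASCL1", "ASCL1", "ASCL1", "NHLH1"
    ),
    target = c(
      "NOTCH", "HES5", "HEY1", "ASCL1", "ASCL1",
      "DLL1", "NHLH1", "TARGETS", "TARGETS"
    ),
    effect = c(
      "activates", "activates", "activates", "represses", "represses",
      "activates", "activates", "activates", "activates"
    ),
    stringsAsFactors = FALSE
  )
}

#' Default conserved-motif plan for the synthetic promoter fixture
#'
#' The placement emulated by the synthetic ortholog promoters: the strict
#' ASCL1/HEY antagonist 7-mer (MHAM) in the Hes5, Dll1, Chga and Chrdl1
#' proximal promoters and the strict ASCL1/NHLH1 antagonist 7-mer (MNAM)
#' in Robo2 and Tagln3. Offsets are TSS-relative positions (negative =
#' upstream, no position 0) of the 5'-most base of the site; they are a
#' fixture choice within the proximal window, not published coordinates.
#'
#' @return data.frame with columns `gene`, `motif`, `offset`, `strand`.
#' @export
conserved_motif_plan <- function() {
  data.frame(
    gene = c("Hes5", "Dll1", "Chga", "Chrdl1", "Robo2", "Tagln3"),
    motif = c("MHAM", "MHAM", "MHAM", "MHAM", "MNAM", "MNAM"),
    offset = c(-87L, -203L, -120L, -310L, -150L, -65L),
    strand = "+",
    stringsAsFactors = FALSE
  )
}
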