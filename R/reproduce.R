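## One-shot recomputation of every derivable cell of the packaged
## reference tables from their measured input rows, with a side-by-side
## comparison against the tabulated values.
##
## Three tabulated cells are documented as non-reproducible from the
## printed inputs and are flagged, never silently passed:
##   - the TFA row: the tabulated values (male 2.67, female 2.06) do not
##     equal trans-vaccenic + trans-C18:2 (4.47, 2.00) under any isomer
##     assignment;
##   - female TI: tabulated 1.74, recomputes to 1.78 from the female
##     column (input-rounding noise);
##   - the overall stearic value (9.86) is inconsistent with the sex
##     means (22.15 / 13.45) although consistent with the overall TI, so
##     the overall SFA and UFA/SFA rows cannot be reproduced from it.
## The tabulated n6/n3 row is a per-sample mean of ratios whose
## underlying replicates are not available, so it is compared as
## aggregation-dependent rather than pass/fail.

.relDiff <- function(a, b) abs(a - b) / abs(b)

#' Recompute the reference dataset's derived rows
#'
#' Recomputes, from the packaged measured input rows only, every
#' derivable quantity of the reference tables: fatty-acid class sums,
#' ratios and health indices per column (male, female, overall), and the
#' protein-basis values, chemical scores, EAAI, BV and NI per FAO/WHO
#' standard. Each recomputed value is compared with its tabulated
#' counterpart at the documented tolerance (0.05 absolute for lipid
#' quantities, 0.5% relative for protein quantities, both derived from
#' two-decimal input rounding propagated through the formulas).
#'
#' @param dialect lipid index dialect; "as_published" (default)
#'   reproduces the tabulated cells, "conventional" marks the
#'   dialect-sensitive cells (n6, hFA, h/H, AI, TI) as expected
#'   mismatches.
#' @param lipidTol absolute tolerance for lipid cells.
#' @param proteinTol relative tolerance for protein cells.
#' @return data.frame with columns `block`, `quantity`, `column`,
#'   `tabulated`, `recomputed`, `diff`, `tolerance`, `pass`,
#'   `known_discrepancy`, `note`; attribute `ok` is TRUE when every cell
#'   passes or is a documented discrepancy.
#' @export
#' @examples
#' rep <- reproduceReference()
#' attr(rep, "ok")
#' subset(rep, known_discrepancy)
reproduceReference <- function(dialect = c("as_published", "conventional"),
                               lipidTol = 0.05, proteinTol = 0.005) {
  dialect <- match.arg(dialect)
  rows <- list()
  add <- function(block, quantity, column, tabulated, recomputed,
                  tolerance, relative = FALSE, known = FALSE, note = "") {
    diff <- if (relative) .relDiff(recomputed, tabulated)
            else abs(recomputed - tabulated)
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, quantity = quantity, column = column,
      tabulated = tabulated, recomputed = recomputed, diff = diff,
      tolerance = tolerance, pass = diff <= tolerance,
      known_discrepancy = known, note = note, stringsAsFactors = FALSE)
  }

  ## ---- lipid block -------------------------------------------------------
  printed <- aubracTable("fatty_acid_indices")
  dialectCells <- if (dialect == "conventional")
    c("n6", "hfa_lower", "h_over_H", "ai", "ti") else character(0)
  for (col in c("male", "female", "overall")) {
    prof <- aubracProfile("fatty_acid", col)
    cls <- sumFattyAcidClasses(prof, dialect, warnMissing = FALSE)
    li <- lipidQualityIndices(prof, dialect)
    rec <- c(n3 = cls@n3, n6 = cls@n6, tfa = cls@tfa, sfa = cls@sfa,
             mufa = cls@mufa, pufa = cls@pufa, ufa = cls@ufa,
             ufa_sfa = cls@ufaSfaRatio, n6_n3 = cls@n6n3Ratio,
             ai = li@ai, ti = li@ti, hfa_upper = li@hfaUpper,
             hfa_lower = li@hfaLower, h_over_H = li@hOverH)
    for (q in printed$quantity) {
      tab <- printed[[col]][printed$quantity == q]
      known <- FALSE; note <- ""
      if (q == "tfa") {
        known <- TRUE
        note <- "tabulated TFA irreconcilable with trans-isomer sum"
      } else if (q == "ti" && col == "female") {
        known <- TRUE
        note <- "tabulated 1.74 recomputes to 1.78 (input rounding)"
      } else if (q %in% c("sfa", "ufa_sfa") && col == "overall") {
        known <- TRUE
        note <- "overall stearic (9.86) inconsistent with sex means"
      } else if (q == "n6_n3") {
        known <- TRUE
        note <- "tabulated row is a per-sample mean of ratios (replicates unavailable)"
      }
      if (q %in% dialectCells) {
        known <- TRUE
        note <- "dialect-sensitive cell under conventional dialect"
      }
      add("lipid", q, col, tab, rec[[q]], lipidTol, known = known,
          note = note)
    }
  }

  ## ---- protein block -----------------------------------------------------
  evalTab <- aubracTable("protein_eval")
  pq <- evaluateProteinQuality(aubracProfile("amino_acid", "overall"),
                               aubracPooledProtein())
  for (g in essentialAaGroups()) {
    add("protein", paste0("basis.", g), "overall",
        evalTab$basis[evalTab$quantity == g],
        pq@basis[[g]], proteinTol, relative = TRUE)
  }
  add("protein", "total_eaa", "overall",
      evalTab$basis[evalTab$quantity == "EAA"], pq@totalEaa, proteinTol,
      relative = TRUE)
  for (s in c("children", "youth", "adults")) {
    for (g in essentialAaGroups())
      add("protein", paste0("cs.", g), s,
          evalTab[[s]][evalTab$quantity == g],
          pq@chemicalScores[g, s], proteinTol, relative = TRUE)
    add("protein", "eaai", s, evalTab[[s]][evalTab$quantity == "EAAI"],
        pq@eaai[[s]], proteinTol, relative = TRUE)
    add("protein", "bv", s, evalTab[[s]][evalTab$quantity == "BV"],
        pq@bv[[s]], proteinTol, relative = TRUE)
    add("protein", "ni", s, evalTab[[s]][evalTab$quantity == "NI"],
        pq@ni[[s]], proteinTol, relative = TRUE)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ok") <- all(out$pass | out$known_discrepancy)
  out
}
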