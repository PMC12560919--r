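## Protein quality scoring against reference amino-acid patterns:
## chemical score, essential amino acid index (Oser's geometric mean),
## biological value and nutritional index.

.pairedGroups <- list("Met+Cys" = c("Met", "Cys"), "Phe+Tyr" = c("Phe", "Tyr"))

.groupValues <- function(values) {
  # collapse single acids into the eight essential scoring groups; a
  # vector already keyed by a group name ("Met+Cys") passes through
  out <- numeric(0)
  for (g in essentialAaGroups()) {
    if (g %in% names(values)) {
      out[g] <- values[[g]]
      next
    }
    members <- if (g %in% names(.pairedGroups)) .pairedGroups[[g]] else g
    present <- intersect(members, names(values))
    out[g] <- if (length(present)) sum(values[present]) else NA_real_
  }
  out
}

#' Convert an amino-acid profile to protein basis
#'
#' Re-expresses g/100 g meat as g/100 g protein (equivalently g/16 g N):
#' each value is multiplied by 100 and divided by the protein percentage.
#' The conversion is linear, so forming the paired groups Met+Cys and
#' Phe+Tyr before or after converting gives the same result.
#'
#' @param profile an [AminoAcidProfile-class] with basis "per_100g_meat".
#' @param proteinPct percent protein of the matrix, in (0, 100].
#' @return A [ProteinBasisProfile-class].
#' @export
#' @examples
#' p <- aminoAcidProfile(c(Ile = 1.28))
#' analyteValues(toProteinBasis(p, 21.615))  # 5.92 g/100 g protein
toProteinBasis <- function(profile, proteinPct) {
  stopifnot(is(profile, "AminoAcidProfile"))
  if (!is.finite(proteinPct) || proteinPct <= 0)
    stop("proteinPct must be > 0")
  if (profile@basis != "per_100g_meat")
    stop("profile is already on basis ", profile@basis)
  new("ProteinBasisProfile",
      values = 100 * analyteValues(profile) / proteinPct,
      sourceProteinPct = proteinPct)
}

#' Chemical score against a reference pattern
#'
#' CS(group) = 100 x (content in the test protein) / (content in the
#' reference pattern), per essential amino-acid group, in percent. The
#' paired groups Met+Cys and Phe+Tyr are formed by summation.
#'
#' @param basis a [ProteinBasisProfile-class] (or named numeric already
#'   keyed by the eight groups, g/100 g protein).
#' @param pattern a [ReferencePattern-class].
#' @return Named numeric over [essentialAaGroups()], percent.
#' @export
#' @examples
#' b <- toProteinBasis(aubracProfile("amino_acid", "overall"),
#'                     aubracPooledProtein())
#' chemicalScore(b, faoWhoPattern("children"))[["Lys"]]  # 173.8
chemicalScore <- function(basis, pattern) {
  stopifnot(is(pattern, "ReferencePattern"))
  values <- if (is(basis, "ProteinBasisProfile")) analyteValues(basis)
            else basis
  g <- .groupValues(values)
  if (anyNA(g))
    stop("amino acid(s) absent from the profile: ",
         paste(names(g)[is.na(g)], collapse = ", "))
  100 * g / pattern@requirements[names(g)]
}

#' Essential amino acid index (EAAI)
#'
#' The geometric mean of the eight chemical scores (Oser's method),
#' computed in log space — exp(mean(log CS)) — so extreme scores (a
#' tryptophan CS above 2000 is realistic for meat against the adult
#' pattern) neither overflow nor lose precision.
#'
#' @param scores named numeric of chemical scores in percent, all > 0.
#' @return percent.
#' @export
#' @examples
#' eaai(c(a = 100, b = 400))  # 200
eaai <- function(scores) {
  if (any(!is.finite(scores) | scores <= 0))
    stop("geometric mean undefined: all chemical scores must be > 0")
  exp(mean(log(scores)))
}

#' Biological value (BV) from the EAAI
#'
#' BV = 1.09 x EAAI - 11.7, the linear regression of nitrogen-balance
#' biological value on the essential amino acid index. The line goes
#' negative below EAAI = 10.73; such values are returned as-is with a
#' warning since they signal a grossly deficient protein, not a
#' computational fault.
#'
#' @param eaaiPct EAAI in percent, >= 0.
#' @return percent.
#' @export
#' @examples
#' biologicalValue(160.25)  # 162.97
biologicalValue <- function(eaaiPct) {
  stopifnot(eaaiPct >= 0)
  bv <- 1.09 * eaaiPct - 11.7
  if (any(bv < 0))
    warning("EAAI below 10.73 gives a negative biological value",
            call. = FALSE)
  bv
}

#' Nutritional index (NI)
#'
#' NI(%) = EAAI x protein% / 100 — the EAAI scaled by how much protein
#' the food actually carries.
#'
#' @param eaaiPct EAAI in percent.
#' @param proteinPct percent protein, in (0, 100].
#' @return percent.
#' @export
#' @examples
#' nutritionalIndex(160.25, 21.615)  # 34.64
nutritionalIndex <- function(eaaiPct, proteinPct) {
  if (!is.finite(proteinPct) || proteinPct <= 0 || proteinPct > 100)
    stop("proteinPct must be in (0, 100]")
  eaaiPct * proteinPct / 100
}

#' Full protein quality evaluation
#'
#' Chains the whole pipeline: convert the fresh-meat amino-acid profile
#' to protein basis, score it against each reference pattern, and derive
#' EAAI, BV, NI and the limiting amino acid per standard. Also reports
#' the total essential amino acids in g/16 g N.
#'
#' @param profile an [AminoAcidProfile-class], basis "per_100g_meat".
#' @param proximate a [ProximateComposition-class], or directly the
#'   protein percentage as a single number.
#' @param patterns list of [ReferencePattern-class] (default: the three
#'   packaged FAO/WHO age-group patterns).
#' @return A [ProteinQualityResult-class].
#' @export
#' @examples
#' evaluateProteinQuality(aubracProfile("amino_acid", "overall"),
#'                        aubracPooledProtein())
evaluateProteinQuality <- function(profile, proximate,
                                   patterns = faoWhoPattern()) {
  proteinPct <- if (is(proximate, "ProximateComposition")) proximate@protein
                else as.numeric(proximate)
  basis <- toProteinBasis(profile, proteinPct)
  if (is(patterns, "ReferencePattern")) patterns <- list(patterns)
  nm <- vapply(patterns, function(p) p@standardName, character(1))
  names(patterns) <- nm
  cs <- vapply(patterns, function(p) chemicalScore(basis, p),
               numeric(length(essentialAaGroups())))
  rownames(cs) <- essentialAaGroups()
  eaaiV <- apply(cs, 2, eaai)
  groups <- .groupValues(analyteValues(basis))
  new("ProteinQualityResult",
      chemicalScores = cs,
      eaai = eaaiV,
      bv = biologicalValue(eaaiV),
      ni = vapply(eaaiV, nutritionalIndex, numeric(1),
                  proteinPct = proteinPct),
      limitingAa = apply(cs, 2, function(s) names(which.min(s))),
      basis = groups,
      totalEaa = sum(groups),
      proteinPct = proteinPct)
}
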