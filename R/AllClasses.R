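#' @import methods
#' @importFrom stats sd aov pnorm qnorm dnorm runif prcomp setNames
#' @importFrom utils read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Canonical analyte vocabularies
## ---------------------------------------------------------------------------

#' Canonical fatty-acid keys
#'
#' The sixteen fatty acids of the reference FAME panel, keyed by lipid
#' shorthand with geometry resolved ("C18:1 cis" is oleic, "C18:1 trans"
#' trans-vaccenic). Geometry-resolved keys are required because the lipid
#' health indices treat cis and trans isomers differently.
#'
#' @return Character vector of canonical fatty-acid names.
#' @export
#' @examples
#' canonicalFattyAcids()
canonicalFattyAcids <- function() {
  c("C10:0", "C12:0", "C14:0", "C14:1", "C15:0", "C16:0", "C16:1", "C17:0",
    "C18:0", "C18:1 cis", "C18:1 trans", "C18:2 cis", "C18:2 trans",
    "C18:3 cis n3", "C20:0", "C20:1")
}

#' Canonical amino-acid keys
#'
#' Three-letter codes for the nineteen amino acids of the hydrolysate panel.
#' "Cys" stands for cystine + cysteine as jointly quantified after acid
#' hydrolysis; "Trp" is total tryptophan from alkaline hydrolysis; "Hyp" is
#' hydroxyproline.
#'
#' @return Character vector of canonical amino-acid names.
#' @export
canonicalAminoAcids <- function() {
  c("Asp", "Glu", "Ala", "Arg", "Cys", "Phe", "Gly", "Hyp", "Ile", "His",
    "Leu", "Lys", "Met", "Pro", "Ser", "Tyr", "Thr", "Trp", "Val")
}

#' The eight essential amino-acid groups scored against reference patterns
#' @return Character vector of group names.
#' @export
essentialAaGroups <- function() {
  c("Ile", "Leu", "Lys", "Met+Cys", "Phe+Tyr", "Thr", "Trp", "Val")
}

# trivial-name / variant-spelling synonym map (lower-cased keys)
.fattyAcidSynonyms <- c(
  "capric"          = "C10:0",
  "lauric"          = "C12:0",
  "myristic"        = "C14:0",
  "myristoleic"     = "C14:1",
  "pentadecanoic"   = "C15:0",
  "palmitic"        = "C16:0",
  "palmitoleic"     = "C16:1",
  "margaric"        = "C17:0",
  "stearic"         = "C18:0",
  "oleic"           = "C18:1 cis",
  "c18:1"           = "C18:1 cis",
  "c18:1:cis"       = "C18:1 cis",
  "trans-vaccenic"  = "C18:1 trans",
  "vaccenic"        = "C18:1 trans",
  "c18:1:trans"     = "C18:1 trans",
  "linoleic"        = "C18:2 cis",
  "c18:2"           = "C18:2 cis",
  "c18:2:cis"       = "C18:2 cis",
  "c18:2:trans"     = "C18:2 trans",
  "alpha-linolenic" = "C18:3 cis n3",
  "linolenic"       = "C18:3 cis n3",
  "c18:3"           = "C18:3 cis n3",
  "c18:3:cis:n3"    = "C18:3 cis n3",
  "c18:3 cis"       = "C18:3 cis n3",
  "arachidic"       = "C20:0",
  "eicosenoic"      = "C20:1"
)

.aminoAcidSynonyms <- c(
  "aspartic acid"      = "Asp", "aspartate" = "Asp",
  "glutamic acid"      = "Glu", "glutamate" = "Glu",
  "alanine"            = "Ala",
  "arginine"           = "Arg",
  "cystine + cysteine" = "Cys", "cystine+cysteine" = "Cys", "cysteine" = "Cys",
  "cystine"            = "Cys",
  "phenylalanine"      = "Phe",
  "glycine"            = "Gly",
  "hydroxyproline"     = "Hyp",
  "isoleucine"         = "Ile",
  "histidine"          = "His",
  "leucine"            = "Leu",
  "lysine"             = "Lys",
  "methionine"         = "Met",
  "proline"            = "Pro",
  "serine"             = "Ser",
  "tyrosine"           = "Tyr",
  "threonine"          = "Thr",
  "tryptophan"         = "Trp", "tryptophan (total)" = "Trp",
  "valine"             = "Val"
)

#' Map analyte names onto the canonical vocabulary
#'
#' Case-insensitive lookup through the packaged synonym map ("Oleic" and
#' "C18:1" both resolve to "C18:1 cis"; "Tryptophan (total)" to "Trp").
#' Names already canonical pass through; unknown names are returned
#' unchanged so callers can decide whether to treat them as annotations.
#'
#' @param x character vector of analyte names.
#' @param type "fatty_acid" or "amino_acid".
#' @return Character vector of the same length with canonical names where
#'   recognised.
#' @export
canonicalizeAnalytes <- function(x, type = c("fatty_acid", "amino_acid")) {
  type <- match.arg(type)
  map <- if (type == "fatty_acid") .fattyAcidSynonyms else .aminoAcidSynonyms
  canon <- if (type == "fatty_acid") canonicalFattyAcids() else canonicalAminoAcids()
  out <- as.character(x)
  low <- tolower(trimws(out))
  hit <- match(low, tolower(canon))
  out[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  syn <- match(low, names(map))
  out[!is.na(syn)] <- unname(map[syn[!is.na(syn)]])
  out
}

## ---------------------------------------------------------------------------
## Composition classes
## ---------------------------------------------------------------------------

#' ProximateComposition
#'
#' Proximate composition of fresh muscle: water, dry matter, protein, fat
#' and minerals (ash), each in percent of fresh weight. Water and dry
#' matter must be complementary (sum 100 within 0.05), and the organic
#' plus mineral fractions may not exceed dry matter by more than 0.5
#' (both tolerances absorb two-decimal reporting rounding).
#'
#' @slot water numeric, percent.
#' @slot dryMatter numeric, percent.
#' @slot protein numeric, percent.
#' @slot fat numeric, percent.
#' @slot minerals numeric, percent.
#' @export
setClass("ProximateComposition",
  representation(water = "numeric", dryMatter = "numeric", protein = "numeric",
                 fat = "numeric", minerals = "numeric"))

setValidity("ProximateComposition", function(object) {
  v <- c(water = object@water, dry_matter = object@dryMatter,
         protein = object@protein, fat = object@fat,
         minerals = object@minerals)
  if (any(!is.finite(v))) return("all fields must be finite")
  if (any(v < 0 | v > 100))
    return(paste0("fields outside [0, 100]: ",
                  paste(names(v)[v < 0 | v > 100], collapse = ", ")))
  if (abs(object@water + object@dryMatter - 100) > 0.05)
    return(sprintf("water + dry matter = %.3f, not 100 (tolerance 0.05)",
                   object@water + object@dryMatter))
  if (object@protein + object@fat + object@minerals > object@dryMatter + 0.5)
    return(sprintf(
      "protein + fat + minerals = %.3f exceeds dry matter %.3f + 0.5",
      object@protein + object@fat + object@minerals, object@dryMatter))
  TRUE
})

#' Construct a ProximateComposition
#'
#' @param water,dryMatter,protein,fat,minerals percent of fresh muscle.
#'   `dryMatter` defaults to `100 - water`.
#' @return A validated [ProximateComposition-class] object.
#' @export
#' @examples
#' proximateComposition(water = 75, protein = 21.85, fat = 1.88,
#'                      minerals = 1.05)
proximateComposition <- function(water, protein, fat, minerals,
                                 dryMatter = 100 - water) {
  new("ProximateComposition", water = as.numeric(water),
      dryMatter = as.numeric(dryMatter), protein = as.numeric(protein),
      fat = as.numeric(fat), minerals = as.numeric(minerals))
}

#' FattyAcidProfile
#'
#' A fatty-acid profile: named vector of percentages of total identified
#' FAME, keyed by geometry-resolved shorthand (see [canonicalFattyAcids()]).
#' Profiles may be partial; `closed` records whether the vector was
#' renormalized to a fixed total.
#'
#' @slot values named numeric, percent of total identified FAME.
#' @slot closed logical, TRUE if renormalized to a fixed total.
#' @export
setClass("FattyAcidProfile",
  representation(values = "numeric", closed = "logical"))

setValidity("FattyAcidProfile", function(object) {
  v <- object@values
  if (is.null(names(v)) || any(!nzchar(names(v))))
    return("values must be a named vector")
  if (anyDuplicated(names(v))) return("duplicate fatty-acid names")
  if (any(v < 0))
    return(paste0("negative abundance for ",
                  paste(names(v)[v < 0], collapse = ", ")))
  if (sum(v) > 100 + 1.0)
    return(sprintf("FAME percentages sum to %.2f > 101", sum(v)))
  if (length(object@closed) != 1) return("closed must be length 1")
  TRUE
})

#' Construct a FattyAcidProfile
#'
#' Analyte names are canonicalized through the synonym map; unrecognised
#' names are kept verbatim (registered extensions).
#'
#' @param values named numeric vector, percent of total identified FAME.
#' @param closed logical; was the profile renormalized to a fixed total?
#' @return A validated [FattyAcidProfile-class] object.
#' @export
#' @examples
#' fattyAcidProfile(c(Oleic = 40, Palmitic = 25, "C18:0" = 20))
fattyAcidProfile <- function(values, closed = FALSE) {
  values <- unlist(values)
  names(values) <- canonicalizeAnalytes(names(values), "fatty_acid")
  new("FattyAcidProfile", values = values, closed = isTRUE(closed))
}

#' AminoAcidProfile
#'
#' Amino-acid profile in g/100 g meat (fresh basis) or g/100 g protein,
#' keyed by three-letter code (see [canonicalAminoAcids()]). On the
#' fresh-meat basis the total is sanity-bounded at 35 g/100 g.
#'
#' @slot values named numeric, grams per 100 g of the declared basis.
#' @slot basis "per_100g_meat" or "per_100g_protein".
#' @export
setClass("AminoAcidProfile",
  representation(values = "numeric", basis = "character"))

setValidity("AminoAcidProfile", function(object) {
  v <- object@values
  if (is.null(names(v)) || any(!nzchar(names(v))))
    return("values must be a named vector")
  if (anyDuplicated(names(v))) return("duplicate amino-acid names")
  if (any(v < 0))
    return(paste0("negative abundance for ",
                  paste(names(v)[v < 0], collapse = ", ")))
  if (!object@basis %in% c("per_100g_meat", "per_100g_protein"))
    return("basis must be per_100g_meat or per_100g_protein")
  if (object@basis == "per_100g_meat" && sum(v) > 35)
    return(sprintf("amino acids sum to %.2f g/100 g meat (> 35, implausible)",
                   sum(v)))
  TRUE
})

#' Construct an AminoAcidProfile
#'
#' @param values named numeric vector of amino-acid contents.
#' @param basis "per_100g_meat" (default) or "per_100g_protein".
#' @return A validated [AminoAcidProfile-class] object.
#' @export
aminoAcidProfile <- function(values, basis = "per_100g_meat") {
  values <- unlist(values)
  names(values) <- canonicalizeAnalytes(names(values), "amino_acid")
  new("AminoAcidProfile", values = values, basis = basis)
}

#' CohortTable
#'
#' A cohort of animal records: one row per animal (or per group-mean
#' pseudo-record), with mandatory `animal_id` and `sex` columns and
#' analyte columns named canonically. `schema` declares which composition
#' block(s) the analyte columns belong to.
#'
#' @slot data data.frame with columns `animal_id`, `sex`, analytes.
#' @slot schema one of "proximate", "fatty_acid", "amino_acid", "combined".
#' @slot provenance free-text source tag.
#' @export
setClass("CohortTable",
  representation(data = "data.frame", schema = "character",
                 provenance = "character"))

setValidity("CohortTable", function(object) {
  d <- object@data
  if (!all(c("animal_id", "sex") %in% names(d)))
    return("data must contain animal_id and sex columns")
  if (anyDuplicated(d$animal_id))
    return("animal_id must be unique within the table")
  if (nrow(d) > 0 && !all(d$sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  if (!object@schema %in% c("proximate", "fatty_acid", "amino_acid", "combined"))
    return("unknown schema")
  TRUE
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat(sprintf("CohortTable (%s): %d record(s) [%d male, %d female], %d analyte column(s)\n",
              object@schema, nrow(d), sum(d$sex == "male"),
              sum(d$sex == "female"),
              ncol(d) - 2L))
  if (nzchar(object@provenance))
    cat("provenance:", object@provenance, "\n")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' FattyAcidClassSummary
#'
#' Fatty-acid class sums and ratios, all in percent of total identified
#' FAME except the two dimensionless ratios. `ufa = mufa + pufa` by
#' construction.
#'
#' @slot sfa,mufa,pufa,ufa,tfa,n3,n6 numeric, percent.
#' @slot ufaSfaRatio,n6n3Ratio numeric, dimensionless (`Inf` when the
#'   denominator class is absent).
#' @slot dialect "as_published" or "conventional" (controls whether the
#'   n-6 class includes the trans C18:2 isomer).
#' @export
setClass("FattyAcidClassSummary",
  representation(sfa = "numeric", mufa = "numeric", pufa = "numeric",
                 ufa = "numeric", tfa = "numeric", n3 = "numeric",
                 n6 = "numeric", ufaSfaRatio = "numeric",
                 n6n3Ratio = "numeric", dialect = "character"))

setValidity("FattyAcidClassSummary", function(object) {
  cls <- c(object@sfa, object@mufa, object@pufa, object@ufa, object@tfa,
           object@n3, object@n6)
  if (any(cls < 0)) return("class sums must be non-negative")
  if (abs(object@ufa - (object@mufa + object@pufa)) > 1e-9)
    return("ufa must equal mufa + pufa")
  if (object@sfa > 0 &&
      abs(object@ufaSfaRatio - object@ufa / object@sfa) > 1e-9)
    return("ufaSfaRatio inconsistent with ufa/sfa")
  TRUE
})

setMethod("show", "FattyAcidClassSummary", function(object) {
  cat(sprintf("FattyAcidClassSummary (dialect: %s)\n", object@dialect))
  v <- c(SFA = object@sfa, MUFA = object@mufa, PUFA = object@pufa,
         UFA = object@ufa, TFA = object@tfa, n3 = object@n3, n6 = object@n6,
         "UFA/SFA" = object@ufaSfaRatio, "n6/n3" = object@n6n3Ratio)
  print(round(v, 3))
})

#' LipidQualityIndices
#'
#' The lipid health indices of a fatty-acid profile: atherogenic index
#' (AI), thrombogenic index (TI), the hypercholesterolemic (HFA) and
#' hypocholesterolemic (hFA) acid sums and their ratio h/H.
#'
#' @slot ai,ti,hOverH numeric, dimensionless.
#' @slot hfaUpper numeric, percent — hypercholesterolemic acids
#'   C12:0 + C14:0 + C16:0.
#' @slot hfaLower numeric, percent — hypocholesterolemic acids: a C18:1
#'   isomer (dialect-dependent) plus PUFA.
#' @slot dialect "as_published" or "conventional".
#' @export
setClass("LipidQualityIndices",
  representation(ai = "numeric", ti = "numeric", hfaUpper = "numeric",
                 hfaLower = "numeric", hOverH = "numeric",
                 dialect = "character"))

setValidity("LipidQualityIndices", function(object) {
  if (any(c(object@ai, object@ti, object@hfaUpper, object@hfaLower) < 0))
    return("indices must be non-negative")
  if (object@hfaUpper > 0 &&
      abs(object@hOverH - object@hfaLower / object@hfaUpper) > 1e-9)
    return("hOverH inconsistent with hFA/HFA")
  TRUE
})

setMethod("show", "LipidQualityIndices", function(object) {
  cat(sprintf("LipidQualityIndices (dialect: %s)\n", object@dialect))
  print(round(c(AI = object@ai, TI = object@ti, HFA = object@hfaUpper,
                hFA = object@hfaLower, "h/H" = object@hOverH), 3))
})

#' ReferencePattern
#'
#' A reference protein requirement pattern: g of each essential amino-acid
#' group per 100 g protein, for one consumer category (FAO/WHO children,
#' youth or adults, or a custom pattern such as whole egg).
#'
#' @slot standardName pattern label.
#' @slot requirements named numeric over the eight groups of
#'   [essentialAaGroups()], g/100 g protein.
#' @slot totalEaa numeric, sum of the requirements.
#' @export
setClass("ReferencePattern",
  representation(standardName = "character", requirements = "numeric",
                 totalEaa = "numeric"))

setValidity("ReferencePattern", function(object) {
  req <- object@requirements
  if (!setequal(names(req), essentialAaGroups()))
    return(paste0("requirements must be keyed by exactly: ",
                  paste(essentialAaGroups(), collapse = ", ")))
  if (any(req <= 0)) return("every requirement must be > 0")
  if (abs(object@totalEaa - sum(req)) > 0.1)
    return("totalEaa must equal the sum of requirements (tolerance 0.1)")
  TRUE
})

#' Construct a custom ReferencePattern
#'
#' @param requirements named numeric over [essentialAaGroups()], in
#'   g/100 g protein.
#' @param standardName label, default "custom".
#' @return A validated [ReferencePattern-class].
#' @export
referencePattern <- function(requirements, standardName = "custom") {
  req <- unlist(requirements)[essentialAaGroups()]
  names(req) <- essentialAaGroups()
  new("ReferencePattern", standardName = standardName, requirements = req,
      totalEaa = sum(req))
}

#' ProteinBasisProfile
#'
#' Amino-acid contents re-expressed per 100 g protein (equivalently
#' g/16 g N under the 6.25 nitrogen-to-protein factor), together with the
#' protein percentage used for the conversion.
#'
#' @slot values named numeric, g/100 g protein.
#' @slot sourceProteinPct percent protein of the source matrix, in (0, 100].
#' @export
setClass("ProteinBasisProfile",
  representation(values = "numeric", sourceProteinPct = "numeric"))

setValidity("ProteinBasisProfile", function(object) {
  if (any(object@values < 0)) return("values must be non-negative")
  if (is.null(names(object@values))) return("values must be named")
  p <- object@sourceProteinPct
  if (!is.finite(p) || p <= 0 || p > 100)
    return("sourceProteinPct must be in (0, 100]")
  TRUE
})

#' ProteinQualityResult
#'
#' End-to-end protein quality evaluation: chemical scores per essential
#' group and standard, EAAI/BV/NI per standard, the limiting amino acid,
#' and the protein-basis profile the scores were computed from.
#'
#' @slot chemicalScores matrix (group x standard), percent.
#' @slot eaai,bv,ni named numeric per standard, percent.
#' @slot limitingAa named character per standard.
#' @slot basis named numeric, g/100 g protein for each essential group.
#' @slot totalEaa numeric, g/16 g N.
#' @slot proteinPct numeric, protein percentage used for conversion.
#' @export
setClass("ProteinQualityResult",
  representation(chemicalScores = "matrix", eaai = "numeric", bv = "numeric",
                 ni = "numeric", limitingAa = "character", basis = "numeric",
                 totalEaa = "numeric", proteinPct = "numeric"))

setValidity("ProteinQualityResult", function(object) {
  cs <- object@chemicalScores
  for (s in colnames(cs)) {
    if (object@eaai[[s]] < min(cs[, s]) - 1e-9 ||
        object@eaai[[s]] > max(cs[, s]) + 1e-9)
      return("eaai must lie between the min and max chemical score")
    if (abs(object@bv[[s]] - (1.09 * object@eaai[[s]] - 11.7)) > 1e-9)
      return("bv must equal 1.09*eaai - 11.7")
    if (object@limitingAa[[s]] != rownames(cs)[which.min(cs[, s])])
      return("limitingAa must be the minimal chemical score group")
  }
  TRUE
})

setMethod("show", "ProteinQualityResult", function(object) {
  cat(sprintf("ProteinQualityResult (protein %.3f%%, total EAA %.2f g/16 g N)\n",
              object@proteinPct, object@totalEaa))
  tab <- rbind(round(object@chemicalScores, 2),
               `EAAI (%)` = round(object@eaai, 2),
               BV = round(object@bv, 2),
               `NI (%)` = round(object@ni, 2))
  print(tab)
  cat("limiting amino acid:",
      paste(sprintf("%s=%s", names(object@limitingAa), object@limitingAa),
            collapse = ", "), "\n")
})

#' PcaResult
#'
#' Principal component analysis of cohort analytes: per-record scores,
#' orthonormal loadings, and percent variance explained per component.
#'
#' @slot scores matrix, records x components.
#' @slot loadings matrix, variables x components.
#' @slot varianceExplained numeric, percent per component (sums to 100).
#' @export
setClass("PcaResult",
  representation(scores = "matrix", loadings = "matrix",
                 varianceExplained = "numeric"))

setValidity("PcaResult", function(object) {
  ve <- object@varianceExplained
  if (any(ve < -1e-9 | ve > 100 + 1e-9))
    return("varianceExplained must be in [0, 100]")
  if (abs(sum(ve) - 100) > 1e-6)
    return("varianceExplained must sum to 100")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-9)
    return("loadings columns must be orthonormal")
  TRUE
})

#' CohortScenario
#'
#' Parameters for the synthetic cohort generator: per-analyte, per-sex
#' truncated-normal models, group sizes, an optional closure total for
#' compositional vectors, and a seed.
#'
#' @slot nMale,nFemale integer group sizes.
#' @slot models data.frame with columns `analyte`, `sex`, `mean`, `sd`,
#'   `lower` (truncation bound, default 0).
#' @slot closureTotal numeric; `NA` disables closure.
#' @slot schema composition block the analytes belong to.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortScenario",
  representation(nMale = "integer", nFemale = "integer",
                 models = "data.frame", closureTotal = "numeric",
                 schema = "character", seed = "integer"))

setValidity("CohortScenario", function(object) {
  m <- object@models
  need <- c("analyte", "sex", "mean", "sd", "lower")
  if (!all(need %in% names(m)))
    return(paste0("models must have columns ", paste(need, collapse = ", ")))
  if (object@nMale + object@nFemale < 1)
    return("nMale + nFemale must be >= 1")
  if (anyDuplicated(m[, c("analyte", "sex")]))
    return("every (analyte, sex) pair must have exactly one model")
  if (any(m$sd < 0)) return("sd must be >= 0")
  if (any(m$mean < m$lower)) return("mean must be >= lower bound")
  TRUE
})

setMethod("show", "CohortScenario", function(object) {
  cat(sprintf("CohortScenario (%s): %d male + %d female, %d analyte(s), seed %d\n",
              object@schema, object@nMale, object@nFemale,
              length(unique(object@models$analyte)), object@seed))
  if (!is.na(object@closureTotal))
    cat(sprintf("closure to %.1f%%\n", object@closureTotal))
})
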