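## Packaged reference dataset: sex-stratified composition tables of
## Longissimus dorsi muscle from Aubrac cattle reared semi-intensively
## (27 males, 22 females). Input rows (measured analytes) are kept
## separate from the tabulated derived rows (class sums and indices) so
## the latter can be recomputed and compared.

#' Packaged Aubrac reference tables
#'
#' Loads one of the packaged composition tables: proximate composition,
#' fatty-acid profile (% of total FAME), amino-acid profile (g/100 g
#' meat), the tabulated derived lipid quantities, the FAO/WHO reference
#' patterns, or the tabulated protein-quality evaluation block.
#'
#' @param name one of "proximate", "fatty_acid", "amino_acid",
#'   "fatty_acid_indices", "patterns", "protein_eval".
#' @return data.frame transcribing the table.
#' @export
#' @examples
#' head(aubracTable("fatty_acid"))
aubracTable <- function(name = c("proximate", "fatty_acid", "amino_acid",
                                 "fatty_acid_indices", "patterns",
                                 "protein_eval")) {
  name <- match.arg(name)
  file <- switch(name,
    proximate          = "aubrac_proximate.csv",
    fatty_acid         = "aubrac_fatty_acids.csv",
    amino_acid         = "aubrac_amino_acids.csv",
    fatty_acid_indices = "aubrac_fatty_acid_indices.csv",
    patterns           = "fao_who_patterns.csv",
    protein_eval       = "aubrac_protein_eval.csv")
  path <- system.file("extdata", file, package = "nutriscore",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Group-mean profile from the packaged reference tables
#'
#' Builds a [FattyAcidProfile-class] or [AminoAcidProfile-class] from the
#' mean column of one sex group (or the overall column) of the packaged
#' tables.
#'
#' @param schema "fatty_acid" or "amino_acid".
#' @param group "male", "female" or "overall".
#' @return A profile object.
#' @export
#' @examples
#' aubracProfile("fatty_acid", "male")
aubracProfile <- function(schema = c("fatty_acid", "amino_acid"),
                          group = c("overall", "male", "female")) {
  schema <- match.arg(schema)
  group <- match.arg(group)
  tab <- aubracTable(schema)
  vals <- setNames(tab[[paste0(group, "_mean")]], tab[[1]])
  if (schema == "fatty_acid") fattyAcidProfile(vals) else aminoAcidProfile(vals)
}

#' Proximate composition of one sex group of the reference dataset
#'
#' @param group "male" or "female".
#' @return A [ProximateComposition-class].
#' @export
aubracProximate <- function(group = c("male", "female")) {
  group <- match.arg(group)
  tab <- aubracTable("proximate")
  v <- setNames(tab[[paste0(group, "_mean")]], tab$component)
  proximateComposition(water = v[["water"]], dryMatter = v[["dry_matter"]],
                       protein = v[["protein"]], fat = v[["fat"]],
                       minerals = v[["minerals"]])
}

#' Sex-pooled protein percentage of the reference dataset
#'
#' The protein percentage used for the sex-pooled protein-basis
#' conversion: by default the unweighted mean of the male and female
#' protein percentages, which is the convention the reference evaluation
#' table follows. A sample-size-weighted mean (27 males, 22 females) is
#' available by flag.
#'
#' @param weighted if TRUE, weight by group sizes 27/22.
#' @return percent protein.
#' @export
aubracPooledProtein <- function(weighted = FALSE) {
  tab <- aubracTable("proximate")
  p <- setNames(tab$male_mean, tab$component)[["protein"]]
  q <- setNames(tab$female_mean, tab$component)[["protein"]]
  if (weighted) (27 * p + 22 * q) / 49 else (p + q) / 2
}

#' Packaged FAO/WHO reference patterns
#'
#' The three age-group requirement patterns (children, youth, adults), in
#' g of each essential amino-acid group per 100 g protein.
#'
#' @param standard "children", "youth" or "adults"; if NULL, a named list
#'   of all three.
#' @return A [ReferencePattern-class] or list of them.
#' @export
#' @examples
#' faoWhoPattern("children")
faoWhoPattern <- function(standard = NULL) {
  tab <- aubracTable("patterns")
  build <- function(s) {
    referencePattern(setNames(tab[[s]], tab$group), standardName = s)
  }
  if (is.null(standard))
    return(setNames(lapply(c("children", "youth", "adults"), build),
                    c("children", "youth", "adults")))
  standard <- match.arg(standard, c("children", "youth", "adults"))
  build(standard)
}

#' Group-mean pseudo-record cohort from the packaged tables
#'
#' Wraps the male and female mean columns of a packaged table as a
#' two-record [CohortTable-class] (provenance "group_mean"), so tabulated
#' group means flow through the same pipeline as per-animal data.
#'
#' @param schema "fatty_acid", "amino_acid" or "proximate".
#' @return A [CohortTable-class] with 2 records.
#' @export
aubracCohort <- function(schema = c("fatty_acid", "amino_acid", "proximate")) {
  schema <- match.arg(schema)
  tab <- aubracTable(schema)
  analytes <- tab[[1]]
  d <- data.frame(animal_id = c("aubrac_male_mean", "aubrac_female_mean"),
                  sex = c("male", "female"), stringsAsFactors = FALSE)
  m <- rbind(tab$male_mean, tab$female_mean)
  colnames(m) <- analytes
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  new("CohortTable", data = d, schema = schema, provenance = "group_mean")
}
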