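#' Extract analyte values from a profile object
#'
#' @param x a [FattyAcidProfile-class], [AminoAcidProfile-class] or
#'   [ProteinBasisProfile-class].
#' @return Named numeric vector.
#' @export
setGeneric("analyteValues", function(x) standardGeneric("analyteValues"))

#' @rdname analyteValues
setMethod("analyteValues", "FattyAcidProfile", function(x) x@values)
#' @rdname analyteValues
setMethod("analyteValues", "AminoAcidProfile", function(x) x@values)
#' @rdname analyteValues
setMethod("analyteValues", "ProteinBasisProfile", function(x) x@values)

#' Underlying data.frame of a cohort
#' @param x a [CohortTable-class].
#' @return data.frame, one row per record.
#' @export
cohortData <- function(x) x@data

#' Schema of a cohort table
#' @param x a [CohortTable-class].
#' @return character scalar.
#' @export
cohortSchema <- function(x) x@schema

#' Number of records in a cohort
#' @param x a [CohortTable-class].
#' @export
setMethod("length", "CohortTable", function(x) nrow(x@data))

#' Extract one record's composition profile from a cohort
#'
#' Pulls the analyte columns of a single record and wraps them in the
#' profile class matching the cohort schema. `NA` analytes are dropped
#' (partial panels).
#'
#' @param cohort a [CohortTable-class] with schema "fatty_acid" or
#'   "amino_acid".
#' @param id `animal_id` of the record (or a row index).
#' @return A [FattyAcidProfile-class] or [AminoAcidProfile-class].
#' @export
recordProfile <- function(cohort, id) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohortData(cohort)
  i <- if (is.numeric(id)) id else match(id, d$animal_id)
  if (is.na(i) || i < 1 || i > nrow(d))
    stop("no record with animal_id ", id)
  vals <- unlist(d[i, setdiff(names(d), c("animal_id", "sex")), drop = FALSE])
  vals <- vals[!is.na(vals)]
  switch(cohortSchema(cohort),
    fatty_acid = fattyAcidProfile(vals),
    amino_acid = aminoAcidProfile(vals),
    stop("recordProfile needs a fatty_acid or amino_acid cohort, got ",
         cohortSchema(cohort)))
}

#' Group-mean composition profile of a cohort
#'
#' Averages each analyte over the records of one sex (or all records),
#' returning a profile object on which the index functions can run.
#'
#' @param cohort a [CohortTable-class], schema "fatty_acid" or "amino_acid".
#' @param group "male", "female" or "overall".
#' @return A profile object matching the schema.
#' @export
meanProfile <- function(cohort, group = c("overall", "male", "female")) {
  group <- match.arg(group)
  d <- cohortData(cohort)
  if (group != "overall") d <- d[d$sex == group, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for group '", group, "'")
  vals <- colMeans(d[, setdiff(names(d), c("animal_id", "sex")),
                     drop = FALSE], na.rm = TRUE)
  switch(cohortSchema(cohort),
    fatty_acid = fattyAcidProfile(vals),
    amino_acid = aminoAcidProfile(vals),
    stop("meanProfile needs a fatty_acid or amino_acid cohort"))
}
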