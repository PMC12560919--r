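## Reading, validating and writing cohort composition tables.

.schemaCanonical <- function(schema) {
  switch(schema,
    fatty_acid = canonicalFattyAcids(),
    amino_acid = canonicalAminoAcids(),
    proximate  = c("water", "dry_matter", "protein", "fat", "minerals"),
    combined   = c(canonicalFattyAcids(), canonicalAminoAcids(),
                   "water", "dry_matter", "protein", "fat", "minerals"))
}

.canonicalizeHeader <- function(nm, schema) {
  if (schema %in% c("fatty_acid", "combined"))
    nm <- canonicalizeAnalytes(nm, "fatty_acid")
  if (schema %in% c("amino_acid", "combined"))
    nm <- canonicalizeAnalytes(nm, "amino_acid")
  if (schema %in% c("proximate", "combined")) {
    low <- gsub("[ .]", "_", tolower(nm))
    prox <- c("water", "dry_matter", "protein", "fat", "minerals",
              "total_fat", "ash")
    hit <- match(low, prox)
    fix <- c("water", "dry_matter", "protein", "fat", "minerals",
             "fat", "minerals")
    nm[!is.na(hit)] <- fix[hit[!is.na(hit)]]
  }
  nm
}

#' Read a cohort composition table
#'
#' Reads a CSV/TSV file with one row per animal (or group-mean
#' pseudo-record), required columns `animal_id` and `sex`, and analyte
#' columns named by canonical name or any registered synonym
#' (case-insensitive). Unknown columns are preserved as annotations.
#' Every embedded type invariant is checked: negative analyte values and
#' a missing sex column are hard errors naming the offending row/column;
#' a FAME row summing above 101 fails validation listing the row.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".tsv"/".txt" for tab, comma otherwise).
#' @param schema "proximate", "fatty_acid", "amino_acid" or "combined".
#' @param provenance free-text source tag stored on the table.
#' @return A validated [CohortTable-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(animal_id = "a1", sex = "male",
#'                      Oleic = 40, Palmitic = 25, check.names = FALSE),
#'           f, row.names = FALSE)
#' readCohort(f, "fatty_acid")
readCohort <- function(path,
                       schema = c("fatty_acid", "amino_acid", "proximate",
                                  "combined"),
                       provenance = path) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.csv(path, sep = sep, check.names = FALSE,
                stringsAsFactors = FALSE)
  names(d) <- .canonicalizeHeader(names(d), schema)
  if (!"sex" %in% names(d))
    stop("missing mandatory 'sex' column (analysis is sex-stratified)")
  if (!"animal_id" %in% names(d))
    stop("missing mandatory 'animal_id' column")
  d$animal_id <- as.character(d$animal_id)
  d$sex <- tolower(as.character(d$sex))

  analytes <- intersect(names(d), .schemaCanonical(schema))
  if (nrow(d) > 0 && length(analytes) == 0)
    stop("no recognised analyte columns for schema '", schema, "'")
  for (a in analytes) {
    d[[a]] <- as.numeric(d[[a]])
    bad <- which(!is.na(d[[a]]) & d[[a]] < 0)
    if (length(bad))
      stop(sprintf("negative value for '%s' in row %d (animal_id %s)",
                   a, bad[1], d$animal_id[bad[1]]))
  }
  if (schema == "fatty_acid" && nrow(d) > 0) {
    fam <- rowSums(d[, analytes, drop = FALSE], na.rm = TRUE)
    bad <- which(fam > 101)
    if (length(bad))
      stop(sprintf(
        "FAME percentages sum to %.2f > 101 in row(s): %s",
        max(fam[bad]), paste(d$animal_id[bad], collapse = ", ")))
  }
  if (schema == "amino_acid" && nrow(d) > 0) {
    tot <- rowSums(d[, analytes, drop = FALSE], na.rm = TRUE)
    bad <- which(tot > 35)
    if (length(bad))
      stop(sprintf(
        "amino acids sum above the 35 g/100 g sanity bound in row(s): %s",
        paste(d$animal_id[bad], collapse = ", ")))
  }
  if (schema %in% c("proximate", "combined") &&
      all(c("water", "dry_matter") %in% names(d)) && nrow(d) > 0) {
    off <- which(abs(d$water + d$dry_matter - 100) > 0.05)
    if (length(off))
      stop(sprintf(
        "water + dry matter differs from 100 beyond 0.05 in row(s): %s",
        paste(d$animal_id[off], collapse = ", ")))
  }
  # unknown columns ride along as annotations
  new("CohortTable", data = d, schema = schema,
      provenance = as.character(provenance))
}

.asReportList <- function(x) {
  if (is(x, "LipidQualityIndices"))
    return(list(AI = x@ai, TI = x@ti, HFA = x@hfaUpper, hFA = x@hfaLower,
                h_over_H = x@hOverH, dialect = x@dialect))
  if (is(x, "FattyAcidClassSummary"))
    return(list(SFA = x@sfa, MUFA = x@mufa, PUFA = x@pufa, UFA = x@ufa,
                TFA = x@tfa, n3 = x@n3, n6 = x@n6,
                UFA_SFA = x@ufaSfaRatio, n6_n3 = x@n6n3Ratio,
                dialect = x@dialect))
  if (is(x, "ProteinQualityResult")) {
    cs <- x@chemicalScores
    return(list(
      chemical_scores = lapply(setNames(colnames(cs), colnames(cs)),
                               function(s) as.list(cs[, s])),
      eaai = as.list(x@eaai), bv = as.list(x@bv), ni = as.list(x@ni),
      limiting_aa = as.list(x@limitingAa), basis = as.list(x@basis),
      total_eaa = x@totalEaa, protein_pct = x@proteinPct))
  }
  if (is(x, "CohortTable"))
    return(list(schema = x@schema, provenance = x@provenance,
                records = x@data))
  if (is(x, "ProteinBasisProfile"))
    return(list(values = as.list(x@values),
                source_protein_pct = x@sourceProteinPct))
  if (is(x, "FattyAcidProfile") || is(x, "AminoAcidProfile"))
    return(as.list(analyteValues(x)))
  if (is.data.frame(x) || is.list(x)) return(x)
  as.list(x)
}

#' Write a result object to CSV or JSON
#'
#' Serialises any finished result (indices, class summaries, protein
#' quality results, cohort tables, plain data.frames) to disk. The
#' round trip is lossless to the numeric precision of the format: JSON is
#' written with full `digits = NA` precision, CSV with 15 significant
#' digits, so re-reading reproduces every numeric field to at least 6
#' significant digits.
#'
#' @param x result object.
#' @param path output file path.
#' @param format "csv" or "json"; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
writeReport <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "json") {
    jsonlite::write_json(.asReportList(x), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", na = "null")
  } else {
    d <- if (is(x, "CohortTable")) cohortData(x)
         else if (is.data.frame(x)) x
         else {
           l <- .asReportList(x)
           flat <- unlist(l)
           data.frame(field = names(flat), value = as.character(
             vapply(flat, function(v)
               if (is.numeric(v)) format(v, digits = 15) else as.character(v),
               character(1))), stringsAsFactors = FALSE)
         }
    if (is.data.frame(d) && any(vapply(d, is.numeric, logical(1)))) {
      num <- vapply(d, is.numeric, logical(1))
      d[num] <- lapply(d[num], function(v) format(v, digits = 15, trim = TRUE))
    }
    write.csv(d, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path path written by [writeReport()] with `format = "json"`.
#' @return The parsed list.
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
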