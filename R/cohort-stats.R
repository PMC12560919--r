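## Sex-stratified descriptive statistics, two-group significance coding,
## amino-acid category aggregation and PCA.

#' Significance code for a p-value
#'
#' Coding convention: `***` p <= 0.001, `**` 0.001 < p <= 0.01,
#' `*` 0.01 < p <= 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significanceCode <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
    ifelse(p <= 0.05, "*", "ns")))
}

#' Sex-stratified descriptive statistics
#'
#' Per-sex and overall mean, SD (n - 1 denominator) and n for each
#' requested analyte column. A single-record group gets SD 0 with a
#' warning.
#'
#' @param cohort a [CohortTable-class].
#' @param variables analyte column names; default all analyte columns.
#' @return data.frame with columns `variable`, `group`, `mean`, `sd`, `n`.
#' @export
describeCohort <- function(cohort, variables = NULL) {
  d <- cohortData(cohort)
  analytes <- setdiff(names(d), c("animal_id", "sex"))
  if (is.null(variables)) variables <- analytes
  unknown <- setdiff(variables, analytes)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  groups <- list(male = d$sex == "male", female = d$sex == "female",
                 overall = rep(TRUE, nrow(d)))
  out <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(names(groups), function(g) {
      x <- d[[v]][groups[[g]]]
      x <- x[!is.na(x)]
      if (!length(x)) return(NULL)
      s <- if (length(x) == 1) {
        warning("single record in group '", g, "': SD reported as 0",
                call. = FALSE)
        0
      } else sd(x)
      data.frame(variable = v, group = g, mean = mean(x), sd = s,
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Two-group sex comparison
#'
#' One-way two-group ANOVA (equal variances) of one analyte between
#' males and females — numerically identical to the pooled two-sample
#' t-test (F = t squared). Welch's unequal-variance test is available by
#' flag.
#'
#' @param cohort a [CohortTable-class] with >= 2 records per sex.
#' @param variable analyte column name.
#' @param welch use Welch's t-test instead of equal-variance ANOVA.
#' @return data.frame with `variable`, `p_value`, `code`.
#' @export
compareSexes <- function(cohort, variable, welch = FALSE) {
  d <- cohortData(cohort)
  if (!variable %in% names(d)) stop("unknown variable: ", variable)
  d <- d[!is.na(d[[variable]]), , drop = FALSE]
  n <- table(factor(d$sex, levels = c("male", "female")))
  if (any(n < 2))
    stop("need >= 2 records per sex, got ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  p <- if (welch) {
    stats::t.test(d[[variable]] ~ d$sex)$p.value
  } else {
    fit <- aov(d[[variable]] ~ factor(d$sex))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }
  data.frame(variable = variable, p_value = p, code = significanceCode(p),
             stringsAsFactors = FALSE)
}

#' Default amino-acid category scheme
#'
#' Membership convention for the analysis categories: essential (eAA,
#' including histidine as semi-essential), flavour/umami-related (fAA:
#' aspartate and glutamate), sweetness-related (sAA) and aromatic /
#' fragrance-related (frAA). Categories may overlap. This is a stated
#' convention of the package, overridable by passing any other named
#' list of member vectors.
#'
#' @return Named list of character vectors of [canonicalAminoAcids()].
#' @export
defaultCategoryScheme <- function() {
  list(
    eAA  = c("Ile", "Leu", "Lys", "Met", "Phe", "Thr", "Trp", "Val", "His"),
    fAA  = c("Asp", "Glu"),
    sAA  = c("Gly", "Ala", "Ser", "Thr", "Pro"),
    frAA = c("Phe", "Tyr", "Trp")
  )
}

#' Aggregate an amino-acid profile into analysis categories
#'
#' Sums member amino acids per category and adds `TotalAA`, the sum over
#' the full panel. Members absent from the profile contribute 0; an empty
#' category sums to 0.
#'
#' @param profile an [AminoAcidProfile-class].
#' @param scheme named list of member vectors
#'   (default [defaultCategoryScheme()]).
#' @return Named numeric, same units as the profile.
#' @export
#' @examples
#' aggregateCategories(aubracProfile("amino_acid", "male"))[["TotalAA"]]
aggregateCategories <- function(profile, scheme = defaultCategoryScheme()) {
  stopifnot(is(profile, "AminoAcidProfile"))
  v <- analyteValues(profile)
  bad <- setdiff(unlist(scheme), canonicalAminoAcids())
  if (length(bad))
    stop("scheme member(s) not in the amino-acid panel: ",
         paste(bad, collapse = ", "))
  out <- vapply(scheme, function(members)
    sum(v[intersect(members, names(v))]), numeric(1))
  c(out, TotalAA = sum(v))
}

#' Principal component analysis of cohort analytes
#'
#' Eigendecomposition of the correlation matrix (`standardize = TRUE`,
#' the default) or covariance matrix of the selected analyte columns.
#' Scores are centred; the sign convention fixes each loading column so
#' its largest-magnitude entry is positive. PCA on fewer than 3 records
#' is refused: component structure from 2 points is meaningless.
#'
#' @param cohort a [CohortTable-class], >= 3 records.
#' @param variables analyte columns (>= 2); default all.
#' @param standardize scale variables to unit variance (correlation PCA).
#' @return A [PcaResult-class].
#' @export
cohortPca <- function(cohort, variables = NULL, standardize = TRUE) {
  d <- cohortData(cohort)
  analytes <- setdiff(names(d), c("animal_id", "sex"))
  if (is.null(variables)) variables <- analytes
  unknown <- setdiff(variables, analytes)
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if (length(variables) < 2) stop("PCA needs >= 2 variables")
  X <- as.matrix(d[, variables, drop = FALSE])
  if (nrow(X) < 3)
    stop("PCA needs >= 3 records; component structure from ", nrow(X),
         " point(s) is meaningless")
  if (anyNA(X)) stop("PCA input contains missing values")
  if (standardize) {
    const <- variables[apply(X, 2, sd) == 0]
    if (length(const))
      stop("constant variable(s) cannot be standardized: ",
           paste(const, collapse = ", "))
  }
  fit <- prcomp(X, center = TRUE, scale. = standardize)
  load <- fit$rotation
  scores <- fit$x
  flip <- apply(load, 2, function(col) sign(col[which.max(abs(col))]))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  rownames(scores) <- d$animal_id
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  names(ve) <- colnames(load)
  new("PcaResult", scores = scores, loadings = load,
      varianceExplained = ve)
}
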