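## Fatty-acid class sums and lipid health indices.
##
## Two dialects are exposed. "as_published" reproduces the reference
## dataset's tabulated rows exactly: its n-6 class includes the trans
## C18:2 isomer and its hypocholesterolemic sum uses trans-vaccenic as
## the C18:1 term. "conventional" follows the usual literature reading:
## cis isomers only. With no trans acids in the profile the two dialects
## coincide.

.faGet <- function(profile, acids, warnMissing = TRUE) {
  v <- analyteValues(profile)
  missing <- setdiff(acids, names(v))
  if (length(missing) && warnMissing)
    warning("missing fatty acid(s) treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  sum(v[intersect(acids, names(v))])
}

.SFA_ACIDS <- c("C10:0", "C12:0", "C14:0", "C15:0", "C16:0", "C17:0",
                "C18:0", "C20:0")
.MUFA_ACIDS <- c("C14:1", "C16:1", "C18:1 cis", "C20:1")  # cis-only C18:1
.PUFA_ACIDS <- c("C18:2 cis", "C18:3 cis n3")
.TFA_ACIDS <- c("C18:1 trans", "C18:2 trans")

#' Fatty-acid class sums and ratios
#'
#' Sums a FAME profile into the standard classes:
#' SFA = C10:0 + C12:0 + C14:0 + C15:0 + C16:0 + C17:0 + C18:0 + C20:0;
#' MUFA = C14:1 + C16:1 + C18:1 cis + C20:1 (the C18:1 term is oleic
#' only — trans-vaccenic is not a MUFA here); PUFA = C18:2 cis +
#' C18:3 cis n3; UFA = MUFA + PUFA; TFA = C18:1 trans + C18:2 trans;
#' n-3 = C18:3 cis n3; n-6 = C18:2 cis (+ C18:2 trans under
#' `as_published`). Acids absent from the profile contribute 0 with a
#' warning, so partial panels remain scoreable.
#'
#' @param profile a [FattyAcidProfile-class].
#' @param dialect "as_published" (default) or "conventional".
#' @param warnMissing warn when a class member is absent from the profile.
#' @return A [FattyAcidClassSummary-class]. When SFA = 0 the UFA/SFA
#'   ratio is the `Inf` sentinel (with a warning); likewise n6/n3 when
#'   n3 = 0.
#' @export
#' @examples
#' sumFattyAcidClasses(aubracProfile("fatty_acid", "male"))
sumFattyAcidClasses <- function(profile,
                                dialect = c("as_published", "conventional"),
                                warnMissing = TRUE) {
  stopifnot(is(profile, "FattyAcidProfile"))
  dialect <- match.arg(dialect)
  sfa <- .faGet(profile, .SFA_ACIDS, warnMissing)
  mufa <- .faGet(profile, .MUFA_ACIDS, warnMissing)
  pufa <- .faGet(profile, .PUFA_ACIDS, warnMissing)
  tfa <- .faGet(profile, .TFA_ACIDS, warnMissing)
  n3 <- .faGet(profile, "C18:3 cis n3", warnMissing = FALSE)
  n6 <- .faGet(profile, "C18:2 cis", warnMissing = FALSE)
  if (dialect == "as_published")
    n6 <- n6 + .faGet(profile, "C18:2 trans", warnMissing = FALSE)
  ufa <- mufa + pufa
  if (sfa > 0) {
    ufaSfa <- ufa / sfa
  } else {
    warning("SFA = 0: UFA/SFA reported as +Inf", call. = FALSE)
    ufaSfa <- Inf
  }
  n6n3 <- if (n3 > 0) n6 / n3 else Inf
  new("FattyAcidClassSummary", sfa = sfa, mufa = mufa, pufa = pufa,
      ufa = ufa, tfa = tfa, n3 = n3, n6 = n6, ufaSfaRatio = ufaSfa,
      n6n3Ratio = n6n3, dialect = dialect)
}

#' Atherogenic index (AI)
#'
#' AI = (C12:0 + C16:0 + 4 x C14:0) / (MUFA + n-6 + n-3), with the class
#' sums of [sumFattyAcidClasses()] under the chosen dialect. Higher
#' values indicate greater atherogenic potential of the fat.
#'
#' @inheritParams sumFattyAcidClasses
#' @return dimensionless index.
#' @export
#' @examples
#' atherogenicIndex(aubracProfile("fatty_acid", "male"))  # 0.799
atherogenicIndex <- function(profile,
                             dialect = c("as_published", "conventional")) {
  dialect <- match.arg(dialect)
  cls <- sumFattyAcidClasses(profile, dialect, warnMissing = FALSE)
  num <- .faGet(profile, "C12:0", FALSE) + .faGet(profile, "C16:0", FALSE) +
    4 * .faGet(profile, "C14:0", FALSE)
  den <- cls@mufa + cls@n6 + cls@n3
  if (den <= 0) stop("no unsaturated fatty acids: AI undefined")
  num / den
}

#' Thrombogenic index (TI)
#'
#' TI = (C14:0 + C16:0 + C18:0) /
#' (0.5 MUFA + 0.5 n-6 + 3 n-3 + n-3/n-6), with class sums under the
#' chosen dialect. The final denominator term divides by the n-6 sum, so
#' a profile without n-6 acids is out of domain.
#'
#' @inheritParams sumFattyAcidClasses
#' @return dimensionless index.
#' @export
#' @examples
#' thrombogenicIndex(aubracProfile("fatty_acid", "male"))  # 2.03
thrombogenicIndex <- function(profile,
                              dialect = c("as_published", "conventional")) {
  dialect <- match.arg(dialect)
  cls <- sumFattyAcidClasses(profile, dialect, warnMissing = FALSE)
  num <- .faGet(profile, "C14:0", FALSE) + .faGet(profile, "C16:0", FALSE) +
    .faGet(profile, "C18:0", FALSE)
  if (cls@n6 <= 0) stop("n-6 sum is 0: TI undefined (n-3/n-6 term)")
  den <- 0.5 * cls@mufa + 0.5 * cls@n6 + 3 * cls@n3 + cls@n3 / cls@n6
  if (den <= 0) stop("TI denominator is 0")
  num / den
}

#' Hypocholesterolemic / hypercholesterolemic fatty-acid ratio (h/H)
#'
#' h/H = (C18:1 + PUFA) / (C12:0 + C14:0 + C16:0). The denominator HFA
#' is the hypercholesterolemic sum; the numerator hFA adds the PUFA sum
#' to a C18:1 isomer chosen by dialect: `as_published` uses trans-vaccenic
#' (C18:1 trans), which reproduces every tabulated hFA and h/H cell of
#' the reference dataset; `conventional` uses oleic (C18:1 cis), the
#' literature convention. The as-published choice is documented as a
#' reproduction dialect, not a recommendation.
#'
#' @inheritParams sumFattyAcidClasses
#' @return Named numeric: `HFA`, `hFA` (percent) and `h_over_H`.
#' @export
#' @examples
#' hypoHyperRatio(aubracProfile("fatty_acid", "male"))  # h/H 0.250
hypoHyperRatio <- function(profile,
                           dialect = c("as_published", "conventional")) {
  dialect <- match.arg(dialect)
  HFA <- .faGet(profile, c("C12:0", "C14:0", "C16:0"), FALSE)
  if (HFA <= 0) stop("no hypercholesterolemic acids: h/H undefined")
  c181 <- if (dialect == "as_published") "C18:1 trans" else "C18:1 cis"
  hFA <- .faGet(profile, c181, FALSE) + .faGet(profile, .PUFA_ACIDS, FALSE)
  c(HFA = HFA, hFA = hFA, h_over_H = hFA / HFA)
}

#' All lipid health indices of one profile
#'
#' Convenience wrapper bundling [atherogenicIndex()],
#' [thrombogenicIndex()] and [hypoHyperRatio()] into a
#' [LipidQualityIndices-class] object.
#'
#' @inheritParams sumFattyAcidClasses
#' @return A [LipidQualityIndices-class].
#' @export
lipidQualityIndices <- function(profile,
                                dialect = c("as_published", "conventional")) {
  dialect <- match.arg(dialect)
  hh <- hypoHyperRatio(profile, dialect)
  new("LipidQualityIndices",
      ai = atherogenicIndex(profile, dialect),
      ti = thrombogenicIndex(profile, dialect),
      hfaUpper = hh[["HFA"]], hfaLower = hh[["hFA"]],
      hOverH = hh[["h_over_H"]], dialect = dialect)
}

#' Omega-6 / omega-3 ratio
#'
#' For a single class summary, the ratio of its class sums. For a cohort,
#' either `mean_of_ratios` (compute the per-record ratio, then average —
#' the convention behind tabulated per-sample ratio rows) or
#' `ratio_of_means` (ratio of the class means of the mean profile).
#'
#' @param x a [FattyAcidClassSummary-class] or a fatty-acid
#'   [CohortTable-class].
#' @param mode "mean_of_ratios" (cohort default) or "ratio_of_means".
#' @param dialect passed to [sumFattyAcidClasses()] for cohort input.
#' @return dimensionless ratio.
#' @export
n6n3Ratio <- function(x, mode = c("mean_of_ratios", "ratio_of_means"),
                      dialect = c("as_published", "conventional")) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  if (is(x, "FattyAcidClassSummary")) {
    if (x@n3 <= 0) stop("n-3 sum is 0: n6/n3 undefined")
    return(x@n6 / x@n3)
  }
  stopifnot(is(x, "CohortTable"))
  summaries <- lapply(seq_len(length(x)), function(i)
    sumFattyAcidClasses(recordProfile(x, i), dialect, warnMissing = FALSE))
  n3 <- vapply(summaries, function(s) s@n3, numeric(1))
  n6 <- vapply(summaries, function(s) s@n6, numeric(1))
  zero <- which(n3 <= 0)
  if (length(zero))
    stop("n-3 sum is 0 for record(s): ",
         paste(cohortData(x)$animal_id[zero], collapse = ", "))
  if (mode == "mean_of_ratios") mean(n6 / n3) else mean(n6) / mean(n3)
}

#' Cohort-level lipid indices
#'
#' Computes the lipid health indices for every record and aggregates.
#' `per_record` (default) computes each index per animal and averages —
#' the mean-of-ratios behaviour that matches per-sample tabulation of
#' ratio quantities. `mean_profile` computes the indices once on the
#' cohort mean profile.
#'
#' @param cohort a fatty-acid [CohortTable-class].
#' @param dialect index dialect.
#' @param aggregate "per_record" or "mean_profile".
#' @param group "overall", "male" or "female".
#' @return Named numeric: AI, TI, HFA, hFA, h_over_H.
#' @export
cohortLipidIndices <- function(cohort,
                               dialect = c("as_published", "conventional"),
                               aggregate = c("per_record", "mean_profile"),
                               group = c("overall", "male", "female")) {
  dialect <- match.arg(dialect)
  aggregate <- match.arg(aggregate)
  group <- match.arg(group)
  d <- cohortData(cohort)
  keep <- if (group == "overall") seq_len(nrow(d)) else which(d$sex == group)
  if (!length(keep)) stop("no records for group '", group, "'")
  one <- function(p) {
    li <- lipidQualityIndices(p, dialect)
    c(AI = li@ai, TI = li@ti, HFA = li@hfaUpper, hFA = li@hfaLower,
      h_over_H = li@hOverH)
  }
  if (aggregate == "mean_profile") {
    sub <- new("CohortTable", data = d[keep, , drop = FALSE],
               schema = cohort@schema, provenance = cohort@provenance)
    return(one(meanProfile(sub, "overall")))
  }
  rowMeans(vapply(keep, function(i) one(recordProfile(cohort, i)),
                  numeric(5)))
}
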