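## Synthetic sex-stratified cohort generator. Each analyte is drawn
## independently per animal from a normal distribution truncated below
## (only the marginal mean +/- SD of each analyte-by-sex cell is known,
## so no covariance structure is imposed). Water and dry matter are
## generated as complements; an optional closure step rescales each
## fatty-acid vector to a fixed total.

# mean and sd actually implied by a normal(mean, sd) truncated below at
# `lower`; for cells several sd above the bound these equal (mean, sd),
# but near-zero analytes are visibly shifted and recovery checks must
# use the implied values
.truncMoments <- function(mean, sd, lower) {
  if (sd == 0) return(c(mean = mean, sd = 0))
  alpha <- (lower - mean) / sd
  Z <- 1 - pnorm(alpha)
  lambda <- exp(stats::dnorm(alpha, log = TRUE) - log(Z))
  c(mean = mean + sd * lambda,
    sd = sd * sqrt(max(0, 1 + alpha * lambda - lambda^2)))
}

# inverse-CDF sampler for a normal truncated at `lower`; deterministic
# under the RNG stream, exact for sd = 0
.rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  pLow <- pnorm(lower, mean, sd)
  if (pLow > 1 - 1e-12)
    stop(sprintf(
      "impossible truncation: mean %.3g with sd %.3g lies below bound %.3g",
      mean, sd, lower))
  qnorm(runif(n, pLow, 1), mean, sd)
}

#' Build a cohort scenario
#'
#' @param models data.frame with columns `analyte`, `sex`, `mean`, `sd`
#'   and optionally `lower` (truncation bound, default 0).
#' @param nMale,nFemale group sizes (defaults 27 and 22, the reference
#'   cohort design).
#' @param closureTotal if set, every generated fatty-acid vector is
#'   rescaled to this total after drawing; `NA` (default) disables
#'   closure, since measured FAME columns do not sum exactly to 100.
#' @param schema composition block of the analytes.
#' @param seed integer RNG seed stored with the scenario.
#' @return A validated [CohortScenario-class].
#' @export
cohortScenario <- function(models, nMale = 27L, nFemale = 22L,
                           closureTotal = NA_real_,
                           schema = c("fatty_acid", "amino_acid",
                                      "proximate"),
                           seed = 1L) {
  schema <- match.arg(schema)
  if (is.null(models$lower)) models$lower <- 0
  new("CohortScenario", nMale = as.integer(nMale),
      nFemale = as.integer(nFemale), models = models,
      closureTotal = as.numeric(closureTotal), schema = schema,
      seed = as.integer(seed))
}

#' Default scenarios from the packaged reference tables
#'
#' Builds a [CohortScenario-class] whose per-analyte, per-sex means and
#' SDs transcribe the packaged Aubrac composition tables — the measured
#' study conditions (27 males, 22 females).
#'
#' @param schema which table: "fatty_acid", "amino_acid" or "proximate".
#' @inheritParams cohortScenario
#' @return A [CohortScenario-class].
#' @export
#' @examples
#' defaultScenario("fatty_acid", seed = 1)
defaultScenario <- function(schema = c("fatty_acid", "amino_acid",
                                       "proximate"),
                            nMale = 27L, nFemale = 22L,
                            closureTotal = NA_real_, seed = 1L) {
  schema <- match.arg(schema)
  tab <- aubracTable(schema)
  analytes <- tab[[1]]
  models <- rbind(
    data.frame(analyte = analytes, sex = "male", mean = tab$male_mean,
               sd = tab$male_sd, lower = 0, stringsAsFactors = FALSE),
    data.frame(analyte = analytes, sex = "female", mean = tab$female_mean,
               sd = tab$female_sd, lower = 0, stringsAsFactors = FALSE))
  cohortScenario(models, nMale = nMale, nFemale = nFemale,
                 closureTotal = closureTotal, schema = schema, seed = seed)
}

.generateGroup <- function(models, n, sex, schema, closureTotal) {
  analytes <- unique(models$analyte)
  draw <- function() {
    m <- matrix(NA_real_, n, length(analytes),
                dimnames = list(NULL, analytes))
    for (a in analytes) {
      row <- models[models$analyte == a & models$sex == sex, ]
      m[, a] <- .rtruncnorm(n, row$mean, row$sd, row$lower)
    }
    m
  }
  m <- draw()
  if (schema == "proximate") {
    # water and dry matter are complementary by construction
    if (all(c("water", "dry_matter") %in% analytes))
      m[, "dry_matter"] <- 100 - m[, "water"]
    # redraw the few records where organic + mineral exceeds dry matter
    ok <- function(mm) mm[, "protein"] + mm[, "fat"] + mm[, "minerals"] <=
      mm[, "dry_matter"] + 0.5
    for (iter in seq_len(1000)) {
      bad <- which(!ok(m))
      if (!length(bad)) break
      repl <- draw()
      if (all(c("water", "dry_matter") %in% analytes))
        repl[, "dry_matter"] <- 100 - repl[, "water"]
      m[bad, ] <- repl[bad, , drop = FALSE]
    }
    if (any(!ok(m)))
      stop("could not generate proximate records satisfying the dry-matter bound")
  }
  if (schema == "fatty_acid" && !is.na(closureTotal))
    m <- m * (closureTotal / rowSums(m))
  m
}

#' Generate a synthetic cohort
#'
#' Draws every analyte independently per animal from its truncated-normal
#' model. A fixed seed makes the output bit-identical across runs.
#'
#' @param scenario a [CohortScenario-class].
#' @param seed RNG seed; defaults to the scenario's own.
#' @return A [CohortTable-class] with `nMale + nFemale` records.
#' @export
#' @examples
#' generateCohort(defaultScenario("fatty_acid", seed = 7))
generateCohort <- function(scenario, seed = scenario@seed) {
  stopifnot(is(scenario, "CohortScenario"))
  set.seed(seed)
  blocks <- list()
  if (scenario@nMale > 0)
    blocks$male <- .generateGroup(scenario@models, scenario@nMale, "male",
                                  scenario@schema, scenario@closureTotal)
  if (scenario@nFemale > 0)
    blocks$female <- .generateGroup(scenario@models, scenario@nFemale,
                                    "female", scenario@schema,
                                    scenario@closureTotal)
  sex <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  m <- do.call(rbind, blocks)
  d <- data.frame(
    animal_id = sprintf("sim_%s_%03d", sex,
                        unlist(lapply(blocks, function(b) seq_len(nrow(b))))),
    sex = sex, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  rownames(d) <- NULL
  new("CohortTable", data = d, schema = scenario@schema,
      provenance = sprintf("synthetic(seed=%d)", seed))
}

#' Model-implied group means of a scenario
#'
#' The per-analyte means the generator actually targets for one sex:
#' the truncated-normal implied means (which coincide with the nominal
#' means wherever the mean sits well above the truncation bound).
#'
#' @param scenario a [CohortScenario-class].
#' @param sex "male" or "female".
#' @return Named numeric of implied means.
#' @export
scenarioImpliedMeans <- function(scenario, sex = c("male", "female")) {
  sex <- match.arg(sex)
  m <- scenario@models[scenario@models$sex == sex, ]
  setNames(vapply(seq_len(nrow(m)), function(i)
    .truncMoments(m$mean[i], m$sd[i], m$lower[i])[["mean"]], numeric(1)),
    m$analyte)
}

#' Parameter recovery check for a generated cohort
#'
#' For each (analyte, sex) cell, the z-score of the sample mean against
#' the generating model: z = (sample mean - implied mean) /
#' (implied sd / sqrt(n)), where the implied moments are those of the
#' truncated normal the generator draws from. Cells with |z| > 3 are
#' flagged; under correct generation about 0.3% of cells should flag.
#' Closure rescaling breaks the per-analyte marginals, so recovery is
#' only meaningful for cohorts generated without closure.
#'
#' @param cohort a [CohortTable-class] generated from `scenario`.
#' @param scenario the generating [CohortScenario-class].
#' @return data.frame with `analyte`, `sex`, `model_mean` (implied),
#'   `sample_mean`, `z`, `flagged`.
#' @export
recoverParameters <- function(cohort, scenario) {
  d <- cohortData(cohort)
  m <- scenario@models
  out <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    x <- d[[m$analyte[i]]][d$sex == m$sex[i]]
    x <- x[!is.na(x)]
    mom <- .truncMoments(m$mean[i], m$sd[i], m$lower[i])
    z <- if (mom[["sd"]] == 0) 0 else
      (mean(x) - mom[["mean"]]) / (mom[["sd"]] / sqrt(length(x)))
    data.frame(analyte = m$analyte[i], sex = m$sex[i],
               model_mean = mom[["mean"]], sample_mean = mean(x), z = z,
               stringsAsFactors = FALSE)
  }))
  out$flagged <- abs(out$z) > 3
  rownames(out) <- NULL
  out
}
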