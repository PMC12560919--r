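# Independent brute-force transcriptions of the index formulas, written
# directly from their definitions and kept separate from the package
# implementation so the two routes can be compared.

oracleClassSums <- function(v, includeTransN6 = TRUE) {
  g <- function(a) if (a %in% names(v)) v[[a]] else 0
  list(
    sfa = g("C10:0") + g("C12:0") + g("C14:0") + g("C15:0") + g("C16:0") +
      g("C17:0") + g("C18:0") + g("C20:0"),
    mufa = g("C14:1") + g("C16:1") + g("C18:1 cis") + g("C20:1"),
    pufa = g("C18:2 cis") + g("C18:3 cis n3"),
    tfa = g("C18:1 trans") + g("C18:2 trans"),
    n3 = g("C18:3 cis n3"),
    n6 = g("C18:2 cis") + if (includeTransN6) g("C18:2 trans") else 0
  )
}

oracleAI <- function(v, includeTransN6 = TRUE) {
  g <- function(a) if (a %in% names(v)) v[[a]] else 0
  cls <- oracleClassSums(v, includeTransN6)
  (g("C12:0") + g("C16:0") + 4 * g("C14:0")) /
    (cls$mufa + cls$n6 + cls$n3)
}

oracleTI <- function(v, includeTransN6 = TRUE) {
  g <- function(a) if (a %in% names(v)) v[[a]] else 0
  cls <- oracleClassSums(v, includeTransN6)
  (g("C14:0") + g("C16:0") + g("C18:0")) /
    (0.5 * cls$mufa + 0.5 * cls$n6 + 3 * cls$n3 + cls$n3 / cls$n6)
}

oracleHH <- function(v, c181 = "C18:1 trans") {
  g <- function(a) if (a %in% names(v)) v[[a]] else 0
  (g(c181) + g("C18:2 cis") + g("C18:3 cis n3")) /
    (g("C12:0") + g("C14:0") + g("C16:0"))
}

# random strictly-positive FAME profile over the full canonical panel,
# scaled to a plausible total
randomFattyAcidProfile <- function() {
  v <- stats::runif(16, 0.05, 10)
  names(v) <- canonicalFattyAcids()
  v * (stats::runif(1, 60, 100) / sum(v))
}

randomScoreVector <- function(n = 8) {
  stats::setNames(exp(stats::runif(n, log(5), log(2500))),
                  paste0("g", seq_len(n)))
}

# direct-product transcription of the geometric mean (n-th root of the
# product), the overflow-prone form the log-space implementation avoids
oracleGeomMean <- function(scores) prod(scores)^(1 / length(scores))
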