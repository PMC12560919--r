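---
title: "Methods: lipid health indices and protein quality scoring"
author: "nutriscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid health indices and protein quality scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscore)
```

## What the package computes

nutriscore evaluates the nutritional quality of meat from two targeted
compositional profiles: a GC-MS FAME fatty-acid profile (each acid in % of
total identified FAME) and a hydrolysate amino-acid profile (g/100 g fresh
meat), plus the proximate composition that links them (protein %). It ships
a reference dataset — sex-stratified composition tables of *Longissimus
dorsi* muscle from Aubrac cattle (27 males, 22 females) — and a synthetic
cohort generator so the whole pipeline is exercisable without external data.

## Lipid health indices

From a fatty-acid profile $x$ (percent of total identified FAME per acid)
the class sums are

- $\mathrm{SFA} = \mathrm{C10{:}0}+\mathrm{C12{:}0}+\mathrm{C14{:}0}+\mathrm{C15{:}0}+\mathrm{C16{:}0}+\mathrm{C17{:}0}+\mathrm{C18{:}0}+\mathrm{C20{:}0}$
- $\mathrm{MUFA} = \mathrm{C14{:}1}+\mathrm{C16{:}1}+\mathrm{C18{:}1}cis+\mathrm{C20{:}1}$
- $\mathrm{PUFA} = \mathrm{C18{:}2}cis+\mathrm{C18{:}3}cis\,n3$, $\mathrm{UFA} = \mathrm{MUFA}+\mathrm{PUFA}$
- $\mathrm{TFA} = \mathrm{C18{:}1}trans+\mathrm{C18{:}2}trans$, $n3 = \mathrm{C18{:}3}cis\,n3$

and the indices are

$$\mathrm{AI} = \frac{\mathrm{C12{:}0}+\mathrm{C16{:}0}+4\,\mathrm{C14{:}0}}{\mathrm{MUFA}+n6+n3},\qquad
\mathrm{TI} = \frac{\mathrm{C14{:}0}+\mathrm{C16{:}0}+\mathrm{C18{:}0}}{0.5\,\mathrm{MUFA}+0.5\,n6+3\,n3+n3/n6},$$

$$h/H = \frac{\mathrm{C18{:}1}+\mathrm{PUFA}}{\mathrm{C12{:}0}+\mathrm{C14{:}0}+\mathrm{C16{:}0}}.$$

### The two dialects

The reference tables resolve C18:1 and C18:2 into cis and trans isomers but
the index formulas say only "C18:1" and "$\sum(n-6)$". Reconciling the
formulas against every tabulated index cell fixes the assignments, and the
package exposes both readings:

- **`as_published`** (default): $n6 = \mathrm{C18{:}2}cis + \mathrm{C18{:}2}trans$
  (male column: $3.99+2.52 = 6.51$, exactly the tabulated n6), and the h/H
  numerator uses **trans-vaccenic** for the C18:1 term (reproducing every
  tabulated hFA cell: $1.95+4.43=6.38$ for males). This dialect exists to
  reproduce the reference tables; it is not a nutritional recommendation.
- **`conventional`**: cis isomers only — $n6 = \mathrm{C18{:}2}cis$ and h/H
  uses oleic — the usual literature convention.

The MUFA sum uses oleic only in both dialects: the tabulated male MUFA
(37.21) equals $0.62+2.39+34.02+0.17$, not the value including
trans-vaccenic. With a trans-free profile the dialects coincide for AI, TI
and all class sums; they cannot coincide for h/H, whose numerators pick
different isomers by construction.

### Scale behaviour

AI, h/H, UFA/SFA and n6/n3 are ratios of sums of the same degree, hence
exactly invariant under rescaling of the profile. TI is **not**: its
denominator adds the dimensionless $n3/n6$ term to percent-scale terms, so
rescaling by $k$ gives $\mathrm{TI}(kx) = k\,\mathrm{num}/(k\,\mathrm{lin} +
n3/n6)$. This is a property of the formula as defined, and the test suite
asserts exactly that transformation law rather than pretending TI is
homogeneous.

### Degenerate inputs

Missing panel acids contribute 0 with a warning (partial panels remain
scoreable). SFA $=0$ makes UFA/SFA the `Inf` sentinel with a warning. A
profile with no unsaturated acids (AI), no n-6 (TI) or no
hypercholesterolemic acids (h/H) is a domain error with a named message.

### Cohort aggregation

Ratio quantities are aggregated per record and then averaged
(`mean_of_ratios`, the default in `n6n3Ratio()` and
`cohortLipidIndices(aggregate = "per_record")`). The reference tables make
this identifiable: the tabulated overall n6/n3 (12.07) disagrees with the
ratio of the overall class means (11.47) but is consistent with a
per-sample mean of ratios. Computing on the mean profile remains available
by flag.

## Protein quality

Amino-acid contents are converted to protein basis,
$a_i^{(p)} = 100\,a_i/\mathrm{protein\%}$ (g/100 g protein, equivalently
g/16 g N), and scored against a reference pattern $r$ over the eight
essential groups (Ile, Leu, Lys, Met+Cys, Phe+Tyr, Thr, Trp, Val):

$$\mathrm{CS}_i = 100\,\frac{a_i^{(p)}}{r_i},\qquad
\mathrm{EAAI} = \Big(\prod_{i=1}^{8}\mathrm{CS}_i\Big)^{1/8},\qquad
\mathrm{BV} = 1.09\,\mathrm{EAAI} - 11.7,\qquad
\mathrm{NI} = \mathrm{EAAI}\cdot\frac{\mathrm{protein\%}}{100}.$$

The three FAO/WHO age-group patterns (children, youth, adults) are
packaged; custom patterns (e.g. whole egg, the classical standard) are
accepted via `referencePattern()`. Chemical scores are reported in percent.
The limiting amino acid is the group with the minimal chemical score.

Numerical choices: the EAAI geometric mean is computed in log space,
$\exp(\mathrm{mean}(\log \mathrm{CS}))$ — meat tryptophan scores above
2300% against the adult pattern, and the direct 8-fold product is
needlessly overflow-prone. The paired groups Met+Cys and Phe+Tyr are formed
by summation; because the basis conversion is linear, summing before or
after converting is identical. The "Cys" panel entry is the jointly
quantified cystine + cysteine; "Trp" is total tryptophan — the only
pairings consistent with the reference basis column (4.58 and 13.88).

For the sex-pooled evaluation the protein percentage is the **unweighted**
mean of the male and female protein percentages (21.615%): it is the only
value that reproduces the reference conversion (Ile $1.28 \to 5.92$, Lys
$2.48 \to 11.47$). A 27/22 sample-size-weighted mean is available via
`aubracPooledProtein(weighted = TRUE)`.

## Reproduction of the reference tables, and its known exceptions

`reproduceReference()` recomputes every derivable cell from the measured
input rows and compares at tolerances chosen to absorb two-decimal input
rounding propagated through the formulas: 0.05 absolute for lipid
quantities, 0.5% relative for protein quantities. Four groups of cells are
flagged as known discrepancies rather than silently passed:

- the tabulated TFA row (male 2.67, female 2.06, overall 2.51) is
  irreconcilable with the definitional trans sum (4.47, 2.00, 3.82);
- the tabulated female TI (1.74) recomputes to 1.78 from the printed female
  column (input-rounding noise);
- the overall stearic value (9.86) is inconsistent with the sex means
  (22.15/13.45), so the overall SFA and UFA/SFA rows cannot be recomputed
  from it — the overall column is otherwise treated as given data (its TI,
  1.54, is consistent with 9.86 and reproduces);
- the tabulated n6/n3 row is a per-sample mean of ratios whose underlying
  replicates are not available, so column-mean recomputation is reported as
  aggregation-dependent.

## The synthetic cohort generator

`generateCohort()` draws each analyte independently per animal from a
normal distribution truncated below at 0, parameterised by the per-sex
mean ± SD of the packaged tables, with the design group sizes 27 males and
22 females as defaults. Only marginal moments are published, so no
covariance structure is imposed — a real cohort's analytes (e.g. C16:0 vs
C18:1) are correlated, so multivariate structure (PCA geometry in
particular) in synthetic cohorts emulates nothing measured, and passing
tests say nothing about real inter-analyte correlation. Sampling uses the
inverse-CDF construction (`qnorm(runif(pnorm(bound), 1))`), which is
deterministic under a seed and degenerates exactly to the mean at SD 0.

Truncation at 0 shifts the implied mean of near-zero analytes (arachidic,
male: nominal $0.08 \pm 0.14$ implies a truncated mean of 0.146), so
parameter-recovery z-scores are computed against the truncated-normal
implied moments — the distribution actually sampled — not the nominal
parameters. Water and dry matter are generated as complements
(DM $= 100 -$ water); proximate records violating the
protein + fat + minerals $\le$ DM + 0.5 bound (about 5% at the male
parameters) are redrawn. Closure of fatty-acid vectors to a fixed total is
off by default — the reference FAME columns themselves sum to 86–100, not
exactly 100 — and when enabled rescales after drawing.

## Statistics

Descriptive summaries use the $n-1$ SD. The sex contrast is the two-group
equal-variance one-way ANOVA (identical to the pooled t-test, $F = t^2$),
with Welch's test by flag, coded `***` ($p \le 0.001$), `**`
($p \le 0.01$), `*` ($p \le 0.05$), `ns`. PCA is the eigendecomposition of
the correlation matrix (covariance by flag) with scores centred and a
deterministic sign convention: each loading column's largest-magnitude
entry is positive. PCA on the two group-mean pseudo-records is refused —
component structure from two points is meaningless, and the reference
figures' loadings come from per-replicate data that are not published,
which is why no tabulated PCA value is reproduced. The default amino-acid
category scheme (essential incl. His; umami Asp/Glu; sweet
Gly/Ala/Ser/Thr/Pro; aromatic Phe/Tyr/Trp) is a documented convention,
fully overridable.

## Problem sizes and test design

Property suites run 1000 random profiles for scale-invariance and oracle
equivalence (tolerances $10^{-12}$ and $10^{-10}$), 200 random two-group
datasets for the $F=t^2$ identity, and 20 random $10\times4$ tables for the
PCA oracle. Recovery checks use 1000 animals per sex; the sex-contrast
power check uses 200 replicates at the design sizes (27/22), where the
strongly dimorphic analytes (oleic acid, total amino acids; standardized
differences above 4) are expected to reach $p \le 0.001$ essentially
always. These sizes make the checks sharp while the full suite stays fast.

## Limitations

- The generator emulates marginal means and SDs only; no inter-analyte
  correlation, no batch or animal-level random effects.
- Chemical scores are not digestibility-corrected (no PDCAAS/DIAAS).
- The as-published h/H dialect reflects the reference tables'
  reverse-engineered convention; for cross-study comparison use
  `conventional`.
- Minerals (ash) are carried through validation but feed no downstream
  index.
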