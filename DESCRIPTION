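Package: nutriscore
Title: Lipid Health Indices and Protein Quality Scoring for Meat Composition
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nutritional-quality evaluation of meat from targeted
    compositional profiles. Computes fatty-acid class sums (SFA, MUFA, PUFA,
    UFA, TFA, omega-3/omega-6) and the lipid health indices AI (atherogenic),
    TI (thrombogenic) and the hypocholesterolemic/hypercholesterolemic ratio
    from GC-MS FAME profiles; scores protein quality against FAO/WHO age-group
    reference patterns via the chemical score, the essential amino acid index
    (Oser's geometric mean), biological value and nutritional index; provides
    sex-stratified cohort descriptive statistics, two-group significance
    coding and PCA; and generates synthetic sex-stratified cohorts from
    tabulated mean/SD parameters so every pipeline stage is exercisable
    without external data. Ships a reference dataset of Aubrac cattle
    Longissimus dorsi composition tables and a one-shot recomputation of all
    derivable index values from their input rows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'fixtures.R'
    'composition-io.R'
    'lipid-quality.R'
    'protein-quality.R'
    'cohort-stats.R'
    'synthetic-cohort.R'
    'reproduce.R'
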