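test_that("describeCohort reports n-1 SD and the three groups", {
  d <- data.frame(animal_id = c("a", "b", "c", "d"),
                  sex = c("male", "male", "female", "female"),
                  x = c(10, 20, 12, 18))
  cohort <- new("CohortTable", data = d, schema = "fatty_acid",
                provenance = "test")
  s <- describeCohort(cohort, "x")
  male <- s[s$group == "male", ]
  expect_equal(male$mean, 15)
  expect_equal(male$sd, 7.0710678, tolerance = 1e-6)   # n-1 denominator
  expect_equal(male$n, 2L)
  expect_setequal(s$group, c("male", "female", "overall"))
  expect_error(describeCohort(cohort, "nope"), "unknown variable")
})

test_that("describeCohort is permutation-invariant and warns on n = 1", {
  scen <- defaultScenario("amino_acid", nMale = 6L, nFemale = 5L, seed = 3L)
  cohort <- generateCohort(scen)
  d <- cohortData(cohort)
  perm <- new("CohortTable", data = d[sample(nrow(d)), ],
              schema = "amino_acid", provenance = "perm")
  s1 <- describeCohort(cohort, c("Lys", "Glu"))
  s2 <- describeCohort(perm, c("Lys", "Glu"))
  expect_equal(s1[order(s1$variable, s1$group), c("mean", "sd", "n")],
               s2[order(s2$variable, s2$group), c("mean", "sd", "n")],
               ignore_attr = TRUE)
  single <- new("CohortTable",
                data = data.frame(animal_id = c("a", "b"),
                                  sex = c("male", "female"), x = c(1, 2)),
                schema = "fatty_acid", provenance = "test")
  expect_warning(s <- describeCohort(single, "x"), "SD reported as 0")
  expect_equal(s$sd[s$group == "male"], 0)
})

test_that("significance codes follow the footnote thresholds", {
  expect_equal(significanceCode(c(0.0004, 0.001, 0.005, 0.03, 0.2)),
               c("***", "***", "**", "*", "ns"))
})

test_that("compareSexes equals the pooled t-test (F = t^2) on random data", {
  set.seed(606)
  for (i in seq_len(200)) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    d <- data.frame(animal_id = as.character(seq_len(n1 + n2)),
                    sex = rep(c("male", "female"), c(n1, n2)),
                    x = stats::rnorm(n1 + n2, mean = rep(c(0, 1), c(n1, n2))))
    cohort <- new("CohortTable", data = d, schema = "fatty_acid",
                  provenance = "sim")
    res <- compareSexes(cohort, "x")
    tt <- stats::t.test(x ~ sex, data = d, var.equal = TRUE)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("compareSexes p-value is affine-invariant and codes correctly", {
  set.seed(7)
  d <- data.frame(animal_id = as.character(1:12),
                  sex = rep(c("male", "female"), each = 6),
                  x = c(stats::rnorm(6, 10), stats::rnorm(6, 30)))
  c1 <- new("CohortTable", data = d, schema = "fatty_acid",
            provenance = "t")
  d2 <- d; d2$x <- -5 * d2$x + 100
  c2 <- new("CohortTable", data = d2, schema = "fatty_acid",
            provenance = "t")
  r1 <- compareSexes(c1, "x"); r2 <- compareSexes(c2, "x")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
  expect_equal(r1$code, significanceCode(r1$p_value))
  # identical groups: no effect
  d$x <- rep(c(1, 2, 3), 4)
  d$x[d$sex == "female"] <- d$x[d$sex == "male"]
  c3 <- new("CohortTable", data = d, schema = "fatty_acid",
            provenance = "t")
  expect_equal(compareSexes(c3, "x")$code, "ns")
  # degenerate group size
  c4 <- new("CohortTable",
            data = data.frame(animal_id = c("a", "b", "c"),
                              sex = c("male", "female", "female"),
                              x = 1:3),
            schema = "fatty_acid", provenance = "t")
  expect_error(compareSexes(c4, "x"), ">= 2 records per sex")
})

test_that("category aggregation matches hand sums on the male column", {
  male <- aubracProfile("amino_acid", "male")
  agg <- aggregateCategories(male)
  expect_equal(agg[["TotalAA"]], 30.59, tolerance = 0.011)
  expect_equal(agg[["fAA"]], 2.67 + 4.31)   # Asp + Glu, hand summation
  expect_equal(aggregateCategories(male, list(empty = character(0)))[["empty"]],
               0)
  expect_error(aggregateCategories(male, list(x = "NotAnAA")), "NotAnAA")
})

test_that("PCA matches a brute-force correlation eigendecomposition", {
  set.seed(808)
  for (i in seq_len(20)) {
    d <- data.frame(animal_id = as.character(1:10),
                    sex = rep(c("male", "female"), 5),
                    matrix(stats::rnorm(40), 10, 4,
                           dimnames = list(NULL, c("v1", "v2", "v3", "v4"))))
    cohort <- new("CohortTable", data = d, schema = "amino_acid",
                  provenance = "sim")
    res <- cohortPca(cohort, c("v1", "v2", "v3", "v4"))
    eig <- eigen(stats::cor(d[, c("v1", "v2", "v3", "v4")]),
                 symmetric = TRUE)
    expect_equal(unname(100 * eig$values / sum(eig$values)),
                 unname(res@varianceExplained), tolerance = 1e-9)
    for (j in 1:4) {
      ref <- eig$vectors[, j]
      ref <- ref * sign(ref[which.max(abs(ref))])
      expect_equal(unname(res@loadings[, j]), ref, tolerance = 1e-9)
    }
    expect_equal(unname(colMeans(res@scores)), rep(0, 4),
                 tolerance = 1e-9)
    expect_equal(sum(res@varianceExplained), 100, tolerance = 1e-9)
  }
})

test_that("two perfectly correlated variables load entirely on F1", {
  d <- data.frame(animal_id = as.character(1:6),
                  sex = rep(c("male", "female"), 3),
                  a = 1:6, b = 2 * (1:6) + 3)
  cohort <- new("CohortTable", data = d, schema = "amino_acid",
                provenance = "t")
  res <- cohortPca(cohort, c("a", "b"))
  expect_equal(res@varianceExplained[[1]], 100, tolerance = 1e-9)
})

test_that("PCA refuses degenerate inputs with clear errors", {
  expect_error(cohortPca(aubracCohort("fatty_acid")), ">= 3 records")
  d <- data.frame(animal_id = as.character(1:5),
                  sex = rep(c("male", "female"), c(3, 2)),
                  a = stats::rnorm(5), const = 1)
  cohort <- new("CohortTable", data = d, schema = "amino_acid",
                provenance = "t")
  expect_error(cohortPca(cohort, c("a", "const")), "const")
})
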