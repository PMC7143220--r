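# audit helpers: re-state each category's arithmetic constraints and check
# a generated record against them
auditRecord <- function(counts, category) {
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  C <- g("C"); H <- g("H"); N <- g("N"); O <- g("O"); P <- g("P")
  S <- g("S")
  switch(category,
    fatty_acyl = C >= 8 && C <= 30 && O >= 2 && O <= 4 && N == 0 &&
      P == 0 && S == 0 && (2 * C + 2 - H) %% 2 == 0 &&
      (2 * C + 2 - H) / 2 >= 1 && (2 * C + 2 - H) / 2 <= 7,
    glycerolipid = P == 0 && N == 0 && O >= 4 && O <= 6 &&
      C >= 3 + 8 * (O - 3) && C <= 3 + 22 * (O - 3) &&
      H == 8 + 2 * (C - 3) - 2 * (O - 3),
    glycerophospholipid = P == 1 && N <= 1 && O >= 7 && O <= 9,
    sphingolipid = N >= 1 && N <= 2 && C >= 30 && C <= 48 && O >= 3 &&
      O <= 12 && P <= 1,
    sterol = C >= 27 && C <= 30 && O >= 1 && O <= 3 &&
      (2 * C + 2 - H) / 2 >= 5 && (2 * C + 2 - H) / 2 <= 8,
    prenol = C %% 5 == 0 && C >= 10 && C <= 40 && O <= 2,
    saccharolipid = O >= 12 && C >= 36 && C <= 84 && N == 0 && P == 0,
    polyketide = C >= 10 && C <= 30 && O / C >= 0.2 - 0.51 / C &&
      O / C <= 0.5 + 0.5 / C && N == 0 && P == 0,
    non_lipid = C >= 1 && C <= 12,
    FALSE)
}

test_that("generation is deterministic under a seed and varies across seeds", {
  a <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 25L,
                                             seed = 42L))
  b <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 25L,
                                             seed = 42L))
  expect_identical(a, b)
  c <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 25L,
                                             seed = 43L))
  expect_false(identical(a$formula, c$formula))
  expect_equal(nrow(a), 25L * 9L)  # records-per-label count contract
})

test_that("every generated record satisfies its category's rules", {
  recs <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 120L,
                                                seed = 8L))
  for (i in seq_len(nrow(recs))) {
    counts <- parseFormula(recs$formula[i])
    cat <- recs$categories[[i]][1L]
    expect_true(auditRecord(counts, cat),
                label = paste("rule audit:", cat, recs$formula[i]))
  }
  nl <- recs[vapply(recs$categories, function(x) x[1L], "") == "non_lipid", ]
  masses <- vapply(nl$formula, function(f) monoisotopicMass(f), 0,
                   USE.NAMES = FALSE)
  expect_true(all(masses < 350))
})

test_that("overlap injects secondary labels without breaking determinism", {
  spec <- generatorSpec(recordsPerLabel = 50L, seed = 12L, overlap = 0.2)
  recs <- generateLabeledFormulas(spec)
  expect_identical(recs, generateLabeledFormulas(spec))
  expect_gt(sum(lengths(recs$categories) > 1L), 0L)
  expect_true(all(lengths(recs$categories) <= 2L))
})

test_that("true formulas recur at the configured rate in assignment tables", {
  u <- generateAssignments(nSamples = 10L, nTrueFormulas = 50L,
                           recurrence = 0.8, decoysPerSample = 0L,
                           seed = 7L)
  expect_identical(u, generateAssignments(nSamples = 10L,
                                          nTrueFormulas = 50L,
                                          recurrence = 0.8,
                                          decoysPerSample = 0L, seed = 7L))
  # with no decoys, every row is a recurring true formula
  counts <- table(u$formula)
  expect_lte(length(counts), 52L)
  perFormula <- tapply(u$sample_id, u$formula,
                       function(s) length(unique(s)))
  expect_equal(mean(perFormula), 8, tolerance = 0.1)  # binomial mean n*p
  # every m/z bin of the study design is populated
  bins <- findInterval(tapply(u$peak_mz, u$formula, stats::median),
                       c(0, 400, 800, 1200, 1600), rightmost.closed = TRUE)
  expect_setequal(unique(bins), 1:4)
})

test_that("shifted tables have decoy-level recurrence and more decoys", {
  u <- generateAssignments(seed = 3L)
  s <- generateAssignments(seed = 3L, shifted = TRUE)
  perFormula <- function(df) tapply(df$sample_id, df$formula,
                                    function(x) length(unique(x)))
  # recurring true formulas dominate the top of the unshifted table only
  expect_gt(mean(sort(perFormula(u), decreasing = TRUE)[1:60]), 5)
  expect_lt(max(perFormula(s)), 4)
  # shifted emulation inflates the decoy load
  expect_gt(nrow(s[!duplicated(s$formula), ]) /
              length(unique(s$sample_id)), 40)
})

test_that("synthetic fixtures serialize to SDF and XML faithfully", {
  recs <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 5L,
                                                seed = 2L))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeSdf(recs, sdf)
  back <- loadLipidRecords(sdf, format = "sdf",
                           fieldMap = list(formula = "FORMULA",
                                           category = "CATEGORY",
                                           class = "MAIN_CLASS"))
  expect_equal(back$formula, recs$formula)
  xml <- withr::local_tempfile(fileext = ".xml")
  writeHmdbXml(recs, xml)
  nl <- loadNonLipids(xml, format = "xml")
  expect_equal(nrow(nl), nrow(recs))
})
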