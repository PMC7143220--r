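makeRecordDf <- function(formula, category, class, source = "lmsd") {
  data.frame(formula = formula, categories = I(as.list(category)),
             classes = I(as.list(class)), source = source,
             stringsAsFactors = FALSE)
}

test_that("lipid records load from TSV and tag-field SDF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("formula\tcategory\tclass",
               "C16H32O2\tFatty Acyls [FA]\tFA01"), tsv)
  recs <- loadLipidRecords(tsv, format = "tsv")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$formula, "C16H32O2")
  expect_equal(recs$categories[[1L]], "Fatty Acyls [FA]")
  expect_equal(recs$classes[[1L]], "FA01")

  sdfRecs <- makeRecordDf(c("C16H32O2", "C19H38O4", "C45H86NO13P"),
                          c("fatty_acyl", "glycerolipid", "sphingolipid"),
                          c("fatty_acid", "monoradylglycerol",
                            "phosphosphingolipid"))
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeSdf(sdfRecs, sdf)
  loaded <- loadLipidRecords(sdf, format = "sdf",
                             fieldMap = list(formula = "FORMULA",
                                             category = "CATEGORY",
                                             class = "MAIN_CLASS"))
  expect_equal(nrow(loaded), 3L)
  expect_equal(loaded$formula, sdfRecs$formula)
  expect_equal(unlist(loaded$categories), unlist(sdfRecs$categories))
})

test_that("malformed lipid entries are skipped and a bad field map aborts", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("formula\tcategory\tclass",
               "C16H32O2\tfatty_acyl\tfatty_acid",
               "C18H36O2\tfatty_acyl\tfatty_acid",
               "C20H40O2\tfatty_acyl\tfatty_acid",
               "not-a-formula\tfatty_acyl\tfatty_acid",
               "C6H12O6\t\tx"), tsv)
  expect_message(recs <- loadLipidRecords(tsv), "2 malformed")
  expect_equal(nrow(recs), 3L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("formula\tcategory\tclass",
               "??\ta\tb", "!!\ta\tb", "C2H6\ta\tb"), bad)
  expect_error(suppressMessages(loadLipidRecords(bad)), "field map")
  expect_error(loadLipidRecords(tsv, fieldMap = list(formula = "nope",
                                                     category = "category",
                                                     class = "class")),
               "missing")
})

test_that("non-lipid loading filters lipid taxonomy entries", {
  recs <- makeRecordDf(c("C6H12O6", "C5H9NO4", "C16H32O2", "C3H7NO2",
                         "C44H86NO8P"),
                       rep("x", 5L), rep("x", 5L))
  xml <- withr::local_tempfile(fileext = ".xml")
  writeHmdbXml(recs, xml,
               superClass = c("Organic oxygen compounds", "Organic acids",
                              "Lipids and lipid-like molecules",
                              "Organic acids",
                              "Lipids and lipid-like molecules"))
  nl <- loadNonLipids(xml, format = "xml")
  expect_equal(nrow(nl), 3L)
  expect_true(all(unlist(nl$categories) == "non_lipid"))
  expect_true(all(unlist(nl$classes) == "non_lipid"))
  expect_false("C16H32O2" %in% nl$formula)

  # duplicates are kept: de-duplication happens later
  xml2file <- withr::local_tempfile(fileext = ".xml")
  writeHmdbXml(makeRecordDf(c("C6H12O6", "C6H12O6"), c("x", "x"),
                            c("x", "x")), xml2file)
  expect_equal(nrow(loadNonLipids(xml2file, format = "xml")), 2L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("formula\tsuper_class", empty)
  expect_equal(nrow(loadNonLipids(empty, format = "tsv")), 0L)
})

test_that("de-duplication unions labels over isomeric formulas", {
  recs <- makeRecordDf(c("C41H78O6", "C41H78O6"),
                       c("glycerolipid", "glycerophospholipid"),
                       c("diradylglycerol", "anionic_glycerophospholipid"))
  ts <- deduplicateRecords(recs)
  expect_equal(length(ts), 1L)
  expect_setequal(trainingRecords(ts)$categories[[1L]],
                  c("glycerolipid", "glycerophospholipid"))

  many <- makeRecordDf(rep("C16H32O2", 10L), rep("fatty_acyl", 10L),
                       rep("fatty_acid", 10L))
  expect_equal(length(deduplicateRecords(many)), 1L)
})

test_that("de-duplication is idempotent and conserves labels", {
  recs <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 40L,
                                                seed = 3L))
  ts <- deduplicateRecords(recs)
  # independent distinct-formula count
  expect_equal(length(ts), length(unique(recs$formula)))
  ts2 <- deduplicateRecords(trainingRecords(ts))
  expect_equal(trainingRecords(ts2)$formula, trainingRecords(ts)$formula)
  expect_identical(trainingRecords(ts2)$categories,
                   trainingRecords(ts)$categories)
  # label conservation (no non_lipid conflicts in this draw direction)
  expect_setequal(unique(unlist(trainingRecords(ts)$categories)),
                  unique(unlist(recs$categories)))
  # class -> parent consistency inside each record
  parents <- classParents(ts)
  for (i in seq_len(length(ts))) {
    r <- trainingRecords(ts)[i, ]
    expect_true(all(parents[r$classes[[1L]]] %in% r$categories[[1L]]))
  }
})

test_that("lipid labels beat non_lipid when a formula appears in both", {
  lipid <- makeRecordDf("C16H32O2", "fatty_acyl", "fatty_acid")
  nonLipid <- makeRecordDf(c("C16H32O2", "C6H12O6"),
                           c("non_lipid", "non_lipid"),
                           c("non_lipid", "non_lipid"), source = "hmdb")
  ts <- buildTrainingSet(list(lipid), nonLipid)
  expect_equal(length(ts), 2L)
  rec <- trainingRecords(ts)
  fa <- rec[rec$formula == "C16H32O2", ]
  expect_identical(fa$categories[[1L]], "fatty_acyl")
  expect_false("non_lipid" %in% fa$categories[[1L]])
  glc <- rec[rec$formula == "C6H12O6", ]
  expect_identical(glc$categories[[1L]], "non_lipid")
})

test_that("training sets combine sources and can exclude in-silico records", {
  set.seed(9)
  lmsd <- makeRecordDf(paste0("C", 10:29, "H", 2 * (10:29), "O2"),
                       rep("fatty_acyl", 20L), rep("fatty_acid", 20L))
  lmissd <- makeRecordDf(paste0("C", 30:39, "H", 2 * (30:39), "O3"),
                         rep("fatty_acyl", 10L), rep("fatty_acid", 10L),
                         source = "lmissd")
  hmdb <- makeRecordDf(paste0("C", 1:15, "H", 2 * (1:15) + 2, "O"),
                       rep("non_lipid", 15L), rep("non_lipid", 15L),
                       source = "hmdb")
  both <- buildTrainingSet(list(lmsd, lmissd), hmdb)
  expect_equal(length(both), 45L)
  lmsdOnly <- buildTrainingSet(list(lmsd, lmissd), hmdb,
                               includeInsilico = FALSE)
  expect_equal(length(lmsdOnly), 35L)
  expect_error(buildTrainingSet(list(), hmdb), "at least one")
})

test_that("training sets round-trip through TSV", {
  ts <- smallTrainingSet()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrainingSet(ts, path)
  back <- readTrainingSet(path)
  expect_equal(length(back), length(ts))
  expect_setequal(categoryLabels(back), categoryLabels(ts))
  expect_identical(classParents(back)[sort(names(classParents(back)))],
                   classParents(ts)[sort(names(classParents(ts)))])
  i <- match("C16H32O2", trainingRecords(back)$formula)
  if (!is.na(i)) {
    j <- match("C16H32O2", trainingRecords(ts)$formula)
    expect_setequal(trainingRecords(back)$categories[[i]],
                    trainingRecords(ts)$categories[[j]])
  }
})
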