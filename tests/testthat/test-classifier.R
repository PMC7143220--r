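test_that("precision follows tp/(tp+fp) and is undefined without positives", {
  expect_equal(precisionFromCounts(99, 0), 1.0)
  expect_equal(precisionFromCounts(0, 5), 0)
  expect_true(is.na(precisionFromCounts(0, 0)))
  met <- evaluateOob(smallHierarchyModel(), smallTrainingSet())
  defined <- !is.na(met$precision)
  expect_true(all(abs(met$precision[defined] -
                        met$tp[defined] / (met$tp + met$fp)[defined])
                  < 1e-12))
  expect_true(all(met$tp <= met$n_entries))
})

test_that("hierarchy training builds one binary model per viable label", {
  ts <- smallTrainingSet()
  m <- smallHierarchyModel()
  expect_s4_class(m, "LipidHierarchyModel")
  expect_setequal(names(m@categoryModels), categoryLabels(ts))
  expect_true(all(names(m@classModels) %in% classLabels(ts)))
  expect_true(all(classParents(ts)[names(m@classModels)] %in%
                    names(m@categoryModels)))
  expect_equal(m@trainingInfo$nTrees, 80L)
})

test_that("labels with too few positives are skipped with a warning", {
  recs <- rbind(
    generateLabeledFormulas(generatorSpec(recordsPerLabel = 30L, seed = 4L,
                                          labels = c("fatty_acyl",
                                                     "non_lipid"))),
    data.frame(formula = c("C30H50", "C35H60", "C40H66"),
               categories = I(list("prenol", "prenol", "prenol")),
               classes = I(list("isoprenoid_hydrocarbon",
                                "isoprenoid_hydrocarbon",
                                "isoprenoid_hydrocarbon")),
               source = "synthetic")
  )
  ts <- deduplicateRecords(recs)
  expect_warning(m <- trainHierarchy(ts, nTrees = 30L, seed = 2L),
                 "skipped")
  expect_false("prenol" %in% names(m@categoryModels))
  expect_true("fatty_acyl" %in% names(m@categoryModels))
})

test_that("training and prediction are deterministic under a fixed seed", {
  ts <- smallTrainingSet()
  probes <- c("C16H32O2", "C6H12O6", "C45H86NO13P", "C57H104O6")
  m1 <- suppressWarnings(trainHierarchy(ts, nTrees = 40L, seed = 9L,
                                        minPositives = 5L))
  m2 <- suppressWarnings(trainHierarchy(ts, nTrees = 40L, seed = 9L,
                                        minPositives = 5L))
  p1 <- predictLabels(m1, probes)
  p2 <- predictLabels(m2, probes)
  expect_identical(p1$categoryVotes, p2$categoryVotes)
  expect_identical(p1$categories, p2$categories)
  m3 <- suppressWarnings(trainHierarchy(ts, nTrees = 40L, seed = 10L,
                                        minPositives = 5L))
  expect_false(identical(p1$categoryVotes,
                         predictLabels(m3, probes)$categoryVotes))
})

test_that("class predictions are gated by their parent category", {
  m <- smallHierarchyModel()
  probes <- trainingRecords(smallTrainingSet())$formula[1:200]
  pred <- predictLabels(m, probes)
  for (i in seq_along(probes)) {
    cls <- pred$classes[[i]]
    if (length(cls) == 0L) next
    expect_true(all(m@classParent[cls] %in% pred$categories[[i]]))
  }
  # ungated vote slots stay NA
  expect_true(all(is.na(pred$classVotes) | pred$classVotes >= 0))
})

test_that("prediction handles no-category inputs and config mismatches", {
  m <- smallHierarchyModel()
  # a formula wildly unlike any training rule can fire nothing
  pred <- predictLabels(m, list(c(H = 90L, S = 7L)), threshold = 0.95)
  expect_length(pred$categories[[1L]], 0L)
  feats <- featurizeFormulas("C16H32O2", k = 6L)
  expect_error(predictLabels(m, feats), "feature configuration mismatch")
})

test_that("monolithic training replicates multi-label records and needs
           two labels", {
  ts <- smallTrainingSet()
  m <- trainMonolithic(ts, nTrees = 40L, seed = 3L)
  nCatRows <- sum(lengths(trainingRecords(ts)$categories))
  expect_equal(length(m@categoryForest$y), nCatRows)
  expect_gt(nCatRows, length(ts))  # dedup produced multi-label records
  out <- predictMonolithic(m, c("C16H32O2", "C16H32O2"))
  expect_identical(out$category[1L], out$category[2L])
  expect_identical(out$class[1L], out$class[2L])

  single <- deduplicateRecords(
    generateLabeledFormulas(generatorSpec(recordsPerLabel = 25L, seed = 6L,
                                          labels = "fatty_acyl")))
  expect_error(trainMonolithic(single, nTrees = 10L, seed = 1L),
               "two distinct labels")
})

test_that("label tallies count every fired label and track no-category", {
  tally <- tallyLabels(list(c("glycerolipid", "glycerophospholipid"),
                            character()))
  expect_equal(tally$predictions[tally$label == "glycerolipid"], 1L)
  expect_equal(tally$predictions[tally$label == "glycerophospholipid"], 1L)
  expect_equal(tally$predictions[tally$label == "no category"], 1L)
  expect_gt(sum(tally$predictions), 2L)  # labels outnumber formulas
  expect_equal(tally$percent[tally$label == "glycerolipid"], 50)

  none <- tallyLabels(rep(list(character()), 10L),
                      labels = c("fatty_acyl"))
  expect_equal(none$predictions[none$label == "no category"], 10L)
  expect_equal(none$predictions[none$label == "fatty_acyl"], 0L)
})

test_that("classifyTable skips unparseable rows and counts them", {
  m <- smallHierarchyModel()
  formulas <- c("C16H32O2", "garbage!!", "C6H12O6")
  tab <- classifyTable(m, formulas)
  expect_equal(attr(tab, "skipped"), 1L)
  expect_equal(tab$label[nrow(tab)], "no category")
  expect_true(all(tab$predictions >= 0))
})

test_that("models persist with their feature configuration", {
  m <- smallHierarchyModel()
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  back <- loadModel(path)
  expect_s4_class(back, "LipidHierarchyModel")
  expect_identical(back@featureConfig, m@featureConfig)
  expect_identical(predictLabels(back, "C16H32O2")$categoryVotes,
                   predictLabels(m, "C16H32O2")$categoryVotes)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(loadModel(bad), "not a lipidForest model")
})
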