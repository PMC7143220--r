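# Random Forest organizations for lipid label prediction: a hierarchy of
# binary one-vs-rest forests (one per category, gating one per class), and
# the simpler monolithic pair of multiclass forests it is compared against.
# The forests themselves come from the randomForest package; this file owns
# the one-vs-rest construction, the gating, and the out-of-bag accounting.

#' @importFrom randomForest randomForest
#' @importFrom stats predict
NULL

.DEFAULT_TREES <- 500L

.tsFeatures <- function(ts, table, k) {
  featurizeFormulas(ts@records$formula, table = table, k = k)
}

.labelMatrix <- function(labelSets, labels) {
  m <- vapply(labels, function(lb) {
    vapply(labelSets, function(s) lb %in% s, logical(1L))
  }, logical(length(labelSets)))
  matrix(m, ncol = length(labels), dimnames = list(NULL, labels))
}

.trainBinary <- function(x, pos, nTrees, seed) {
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  .withSeed(seed, randomForest::randomForest(x = x, y = y, ntree = nTrees))
}

.checkFeatureConfig <- function(model, features) {
  fc <- model@featureConfig
  if (!identical(attr(features, "k"), fc$k) ||
      !identical(attr(features, "tableVersion"), fc$tableVersion)) {
    stop("feature configuration mismatch: model expects k = ", fc$k,
         ", isotope table ", fc$tableVersion)
  }
}

.asFeatures <- function(model, x, table) {
  fc <- model@featureConfig
  if (is.data.frame(x) && "mass" %in% names(x)) {
    .checkFeatureConfig(model, x)
    return(x)
  }
  featurizeFormulas(x, table = table, k = fc$k)
}

#' Train the hierarchical model organization
#'
#' One binary one-vs-rest Random Forest is trained per category label
#' (positives: records whose category set contains the label; negatives:
#' all other records) and per class label within each category.  Class
#' models are later evaluated only for inputs whose parent category model
#' fired.  Labels with fewer than `minPositives` positive records are
#' skipped with a warning rather than trained into degenerate forests.
#'
#' @param ts A [TrainingSet-class] with at least two labels.
#' @param nTrees Trees per forest (default 500).
#' @param seed Integer seed; training is deterministic given
#'   (data, seed, nTrees).
#' @param k Number of fractional mass digits in the feature vector.
#' @param table Isotope mass table.
#' @param minPositives Minimum positive count for a label to be trained.
#' @return A [LipidHierarchyModel-class].
#' @seealso [predictLabels()], [evaluateOob()], [classifyTable()]
#' @export
trainHierarchy <- function(ts, nTrees = .DEFAULT_TREES, seed = 1L,
                           k = 4L, table = isotopeMassTable(),
                           minPositives = 10L) {
  if (length(ts) == 0L) stop("empty training set")
  allLabels <- c(ts@categoryVocabulary, ts@classVocabulary)
  if (length(unique(allLabels)) < 2L) {
    stop("training requires at least two labels")
  }
  x <- .tsFeatures(ts, table, k)
  catPos <- .labelMatrix(ts@records$categories, ts@categoryVocabulary)
  clsPos <- .labelMatrix(ts@records$classes, ts@classVocabulary)
  skipped <- character()
  catModels <- list()
  for (i in seq_along(ts@categoryVocabulary)) {
    lb <- ts@categoryVocabulary[i]
    if (sum(catPos[, lb]) < minPositives) {
      skipped <- c(skipped, lb)
      next
    }
    catModels[[lb]] <- .trainBinary(x, catPos[, lb], nTrees, seed + i)
  }
  clsModels <- list()
  trainedParents <- names(catModels)
  for (j in seq_along(ts@classVocabulary)) {
    lb <- ts@classVocabulary[j]
    parent <- ts@classParent[[lb]]
    if (!parent %in% trainedParents || sum(clsPos[, lb]) < minPositives) {
      skipped <- c(skipped, lb)
      next
    }
    clsModels[[lb]] <- .trainBinary(x, clsPos[, lb], nTrees,
                                    seed + 1000L + j)
  }
  if (length(skipped) > 0L) {
    warning("labels skipped (fewer than ", minPositives,
            " positives or untrained parent): ",
            paste(skipped, collapse = ", "))
  }
  if (length(catModels) == 0L) stop("no category model could be trained")
  new("LipidHierarchyModel",
      categoryModels = catModels,
      classModels = clsModels,
      classParent = ts@classParent,
      featureConfig = list(k = as.integer(k),
                           tableVersion = .tableVersion(table)),
      seed = as.integer(seed),
      trainingInfo = list(
        nTrees = as.integer(nTrees),
        nRecords = length(ts),
        positives = c(colSums(catPos), colSums(clsPos)),
        skipped = skipped
      ))
}

#' Train the monolithic model organization
#'
#' A single multiclass forest over all category labels and a second over
#' all class labels, both on the identical feature matrix.  Records
#' carrying several labels are replicated once per label for multiclass
#' training.
#'
#' @inheritParams trainHierarchy
#' @return A [LipidMonolithicModel-class].
#' @export
trainMonolithic <- function(ts, nTrees = .DEFAULT_TREES, seed = 1L,
                            k = 4L, table = isotopeMassTable()) {
  if (length(ts) == 0L) stop("empty training set")
  x <- .tsFeatures(ts, table, k)
  expand <- function(labelSets) {
    idx <- rep(seq_along(labelSets), lengths(labelSets))
    list(rows = idx, y = unlist(labelSets, use.names = FALSE))
  }
  fitMulti <- function(labelSets, offset) {
    e <- expand(labelSets)
    if (length(unique(e$y)) < 2L) {
      stop("monolithic training requires at least two distinct labels; ",
           "a single-class forest is degenerate")
    }
    .withSeed(seed + offset,
              randomForest::randomForest(x = x[e$rows, , drop = FALSE],
                                         y = factor(e$y), ntree = nTrees))
  }
  catForest <- fitMulti(ts@records$categories, 1L)
  clsForest <- fitMulti(ts@records$classes, 2L)
  new("LipidMonolithicModel",
      categoryForest = catForest,
      classForest = clsForest,
      featureConfig = list(k = as.integer(k),
                           tableVersion = .tableVersion(table)),
      seed = as.integer(seed),
      trainingInfo = list(nTrees = as.integer(nTrees),
                          nRecords = length(ts)))
}

.voteMatrix <- function(models, x) {
  if (length(models) == 0L || nrow(x) == 0L) {
    return(matrix(numeric(), nrow = nrow(x), ncol = length(models),
                  dimnames = list(NULL, names(models))))
  }
  votes <- vapply(models, function(m) {
    stats::predict(m, newdata = x, type = "vote")[, "pos"]
  }, numeric(nrow(x)))
  matrix(votes, ncol = length(models), dimnames = list(NULL, names(models)))
}

#' Predict lipid categories and classes with the hierarchical model
#'
#' A category fires when its binary model's positive vote fraction reaches
#' the threshold; class models are evaluated only for inputs whose parent
#' category fired.  An input may fire zero labels ("no category") or a
#' category but none of its classes ("no class").
#'
#' @param model A [LipidHierarchyModel-class].
#' @param x Character vector of formulas, list of count vectors, or a
#'   precomputed feature `data.frame` from [featurizeFormulas()] (must match
#'   the model's feature configuration).
#' @param threshold Positive vote fraction needed to fire (default 0.5,
#'   majority vote).
#' @param table Isotope mass table used when `x` needs featurizing.
#' @return List with per-input `categories` and `classes` (lists of
#'   character vectors) and the raw vote matrices `categoryVotes`,
#'   `classVotes`.
#' @export
predictLabels <- function(model, x, threshold = 0.5,
                          table = isotopeMassTable()) {
  stopifnot(is(model, "LipidHierarchyModel"))
  feats <- .asFeatures(model, x, table)
  catVotes <- .voteMatrix(model@categoryModels, feats)
  catFired <- catVotes >= threshold
  n <- nrow(feats)
  clsVotes <- matrix(NA_real_, nrow = n, ncol = length(model@classModels),
                     dimnames = list(NULL, names(model@classModels)))
  for (lb in names(model@classModels)) {
    parent <- model@classParent[[lb]]
    rows <- which(catFired[, parent])
    if (length(rows) == 0L) next
    clsVotes[rows, lb] <- stats::predict(model@classModels[[lb]],
                                         newdata = feats[rows, , drop = FALSE],
                                         type = "vote")[, "pos"]
  }
  clsFired <- !is.na(clsVotes) & clsVotes >= threshold
  list(
    categories = lapply(seq_len(n), function(i) colnames(catFired)[catFired[i, ]]),
    classes = lapply(seq_len(n), function(i) colnames(clsFired)[clsFired[i, ]]),
    categoryVotes = catVotes,
    classVotes = clsVotes
  )
}

#' Predict with the monolithic model
#'
#' Returns the highest-vote category and class label for each input.  The
#' two forests vote independently, so the class label can contradict the
#' category label -- there is no gating in the monolithic organization.
#'
#' @param model A [LipidMonolithicModel-class].
#' @inheritParams predictLabels
#' @return `data.frame` with columns `category` and `class`.
#' @export
predictMonolithic <- function(model, x, table = isotopeMassTable()) {
  stopifnot(is(model, "LipidMonolithicModel"))
  feats <- .asFeatures(model, x, table)
  data.frame(
    category = as.character(stats::predict(model@categoryForest,
                                           newdata = feats)),
    class = as.character(stats::predict(model@classForest,
                                        newdata = feats)),
    stringsAsFactors = FALSE
  )
}

#' Precision from true/false positive counts
#'
#' `tp / (tp + fp)`, or `NA` when no positive prediction was made (the
#' quantity is then undefined).
#'
#' @param tp,fp Non-negative integer counts.
#' @return Numeric in `[0, 1]`, or `NA`.
#' @examples
#' precisionFromCounts(1681, 324)  # 0.838 to three decimals
#' @export
precisionFromCounts <- function(tp, fp) {
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

.metricsRow <- function(label, truePos, predPos) {
  tp <- sum(truePos & predPos)
  fp <- sum(!truePos & predPos)
  data.frame(
    label = label,
    precision = precisionFromCounts(tp, fp),
    oob_accuracy = mean(predPos == truePos),
    n_entries = sum(truePos),
    tp = tp,
    fp = fp,
    stringsAsFactors = FALSE
  )
}

#' Out-of-bag accuracy and precision per label
#'
#' Every training record is scored by the trees that did not sample it
#' (the out-of-bag vote), giving an internal estimate of generalization
#' accuracy without sacrificing training data to a held-out fold.  For
#' each label: `oob_accuracy` is the fraction of all records whose
#' out-of-bag vote classifies them correctly for that one-vs-rest binary
#' problem, `tp` the positives predicted positive out-of-bag, `fp` the
#' negatives predicted positive, and `precision = tp / (tp + fp)`.
#'
#' @param model A [LipidHierarchyModel-class] or
#'   [LipidMonolithicModel-class] trained on `ts`.
#' @param ts The [TrainingSet-class] the model was trained on (record order
#'   must match training).
#' @return `data.frame` with columns
#'   `label, precision, oob_accuracy, n_entries, tp, fp`.
#' @export
evaluateOob <- function(model, ts) {
  if (is(model, "LipidHierarchyModel")) {
    if (model@trainingInfo$nRecords != length(ts)) {
      stop("training set does not match the model (record count differs)")
    }
    catPos <- .labelMatrix(ts@records$categories, ts@categoryVocabulary)
    clsPos <- .labelMatrix(ts@records$classes, ts@classVocabulary)
    oneLevel <- function(models, pos, level) {
      do.call(rbind, lapply(names(models), function(lb) {
        votes <- models[[lb]]$votes[, "pos"]
        votes[is.nan(votes)] <- 0
        cbind(.metricsRow(lb, pos[, lb], votes >= 0.5), level = level)
      }))
    }
    out <- rbind(oneLevel(model@categoryModels, catPos, "category"),
                 oneLevel(model@classModels, clsPos, "class"))
    rownames(out) <- NULL
    return(out)
  }
  if (is(model, "LipidMonolithicModel")) {
    if (model@trainingInfo$nRecords != length(ts)) {
      stop("training set does not match the model (record count differs)")
    }
    oneForest <- function(forest, labelSets, level) {
      idx <- rep(seq_along(labelSets), lengths(labelSets))
      truth <- unlist(labelSets, use.names = FALSE)
      pred <- as.character(forest$predicted)
      do.call(rbind, lapply(sort(unique(truth)), function(lb) {
        cbind(.metricsRow(lb, truth == lb, pred == lb), level = level)
      }))
    }
    out <- rbind(oneForest(model@categoryForest, ts@records$categories,
                           "category"),
                 oneForest(model@classForest, ts@records$classes, "class"))
    rownames(out) <- NULL
    return(out)
  }
  stop("unsupported model type: ", class(model)[1L])
}

#' Tally fired labels over a batch of formulas
#'
#' Each fired label increments its tally, so a formula firing several
#' categories is counted once per category and tallies may sum to more
#' than the number of formulas.  Formulas firing no label are counted
#' under `"no category"`.  Percentages are computed against the formula
#' count (and may therefore sum above 100).
#'
#' @param labelSets List of character vectors (fired labels per formula).
#' @param nFormulas Number of formulas classified.
#' @param labels Optional label universe fixing the row order; fired labels
#'   outside it are appended.
#' @return `data.frame` with columns `label`, `predictions`, `percent`,
#'   ending with the `"no category"` row.
#' @export
tallyLabels <- function(labelSets, nFormulas = length(labelSets),
                        labels = NULL) {
  fired <- unlist(labelSets, use.names = FALSE)
  counts <- table(fired)
  if (is.null(labels)) {
    labels <- sort(unique(fired))
  } else {
    labels <- union(labels, names(counts))
  }
  n <- stats::setNames(rep(0L, length(labels)), labels)
  n[names(counts)] <- as.integer(counts)
  noCat <- sum(lengths(labelSets) == 0L)
  out <- data.frame(
    label = c(labels, "no category"),
    predictions = c(as.integer(n), noCat),
    stringsAsFactors = FALSE
  )
  out$percent <- if (nFormulas > 0) 100 * out$predictions / nFormulas else 0
  out
}

#' Classify a formula list and tally the fired labels
#'
#' Runs every parseable formula through the hierarchical model and
#' tallies fired labels at the requested level, Table-style: one row per
#' label with prediction count and percent of classified formulas, plus a
#' `"no category"` row for formulas firing nothing.  Unparseable rows are
#' skipped and counted in the `skipped` attribute.
#'
#' @param model A [LipidHierarchyModel-class].
#' @param formulas Character vector of formula strings.
#' @param threshold Vote-fraction threshold, see [predictLabels()].
#' @param level `"category"` or `"class"`.
#' @param table Isotope mass table.
#' @return Tally `data.frame` (see [tallyLabels()]) with attribute
#'   `skipped` (number of unparseable formulas).
#' @export
classifyTable <- function(model, formulas, threshold = 0.5,
                          level = c("category", "class"),
                          table = isotopeMassTable()) {
  level <- match.arg(level)
  parsed <- lapply(formulas, function(x) {
    tryCatch(parseFormula(x), error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1L))
  skipped <- sum(!ok)
  pred <- predictLabels(model, parsed[ok], threshold = threshold,
                        table = table)
  sets <- if (level == "category") pred$categories else pred$classes
  universe <- if (level == "category") {
    names(model@categoryModels)
  } else {
    names(model@classModels)
  }
  out <- tallyLabels(sets, nFormulas = sum(ok), labels = universe)
  attr(out, "skipped") <- skipped
  out
}

#' Persist / restore a trained model
#'
#' The archive embeds the feature configuration (digit count and isotope
#' table version), label vocabularies and training seed, so later
#' classification runs are reproducible and refuse mismatched feature
#' configurations.
#'
#' @param model A trained model object.
#' @param path File path for the archive.
#' @return `saveModel` returns `path` invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "LipidHierarchyModel") ||
              is(model, "LipidMonolithicModel"))
  saveRDS(list(format = "lipidForest-model-1", model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "lipidForest-model-1")) {
    stop("not a lipidForest model archive: ", path)
  }
  validObject(obj$model)
  obj$model
}
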