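#' @import methods
NULL

#' TrainingSet: de-duplicated multi-label formula records
#'
#' One record per distinct molecular formula (exact element-count map, so
#' isomers collapse but isobars do not), each carrying the union of lipid
#' category and class labels observed for that formula across all sources,
#' plus the label vocabularies and the class-to-parent-category map.
#'
#' @slot records `data.frame` with columns `formula` (canonical Hill
#'   string), `categories` (list of character), `classes` (list of
#'   character), `source` (character provenance tag).
#' @slot categoryVocabulary Ordered character vector of category labels.
#' @slot classVocabulary Ordered character vector of class labels.
#' @slot classParent Named character vector mapping each class label to its
#'   single parent category.
#' @seealso [deduplicateRecords()], [buildTrainingSet()]
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(
    records = "data.frame",
    categoryVocabulary = "character",
    classVocabulary = "character",
    classParent = "character"
  )
)

setValidity("TrainingSet", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("formula", "categories", "classes", "source")
  if (!all(need %in% names(r))) {
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(r$formula)) {
    msgs <- c(msgs, "records must be unique by formula")
  }
  if (any(lengths(r$categories) == 0L)) {
    msgs <- c(msgs, "every record needs at least one category label")
  }
  cls <- unique(unlist(r$classes, use.names = FALSE))
  if (!all(cls %in% names(object@classParent))) {
    msgs <- c(msgs, "every class label must have a parent category")
  }
  if (length(object@classParent) > 0L &&
      !all(object@classParent %in% object@categoryVocabulary)) {
    msgs <- c(msgs, "class parents must appear in the category vocabulary")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' @describeIn TrainingSet Number of unique-formula records.
#' @param x,object A `TrainingSet`.
#' @export
setMethod("length", "TrainingSet", function(x) nrow(x@records))

#' Accessors for TrainingSet
#'
#' @param ts A [TrainingSet-class] object.
#' @return `trainingRecords`: the records `data.frame`; `categoryLabels` /
#'   `classLabels`: label vocabularies; `classParents`: named character
#'   vector class -> parent category.
#' @name trainingset-accessors
NULL

#' @rdname trainingset-accessors
#' @export
trainingRecords <- function(ts) ts@records

#' @rdname trainingset-accessors
#' @export
categoryLabels <- function(ts) ts@categoryVocabulary

#' @rdname trainingset-accessors
#' @export
classLabels <- function(ts) ts@classVocabulary

#' @rdname trainingset-accessors
#' @export
classParents <- function(ts) ts@classParent

setMethod("show", "TrainingSet", function(object) {
  cat("TrainingSet with", nrow(object@records), "unique formulas\n")
  cat("  categories:", paste(object@categoryVocabulary, collapse = ", "),
      "\n")
  cat("  classes:", length(object@classVocabulary), "labels\n")
  multi <- sum(lengths(object@records$categories) > 1L)
  cat("  multi-category records:", multi, "\n")
})

#' HullRegion: facet representation of a convex hull over lattice points
#'
#' Membership is `normals %*% x <= offsets + eps` for every facet row,
#' together with `|eqNormals %*% x - eqOffsets| <= eps` for the equality
#' constraints describing a rank-deficient (affinely degenerate) point set.
#'
#' @slot normals Facet normal matrix (one row per facet, unit norm).
#' @slot offsets Facet offsets.
#' @slot eqNormals Equality-constraint normals (0 rows when full rank).
#' @slot eqOffsets Equality-constraint offsets.
#' @slot vertices Matrix of hull vertices (subset of the input points).
#' @slot bbox 2 x d matrix of per-dimension integer bounds (rows: min, max).
#' @slot dimension Ambient dimension.
#' @seealso [buildHull()], [hullContains()], [enumerateLattice()]
#' @exportClass HullRegion
setClass("HullRegion",
  representation(
    normals = "matrix",
    offsets = "numeric",
    eqNormals = "matrix",
    eqOffsets = "numeric",
    vertices = "matrix",
    bbox = "matrix",
    dimension = "integer"
  )
)

setValidity("HullRegion", function(object) {
  d <- object@dimension
  msgs <- character()
  if (ncol(object@normals) != d && nrow(object@normals) > 0L) {
    msgs <- c(msgs, "facet normals must have one column per dimension")
  }
  if (nrow(object@normals) != length(object@offsets)) {
    msgs <- c(msgs, "one offset per facet required")
  }
  if (ncol(object@vertices) != d) {
    msgs <- c(msgs, "vertices must live in the ambient dimension")
  }
  if (!all(dim(object@bbox) == c(2L, d))) {
    msgs <- c(msgs, "bbox must be a 2 x d matrix")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

setMethod("show", "HullRegion", function(object) {
  cat("HullRegion in", object@dimension, "dimensions\n")
  cat("  facets:", nrow(object@normals),
      " equality constraints:", nrow(object@eqNormals), "\n")
  cat("  vertices:", nrow(object@vertices), "\n")
  bb <- apply(object@bbox, 2L, paste, collapse = "..")
  cat("  bounding box:", paste(bb, collapse = " x "), "\n")
})

#' LipidHierarchyModel: per-label binary forests organized hierarchically
#'
#' One binary one-vs-rest Random Forest per lipid category (including
#' `non_lipid`) and one per lipid class; class models are only evaluated
#' for inputs whose parent category model fired.
#'
#' @slot categoryModels Named list of per-category binary forests.
#' @slot classModels Named list of per-class binary forests.
#' @slot classParent Named character vector class -> parent category.
#' @slot featureConfig List with `k` (mass digit count) and `tableVersion`.
#' @slot seed Integer seed the forests were trained with.
#' @slot trainingInfo List: label positive counts, skipped labels, n trees.
#' @seealso [trainHierarchy()], [predictLabels()], [evaluateOob()]
#' @exportClass LipidHierarchyModel
setClass("LipidHierarchyModel",
  representation(
    categoryModels = "list",
    classModels = "list",
    classParent = "character",
    featureConfig = "list",
    seed = "integer",
    trainingInfo = "list"
  )
)

setValidity("LipidHierarchyModel", function(object) {
  cls <- names(object@classModels)
  if (!all(cls %in% names(object@classParent))) {
    return("every class model needs a parent category")
  }
  parents <- object@classParent[cls]
  if (!all(parents %in% names(object@categoryModels))) {
    return("every class model's parent must have a category model")
  }
  TRUE
})

setMethod("show", "LipidHierarchyModel", function(object) {
  cat("LipidHierarchyModel\n")
  cat("  category models:", paste(names(object@categoryModels),
                                  collapse = ", "), "\n")
  cat("  class models:", length(object@classModels), "\n")
  cat("  trees per forest:", object@trainingInfo$nTrees,
      " seed:", object@seed, "\n")
  cat("  features: k =", object@featureConfig$k,
      ", isotope table", object@featureConfig$tableVersion, "\n")
})

#' LipidMonolithicModel: single multiclass forests for category and class
#'
#' One multiclass Random Forest over all category labels and one over all
#' class labels, trained on the identical feature matrix (multi-label
#' records replicated once per label).  Category and class predictions are
#' made independently, so a predicted class can contradict the predicted
#' category -- the documented weakness of the monolithic organization.
#'
#' @slot categoryForest Multiclass forest over category labels.
#' @slot classForest Multiclass forest over class labels.
#' @slot featureConfig List with `k` and `tableVersion`.
#' @slot seed Integer training seed.
#' @slot trainingInfo List of training metadata.
#' @seealso [trainMonolithic()], [predictMonolithic()]
#' @exportClass LipidMonolithicModel
setClass("LipidMonolithicModel",
  representation(
    categoryForest = "ANY",
    classForest = "ANY",
    featureConfig = "list",
    seed = "integer",
    trainingInfo = "list"
  )
)

setMethod("show", "LipidMonolithicModel", function(object) {
  cat("LipidMonolithicModel\n")
  cat("  category labels:", length(object@categoryForest$classes), "\n")
  cat("  class labels:", length(object@classForest$classes), "\n")
  cat("  trees per forest:", object@trainingInfo$nTrees,
      " seed:", object@seed, "\n")
})
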