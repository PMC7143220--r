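# Molecular formulas are represented as named integer vectors
# (element symbol -> atom count, all counts >= 1, absent elements omitted).
# Everything downstream -- feature vectors, training sets, hull points --
# consumes this representation.

.CHONPS <- c("C", "H", "N", "O", "P", "S")

#' Parse a molecular formula string
#'
#' Parses a Hill-style concatenation of element symbols with optional
#' positive integer counts (e.g. `"C16H32O2"`).  Charges, adducts, isotope
#' labels and parentheses are not part of the dialect: untargeted
#' formula-assignment tools emit plain non-adducted elemental formulas, and
#' adduct arithmetic is out of scope.
#'
#' @param text Single non-empty formula string.
#' @return Named integer vector of atom counts (element -> count).  Repeated
#'   element symbols are summed.
#' @examples
#' parseFormula("C16H32O2")
#' parseFormula("H2O")
#' @seealso [formatFormula()] for the inverse, [featurize()].
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  if (!nzchar(text)) stop("cannot parse empty formula string")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text)) {
    stop("malformed formula string: '", text, "'")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  bad <- !(syms %in% .PERIODIC_SYMBOLS)
  if (any(bad)) {
    stop("unknown element symbol '", syms[bad][1L], "' in formula '",
         text, "'")
  }
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (anyNA(counts)) stop("unreadable atom count in formula '", text, "'")
  if (any(counts == 0L)) {
    stop("zero atom count for element '", syms[counts == 0L][1L],
         "' in formula '", text, "'")
  }
  out <- tapply(counts, syms, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  .hillOrder(counts)
}

# Hill order: C first, H second, remaining elements alphabetical; when no
# carbon is present, all elements alphabetical.
.hillOrder <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts[ord]
}

#' Format a molecular formula in Hill notation
#'
#' @param counts Named integer vector of atom counts.
#' @return Single formula string; counts of 1 are omitted.
#' @examples
#' formatFormula(c(C = 16L, H = 32L, O = 2L))
#' @export
formatFormula <- function(counts) {
  counts <- .checkFormula(counts)
  counts <- .hillOrder(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

.checkFormula <- function(counts) {
  if (is.character(counts)) return(parseFormula(counts))
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be a named vector")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("atom counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula must contain at least one atom")
  storage.mode(counts) <- "integer"
  counts
}

#' Theoretical monoisotopic mass of a formula
#'
#' Sum over atoms of the mass of each element's most naturally abundant
#' isotope.  Recomputing the theoretical mass from the formula (rather than
#' using an observed peak m/z) removes mass error as a confound at the
#' classification step.
#'
#' @param counts Molecular formula (named counts, or a formula string).
#' @param table Isotope mass table, see [isotopeMassTable()].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")
#' @export
monoisotopicMass <- function(counts, table = isotopeMassTable()) {
  counts <- .checkFormula(counts)
  missing <- setdiff(names(counts), names(table))
  if (length(missing) > 0L) {
    stop("no isotope mass for element '", missing[1L],
         "' in table version ", .tableVersion(table))
  }
  sum(counts * table[names(counts)])
}

#' Hydrogen deficit due to unsaturation
#'
#' Number of hydrogens missing relative to a saturated acyclic compound with
#' the same skeleton, i.e. twice the ring-plus-double-bond-equivalent count:
#' `2*C + 2 + N + P - H` under the fixed valence convention C=4, N=3, P=3,
#' O and S divalent (contributing 0), all other elements 0.  The value may
#' be negative for chemically impossible formulas; these arise during hull
#' enumeration and must remain computable.
#'
#' @inheritParams monoisotopicMass
#' @return Signed integer.
#' @examples
#' missingHydrogens("C16H32O2")  # 2: one degree of unsaturation
#' @export
missingHydrogens <- function(counts) {
  counts <- .checkFormula(counts)
  n <- function(el) if (el %in% names(counts)) counts[[el]] else 0L
  2L * n("C") + 2L + n("N") + n("P") - n("H")
}

.featureNames <- function(k) {
  c("c", "h", "n", "o", "p", "s", "other", "mass", "missing_h",
    paste0("d", seq_len(k)))
}

# Fractional digits of the mass: the mass is rounded to k decimal places and
# the first k fractional digits are read off.  sprintf does the rounding.
.massDigits <- function(mass, k) {
  frac <- sub("^[^.]*\\.", "", sprintf("%.*f", k, mass))
  m <- matrix(as.integer(unlist(strsplit(frac, "", fixed = TRUE),
                                use.names = FALSE)),
              ncol = k, byrow = TRUE)
  colnames(m) <- paste0("d", seq_len(k))
  m
}

#' Build the chemically descriptive feature vector for one formula
#'
#' The feature vector contains the atom count for each CHONPS element, the
#' summed count of all other elements, the theoretical monoisotopic mass,
#' the hydrogen deficit due to unsaturation, and the first `k` fractional
#' digits of the mass (after rounding the mass to `k` decimal places).  It
#' is a pure function of the formula.
#'
#' @inheritParams monoisotopicMass
#' @param k Number of fractional mass digits (default 4, roughly matching
#'   the ~1 ppm digital resolution of modern FT-MS instruments at 1000 Da).
#' @return Named numeric vector with elements
#'   `c,h,n,o,p,s,other,mass,missing_h,d1..dk`.
#' @examples
#' featurize("C16H32O2")
#' @export
featurize <- function(counts, table = isotopeMassTable(), k = 4L) {
  drop(as.matrix(featurizeFormulas(list(counts), table = table, k = k)))
}

#' Build a feature matrix for many formulas
#'
#' @param formulas Character vector of formula strings, or a list of named
#'   count vectors.
#' @inheritParams featurize
#' @return `data.frame` with one row per formula, columns
#'   `c,h,n,o,p,s,other,mass,missing_h,d1..dk` (the fixed export order).
#'   Carries attributes `k` and `tableVersion`.
#' @export
featurizeFormulas <- function(formulas, table = isotopeMassTable(), k = 4L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (is.character(formulas)) formulas <- lapply(formulas, parseFormula)
  formulas <- lapply(formulas, .checkFormula)
  n <- length(formulas)
  counts6 <- matrix(0L, nrow = n, ncol = 6L,
                    dimnames = list(NULL, .CHONPS))
  other <- integer(n)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    f <- formulas[[i]]
    present <- intersect(names(f), .CHONPS)
    counts6[i, present] <- f[present]
    other[i] <- sum(f[setdiff(names(f), .CHONPS)])
    mass[i] <- monoisotopicMass(f, table = table)
  }
  .featuresFromCounts(counts6, other = other, mass = mass, k = k,
                      tableVersion = .tableVersion(table))
}

# Fast path shared with hull enumeration: build features straight from a
# CHONPS count matrix (columns C,H,N,O,P,S).
.featuresFromCounts <- function(counts6, other = NULL, mass = NULL,
                                table = NULL, k = 4L,
                                tableVersion = NULL) {
  stopifnot(ncol(counts6) == 6L)
  colnames(counts6) <- .CHONPS
  if (is.null(other)) other <- integer(nrow(counts6))
  if (is.null(mass)) {
    mass <- drop(counts6 %*% table[.CHONPS])
    tableVersion <- .tableVersion(table)
  }
  mh <- 2L * counts6[, "C"] + 2L + counts6[, "N"] + counts6[, "P"] -
    counts6[, "H"]
  out <- data.frame(
    c = counts6[, "C"], h = counts6[, "H"], n = counts6[, "N"],
    o = counts6[, "O"], p = counts6[, "P"], s = counts6[, "S"],
    other = other, mass = mass, missing_h = mh
  )
  out <- cbind(out, as.data.frame(.massDigits(mass, k)))
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "tableVersion") <- tableVersion
  out
}

#' Read a formula list from a TSV file
#'
#' One formula per line; extra columns are preserved.  A headerless
#' single-column file is also accepted.
#'
#' @param path Path to a TSV file.
#' @param column Name of the formula column when a header is present.
#' @return `data.frame` with at least a `formula` character column.
#' @export
readFormulaTable <- function(path, column = "formula") {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl(column, first, fixed = TRUE)
  df <- utils::read.delim(path, header = hasHeader,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!hasHeader) names(df)[1L] <- column
  if (!column %in% names(df)) {
    stop("no '", column, "' column in ", path)
  }
  names(df)[names(df) == column] <- "formula"
  df
}

#' Write a feature matrix to TSV
#'
#' Columns are written in the fixed documented order
#' `c,h,n,o,p,s,other,mass,missing_h,d1..dk`.
#'
#' @param features Output of [featurizeFormulas()].
#' @param path Output path.
#' @export
writeFeatureMatrix <- function(features, path) {
  k <- attr(features, "k")
  if (is.null(k)) k <- sum(grepl("^d[0-9]+$", names(features)))
  cols <- .featureNames(k)
  utils::write.table(features[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
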