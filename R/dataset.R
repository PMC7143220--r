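# Training-set construction: load labeled lipid records (LMSD/LMISSD-style)
# and non-lipid metabolite records (HMDB-style), de-duplicate isomers by
# mapping each distinct formula to the union of its observed labels.

#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_text
NULL

.NON_LIPID <- "non_lipid"

# Canonicalize a raw label data.frame into the internal record layout:
# formula (canonical Hill string), categories/classes (list columns),
# source.  Unparseable formulas are dropped and counted by the caller.
.makeRecords <- function(formula, category, class, source) {
  data.frame(
    formula = formula,
    categories = I(as.list(category)),
    classes = I(as.list(class)),
    source = rep_len(source, length(formula)),
    stringsAsFactors = FALSE
  )
}

.canonicalize <- function(formulas) {
  vapply(formulas, function(x) {
    tryCatch(formatFormula(parseFormula(x)), error = function(e) NA_character_)
  }, character(1L), USE.NAMES = FALSE)
}

# Minimal reader for the SDF tag-field dialect: entries separated by $$$$,
# data fields introduced by "> <NAME>".  Only tag fields are consumed; the
# structure block is ignored.
.readSdfTags <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entryId <- cumsum(c(TRUE, lines[-length(lines)] == "$$$$"))
  lapply(split(lines, entryId), function(entry) {
    tagAt <- grep("^> *<.*>", entry)
    if (length(tagAt) == 0L) return(list())
    tags <- sub("^> *<([^>]*)>.*$", "\\1", entry[tagAt])
    vals <- vapply(tagAt, function(i) {
      if (i + 1L <= length(entry)) trimws(entry[i + 1L]) else ""
    }, character(1L))
    stats::setNames(as.list(vals), tags)
  })
}

#' Load labeled lipid records
#'
#' Reads lipid records with formula, category and class fields from either
#' a tag-field SDF (LMSD-style export) or a TSV (LMISSD-style export).
#' Malformed entries (missing or unparseable formula, missing labels) are
#' skipped with a reported count; more than 50% skipped entries aborts,
#' since that usually means the field map does not match the export
#' dialect.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"sdf"`.
#' @param fieldMap Named list giving the formula, category and class field
#'   names (TSV column names or SDF tag names).
#' @param source Provenance tag stored on each record
#'   (`"lmsd"`, `"lmissd"`, `"hmdb"`, or `"synthetic"`).
#' @return Record `data.frame` (formula, categories, classes, source), one
#'   row per input entry, not yet de-duplicated.
#' @seealso [loadNonLipids()], [deduplicateRecords()], [buildTrainingSet()]
#' @export
loadLipidRecords <- function(path, format = c("tsv", "sdf"),
                             fieldMap = list(formula = "formula",
                                             category = "category",
                                             class = "class"),
                             source = "lmsd") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, colClasses = "character",
                        stringsAsFactors = FALSE),
      error = function(e) stop("unparseable TSV file ", path, ": ",
                               conditionMessage(e))
    )
    need <- unlist(fieldMap[c("formula", "category", "class")])
    if (!all(need %in% names(df))) {
      stop("field map names missing from ", path, ": ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    raw <- data.frame(formula = df[[fieldMap$formula]],
                      category = df[[fieldMap$category]],
                      class = df[[fieldMap$class]],
                      stringsAsFactors = FALSE)
  } else {
    entries <- .readSdfTags(path)
    raw <- do.call(rbind, lapply(entries, function(e) {
      g <- function(f) {
        v <- e[[fieldMap[[f]]]]
        if (is.null(v)) NA_character_ else v
      }
      data.frame(formula = g("formula"), category = g("category"),
                 class = g("class"), stringsAsFactors = FALSE)
    }))
    if (is.null(raw)) raw <- data.frame(formula = character(),
                                        category = character(),
                                        class = character())
  }
  canon <- .canonicalize(raw$formula)
  ok <- !is.na(canon) & nzchar(raw$category) & !is.na(raw$category) &
    nzchar(raw$class) & !is.na(raw$class)
  skipped <- sum(!ok)
  if (skipped > 0L) {
    message(skipped, " malformed entr", if (skipped == 1L) "y" else "ies",
            " skipped while reading ", path)
  }
  if (nrow(raw) > 0L && skipped > nrow(raw) / 2) {
    stop("more than half of the entries in ", path,
         " were skipped; is the field map right?")
  }
  .makeRecords(canon[ok], raw$category[ok], raw$class[ok], source)
}

#' Load non-lipid metabolite records
#'
#' Reads metabolite records from an HMDB-style XML export or a TSV, removes
#' entries matching the lipid filter, and labels everything that remains
#' with the extra category and class `non_lipid`.  These records serve as
#' true negatives during training.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"xml"`.
#' @param lipidFilter Either the taxonomy super-class string whose entries
#'   are removed (default `"Lipids and lipid-like molecules"`), or a
#'   predicate function over super-class strings returning `TRUE` for
#'   entries to remove.
#' @param fieldMap For TSV input, the formula and super-class column names;
#'   for XML, the element names of the metabolite node, formula node and
#'   super-class node.
#' @return Record `data.frame` with every row labeled `non_lipid`.
#' @export
loadNonLipids <- function(path, format = c("tsv", "xml"),
                          lipidFilter = "Lipids and lipid-like molecules",
                          fieldMap = list(entry = "metabolite",
                                          formula = "chemical_formula",
                                          superClass = "super_class")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(.makeRecords(character(), list(), list(),
                                            "hmdb")[0L, ])
    if (!fieldMap$formula %in% names(df)) {
      stop("no '", fieldMap$formula, "' column in ", path)
    }
    formulas <- df[[fieldMap$formula]]
    super <- if (fieldMap$superClass %in% names(df)) {
      df[[fieldMap$superClass]]
    } else {
      rep("", nrow(df))
    }
  } else {
    doc <- tryCatch(xml2::read_xml(path),
                    error = function(e) stop("unparseable XML file ", path,
                                             ": ", conditionMessage(e)))
    nodes <- xml2::xml_find_all(doc, paste0(".//", fieldMap$entry))
    formulas <- vapply(nodes, function(nd) {
      xml2::xml_text(xml2::xml_find_first(nd,
                                          paste0(".//", fieldMap$formula)))
    }, character(1L))
    super <- vapply(nodes, function(nd) {
      v <- xml2::xml_text(xml2::xml_find_first(nd,
                                               paste0(".//",
                                                      fieldMap$superClass)))
      if (is.na(v)) "" else v
    }, character(1L))
  }
  isLipid <- if (is.function(lipidFilter)) {
    vapply(super, lipidFilter, logical(1L), USE.NAMES = FALSE)
  } else {
    super %in% lipidFilter
  }
  formulas <- formulas[!isLipid]
  canon <- .canonicalize(formulas)
  skipped <- sum(is.na(canon))
  if (skipped > 0L) {
    message(skipped, " malformed non-lipid entr",
            if (skipped == 1L) "y" else "ies", " skipped in ", path)
  }
  if (length(canon) > 0L && skipped > length(canon) / 2) {
    stop("more than half of the entries in ", path, " were skipped")
  }
  canon <- canon[!is.na(canon)]
  .makeRecords(canon, rep(.NON_LIPID, length(canon)),
               rep(.NON_LIPID, length(canon)), "hmdb")
}

# Derive the class -> parent category map.  Rows with a single category
# pair unambiguously with all their classes; multi-category rows (merged
# isomer records) cannot tell which class belongs to which category, so
# they are only consulted for classes that never appear in an unambiguous
# row.  Genuinely conflicting parents keep the most frequent pairing with
# a warning.
.deriveClassParents <- function(records) {
  collectPairs <- function(singleOnly, wanted = NULL) {
    do.call(rbind, Map(function(cats, cls) {
      if (!is.null(wanted)) cls <- intersect(cls, wanted)
      if (length(cls) == 0L) return(NULL)
      if (singleOnly && length(cats) != 1L) return(NULL)
      expand.grid(class = cls, parent = cats, stringsAsFactors = FALSE)
    }, records$categories, records$classes))
  }
  majority <- function(pairs, warn) {
    if (is.null(pairs) || nrow(pairs) == 0L) {
      return(stats::setNames(character(), character()))
    }
    tab <- table(pairs$class, pairs$parent)
    parents <- colnames(tab)[apply(tab, 1L, which.max)]
    names(parents) <- rownames(tab)
    conflicted <- rowSums(tab > 0L) > 1L
    if (warn && any(conflicted)) {
      warning("class labels with conflicting parent categories: ",
              paste(rownames(tab)[conflicted], collapse = ", "),
              " (most frequent pairing kept)")
    }
    parents
  }
  parents <- majority(collectPairs(TRUE), warn = TRUE)
  orphans <- setdiff(unique(unlist(records$classes, use.names = FALSE)),
                     names(parents))
  if (length(orphans) > 0L) {
    parents <- c(parents,
                 majority(collectPairs(FALSE, wanted = orphans),
                          warn = FALSE))
  }
  parents
}

#' De-duplicate labeled records into a TrainingSet
#'
#' Isomers share a molecular formula but can belong to different lipid
#' categories and classes, so each distinct element-count map is collapsed
#' to a single record carrying the union of all labels observed for it.
#' A formula observed both as a lipid and as `non_lipid` keeps only its
#' lipid labels: lipid identity dominates, mirroring the removal of known
#' lipids from the non-lipid source.
#'
#' @param records Record `data.frame` as produced by [loadLipidRecords()],
#'   [loadNonLipids()] or [generateLabeledFormulas()].
#' @return A [TrainingSet-class].
#' @export
deduplicateRecords <- function(records) {
  if (nrow(records) == 0L) stop("no records to de-duplicate")
  classParent <- .deriveClassParents(records)
  idx <- split(seq_len(nrow(records)), records$formula)
  rows <- lapply(idx, function(i) {
    cats <- sort(unique(unlist(records$categories[i], use.names = FALSE)))
    cls <- sort(unique(unlist(records$classes[i], use.names = FALSE)))
    if (length(setdiff(cats, .NON_LIPID)) > 0L) {
      cats <- setdiff(cats, .NON_LIPID)
      cls <- setdiff(cls, .NON_LIPID)
    }
    list(formula = records$formula[i[1L]], categories = cats, classes = cls,
         source = paste(sort(unique(records$source[i])), collapse = "+"))
  })
  out <- data.frame(
    formula = vapply(rows, `[[`, character(1L), "formula"),
    categories = I(lapply(rows, `[[`, "categories")),
    classes = I(lapply(rows, `[[`, "classes")),
    source = vapply(rows, `[[`, character(1L), "source"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  catVocab <- sort(unique(unlist(out$categories, use.names = FALSE)))
  clsVocab <- sort(unique(unlist(out$classes, use.names = FALSE)))
  classParent <- classParent[intersect(names(classParent), clsVocab)]
  new("TrainingSet", records = out, categoryVocabulary = catVocab,
      classVocabulary = clsVocab, classParent = classParent)
}

#' Build a training set from lipid and non-lipid sources
#'
#' Concatenates the given record tables and de-duplicates them.  Formulas
#' present in both a lipid source and the non-lipid source keep only their
#' lipid labels.
#'
#' @param lipidSources List of record `data.frame`s from lipid databases.
#' @param nonLipidSource Record `data.frame` of non-lipid metabolites.
#' @param includeInsilico If `FALSE`, records whose source tag is
#'   `"lmissd"` (in-silico generated lipids) are excluded.
#' @return A [TrainingSet-class].
#' @export
buildTrainingSet <- function(lipidSources, nonLipidSource,
                             includeInsilico = TRUE) {
  if (is.data.frame(lipidSources)) lipidSources <- list(lipidSources)
  if (length(lipidSources) == 0L) stop("at least one lipid source required")
  all <- do.call(rbind, c(lipidSources, list(nonLipidSource)))
  if (!includeInsilico) all <- all[all$source != "lmissd", , drop = FALSE]
  if (nrow(all) == 0L) stop("empty union of training sources")
  deduplicateRecords(all)
}

#' Write / read a TrainingSet as TSV
#'
#' Serialized layout: one row per unique formula with pipe-joined category
#' and class labels plus the provenance tag, for inspection and re-loading.
#'
#' @param ts A [TrainingSet-class].
#' @param path File path.
#' @return `writeTrainingSet` returns `path` invisibly; `readTrainingSet`
#'   returns a [TrainingSet-class].
#' @export
writeTrainingSet <- function(ts, path) {
  df <- data.frame(
    formula = ts@records$formula,
    categories = vapply(ts@records$categories, paste, character(1L),
                        collapse = "|"),
    classes = vapply(ts@records$classes, paste, character(1L),
                     collapse = "|"),
    source = ts@records$source,
    stringsAsFactors = FALSE
  )
  # the class -> parent map is not recoverable from multi-label rows, so it
  # rides along as a comment line
  header <- paste0("# classParent: ",
                   paste(names(ts@classParent), ts@classParent,
                         sep = "=", collapse = "|"))
  writeLines(header, path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE)
  )
  invisible(path)
}

#' @rdname writeTrainingSet
#' @export
readTrainingSet <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "#")
  records <- .makeRecords(df$formula,
                          strsplit(df$categories, "|", fixed = TRUE),
                          strsplit(df$classes, "|", fixed = TRUE),
                          df$source)
  ts <- deduplicateRecords(records)
  first <- readLines(path, n = 1L)
  if (grepl("^# classParent: ", first)) {
    spec <- sub("^# classParent: ", "", first)
    if (nzchar(spec)) {
      kv <- strsplit(strsplit(spec, "|", fixed = TRUE)[[1L]], "=",
                     fixed = TRUE)
      parents <- vapply(kv, `[`, character(1L), 2L)
      names(parents) <- vapply(kv, `[`, character(1L), 1L)
      keep <- intersect(names(parents), ts@classVocabulary)
      ts@classParent <- parents[keep]
      validObject(ts)
    }
  }
  ts
}
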