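# Cross-sample assignment correspondence: a formula assigned in many
# samples of a dataset is far more likely to be a correct assignment than
# one appearing in a single spectrum, so the per-formula distinct-sample
# count at an E-value cutoff -- binned by m/z -- separates corroborated
# assignments from artifactual ones.

.DEFAULT_MZ_BREAKS <- c(0, 400, 800, 1200, 1600)

#' Load a per-sample formula-assignment table
#'
#' TSV with mandatory columns `sample_id`, `peak_mz`, `formula`, `e_value`
#' and an optional pipe-joined `labels` column of predicted categories.
#' Rows with non-positive m/z, negative E-value, or unreadable numbers are
#' skipped and counted.
#'
#' @param path Input TSV.
#' @return `data.frame` of assignment records with attribute `skipped`.
#' @export
loadAssignments <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "peak_mz", "formula", "e_value")
  if (!all(need %in% names(df))) {
    stop("assignment table ", path, " lacks mandatory column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!"labels" %in% names(df)) df$labels <- ""
  mz <- suppressWarnings(as.numeric(df$peak_mz))
  ev <- suppressWarnings(as.numeric(df$e_value))
  ok <- !is.na(mz) & mz > 0 & !is.na(ev) & ev >= 0 & nzchar(df$formula)
  skipped <- sum(!ok)
  if (skipped > 0L) {
    message(skipped, " malformed assignment row",
            if (skipped == 1L) "" else "s", " skipped in ", path)
  }
  out <- data.frame(
    sample_id = df$sample_id[ok],
    peak_mz = mz[ok],
    formula = df$formula[ok],
    e_value = ev[ok],
    labels = df$labels[ok],
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

.splitLabels <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, "|", fixed = TRUE)[[1L]]
}

#' Cross-sample correspondence of assigned formulas
#'
#' Retains records with `e_value <= eCutoff` (and, when `lipidOnly`, only
#' records whose label set contains a lipid category, i.e. anything other
#' than `non_lipid`), then counts the distinct samples each formula was
#' assigned in.  The representative m/z of a formula is the median of its
#' retained peak m/z values.
#'
#' @param records Assignment `data.frame` from [loadAssignments()] or
#'   [generateAssignments()].
#' @param eCutoff E-value cutoff; records above it are dropped.
#' @param lipidOnly Keep only lipid-classified records.
#' @return `data.frame` with one row per formula: `formula`, `n_samples`,
#'   `min_e`, `mz`, `labels` (pipe-joined union).
#' @seealso [correspondenceHistogram()], [compareShifted()]
#' @export
assignmentCorrespondence <- function(records, eCutoff = 0.1,
                                     lipidOnly = FALSE) {
  if (nrow(records) == 0L) stop("no assignment records")
  keep <- records$e_value <= eCutoff
  if (lipidOnly) {
    lab <- lapply(records$labels, .splitLabels)
    keep <- keep & vapply(lab, function(l) {
      length(setdiff(l, .NON_LIPID)) > 0L
    }, logical(1L))
  }
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(data.frame(formula = character(), n_samples = integer(),
                      min_e = numeric(), mz = numeric(),
                      labels = character(), stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(r)), r$formula)
  out <- data.frame(
    formula = names(idx),
    n_samples = vapply(idx, function(i) length(unique(r$sample_id[i])),
                       integer(1L)),
    min_e = vapply(idx, function(i) min(r$e_value[i]), numeric(1L)),
    mz = vapply(idx, function(i) stats::median(r$peak_mz[i]), numeric(1L)),
    labels = vapply(idx, function(i) {
      paste(sort(unique(unlist(lapply(r$labels[i], .splitLabels)))),
            collapse = "|")
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.binLabels <- function(breaks) {
  n <- length(breaks) - 1L
  vapply(seq_len(n), function(i) {
    close <- if (i == n) "]" else ")"
    sprintf("[%g,%g%s", breaks[i], breaks[i + 1L], close)
  }, character(1L))
}

.assignBins <- function(mz, breaks) {
  bins <- .binLabels(breaks)
  idx <- findInterval(mz, breaks, rightmost.closed = TRUE)
  lab <- rep("overflow", length(mz))
  inside <- idx >= 1L & idx <= length(bins)
  lab[inside] <- bins[idx[inside]]
  factor(lab, levels = c(bins, "overflow"))
}

#' Histogram of correspondence counts per m/z bin
#'
#' Places every formula in the m/z bin of its representative m/z and
#' tabulates, per bin, how many formulas were assigned in 1, 2, ...
#' samples.  Formulas outside all bins land in an `overflow` bin with a
#' message.  Default bins are 400 Da wide up to 1600.
#'
#' @param tab Correspondence table from [assignmentCorrespondence()].
#' @param breaks Ascending m/z bin edges.
#' @return `data.frame` with columns `bin`, `correspondence`, `n_formulas`.
#' @export
correspondenceHistogram <- function(tab, breaks = .DEFAULT_MZ_BREAKS) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("bin edges must be strictly ascending")
  }
  bins <- .binLabels(breaks)
  if (nrow(tab) == 0L) {
    return(data.frame(bin = factor(bins, levels = c(bins, "overflow")),
                      correspondence = NA_integer_, n_formulas = 0L))
  }
  binned <- .assignBins(tab$mz, breaks)
  if (any(binned == "overflow")) {
    message(sum(binned == "overflow"),
            " formulas outside the m/z bins placed in the overflow bin")
  }
  counts <- as.data.frame(base::table(bin = binned,
                                      correspondence = tab$n_samples),
                          stringsAsFactors = FALSE)
  counts$correspondence <- as.integer(counts$correspondence)
  counts$bin <- factor(counts$bin, levels = c(bins, "overflow"))
  names(counts)[names(counts) == "Freq"] <- "n_formulas"
  counts[order(counts$bin, counts$correspondence), , drop = FALSE]
}

#' Compare unshifted vs shifted correspondence tables
#'
#' Summarizes, per m/z bin, the mean and maximum correspondence of the two
#' tables, the number of formulas at or above a correspondence floor, and
#' the signed corroboration gap (unshifted mean minus shifted mean).  For
#' correct assignments the gap is positive: real formulas recur across
#' samples while artifactual assignments from miscalibrated spectra are
#' mostly sample-unique.  Empty bins contribute a mean of 0.
#'
#' @param unshifted,shifted Correspondence tables built with the same
#'   cutoff and filtering.
#' @param breaks m/z bin edges (must be the same binning for both tables).
#' @param floor Correspondence floor for the `n_above_floor` counts.
#' @return `data.frame` with one row per bin: means, maxima, floor counts
#'   for both tables and `gap`.
#' @export
compareShifted <- function(unshifted, shifted,
                           breaks = .DEFAULT_MZ_BREAKS, floor = 3L) {
  summarize <- function(tab, suffix) {
    bins <- .assignBins(tab$mz, breaks)
    lev <- levels(bins)
    agg <- function(f, default) {
      vapply(lev, function(b) {
        v <- tab$n_samples[bins == b]
        if (length(v) == 0L) default else f(v)
      }, numeric(1L))
    }
    out <- data.frame(
      bin = factor(lev, levels = lev),
      mean = agg(mean, 0),
      max = agg(max, 0),
      n_above_floor = agg(function(v) sum(v >= floor), 0)
    )
    names(out)[-1L] <- paste0(names(out)[-1L], suffix)
    out
  }
  u <- summarize(unshifted, "_unshifted")
  s <- summarize(shifted, "_shifted")
  out <- cbind(u, s[, -1L, drop = FALSE])
  out$gap <- out$mean_unshifted - out$mean_shifted
  # drop the overflow row when nothing landed there
  if (all(out$n_above_floor_unshifted[out$bin == "overflow"] == 0) &&
      !any(c(.assignBins(unshifted$mz, breaks),
             .assignBins(shifted$mz, breaks)) == "overflow")) {
    out <- out[out$bin != "overflow", , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an assignment or correspondence table to TSV
#'
#' @param df Table to write.
#' @param path Output path.
#' @export
writeAssignments <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
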