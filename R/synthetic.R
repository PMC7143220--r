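# Synthetic study data: labeled lipid-like and non-lipid formulas built
# from per-category composition rules, plus multi-sample assignment tables
# with recurring true formulas and per-sample decoys.  The rules are
# deliberate caricatures of each lipid category's elemental composition --
# engineered for class separability comparable to curated databases, not
# for chemical truth -- and every rule is overridable through the
# generator specification.

.SYNTH_CATEGORIES <- c("fatty_acyl", "glycerolipid", "glycerophospholipid",
                       "sphingolipid", "sterol", "prenol", "saccharolipid",
                       "polyketide", "non_lipid")

#' Generator specification for synthetic labeled formulas
#'
#' @param recordsPerLabel Records generated per category label.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param labels Category labels to generate (defaults to the eight lipid
#'   categories plus `non_lipid`).
#' @param overlap Fraction of records that additionally receive a second,
#'   neighboring category label, to stress-test precision (default 0).
#' @return A `GeneratorSpec` (list with class attribute).
#' @seealso [generateLabeledFormulas()]
#' @export
generatorSpec <- function(recordsPerLabel = 400L, seed = 1L,
                          labels = .SYNTH_CATEGORIES, overlap = 0) {
  stopifnot(recordsPerLabel >= 1L, overlap >= 0, overlap <= 1,
            all(labels %in% .SYNTH_CATEGORIES))
  structure(list(recordsPerLabel = as.integer(recordsPerLabel),
                 seed = as.integer(seed),
                 labels = labels,
                 overlap = overlap),
            class = "GeneratorSpec")
}

# One rule per category.  Each rule returns list(counts, class) for a
# single record; counts omit zero elements.
.acylChain <- function() {
  n <- sample(8:22, 1L)
  c(C = n, H = 2L * n - 2L, O = 1L)  # CnH2n-2O condensation residue
}

.synthRules <- list(
  fatty_acyl = function() {
    C <- sample(8:30, 1L)
    d <- sample(1:7, 1L)
    O <- sample(2:4, 1L)
    list(counts = c(C = C, H = 2L * C + 2L - 2L * d, O = O),
         class = if (O == 2L) "fatty_acid" else "oxygenated_fatty_acyl")
  },
  glycerolipid = function() {
    k <- sample(1:3, 1L)
    arms <- replicate(k, .acylChain())
    counts <- c(C = 3L + sum(arms["C", ]),
                H = 8L + sum(arms["H", ]),
                O = 3L + k)
    list(counts = counts,
         class = c("monoradylglycerol", "diradylglycerol",
                   "triradylglycerol")[k])
  },
  glycerophospholipid = function() {
    k <- sample(1:3, 1L)
    arms <- replicate(k, .acylChain())
    N <- sample(0:1, 1L)
    counts <- c(C = 3L + sum(arms["C", ]),
                H = 9L + sum(arms["H", ]),
                N = N,
                O = 6L + k,
                P = 1L)
    list(counts = counts[counts > 0L],
         class = if (N == 1L) "aminoglycerophospholipid" else
           "anionic_glycerophospholipid")
  },
  sphingolipid = function() {
    C <- sample(30:48, 1L)
    N <- sample(1:2, 1L)
    O <- sample(3:12, 1L)
    P <- stats::rbinom(1L, 1L, 0.25)
    d <- sample(1:6, 1L)
    counts <- c(C = C, H = 2L * C + 2L + N + P - 2L * d, N = N, O = O,
                P = P)
    cls <- if (P == 1L) "phosphosphingolipid" else if (O >= 7L)
      "glycosphingolipid" else "ceramide"
    list(counts = counts[counts > 0L], class = cls)
  },
  sterol = function() {
    C <- sample(27:30, 1L)
    d <- sample(5:8, 1L)
    O <- sample(1:3, 1L)
    list(counts = c(C = C, H = 2L * C + 2L - 2L * d, O = O),
         class = if (O == 1L) "sterol" else "steryl_conjugate")
  },
  prenol = function() {
    m <- sample(2:8, 1L)
    d <- sample(0:3, 1L)
    O <- sample(0:2, 1L)
    counts <- c(C = 5L * m, H = 8L * m - 2L * d, O = O)
    list(counts = counts[counts > 0L],
         class = if (O > 0L) "polyprenol" else "isoprenoid_hydrocarbon")
  },
  saccharolipid = function() {
    C <- sample(20:40, 1L)   # sugar core
    O <- sample(10:16, 1L)
    d <- sample(2:6, 1L)
    arms <- replicate(2L, .acylChain())
    counts <- c(C = C + sum(arms["C", ]),
                H = 2L * C + 2L - 2L * d + sum(arms["H", ]),
                O = O + 2L)
    list(counts = counts, class = "acylated_sugar")
  },
  polyketide = function() {
    C <- sample(10:30, 1L)
    O <- max(1L, round(C * stats::runif(1L, 0.2, 0.5)))
    d <- sample(4:min(12L, C), 1L)
    H <- 2L * C + 2L - 2L * d
    if (H < 2L) H <- 2L
    list(counts = c(C = C, H = H, O = O),
         class = if (d >= 8L) "aromatic_polyketide" else "macrolide")
  },
  non_lipid = function() {
    repeat {
      C <- sample(1:12, 1L)
      N <- sample(0:3, 1L)
      O <- sample(0:6, 1L)
      P <- stats::rbinom(1L, 1L, 0.2)
      S <- stats::rbinom(1L, 1L, 0.15)
      dmax <- max(0L, C + 1L)
      d <- sample(0:dmax, 1L)
      H <- max(0L, 2L * C + 2L + N + P - 2L * d)
      counts <- c(C = C, H = H, N = N, O = O, P = P, S = S)
      counts <- counts[counts > 0L]
      if (length(counts) == 0L) next
      if (monoisotopicMass(counts) < 350) {
        return(list(counts = counts, class = "non_lipid"))
      }
    }
  }
)

#' Generate labeled lipid-like and non-lipid formula records
#'
#' Draws `recordsPerLabel` formulas per category from the composition
#' rules (fatty acyls as CnH2n+2-2dO2..4; glycerolipids as a glycerol
#' backbone plus 1-3 acyl condensations; glycerophospholipids as a
#' glycerolipid core plus a phosphate and optional nitrogen; sphingolipids
#' as large nitrogenous formulas; sterols, prenols, saccharolipids and
#' polyketides analogously; plus small CHNOPS non-lipids under 350 Da).
#' Every record carries the label(s) of the rule that generated it; the
#' same formula can arise under two labels, exercising the multi-label
#' union semantics of de-duplication.
#'
#' @param spec A [generatorSpec()].
#' @return Record `data.frame` (formula, categories, classes, source =
#'   `"synthetic"`), one row per generated record, not de-duplicated.
#' @export
generateLabeledFormulas <- function(spec = generatorSpec()) {
  stopifnot(inherits(spec, "GeneratorSpec"))
  .withSeed(spec$seed, {
    rows <- lapply(spec$labels, function(lb) {
      rule <- .synthRules[[lb]]
      recs <- lapply(seq_len(spec$recordsPerLabel), function(i) rule())
      data.frame(
        formula = vapply(recs, function(r) formatFormula(r$counts),
                         character(1L)),
        category = lb,
        class = vapply(recs, `[[`, character(1L), "class"),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
    cats <- as.list(df$category)
    cls <- as.list(df$class)
    if (spec$overlap > 0) {
      lipid <- setdiff(spec$labels, .NON_LIPID)
      flip <- which(stats::runif(nrow(df)) < spec$overlap &
                      df$category != .NON_LIPID)
      for (i in flip) {
        extra <- sample(setdiff(lipid, df$category[i]), 1L)
        cats[[i]] <- c(cats[[i]], extra)
      }
    }
    .makeRecords(df$formula, cats, cls, "synthetic")
  })
}

.randomChonpsFormula <- function(maxMass = 1600) {
  repeat {
    C <- sample(1:80, 1L)
    N <- sample(0:3, 1L)
    O <- sample(0:20, 1L)
    P <- stats::rbinom(1L, 1L, 0.15)
    S <- stats::rbinom(1L, 1L, 0.1)
    H <- sample(0:(2L * C + 2L + N + P), 1L)
    counts <- c(C = C, H = H, N = N, O = O, P = P, S = S)
    counts <- counts[counts > 0L]
    if (monoisotopicMass(counts) < maxMass) return(counts)
  }
}

#' Generate multi-sample assignment tables with known ground truth
#'
#' Emulates the per-sample formula-assignment lists an untargeted FT-MS
#' assignment tool produces.  True formulas are lipid-labeled records from
#' the composition rules, sampled stratified across the default m/z bins
#' so every bin contains recurring lipid-classified formulas; each appears
#' in a sample with probability `recurrence` and a low-mode E-value.
#' Decoys are per-sample random CHONPS formulas at higher-mode E-values,
#' carrying a lipid label with probability 0.35 (miscalibrated spectra
#' still get classified).  With `shifted = TRUE` the table emulates a
#' gross mass miscalibration: true formulas no longer corroborate (each
#' appears in a single sample) and the decoy count grows by 5%.
#'
#' @param nSamples Number of samples.
#' @param nTrueFormulas Number of recurring true formulas (stratified over
#'   the four default m/z bins).
#' @param recurrence Per-sample inclusion probability of a true formula.
#' @param decoysPerSample Decoy assignments per sample.
#' @param shifted Emulate the miscalibrated (shifted) dataset.
#' @param seed Integer seed.
#' @return Assignment `data.frame` with columns `sample_id`, `peak_mz`,
#'   `formula`, `e_value`, `labels`.
#' @seealso [assignmentCorrespondence()], [compareShifted()]
#' @export
generateAssignments <- function(nSamples = 10L, nTrueFormulas = 60L,
                                recurrence = 0.8, decoysPerSample = 40L,
                                shifted = FALSE, seed = 1L) {
  stopifnot(nSamples >= 1L, nTrueFormulas >= 4L, recurrence > 0,
            recurrence <= 1, decoysPerSample >= 0L)
  .withSeed(seed + 77L * shifted, {
    pool <- generateLabeledFormulas(generatorSpec(recordsPerLabel = 200L,
                                                  seed = seed + 13L))
    lipid <- lengths(lapply(pool$categories, setdiff, .NON_LIPID)) > 0L
    pool <- pool[lipid, , drop = FALSE]
    pool <- pool[!duplicated(pool$formula), , drop = FALSE]
    mass <- vapply(pool$formula, function(f) monoisotopicMass(f),
                   numeric(1L), USE.NAMES = FALSE)
    bin <- findInterval(mass, .DEFAULT_MZ_BREAKS, rightmost.closed = TRUE)
    perBin <- ceiling(nTrueFormulas / 4)
    trueIdx <- unlist(lapply(1:4, function(b) {
      cand <- which(bin == b)
      if (length(cand) < perBin) {
        stop("generator rule infeasibility: only ", length(cand),
             " candidate true formulas in m/z bin ", b)
      }
      sample(cand, perBin)
    }))
    trueIdx <- trueIdx[seq_len(min(length(trueIdx), nTrueFormulas))]
    if (shifted) decoysPerSample <- as.integer(round(decoysPerSample * 1.05))
    samples <- sprintf("S%02d", seq_len(nSamples))
    rows <- list()
    for (ti in trueIdx) {
      present <- if (shifted) {
        samples[sample(nSamples, 1L)]
      } else {
        samples[stats::runif(nSamples) < recurrence]
      }
      if (length(present) == 0L) present <- samples[sample(nSamples, 1L)]
      labs <- paste(pool$categories[[ti]], collapse = "|")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = present,
        peak_mz = mass[ti] + stats::rnorm(length(present), 0, 2e-4),
        formula = pool$formula[ti],
        e_value = pmin(1, stats::rlnorm(length(present), log(0.02), 0.8)),
        labels = labs,
        stringsAsFactors = FALSE
      )
    }
    lipidLabels <- setdiff(.SYNTH_CATEGORIES, .NON_LIPID)
    for (s in samples) {
      if (decoysPerSample == 0L) next
      dec <- replicate(decoysPerSample, .randomChonpsFormula(),
                       simplify = FALSE)
      labs <- vapply(seq_along(dec), function(i) {
        u <- stats::runif(1L)
        if (u < 0.35) sample(lipidLabels, 1L)
        else if (u < 0.70) .NON_LIPID
        else ""
      }, character(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s,
        peak_mz = vapply(dec, monoisotopicMass, numeric(1L)) +
          stats::rnorm(decoysPerSample, 0, 2e-4),
        formula = vapply(dec, formatFormula, character(1L)),
        e_value = pmin(1, stats::rlnorm(decoysPerSample, log(0.25), 0.8)),
        labels = labs,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write synthetic records as a tag-field SDF fixture
#'
#' Produces a minimal SDF in the tag-field dialect consumed by
#' [loadLipidRecords()]: a stub header and the formula/category/class data
#' fields (no structure block).  Intended for fixtures and round-trip
#' tests; labeled synthetic, never a database export.
#'
#' @param records Record `data.frame` (single-label rows are written; the
#'   first category/class of each row is used).
#' @param path Output path.
#' @param tags Tag names for the three fields.
#' @export
writeSdf <- function(records, path,
                     tags = c(formula = "FORMULA", category = "CATEGORY",
                              class = "MAIN_CLASS")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(
      paste0("SYNTH-", i), "  synthetic", "",
      "  0  0  0  0  0  0  0  0  0  0999 V2000", "M  END",
      paste0("> <", tags[["formula"]], ">"), records$formula[i], "",
      paste0("> <", tags[["category"]], ">"),
      records$categories[[i]][1L], "",
      paste0("> <", tags[["class"]], ">"), records$classes[[i]][1L], "",
      "$$$$"), con)
  }
  invisible(path)
}

#' Write synthetic records as an HMDB-style XML fixture
#'
#' Minimal metabolite XML (synthetic, not a database export) readable by
#' [loadNonLipids()]: one `<metabolite>` node per record with a
#' `<chemical_formula>` and a taxonomy `<super_class>`.
#'
#' @param records Record `data.frame`.
#' @param path Output path.
#' @param superClass Character vector (recycled) of taxonomy super-class
#'   strings; use `"Lipids and lipid-like molecules"` to mark entries the
#'   default lipid filter should remove.
#' @export
writeHmdbXml <- function(records, path, superClass = "Organic acids") {
  superClass <- rep_len(superClass, nrow(records))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    gsub("<", "&lt;", x, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<hmdb>")
  for (i in seq_len(nrow(records))) {
    lines <- c(lines,
               "  <metabolite>",
               paste0("    <accession>SYNTH", sprintf("%05d", i),
                      "</accession>"),
               paste0("    <chemical_formula>", esc(records$formula[i]),
                      "</chemical_formula>"),
               "    <taxonomy>",
               paste0("      <super_class>", esc(superClass[i]),
                      "</super_class>"),
               "    </taxonomy>",
               "  </metabolite>")
  }
  writeLines(c(lines, "</hmdb>"), path)
  invisible(path)
}
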