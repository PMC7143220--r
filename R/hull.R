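# Convex hull over molecular formulas viewed as integer lattice points in
# CHONPS space, and enumeration of every lattice point inside the hull.
# The hull is built with an incremental beneath-beyond algorithm working in
# the affine subspace actually spanned by the points, so rank-deficient
# inputs (e.g. all points sharing a sulfur count) become equality
# constraints rather than failures.  Enumeration scans the integer bounding
# box in lexicographic order with interval pruning from the facet
# inequalities, which preserves the exact output set of an unpruned scan.

# --- geometry helpers -------------------------------------------------------

# Orthonormal basis of the affine span of pts; rank decided by SVD.
.affineFrame <- function(pts, tol = 1e-9) {
  center <- colMeans(pts)
  x <- sweep(pts, 2L, center)
  s <- svd(x, nu = 0L, nv = ncol(x))  # full V even when n < d
  scale <- max(s$d, 1)
  r <- sum(s$d > tol * scale)
  d <- ncol(pts)
  list(center = center,
       basis = s$v[, seq_len(r), drop = FALSE],
       null = if (r < d) s$v[, seq(r + 1L, d), drop = FALSE] else
         matrix(numeric(), nrow = d, ncol = 0L),
       rank = r)
}

# Unit normal of the hyperplane through the rows of v (r points in r-space),
# or NULL if they are affinely dependent.
.facetNormal <- function(v, tol = 1e-9) {
  r <- ncol(v)
  m <- sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])
  s <- svd(m, nu = 0L, nv = r)
  if (r > 1L && s$d[r - 1L] <= tol * max(s$d[1L], 1)) return(NULL)
  s$v[, r]
}

# Greedy selection of r+1 affinely independent rows of y (full rank r).
.initialSimplex <- function(y, tol = 1e-9) {
  n <- nrow(y)
  r <- ncol(y)
  picked <- 1L
  for (step in seq_len(r)) {
    base <- y[picked, , drop = FALSE]
    dirs <- if (length(picked) == 1L) {
      matrix(numeric(), nrow = 0L, ncol = r)
    } else {
      sweep(base[-1L, , drop = FALSE], 2L, base[1L, ])
    }
    q <- if (nrow(dirs) > 0L) qr(t(dirs)) else NULL
    resid <- vapply(seq_len(n), function(i) {
      v <- y[i, ] - base[1L, ]
      if (!is.null(q)) v <- v - qr.fitted(q, v)
      sqrt(sum(v^2))
    }, numeric(1L))
    resid[picked] <- 0
    best <- which.max(resid)
    if (resid[best] <= tol) stop("points are not full rank in the frame")
    picked <- c(picked, best)
  }
  picked
}

# Beneath-beyond hull of full-rank points y (n x r, r >= 2).  Returns a
# list of facets: vertex index sets, unit normals, offsets (a.x <= b).
.beneathBeyond <- function(y, tol) {
  r <- ncol(y)
  simplex <- .initialSimplex(y)
  c0 <- colMeans(y[simplex, , drop = FALSE])
  mkFacet <- function(vidx) {
    a <- .facetNormal(y[vidx, , drop = FALSE])
    if (is.null(a)) return(NULL)
    b <- sum(a * y[vidx[1L], ])
    if (sum(a * c0) > b) {
      a <- -a
      b <- -b
    }
    list(v = sort(vidx), a = a, b = b)
  }
  facets <- list()
  for (drop in seq_along(simplex)) {
    f <- mkFacet(simplex[-drop])
    if (is.null(f)) stop("degenerate initial simplex")
    facets[[length(facets) + 1L]] <- f
  }
  rest <- setdiff(seq_len(nrow(y)), simplex)
  for (i in rest) {
    p <- y[i, ]
    vis <- which(vapply(facets, function(f) sum(f$a * p) - f$b > tol,
                        logical(1L)))
    if (length(vis) == 0L) next
    # horizon ridges: (r-1)-subsets appearing in exactly one visible facet
    ridges <- do.call(rbind, lapply(vis, function(fi) {
      v <- facets[[fi]]$v
      m <- vapply(seq_along(v), function(j) v[-j], integer(length(v) - 1L))
      if (is.matrix(m)) t(m) else matrix(m, ncol = 1L)
    }))
    key <- apply(ridges, 1L, paste, collapse = ",")
    horizon <- ridges[key %in% names(which(table(key) == 1L)), ,
                      drop = FALSE]
    newFacets <- list()
    for (h in seq_len(nrow(horizon))) {
      f <- mkFacet(c(horizon[h, ], i))
      if (is.null(f)) next  # coplanar sliver; neighbors cover it
      newFacets[[length(newFacets) + 1L]] <- f
    }
    facets <- c(facets[-vis], newFacets)
  }
  facets
}

#' Build a convex hull around formulas in element-count space
#'
#' Each molecular formula is a point in an integer lattice (one dimension
#' per element, CHONPS by default).  Generator points at or above the mass
#' limit are excluded first, mirroring how the hull of plausible
#' biological formulas is anchored to database entries below 1600 Da;
#' enumerated interior points are not mass-filtered unless requested at
#' enumeration/classification time.
#'
#' @param points Character vector of formulas, or an integer matrix of
#'   lattice coordinates (one row per point).
#' @param massLimit Generator points with monoisotopic mass `>= massLimit`
#'   (Da) are excluded before hull construction; `NULL` disables the
#'   filter (always disabled for bare coordinate matrices).
#' @param table Isotope mass table (for the mass filter).
#' @param elements Lattice dimensions when `points` are formulas; formulas
#'   containing any other element are excluded (the hull is CHONPS-only).
#' @return A [HullRegion-class].
#' @examples
#' sq <- buildHull(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
#' nrow(enumerateLattice(sq))  # 9: the 3 x 3 grid
#' @export
buildHull <- function(points, massLimit = 1600, table = isotopeMassTable(),
                      elements = .CHONPS) {
  if (is.character(points)) {
    parsed <- lapply(points, parseFormula)
    keep <- vapply(parsed, function(f) all(names(f) %in% elements),
                   logical(1L))
    if (any(!keep)) {
      message(sum(!keep), " formulas with elements outside (",
              paste(elements, collapse = ""), ") excluded from the hull")
    }
    parsed <- parsed[keep]
    if (!is.null(massLimit)) {
      mass <- vapply(parsed, monoisotopicMass, numeric(1L), table = table)
      heavy <- mass >= massLimit
      if (any(heavy)) {
        message(sum(heavy), " generator formulas at or above ", massLimit,
                " Da excluded")
      }
      parsed <- parsed[!heavy]
    }
    pts <- matrix(0, nrow = length(parsed), ncol = length(elements),
                  dimnames = list(NULL, elements))
    for (i in seq_along(parsed)) {
      f <- parsed[[i]]
      pts[i, names(f)] <- f
    }
  } else {
    pts <- as.matrix(points)
    storage.mode(pts) <- "double"
  }
  pts <- unique(pts)
  d <- ncol(pts)
  if (nrow(pts) < 2L) {
    if (nrow(pts) == 0L) stop("no points left to build a hull from")
    # single point: pure equality constraints
    return(new("HullRegion",
               normals = matrix(numeric(), 0L, d),
               offsets = numeric(),
               eqNormals = diag(d),
               eqOffsets = as.numeric(pts[1L, ]),
               vertices = pts,
               bbox = rbind(pts[1L, ], pts[1L, ]),
               dimension = as.integer(d)))
  }
  frame <- .affineFrame(pts)
  r <- frame$rank
  scale <- max(abs(pts), 1)
  tol <- 1e-7 * scale
  y <- sweep(pts, 2L, frame$center) %*% frame$basis
  if (r == 0L) stop("degenerate point set")
  if (r == 1L) {
    facetsA <- rbind(1, -1)
    facetsB <- c(max(y), -min(y))
    vertIdx <- c(which.max(y), which.min(y))
  } else {
    if (nrow(pts) < r + 1L) stop("too few points for a hull of rank ", r)
    facets <- .beneathBeyond(y, tol)
    facetsA <- do.call(rbind, lapply(facets, `[[`, "a"))
    facetsB <- vapply(facets, `[[`, numeric(1L), "b")
    vertIdx <- sort(unique(unlist(lapply(facets, `[[`, "v"))))
  }
  # map inequalities from frame coordinates back to the ambient lattice:
  # a.(B'(x - center)) <= b  <=>  (B a).x <= b + (B a).center
  normals <- facetsA %*% t(frame$basis)
  offsets <- facetsB + drop(normals %*% frame$center)
  eqN <- t(frame$null)
  eqB <- drop(eqN %*% frame$center)
  vertices <- pts[vertIdx, , drop = FALSE]
  hull <- new("HullRegion",
              normals = normals,
              offsets = offsets,
              eqNormals = eqN,
              eqOffsets = as.numeric(eqB),
              vertices = vertices,
              bbox = rbind(floor(apply(vertices, 2L, min) + 0.5),
                           floor(apply(vertices, 2L, max) + 0.5)),
              dimension = as.integer(d))
  inside <- hullContains(hull, pts)
  if (!all(inside)) {
    stop("hull construction failed: ", sum(!inside),
         " generator points fall outside the facet representation")
  }
  hull
}

.facetEps <- function(hull) 1e-9 * pmax(1, abs(hull@offsets))

#' Test lattice points for hull membership
#'
#' A point is inside when every facet inequality holds within a tolerance
#' of `1e-9` scaled by the facet offset magnitude, so boundary lattice
#' points (including the hull's own generators) count as inside.
#'
#' @param hull A [HullRegion-class].
#' @param points Numeric vector (one point) or matrix (one row per point).
#' @return Logical vector.
#' @export
hullContains <- function(hull, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != hull@dimension) {
    stop("points have dimension ", ncol(points), ", hull has ",
         hull@dimension)
  }
  ok <- rep(TRUE, nrow(points))
  if (nrow(hull@eqNormals) > 0L) {
    dev <- abs(sweep(points %*% t(hull@eqNormals), 2L, hull@eqOffsets))
    ok <- ok & apply(dev <= 1e-7, 1L, all)
  }
  if (nrow(hull@normals) > 0L) {
    slack <- sweep(points %*% t(hull@normals), 2L, hull@offsets)
    eps <- .facetEps(hull)
    ok <- ok & apply(sweep(slack, 2L, eps, `<=`), 1L, all)
  }
  ok
}

# All constraints as A x <= b with the membership tolerance folded in.
.hullInequalities <- function(hull) {
  a <- hull@normals
  b <- hull@offsets + .facetEps(hull)
  if (nrow(hull@eqNormals) > 0L) {
    a <- rbind(a, hull@eqNormals, -hull@eqNormals)
    b <- c(b, hull@eqOffsets + 1e-7, -hull@eqOffsets + 1e-7)
  }
  list(a = a, b = b)
}

#' Enumerate every lattice point inside a hull
#'
#' Scans the integer bounding box in lexicographic coordinate order,
#' pruning subtrees whose partial coordinate prefix already violates a
#' facet inequality for every completion inside the box.  Pruning changes
#' the cost, never the output: the result is exactly the set of integer
#' points `p` with `hullContains(hull, p)`.
#'
#' @param hull A [HullRegion-class].
#' @param callback Optional function called with successive chunks
#'   (matrices of lattice points); when supplied, points are streamed and
#'   not accumulated, and the total count is returned.
#' @param chunkSize Rows per callback chunk.
#' @return Integer matrix of lattice points (lexicographic order), or the
#'   total count when `callback` is given.
#' @export
enumerateLattice <- function(hull, callback = NULL, chunkSize = 8192L) {
  d <- hull@dimension
  lo <- hull@bbox[1L, ]
  hi <- hull@bbox[2L, ]
  cons <- .hullInequalities(hull)
  a <- cons$a
  b <- cons$b
  nc <- nrow(a)
  buf <- matrix(0L, nrow = chunkSize, ncol = d)
  nbuf <- 0L
  total <- 0L
  out <- list()
  flush <- function() {
    if (nbuf == 0L) return(invisible())
    chunk <- buf[seq_len(nbuf), , drop = FALSE]
    if (is.null(callback)) {
      out[[length(out) + 1L]] <<- chunk
    } else {
      callback(chunk)
    }
    total <<- total + nbuf
    nbuf <<- 0L
    invisible()
  }
  point <- numeric(d)
  # contribution bounds of the remaining free dimensions for every row
  freeMin <- function(j) {
    if (j > d) return(numeric(nc))
    cols <- seq(j, d)
    sub <- a[, cols, drop = FALSE]
    rowSums(pmin(sub * rep(lo[cols], each = nc),
                 sub * rep(hi[cols], each = nc)))
  }
  recurse <- function(j, fixedContrib) {
    rem <- freeMin(j + 1L)
    # feasible interval for coordinate j from every constraint
    lb <- lo[j]
    ub <- hi[j]
    for (rr in seq_len(nc)) {
      coef <- a[rr, j]
      slack <- b[rr] - fixedContrib[rr] - rem[rr]
      if (abs(coef) < 1e-12) {
        if (slack < 0) return(invisible())
      } else if (coef > 0) {
        ub <- min(ub, floor(slack / coef + 1e-9))
      } else {
        lb <- max(lb, ceiling(slack / coef - 1e-9))
      }
    }
    if (lb > ub) return(invisible())
    for (v in lb:ub) {
      point[j] <<- v
      contrib <- fixedContrib + a[, j] * v
      if (j == d) {
        if (all(contrib <= b + 1e-12)) {
          if (nbuf == chunkSize) flush()
          nbuf <<- nbuf + 1L
          buf[nbuf, ] <<- point
        }
      } else {
        recurse(j + 1L, contrib)
      }
    }
    invisible()
  }
  if (all(lo <= hi)) recurse(1L, numeric(nc))
  flush()
  if (is.null(callback)) {
    res <- if (length(out) == 0L) {
      matrix(integer(), 0L, d)
    } else {
      do.call(rbind, out)
    }
    colnames(res) <- colnames(hull@bbox)
    res
  } else {
    total
  }
}

#' Classify every formula inside a hull and tally the fired labels
#'
#' Streams the enumerated lattice points through featurization and the
#' hierarchical classifier, producing a per-label tally (label,
#' predictions, percent of hull formulas).  Points with zero atoms are
#' skipped.  Because a formula can fire several categories, tallies plus
#' the no-category count can exceed the point count.
#'
#' @param hull A [HullRegion-class] whose dimensions are the CHONPS
#'   elements (in that order).
#' @param model A [LipidHierarchyModel-class].
#' @param threshold Vote-fraction threshold.
#' @param table Isotope mass table.
#' @param level `"category"` or `"class"`.
#' @param massLimitEnumerated Optional mass cutoff (Da) applied to the
#'   enumerated formulas themselves before classification; by default
#'   interior points are classified regardless of mass.
#' @param chunkSize Lattice points classified per streamed chunk.
#' @return Tally `data.frame` with columns `label, predictions, percent`
#'   and attribute `nFormulas` (number of classified lattice formulas).
#' @export
classifyHull <- function(hull, model, threshold = 0.5,
                         table = isotopeMassTable(),
                         level = c("category", "class"),
                         massLimitEnumerated = NULL, chunkSize = 8192L) {
  level <- match.arg(level)
  stopifnot(hull@dimension == 6L)
  universe <- if (level == "category") {
    names(model@categoryModels)
  } else {
    names(model@classModels)
  }
  counts <- stats::setNames(rep(0, length(universe)), universe)
  noCat <- 0
  nFormulas <- 0
  k <- model@featureConfig$k
  consume <- function(chunk) {
    keep <- rowSums(chunk) > 0L
    chunk <- chunk[keep, , drop = FALSE]
    if (nrow(chunk) == 0L) return(invisible())
    feats <- .featuresFromCounts(chunk, table = table, k = k)
    if (!is.null(massLimitEnumerated)) {
      feats <- feats[feats$mass < massLimitEnumerated, , drop = FALSE]
      if (nrow(feats) == 0L) return(invisible())
    }
    attr(feats, "k") <- k
    attr(feats, "tableVersion") <- .tableVersion(table)
    pred <- predictLabels(model, feats, threshold = threshold)
    sets <- if (level == "category") pred$categories else pred$classes
    fired <- unlist(sets, use.names = FALSE)
    if (length(fired) > 0L) {
      tt <- base::table(fired)
      counts[names(tt)] <<- counts[names(tt)] + as.numeric(tt)
    }
    noCat <<- noCat + sum(lengths(sets) == 0L)
    nFormulas <<- nFormulas + nrow(feats)
    invisible()
  }
  enumerateLattice(hull, callback = consume, chunkSize = chunkSize)
  out <- data.frame(
    label = c(universe, "no category"),
    predictions = c(as.numeric(counts), noCat),
    stringsAsFactors = FALSE
  )
  out$percent <- if (nFormulas > 0) 100 * out$predictions / nFormulas else 0
  attr(out, "nFormulas") <- nFormulas
  out
}
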