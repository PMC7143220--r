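# Independent oracles and shared fixtures.  The oracles restate their own
# reference data and use none of the package's computation paths.

# Per-atom mass summation with its own copy of the most-abundant-isotope
# masses, written independently of the package's vectorized lookup.
oracleMass <- function(formulaString) {
  ref <- list(C = 12.0, H = 1.00782503207, N = 14.0030740048,
              O = 15.9949146196, P = 30.97376163, S = 31.97207100)
  total <- 0
  rest <- formulaString
  while (nzchar(rest)) {
    sym <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    rest <- sub("^[A-Z][a-z]?", "", rest)
    num <- regmatches(rest, regexpr("^[0-9]*", rest))
    rest <- sub("^[0-9]*", "", rest)
    count <- if (nzchar(num)) as.integer(num) else 1L
    for (i in seq_len(count)) total <- total + ref[[sym]]
  }
  total
}

# Convex-combination (Caratheodory) membership test: p is in the hull of
# pts iff some affinely independent subset of at most d+1 points carries a
# non-negative barycentric representation of p.  Least-squares solve plus
# residual check handles lower-dimensional faces.
oracleInHull <- function(pts, p, tol = 1e-7) {
  d <- ncol(pts)
  n <- nrow(pts)
  target <- c(p, 1)
  for (k in seq_len(min(n, d + 1L))) {
    subsets <- utils::combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      v <- pts[subsets[, j], , drop = FALSE]
      a <- rbind(t(v), rep(1, k))
      lam <- tryCatch(qr.solve(a, target, tol = 1e-12),
                      error = function(e) NULL)
      if (is.null(lam)) next
      if (all(lam >= -tol) && max(abs(a %*% lam - target)) < tol) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Lattice-point count of a convex lattice polygon via Pick's theorem:
# interior + boundary = A + B/2 + 1.
oraclePickCount <- function(vertices) {
  ctr <- colMeans(vertices)
  ord <- order(atan2(vertices[, 2] - ctr[2], vertices[, 1] - ctr[1]))
  v <- vertices[ord, , drop = FALSE]
  nv <- nrow(v)
  nxt <- c(seq_len(nv)[-1L], 1L)
  area2 <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2]))
  boundary <- sum(vapply(seq_len(nv), function(i) {
    dx <- abs(v[nxt[i], 1] - v[i, 1])
    dy <- abs(v[nxt[i], 2] - v[i, 2])
    if (dx + dy == 0) 0L else .gcd(dx, dy)
  }, integer(1L)))
  area2 / 2 + boundary / 2 + 1
}

.gcd <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# Shared fixtures: the default synthetic study (the stand-in for curated
# database training) is expensive, so it is built once per test run.
.fixtures <- new.env(parent = emptyenv())

defaultTrainingSet <- function() {
  if (is.null(.fixtures$ts)) {
    .fixtures$ts <- deduplicateRecords(
      generateLabeledFormulas(generatorSpec(recordsPerLabel = 400L,
                                            seed = 1L)))
  }
  .fixtures$ts
}

fullHierarchyModel <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- trainHierarchy(defaultTrainingSet(), nTrees = 500L,
                                      seed = 1L)
  }
  .fixtures$model
}

smallTrainingSet <- function() {
  if (is.null(.fixtures$smallTs)) {
    .fixtures$smallTs <- deduplicateRecords(
      generateLabeledFormulas(generatorSpec(recordsPerLabel = 60L,
                                            seed = 11L)))
  }
  .fixtures$smallTs
}

smallHierarchyModel <- function() {
  if (is.null(.fixtures$smallModel)) {
    .fixtures$smallModel <- suppressWarnings(
      trainHierarchy(smallTrainingSet(), nTrees = 80L, seed = 5L,
                     minPositives = 5L))
  }
  .fixtures$smallModel
}

randomChonpsCounts <- function() {
  counts <- c(C = sample(1:60, 1L), H = sample(1:120, 1L),
              N = sample(0:4, 1L), O = sample(0:15, 1L),
              P = sample(0:2, 1L), S = sample(0:2, 1L))
  counts[counts > 0L]
}
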