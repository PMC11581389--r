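# Shared fixtures, all generated in code.

# Small fully observed cohort with a mild signal, for plumbing tests.
makeCohort <- function(nPos = 12, nNeg = 28, delta = 0, seed = 1,
                       horizon = "5y") {
  if (delta > 0)
    simulateSeparableCohort(c(nPos, nNeg), 5, delta, seed,
                            horizon = horizon)$cohort
  else
    simulateCohort(simulationConfig(c(nPos, nNeg), seed = seed,
                                    horizon = horizon))
}

# Plain numeric matrix cohort for geometry tests (values handed straight to
# layout operations).
randomMatrix <- function(n, p, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(matrix(runif(n * p), n, p,
                    dimnames = list(NULL, paste0("f", seq_len(p)))))
}

# Brute-force convex hull: a point is a vertex iff it is not inside the
# hull of the others (O(m^3) via linear programming-free test: point inside
# triangle of any 3 others).
bruteHullVertices <- function(pts) {
  m <- nrow(pts)
  inTriangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
      (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
  }
  vapply(seq_len(m), function(i) {
    others <- setdiff(seq_len(m), i)
    combs <- combn(others, 3)
    !any(vapply(seq_len(ncol(combs)), function(k)
      inTriangle(pts[i, ], pts[combs[1, k], ], pts[combs[2, k], ],
                 pts[combs[3, k], ]), TRUE))
  }, TRUE)
}

# Exhaustive minimum-area rectangle over a dense orientation sweep.
sweepMinRectArea <- function(pts, step = 0.01) {
  angles <- seq(0, 90 - step, by = step)
  areas <- vapply(angles, function(a) {
    r <- a * pi / 180
    R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
    q <- pts %*% R
    diff(range(q[, 1])) * diff(range(q[, 2]))
  }, 0)
  min(areas)
}

# AUC by exhaustive pair counting: concordant + half ties over all
# positive-negative pairs.
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Tiny image set with deterministic content.
makeImages <- function(n = 2, grid = c(30, 30), seed = 1) {
  set.seed(seed)
  arr <- array(runif(prod(grid) * n), c(grid, n))
  new("PatientImageSet", pixels = arr,
      patientIds = sprintf("I%02d", seq_len(n)))
}
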