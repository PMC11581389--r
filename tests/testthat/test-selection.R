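# selection_classifier: rank-sum filter, Gini median rule, stability
# intersection, linear SVM.

test_that("rank-sum filter agrees with wilcox.test on both code paths", {
  set.seed(3)
  g <- rep(c(0L, 1L), c(9, 7))
  # tie-free columns: exact path
  x <- matrix(rnorm(16 * 40), 16)
  f <- univariateFilter(x, g)
  ref <- apply(x, 2, function(v)
    wilcox.test(v[g == 1], v[g == 0], exact = TRUE)$p.value)
  expect_equal(f$pValues, ref, tolerance = 1e-12)

  # tied columns: tie-corrected normal approximation
  xt <- matrix(sample(0:3, 16 * 40, replace = TRUE), 16)
  ft <- univariateFilter(xt, g)
  reft <- apply(xt, 2, function(v)
    suppressWarnings(wilcox.test(v[g == 1], v[g == 0], exact = FALSE,
                                 correct = FALSE)$p.value))
  expect_equal(ft$pValues, reft, tolerance = 1e-12)

  # n1 = n2 = 3 fully separated: exact two-sided p from the 20 assignments
  sep <- matrix(c(1, 2, 3, 10, 11, 12), 6)
  fe <- univariateFilter(sep, c(0, 0, 0, 1, 1, 1))
  enum <- combn(6, 3)
  v <- sep[, 1]
  stats <- apply(enum, 2, function(idx) sum(rank(v)[idx]))
  obs <- sum(rank(v)[4:6])
  pEnum <- min(1, 2 * mean(stats >= obs))
  expect_equal(fe$pValues, pEnum)
  expect_equal(pEnum, 0.1)

  # constant column -> p = 1, excluded by the mask
  fc <- univariateFilter(cbind(rep(1, 16), rnorm(16)), g)
  expect_equal(fc$pValues[1], 1)
  expect_false(fc$mask[1])
  expect_error(univariateFilter(x, rep(0L, 16)), "both classes")
})

test_that("rank-sum p-values are invariant under monotone transforms", {
  set.seed(5)
  g <- rep(c(0L, 1L), each = 12)
  x <- matrix(rexp(24 * 10), 24)
  p0 <- univariateFilter(x, g)$pValues
  expect_equal(univariateFilter(log(x + 1), g)$pValues, p0)
  expect_equal(univariateFilter(x^3, g)$pValues, p0)
})

test_that("Gini median rule keeps strictly-above-median importances", {
  # all-equal importances (constant features) -> nothing selected
  xconst <- matrix(1, 30, 4, dimnames = list(NULL, paste0("c", 1:4)))
  y <- rep(c(0L, 1L), 15)
  gs <- giniSelect(xconst, y, numTrees = 50, seed = 2)
  expect_false(any(gs$selected))

  # graded signals give distinct importances: floor(k/2) survive
  set.seed(6)
  n <- 120
  y2 <- rep(c(0L, 1L), each = n / 2)
  x <- sapply(c(2, 1.2, 0.7, 0.35, 0.1), function(d)
    rnorm(n) + d * y2)
  gs2 <- giniSelect(x, y2, numTrees = 300, seed = 3)
  expect_equal(anyDuplicated(gs2$importances), 0)
  expect_equal(sum(gs2$selected), floor(ncol(x) / 2))

  # planted 5 of 200: informative features recovered across seeds
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    yy <- rep(c(0L, 1L), each = 50)
    xx <- matrix(rnorm(100 * 200), 100)
    xx[, 1:5] <- xx[, 1:5] + 2.5 * yy
    sel <- giniSelect(xx, yy, numTrees = 300, seed = s)$selected
    all(sel[1:5])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("stability selection intersects across every fold of every
           round", {
  set.seed(8)
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 80), n)
  # graded planted strengths so the importance ranking is stable
  x[, 1:5] <- x[, 1:5] + outer(y, c(3.5, 2.8, 2.2, 1.7, 1.3))
  colnames(x) <- paste0("f", 1:80)

  st <- stableFeatures(x, y, cvScheme(5, 2, seed = 4), pThreshold = 0.005,
                       numTrees = 200)
  sels <- attr(st, "selections")
  expect_length(sels, 10)
  expect_identical(sort(Reduce(intersect, sels)), as.integer(st))
  # a feature absent from even one fold is excluded
  missedOnce <- setdiff(Reduce(union, sels), st)
  for (f in missedOnce)
    expect_true(any(!vapply(sels, function(s) f %in% s, TRUE)))
  # the planted block dominates the stable set
  expect_true(all(st %in% 1:5))
  expect_gt(length(st), 0)

  # degenerate scheme = a single selection pass
  st1 <- stableFeatures(x, y, cvScheme(1, 1, seed = 4),
                        pThreshold = 0.005, numTrees = 200)
  one <- selectFeatures(x, y, 0.005, numTrees = 200,
                        seed = cvScheme(1, 1, seed = 4)$seed + 977L)
  expect_identical(as.integer(st1), which(one@selectedMask))

  # pure noise: the intersection collapses and reports diagnostics
  xn <- matrix(rnorm(60 * 300), 60)
  yn <- rep(c(0L, 1L), each = 30)
  expect_error(stableFeatures(xn, yn, cvScheme(4, 2, seed = 9),
                              numTrees = 100),
               "empty stable selection")
})

test_that("linear SVM separates, flips with labels and hits the 2-point
           midpoint", {
  x <- matrix(c(-2, -1, 1, 2), 4, 1)
  y <- c(0L, 0L, 1L, 1L)
  m <- trainSvm(x, y)
  sc <- decisionScores(m, x)
  expect_equal(rocAuc(sc, y), 1)
  expect_true(all(sc[y == 1L] > sc[y == 0L]))

  # label flip negates the decision function
  mf <- trainSvm(x, 1L - y)
  expect_equal(decisionScores(mf, x), -sc, tolerance = 1e-6)

  # two-point problem: boundary at the midpoint (closed-form solution)
  x2 <- matrix(c(-1, 3), 2, 1)
  m2 <- trainSvm(x2, c(0L, 1L))
  mid <- matrix(1, 1, 1)
  expect_equal(decisionScores(m2, mid), 0, tolerance = 1e-8)
  expect_equal(decisionScores(m2, x2), c(-1, 1) * decisionScores(m2, x2)[2],
               tolerance = 1e-6)
  expect_error(trainSvm(x, rep(1L, 4)), "both classes")
})
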