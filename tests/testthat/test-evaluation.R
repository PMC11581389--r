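# evaluation: AUC, Youden point, CV summaries, permutation test,
# patient correlations.

test_that("AUC equals pair counting, the rank-sum identity and pROC", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.3, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               pairCountAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  set.seed(12)
  for (rep in 1:10) {
    y <- rep(c(0L, 1L), c(7, 5))
    s <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)  # force ties
    a <- rocAuc(s, y)
    expect_equal(a, pairCountAuc(s, y))
    # rank-sum identity
    u <- sum(rank(s)[y == 1]) - 5 * 6 / 2
    expect_equal(a, u / 35)
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                     direction = "<"))))
  }
  # label flip maps a -> 1 - a
  s <- rnorm(12); y <- rep(c(0L, 1L), 6)
  expect_equal(rocAuc(s, y), 1 - rocAuc(s, 1L - y))
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
})

test_that("Youden point maximizes J over an exhaustive sweep", {
  # separable: J = 1 and perfect metrics
  r <- evaluateScores(c(-2, -1, 1, 2), c(0, 0, 1, 1))
  expect_equal(r@sensitivity, 1)
  expect_equal(r@specificity, 1)
  expect_equal(r@accuracy, 1)
  expect_equal(r@precision, 1)

  # all-tied scores: J = 0
  yp0 <- youdenPoint(rep(1, 8), rep(c(0, 1), 4))
  expect_equal(yp0$j, 0)

  # mixed example vs brute-force threshold sweep
  s <- c(0.1, 0.9, 0.4, 0.45, 0.6, 0.2)
  y <- c(0, 1, 0, 1, 1, 0)
  yp <- youdenPoint(s, y)
  thrs <- sort(unique(c(s - 1e-9, s + 1e-9, -Inf, Inf)))
  js <- vapply(thrs, function(t) {
    pos <- s >= t
    sum(pos & y == 1) / sum(y == 1) + sum(!pos & y == 0) / sum(y == 0) - 1
  }, 0)
  expect_equal(yp$j, max(js), tolerance = 1e-12)
  # metrics recompute from the stored confusion counts (validity check)
  rr <- evaluateScores(s, y)
  expect_true(validObject(rr))
  cf <- rr@confusion
  expect_equal(rr@accuracy, unname((cf["tp"] + cf["tn"]) / sum(cf)))
})

test_that("CV summaries match a sorted-list quantile oracle", {
  set.seed(14)
  aucs <- runif(100, 0.6, 0.9)
  reports <- data.frame(auc = aucs, accuracy = runif(100),
                        sensitivity = runif(100),
                        specificity = runif(100), precision = runif(100))
  sm <- summarizeCv(reports)
  expect_equal(sm$median[sm$metric == "auc"], median(aucs))
  expect_equal(sm$q1[sm$metric == "auc"],
               quantile(aucs, 0.25, names = FALSE))
  expect_equal(sm$q3[sm$metric == "auc"],
               quantile(aucs, 0.75, names = FALSE))

  # identical folds collapse median = q1 = q3
  same <- data.frame(auc = rep(0.8, 10), accuracy = rep(0.7, 10),
                     sensitivity = rep(0.6, 10),
                     specificity = rep(0.9, 10), precision = rep(0.5, 10))
  sms <- summarizeCv(same)
  expect_true(all(sms$median == sms$q1 & sms$q1 == sms$q3))

  # hold-out flags
  ho <- evaluateScores(c(-1, -0.5, 0.5, 1, 2, -2), c(0, 0, 1, 1, 1, 0))
  smh <- summarizeCv(same, ho)
  expect_true(all(c("holdout", "withinIqr") %in% colnames(smh)))
  expect_error(summarizeCv(data.frame()), "no fold reports")
  expect_error(summarizeCv(data.frame(auc = NA_real_)), "empty")
})

test_that("permutation estimators obey the add-one formulas", {
  # separable tabular features: observed AUC = 1, null far below
  set.seed(15)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 30), n)
  x[, 1:4] <- x[, 1:4] + 4 * y
  colnames(x) <- paste0("f", 1:30)
  co <- clinicalCohort(x, y)
  split <- stratifiedHoldout(co, 0.7, seed = 2)

  pr <- permutationTest(x, y, split, nPermutations = 50, seed = 3,
                        mode = "refit", pThreshold = 0.01, numTrees = 100)
  expect_equal(pr@observedAuc, 1)
  expect_length(pr@nullAucs, 50)
  # all nulls <= observed (observed is the maximum attainable)
  expect_equal(pr@pValuePaper, 1)
  b <- sum(pr@nullAucs >= pr@observedAuc)
  expect_equal(pr@pValueStandard, (b + 1) / 51)
  expect_lt(pr@pValueStandard, 0.1)

  # rescore mode reuses the fixed model
  pr2 <- permutationTest(x, y, split, nPermutations = 100, seed = 4,
                         mode = "rescore", pThreshold = 0.01,
                         numTrees = 100)
  expect_equal(pr2@pValuePaper,
               (sum(pr2@nullAucs <= pr2@observedAuc) + 1) / 101)

  # tie-free complementarity of the two conventions
  if (!any(pr2@nullAucs == pr2@observedAuc))
    expect_gte(pr2@pValueStandard + pr2@pValuePaper, 1 + 1 / 101)

  # determinism
  pr3 <- permutationTest(x, y, split, nPermutations = 50, seed = 3,
                         mode = "refit", pThreshold = 0.01, numTrees = 100)
  expect_identical(pr3@nullAucs, pr@nullAucs)
})

test_that("patient Spearman matrices match rank-then-Pearson", {
  set.seed(16)
  v <- matrix(rnorm(4 * 28), 4)
  ps <- patientSpearman(v)
  expect_equal(diag(ps$rho), rep(1, 4))
  expect_equal(ps$rho, t(ps$rho))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(ps$rho[i, j], cor(rank(v[i, ]), rank(v[j, ])),
                 tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(v[i, ], v[j, ], method = "spearman"))
    expect_equal(ps$rho[i, j], unname(ct$estimate), tolerance = 1e-12)
  }
  # reversed ranks give rho = -1
  m <- rbind(1:28, 28:1)
  expect_equal(patientSpearman(m)$rho[1, 2], -1)
  # constant patient flagged, not an error
  mc <- rbind(rep(1, 28), rnorm(28), rnorm(28))
  psc <- patientSpearman(mc)
  expect_identical(psc$flagged, 1L)
  expect_true(is.na(psc$rho[1, 2]))
})
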