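# tab2img geometry: normalization, embedding, hull, rectangle, raster.

test_that("min-max normalization clips, freezes and zeroes constants", {
  m <- cbind(a = c(0, 5, 10), b = c(2, 2, 2))
  np <- fitNormalization(m)
  expect_equal(np@min, c(a = 0, b = 2))
  expect_equal(np@max, c(a = 10, b = 2))
  out <- applyNormalization(m, np)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0, 0))
  # out-of-range test values clip to [0, 1]; constants stay at 0
  expect_equal(applyNormalization(cbind(a = c(-3, 12), b = c(1, 3)), np),
               cbind(a = c(0, 1), b = c(0, 0)))
})

test_that("kernel-PCA embedding is centred, sign-fixed and matches an
           independent eigendecomposition", {
  X <- randomMatrix(6, 5, seed = 11)
  co <- kpcaEmbedFeatures(X, sigma = 0.8)
  expect_equal(dim(co), c(5, 2))
  # centred-kernel identity: zero mean per component
  expect_lt(max(abs(colMeans(co))), 1e-9)
  # positive largest-magnitude loading per component
  for (j in 1:2) expect_gt(co[which.max(abs(co[, j])), j], 0)

  # identical feature columns embed identically
  X2 <- cbind(X, X[, 3])
  co2 <- kpcaEmbedFeatures(X2, sigma = 0.8)
  expect_equal(co2[3, ], co2[6, ], tolerance = 1e-10, ignore_attr = TRUE)

  # independent route: kernlab's kernel PCA on the same feature points
  skipIf <- !requireNamespace("kernlab", quietly = TRUE)
  if (!skipIf) {
    kp <- kernlab::kpca(t(X), kernel = "rbfdot",
                        kpar = list(sigma = 1 / (2 * 0.8^2)), features = 2)
    # kernlab scales the kernel eigenvalues by 1/m; its projections are
    # sqrt(m) times the centred-kernel scores
    ref <- kernlab::rotated(kp) / sqrt(ncol(X))
    for (j in 1:2) {
      a <- co[, j]; b <- ref[, j]
      if (sum(a * b) < 0) b <- -b
      expect_equal(a, b, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }

  # degenerate kernel: all feature points coincident
  expect_error(kpcaEmbedFeatures(matrix(1, 4, 3), sigma = 1),
               "embedding error")
})

test_that("convex hull matches the brute-force vertex characterization", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convexHull(sq)
  expect_false(h$degenerate)
  expect_setequal(h$indices, 1:4)
  # counter-clockwise from the lexicographically smallest vertex
  expect_equal(h$vertices[1, ], c(0, 0))
  ccwArea <- sum(h$vertices[, 1] *
                   h$vertices[c(2:nrow(h$vertices), 1), 2] -
                 h$vertices[c(2:nrow(h$vertices), 1), 1] *
                   h$vertices[, 2])
  expect_gt(ccwArea, 0)

  # collinear cloud -> degenerate with the two extremes
  line <- cbind(1:5, 2 * (1:5) + 1)
  hl <- convexHull(line)
  expect_true(hl$degenerate)
  expect_equal(hl$vertices, rbind(c(1, 3), c(5, 11)), ignore_attr = TRUE)

  # 30 random points vs O(m^3) oracle
  set.seed(21)
  pts <- matrix(rnorm(60), 30, 2)
  expect_setequal(convexHull(pts)$indices, which(bruteHullVertices(pts)))

  # collinear boundary points are not vertices
  tri <- rbind(c(0, 0), c(2, 0), c(1, 0), c(0, 2), c(0, 1), c(1, 1))
  expect_setequal(convexHull(tri)$indices, c(1, 2, 4))
})

test_that("minimum-area rectangle matches the orientation-sweep oracle", {
  sq <- convexHull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  r <- minAreaRect(sq)
  expect_equal(r$width * r$height, 1, tolerance = 1e-12)
  expect_equal(r$angle, 0)

  rot45 <- sqrt(2) / 2 * rbind(c(-1, 0), c(0, -1), c(1, 0), c(0, 1))
  r45 <- minAreaRect(convexHull(rot45))
  expect_equal(r45$width * r45$height, 1, tolerance = 1e-9)
  expect_equal(r45$angle, 45)

  set.seed(31)
  for (rep in 1:3) {
    pts <- matrix(rnorm(50), 25, 2)
    r <- minAreaRect(convexHull(pts))
    area <- r$width * r$height
    # the discretized sweep can only overestimate the true minimum
    expect_lte(area, sweepMinRectArea(pts, step = 0.005) + 1e-9)
    expect_lt(sweepMinRectArea(pts, step = 0.005) - area, 1e-3)
    aabb <- diff(range(pts[, 1])) * diff(range(pts[, 2]))
    expect_lte(area, aabb + 1e-9)
    # the rectangle extents at its own angle reproduce width and height
    ext <- ClinImage:::rotatedExtents(pts, r$angle)
    expect_equal(diff(ext$xr), r$width, tolerance = 1e-9)
    expect_equal(diff(ext$yr), r$height, tolerance = 1e-9)
  }
})

test_that("rasterization maps corners, groups collisions and conserves
           features", {
  coords <- rbind(c(0, 0), c(10, 0), c(0, 4), c(10, 4))
  rect <- minAreaRect(convexHull(coords))
  ras <- rasterizeLayout(coords, rect, grid = c(10, 10))
  px <- ras$pixelOfFeature
  expect_setequal(paste(px[, 1], px[, 2]),
                  c("9 0", "9 9", "0 0", "0 9"))

  # identical coordinates share one pixel and one group of size 2
  coords2 <- rbind(coords, c(10, 4))
  ras2 <- rasterizeLayout(coords2, rect, grid = c(10, 10))
  expect_equal(sort(lengths(ras2$collisionGroups), decreasing = TRUE)[1], 2)

  # conservation: distinct pixels + collision surplus = feature count
  set.seed(41)
  pts <- matrix(rnorm(56), 28, 2)
  rr <- minAreaRect(convexHull(pts))
  rs <- rasterizeLayout(pts, rr, grid = c(8, 8))
  expect_equal(length(rs$collisionGroups) +
                 sum(lengths(rs$collisionGroups) - 1L), 28)
  expect_error(rasterizeLayout(pts, rr, grid = c(1, 8)), "config error")
})

test_that("images render feature values with mean-collision handling", {
  co <- makeCohort(6, 10, seed = 5)
  ft <- fitTransformImages(co, grid = c(20, 20))
  imgs <- ft$images

  # all-zero patient renders an all-zero image
  zeroRow <- numeric(28)
  expect_equal(max(abs(renderImage(zeroRow, ft$layout))), 0)

  # identical patients give identical images
  v <- cohortValues(co)
  v[2, ] <- v[1, ]
  co2 <- clinicalCohort(v, cohortLabels(co), horizon = "5y")
  imgs2 <- transformImages(co2, ft$layout)
  expect_identical(imgs2@pixels[, , 1], imgs2@pixels[, , 2])

  # collision group {a, b} with values .2/.8 averages to .5
  lay <- ft$layout
  g2 <- which(lengths(lay@collisionGroups) >= 2)
  vals <- numeric(28)
  if (length(g2)) {
    grp <- lay@collisionGroups[[g2[1]]][1:2]
    vals[grp] <- c(0.2, 0.8)
    img <- renderImage(vals, lay)
    px <- lay@pixelOfFeature[grp[1], ]
    expect_equal(img[px[1] + 1, px[2] + 1],
                 mean(vals[lay@collisionGroups[[g2[1]]]]))
  } else {
    vals[3] <- 0.7
    img <- renderImage(vals, lay)
    px <- lay@pixelOfFeature[3, ]
    expect_equal(img[px[1] + 1, px[2] + 1], 0.7)
  }

  # transform() on the training cohort reproduces fit output exactly
  expect_identical(transformImages(co, ft$layout)@pixels, imgs@pixels)

  # monotone intensity in the feature value (non-colliding feature)
  solo <- which(lengths(lay@collisionGroups) == 1)[1]
  fIdx <- lay@collisionGroups[[solo]][1]
  px <- lay@pixelOfFeature[fIdx, ]
  vv <- numeric(28); vv[fIdx] <- 0.3
  lo <- renderImage(vv, lay)[px[1] + 1, px[2] + 1]
  vv[fIdx] <- 0.9
  hi <- renderImage(vv, lay)[px[1] + 1, px[2] + 1]
  expect_gt(hi, lo)
})

test_that("layout fitting is deterministic and uses training data only", {
  co <- makeCohort(8, 12, seed = 6)
  l1 <- fitImageLayout(cohortValues(co))
  l2 <- fitImageLayout(cohortValues(co))
  expect_identical(l1@coords, l2@coords)
  expect_identical(l1@pixelOfFeature, l2@pixelOfFeature)

  # JSON round-trip is bit-faithful
  path <- tempfile(fileext = ".json")
  layoutToJson(l1, path)
  back <- layoutFromJson(path)
  expect_identical(back@coords, l1@coords)
  expect_identical(back@pixelOfFeature, l1@pixelOfFeature)
  expect_identical(back@norm@min, l1@norm@min)
  expect_identical(back@rotation, l1@rotation)
  expect_identical(back@collisionGroups, l1@collisionGroups)
})
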