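# tab2img: fit a 2D feature layout on training patients and render one
# grayscale image per patient; the fitted layout is frozen and reused
# unchanged on unseen patients.  Every operation here is deterministic.

#' Fit per-feature min-max normalization
#'
#' @param values training matrix, no missing values.
#' @return a [NormalizationParams-class].
#' @export
fitNormalization <- function(values) {
  stopifnot(!anyNA(values))
  new("NormalizationParams",
      min = apply(values, 2, min), max = apply(values, 2, max))
}

#' Apply fitted min-max normalization
#'
#' Maps `x` to `(x - min) / (max - min)`, clipping out-of-range values to
#' \[0, 1\]; features constant on the training data map to 0.
#'
#' @param values matrix to normalize (any rows; columns as in training).
#' @param params a fitted [NormalizationParams-class].
#' @return a matrix with entries in \[0, 1\].
#' @export
applyNormalization <- function(values, params) {
  span <- params@max - params@min
  out <- sweep(values, 2, params@min)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Median-heuristic Gaussian kernel width
#'
#' Median pairwise Euclidean distance among the feature points (columns of
#' the normalized training matrix): a scale-free default for the embedding
#' kernel.
#'
#' @param normValues normalized training matrix (patients x features).
#' @return a positive scalar.
#' @export
medianHeuristicSigma <- function(normValues) {
  d <- dist(t(normValues))
  s <- median(d)
  if (!is.finite(s) || s <= 0)
    stop("embedding error: feature points are coincident; ",
         "cannot choose a kernel width")
  s
}

#' Embed the features into the plane with Gaussian-kernel PCA
#'
#' Treats each feature as one point in patient space (a column of the
#' normalized training matrix), forms the p x p Gaussian kernel
#' `K_ij = exp(-||f_i - f_j||^2 / (2 sigma^2))`, double-centres it and
#' returns the scores on the top two eigenvectors scaled by the square root
#' of their eigenvalues.  The sign of each component is fixed so that its
#' largest-magnitude loading is positive; each component has zero mean
#' across features.
#'
#' @param normValues normalized training matrix (patients x features),
#'   at least 3 patients.
#' @param sigma kernel width; `NULL` uses [medianHeuristicSigma()].
#' @return p x 2 coordinate matrix with attribute `"sigma"`.
#' @export
kpcaEmbedFeatures <- function(normValues, sigma = NULL) {
  stopifnot(nrow(normValues) >= 3)
  sigma <- sigma %||% medianHeuristicSigma(normValues)
  stopifnot(sigma > 0)
  d2 <- as.matrix(dist(t(normValues)))^2
  K <- exp(-d2 / (2 * sigma^2))
  p <- nrow(K)
  H <- diag(p) - matrix(1 / p, p, p)
  Kc <- H %*% K %*% H
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  tol <- 1e-12 * max(abs(e$values), 1)
  if (sum(e$values > tol) < 2L)
    stop("embedding error: fewer than 2 positive kernel eigenvalues; ",
         "try a larger sigma")
  scores <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  for (j in 1:2) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(normValues), c("PC1", "PC2"))
  attr(scores, "sigma") <- sigma
  scores
}

#' Convex hull of a planar point set
#'
#' Andrew monotone chain.  Returns the minimal vertex set in
#' counter-clockwise order starting at the lexicographically smallest
#' vertex; collinear boundary points are excluded.  When all points are
#' collinear the two extreme points are returned with `degenerate = TRUE`
#' (handled downstream as a zero-height rectangle).
#'
#' @param points m x 2 matrix, m >= 3, not all coincident.
#' @return list with `vertices` (k x 2 matrix), `indices` (row indices of
#'   the vertices in `points`) and `degenerate` (logical).
#' @export
convexHull <- function(points) {
  points <- unname(as.matrix(points))
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  o <- order(points[, 1], points[, 2])
  uniq <- o[!duplicated(points[o, , drop = FALSE])]
  if (length(uniq) < 2L) stop("all points are coincident")
  cross <- function(oi, ai, bi)
    (points[ai, 1] - points[oi, 1]) * (points[bi, 2] - points[oi, 2]) -
    (points[ai, 2] - points[oi, 2]) * (points[bi, 1] - points[oi, 1])
  chain <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(h[length(h) - 1], h[length(h)], i) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- chain(uniq)
  upper <- chain(rev(uniq))
  idx <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(idx) < 3L) {          # collinear: keep the two extremes
    idx <- c(uniq[1], uniq[length(uniq)])
    return(list(vertices = points[idx, , drop = FALSE], indices = idx,
                degenerate = TRUE))
  }
  list(vertices = points[idx, , drop = FALSE], indices = idx,
       degenerate = FALSE)
}

rotationMatrix <- function(angleDeg) {
  a <- angleDeg * pi / 180
  matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
}

# Extents of `pts` in the frame rotated clockwise by `angleDeg`.
rotatedExtents <- function(pts, angleDeg) {
  r <- pts %*% t(rotationMatrix(-angleDeg))
  list(xr = range(r[, 1]), yr = range(r[, 2]))
}

#' Minimum-area bounding rectangle of a convex hull
#'
#' Rotating-calipers sweep over the hull-edge orientations (the optimal
#' rectangle is flush with a hull edge).  The angle is normalized to
#' \[0, 90) degrees; area ties are broken by the smallest angle.  A
#' degenerate (collinear) hull yields a zero-height rectangle along the
#' point direction.
#'
#' @param hull result of [convexHull()].
#' @return list with `center` (original frame), `width` (extent along the
#'   `angle` direction), `height` (perpendicular extent) and `angle`
#'   (degrees in \[0, 90)).
#' @export
minAreaRect <- function(hull) {
  v <- hull$vertices
  edgeAngle <- function(a, b) {
    ang <- atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi
    ang <- ang %% 90
    if (ang >= 90) ang - 90 else ang
  }
  if (isTRUE(hull$degenerate)) {
    ang <- edgeAngle(v[1, ], v[2, ])
    ext <- rotatedExtents(v, ang)
    wh <- c(diff(ext$xr), diff(ext$yr))
    mid <- c(mean(ext$xr), mean(ext$yr)) %*% t(rotationMatrix(ang))
    return(list(center = as.numeric(mid), width = wh[1], height = wh[2],
                angle = ang))
  }
  k <- nrow(v)
  best <- NULL
  for (i in seq_len(k)) {
    ang <- edgeAngle(v[i, ], v[(i %% k) + 1, ])
    ext <- rotatedExtents(v, ang)
    area <- diff(ext$xr) * diff(ext$yr)
    if (is.null(best) || area < best$area - 1e-12 ||
        (abs(area - best$area) <= 1e-12 && ang < best$angle)) {
      mid <- c(mean(ext$xr), mean(ext$yr)) %*% t(rotationMatrix(ang))
      best <- list(center = as.numeric(mid), width = diff(ext$xr),
                   height = diff(ext$yr), angle = ang, area = area)
    }
  }
  best$area <- NULL
  best
}

#' Map embedded features onto a pixel grid
#'
#' Rotates the coordinates so the rectangle's longer side is horizontal,
#' maps the rectangle affinely onto the grid (half-open intervals, boundary
#' points clamped inside) and takes the floor of the scaled coordinates.
#' Pixels are 0-based (row, col) with origin top-left.  Features landing on
#' one pixel form one collision group.
#'
#' @param coords p x 2 feature coordinates.
#' @param rect result of [minAreaRect()] fitted on the same coordinates.
#' @param grid `c(rows, cols)`, both >= 2.
#' @return list with `pixelOfFeature` (p x 2 integer matrix),
#'   `collisionGroups` (list of feature-index vectors) and `rotation`
#'   (the 2 x 2 matrix applied to the coordinates).
#' @export
rasterizeLayout <- function(coords, rect, grid = c(50L, 50L)) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 2L))
    stop("config error: grid must be at least 2 x 2")
  beta <- if (rect$width >= rect$height) rect$angle else rect$angle - 90
  rot <- rotationMatrix(-beta)
  pts <- coords %*% t(rot)
  ctr <- as.numeric(rect$center %*% t(rot))
  w <- max(rect$width, rect$height)
  h <- min(rect$width, rect$height)
  x0 <- ctr[1] - w / 2
  y1 <- ctr[2] + h / 2
  scaleTo <- function(frac, m) pmin(m - 1L, pmax(0L, as.integer(floor(frac * m))))
  col <- if (w > 0) scaleTo((pts[, 1] - x0) / w, grid[2]) else
    rep(0L, nrow(pts))
  row <- if (h > 0) scaleTo((y1 - pts[, 2]) / h, grid[1]) else
    rep(0L, nrow(pts))
  px <- cbind(row = row, col = col)
  groups <- split(seq_len(nrow(px)), row * grid[2] + col)
  names(groups) <- NULL
  list(pixelOfFeature = px, collisionGroups = groups, rotation = rot)
}

#' Fit the full 2D feature layout on training data
#'
#' Chains min-max normalization, the Gaussian-kernel PCA feature embedding,
#' the convex hull, the minimum-area bounding rectangle, the rotation to
#' landscape orientation and the pixel assignment.  The result is a frozen,
#' train-only artifact.
#'
#' @param trainValues training matrix (patients x features), no missing
#'   values, at least 3 patients.
#' @param sigma Gaussian kernel width; `NULL` for the median heuristic.
#' @param grid raster resolution `c(rows, cols)`, default 50 x 50.
#' @return a [FeatureLayout-class].
#' @export
fitImageLayout <- function(trainValues, sigma = NULL, grid = c(50L, 50L)) {
  norm <- fitNormalization(trainValues)
  X <- applyNormalization(trainValues, norm)
  coords <- kpcaEmbedFeatures(X, sigma)
  sigma <- attr(coords, "sigma")
  attr(coords, "sigma") <- NULL
  hull <- convexHull(coords)
  rect <- minAreaRect(hull)
  ras <- rasterizeLayout(coords, rect, grid)
  new("FeatureLayout", norm = norm, sigma = sigma, coords = coords,
      hull = hull$vertices, hullDegenerate = hull$degenerate,
      rectCenter = rect$center, rectWidth = rect$width,
      rectHeight = rect$height, rectAngle = rect$angle,
      rotation = ras$rotation, grid = as.integer(grid),
      pixelOfFeature = ras$pixelOfFeature,
      collisionGroups = ras$collisionGroups)
}

#' Render one patient image
#'
#' Background pixels are exactly 0; each feature's pixel carries the
#' patient's normalized feature value, colliding features contribute the
#' arithmetic mean of their values.
#'
#' @param normRow length-p vector of normalized values in \[0, 1\].
#' @param layout a fitted [FeatureLayout-class].
#' @return rows x cols numeric matrix in \[0, 1\].
#' @export
renderImage <- function(normRow, layout) {
  img <- matrix(0, layout@grid[1], layout@grid[2])
  px <- layout@pixelOfFeature
  for (g in layout@collisionGroups)
    img[px[g[1], 1] + 1L, px[g[1], 2] + 1L] <- mean(normRow[g])
  img
}

#' Transform a cohort into images with a fitted layout
#'
#' Applies the frozen layout (normalization bounds, coordinates, rectangle
#' and pixel assignments) to every patient of `cohort`; no statistic of
#' `cohort` influences the layout.
#'
#' @param cohort a fully observed [ClinicalCohort-class].
#' @param layout a fitted [FeatureLayout-class].
#' @return a [PatientImageSet-class].
#' @export
transformImages <- function(cohort, layout) {
  if (any(cohort@missingMask))
    stop("cohort has missing values; impute before imaging")
  X <- applyNormalization(cohort@values, layout@norm)
  arr <- array(0, c(layout@grid, nrow(X)))
  for (i in seq_len(nrow(X))) arr[, , i] <- renderImage(X[i, ], layout)
  new("PatientImageSet", pixels = arr, patientIds = cohort@patientIds)
}

#' Fit a layout on a training cohort and render its images
#'
#' @param cohort fully observed training cohort.
#' @param sigma,grid see [fitImageLayout()].
#' @return list with `layout` and `images`.
#' @export
fitTransformImages <- function(cohort, sigma = NULL, grid = c(50L, 50L)) {
  if (any(cohort@missingMask))
    stop("cohort has missing values; impute before imaging")
  layout <- fitImageLayout(cohort@values, sigma, grid)
  list(layout = layout, images = transformImages(cohort, layout))
}

#' Serialize / restore a feature layout as JSON
#'
#' Full double precision is kept, so test-time transforms are
#' bit-reproducible across runs.
#'
#' @param layout a [FeatureLayout-class].
#' @param path JSON path.
#' @return `layoutFromJson()` returns the restored [FeatureLayout-class].
#' @export
layoutToJson <- function(layout, path) {
  obj <- list(format = "clinimage-layout", version = "1",
              normMin = layout@norm@min, normMax = layout@norm@max,
              sigma = layout@sigma,
              featureNames = rownames(layout@coords),
              coordsX = unname(layout@coords[, 1]),
              coordsY = unname(layout@coords[, 2]),
              hullX = unname(layout@hull[, 1]),
              hullY = unname(layout@hull[, 2]),
              hullDegenerate = layout@hullDegenerate,
              rectCenter = layout@rectCenter,
              rectWidth = layout@rectWidth,
              rectHeight = layout@rectHeight,
              rectAngle = layout@rectAngle,
              rotation = as.numeric(layout@rotation),   # column-major 2x2
              grid = layout@grid,
              pixelRow = unname(layout@pixelOfFeature[, 1]),
              pixelCol = unname(layout@pixelOfFeature[, 2]),
              collisionGroups = lapply(layout@collisionGroups, as.integer))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname layoutToJson
#' @export
layoutFromJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  stopifnot(identical(o$format[[1]], "clinimage-layout"))
  coords <- cbind(PC1 = o$coordsX, PC2 = o$coordsY)
  rownames(coords) <- o$featureNames
  px <- cbind(row = as.integer(o$pixelRow), col = as.integer(o$pixelCol))
  new("FeatureLayout",
      norm = new("NormalizationParams",
                 min = setNames(o$normMin, o$featureNames),
                 max = setNames(o$normMax, o$featureNames)),
      sigma = o$sigma, coords = coords,
      hull = cbind(o$hullX, o$hullY),
      hullDegenerate = o$hullDegenerate, rectCenter = o$rectCenter,
      rectWidth = o$rectWidth, rectHeight = o$rectHeight,
      rectAngle = o$rectAngle, rotation = matrix(o$rotation, 2, 2),
      grid = as.integer(o$grid), pixelOfFeature = px,
      collisionGroups = lapply(o$collisionGroups, as.integer))
}

#' Write images as 8-bit grayscale PNG files
#'
#' Intensities are quantized as `round(value * 255)`.
#'
#' @param images a [PatientImageSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeImagePng <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(images@patientIds, ".png"))
  for (i in seq_along(paths))
    png::writePNG(round(images@pixels[, , i] * 255) / 255, paths[i])
  invisible(paths)
}
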