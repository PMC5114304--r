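# brute-force AUC threshold: sort the truncated values and walk the
# cumulative count
loop_auc_threshold <- function(values, pct) {
  q <- quantile(values, c(0.03, 0.97), names = FALSE, type = 7)
  vt <- sort(c(q[1], values[values > q[1] & values < q[2]], q[2]))
  vt[max(1, ceiling(pct / 100 * length(vt)))]
}

test_that("AUC thresholds are truncated-distribution quantiles", {
  set.seed(21)
  v <- runif(1e5, 0, 100)
  expect_equal(auc_threshold(v, 0),
               quantile(v, 0.03, names = FALSE), tolerance = 1e-12)
  expect_equal(auc_threshold(v, 100),
               quantile(v, 0.97, names = FALSE), tolerance = 1e-12)
  expect_lt(abs(auc_threshold(v, 75) - 73.5), 0.5)
  # monotone in pct
  pcts <- seq(0, 100, by = 5)
  th <- vapply(pcts, function(p) auc_threshold(v, p), numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_error(auc_threshold(v, 101), "0, 100")
  # brute-force oracle on small instances (within one sorted-value step)
  set.seed(22)
  for (n in c(200, 1000)) {
    w <- rnorm(n)
    gap <- max(diff(sort(w)))
    for (p in c(25, 60, 75, 90)) {
      expect_lt(abs(auc_threshold(w, p) - loop_auc_threshold(w, p)), gap)
    }
  }
})

test_that("coverage profiles count ROI vertices above threshold", {
  atlas <- small_atlas()
  set.seed(23)
  map <- rnorm(length(atlas$labels))
  idx <- roi_vertices(atlas, "V1")
  map[idx] <- max(map) + 1  # whole ROI above any AUC threshold
  cp <- coverage_profile(map, atlas, "V1", pcts = c(60, 75, 90))
  expect_equal(cp$coverage, c(100, 100, 100))
  # counting contract: fraction >= threshold
  map[idx] <- seq(-10, 10, length.out = length(idx))
  cp2 <- coverage_profile(map, atlas, "V1", pcts = seq(60, 90, 5))
  for (k in seq_len(nrow(cp2))) {
    expect_equal(cp2$coverage[k],
                 100 * mean(map[idx] >= cp2$threshold[k]))
  }
  # non-increasing over pct
  expect_true(all(diff(cp2$coverage) <= 0))
})

test_that("threshold contours are the straddling edge set", {
  p <- build_mesh("planar_patch", 6)
  map <- rep(0, nrow(p$vertices))
  interior <- which(!p$is_boundary)
  v0 <- interior[1]
  map[v0] <- 1
  bc <- binarize_and_contour(p, map, 0.5)
  expect_equal(sum(bc$parcellation$mask), 1)
  # contour = the star of edges around the single interior vertex
  expect_equal(nrow(bc$contour), length(p$neighbors[[v0]]))
  expect_true(all(bc$contour == v0 | bc$contour %in% p$neighbors[[v0]]))
  # degenerate masks have no contour
  expect_equal(nrow(binarize_and_contour(p, map, -1)$contour), 0)
  expect_equal(nrow(binarize_and_contour(p, map, 2)$contour), 0)
})

test_that("contours close into loops on a closed mesh", {
  mesh <- small_mesh()
  set.seed(24)
  for (i in 1:5) {
    map <- geodesic_smooth(mesh, rnorm(nrow(mesh$vertices)), 2)
    thr <- quantile(map, runif(1, 0.2, 0.8))
    bc <- binarize_and_contour(mesh, map, thr)
    expect_true(contour_is_closed(mesh, bc$parcellation$mask))
  }
})

test_that("Jaccard overlap follows the set definition", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, !a), 0)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(jaccard(a, b), jaccard(b, a))
  expect_equal(jaccard(rep(FALSE, 4), rep(FALSE, 4)), 1)
  expect_error(jaccard(a, b[1:3]), "vertex set")
})

test_that("tangent-plane gradients are exact for linear fields", {
  p <- build_mesh("planar_patch", 10, spacing = 0.5)
  f <- 3 * p$vertices[, 1] + 4 * p$vertices[, 2]
  g <- surface_gradient(p, f)
  ok <- !is.na(g$magnitude)
  expect_gt(sum(ok), 0)
  expect_equal(g$magnitude[ok], rep(5, sum(ok)), tolerance = 1e-10)
  # linear in the map
  g2 <- surface_gradient(p, -2 * f)
  expect_equal(g2$magnitude[ok], rep(10, sum(ok)), tolerance = 1e-10)
  # constant field: zero gradient
  gc <- surface_gradient(p, rep(1, nrow(p$vertices)))
  expect_equal(gc$magnitude[ok], rep(0, sum(ok)), tolerance = 1e-12)
  # angle-weighted normals give the same planar answer
  ga <- surface_gradient(p, f, normal_weighting = "angle")
  expect_equal(ga$magnitude[ok], rep(5, sum(ok)), tolerance = 1e-10)
})

test_that("step fields localize high gradients at the step", {
  p <- build_mesh("planar_patch", 18, spacing = 0.5)
  step_x <- 4.7
  f <- as.numeric(p$vertices[, 1] >= step_x)
  g <- surface_gradient(p, f)
  mag <- g$magnitude
  hi <- which(!is.na(mag) & mag >= max(mag, na.rm = TRUE) / 2)
  expect_true(all(abs(p$vertices[hi, 1] - step_x) <= 0.5 + 1e-9))
})

test_that("gradient borders threshold without gap filling", {
  p <- build_mesh("planar_patch", 8)
  g <- surface_gradient(p, p$vertices[, 1])
  defined <- !is.na(g$magnitude)
  all_on <- gradient_borders(g, 0)
  expect_equal(all_on$mask, defined)
  none <- gradient_borders(g, max(g$magnitude, na.rm = TRUE) + 1)
  expect_false(any(none$mask))
  expect_error(gradient_borders(g, -0.1), "non-negative")
})
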