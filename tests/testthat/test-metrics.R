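# straight-loop reference implementations, kept deliberately naive
loop_cov <- function(stack, fwhm) {
  out <- numeric(nrow(stack))
  for (v in seq_len(nrow(stack))) {
    x <- stack[v, ]
    out[v] <- (sd(x) / mean(x)) / fwhm
  }
  out
}
loop_pv <- function(stacks, fwhm) {
  n <- nrow(stacks[[1]])
  out <- numeric(n)
  for (v in seq_len(n)) {
    s <- 0
    for (m in stacks) s <- s + sd(m[v, ])
    out[v] <- (s / length(stacks)) / fwhm
  }
  out
}
loop_cnr <- function(map, roi_idx, nb_idx, ref, minutes) {
  pooled <- c(map[roi_idx], map[nb_idx])
  mu <- mean(pooled)
  sigma <- sqrt(sum((pooled - mu)^2) / (length(pooled) - 1))
  abs(map[roi_idx] - ref) / sigma / sqrt(minutes)
}

test_that("unit rescaling anchors the 3rd and 97th percentiles", {
  v <- 0:100
  r <- rescale_unit(v)
  expect_equal(r[v == 3], 0)
  expect_equal(r[v == 97], 1)
  expect_equal(r[v == 50], (50 - 3) / 94, tolerance = 1e-12)
  # affine invariance
  expect_equal(rescale_unit(2.5 * v + 7), r, tolerance = 1e-12)
  # no clamping outside the anchors
  expect_lt(r[v == 0], 0)
  expect_gt(r[v == 100], 1)
  expect_error(rescale_unit(rep(1, 10)), "degenerate")
})

test_that("FWHM estimators recover the Gaussian width", {
  set.seed(11)
  x <- rnorm(2e5, sd = 3)
  expected <- 2 * sqrt(2 * log(2)) * 3
  expect_lt(abs(estimate_fwhm(x, "kde") - expected) / expected, 0.03)
  expect_lt(abs(estimate_fwhm(x, "histogram") - expected) / expected, 0.03)
  # near point mass collapses toward zero width
  y <- c(rep(1, 5000) + rnorm(5000, 0, 1e-4))
  expect_lt(estimate_fwhm(y), 0.01)
  expect_error(estimate_fwhm(rep(1, 100)), "degenerate")
})

test_that("distribution summary is internally consistent", {
  set.seed(2)
  v <- c(rnorm(5000), rnorm(500, 4))
  ds <- distribution_summary(v)
  expect_lt(ds$p3, ds$p97)
  expect_gt(ds$fwhm_raw, 0)
  expect_equal(ds$auc_quantile(0), ds$p3, tolerance = 1e-12)
  expect_equal(ds$auc_quantile(100), ds$p97, tolerance = 1e-12)
})

test_that("normalized COV matches hand arithmetic and the loop oracle", {
  stack <- cbind(c(9, 5), c(11, 5))
  cov <- cov_vertexwise(stack, 0.4026, "inter")$cov
  expect_equal(cov[1], (sd(c(9, 11)) / 10) / 0.4026, tolerance = 1e-12)
  expect_equal(cov[1], 0.3513, tolerance = 1e-3)
  expect_equal(cov[2], 0, tolerance = 1e-12)
  # loop oracle on a bigger instance
  set.seed(5)
  big <- matrix(rexp(20 * 6) + 1, 20, 6)
  expect_equal(cov_vertexwise(big, 0.35, "inter")$cov,
               loop_cov(big, 0.35), tolerance = 1e-12)
  # identical sessions: intra COV identically zero
  m <- matrix(rnorm(30) + 10, 10, 3)
  intra <- cov_vertexwise(list(cbind(m[, 1], m[, 1])), 0.4, "intra")$cov
  expect_equal(intra, rep(0, 10))
  # positive scaling leaves COV unchanged
  expect_equal(cov_vertexwise(3.7 * big, 0.35, "inter")$cov,
               cov_vertexwise(big, 0.35, "inter")$cov, tolerance = 1e-12)
  expect_error(cov_vertexwise(big[, 1, drop = FALSE], 0.35, "inter"),
               ">= 2 subjects")
  # non-positive mean is marked, not divided
  expect_true(is.na(cov_vertexwise(cbind(c(1, -2), c(2, -1)), 0.4,
                                   "inter")$cov[2]))
})

test_that("parcellability variation is sd over raw FWHM", {
  expect_equal(pv_vertexwise(0.005, 0.0503), 0.0994, tolerance = 1e-3)
  expect_equal(pv_vertexwise(0, 0.0503), 0)
  set.seed(6)
  stacks <- lapply(1:3, function(i) matrix(rnorm(40, 10), 20, 2))
  expect_equal(pv_vertexwise(scan_rescan_sd(stacks), 0.21),
               loop_pv(stacks, 0.21), tolerance = 1e-12)
  # affine transform of the parameter rescales sd and FWHM together
  a <- 3.2
  expect_equal(pv_vertexwise(scan_rescan_sd(lapply(stacks,
                                                   function(m) a * m + 1)),
                             a * 0.21),
               pv_vertexwise(scan_rescan_sd(stacks), 0.21),
               tolerance = 1e-12)
})

test_that("CNR per unit time matches hand arithmetic and the loop oracle", {
  atlas <- small_atlas()
  map <- rep(NA_real_, length(atlas$labels))
  roi_idx <- roi_vertices(atlas, "BA1")[1:2]
  nb_idx <- roi_vertices(atlas, "BG")
  map[roi_vertices(atlas, "BA1")] <- NA
  map[roi_idx] <- 3
  map[nb_idx] <- 1
  res <- cnr_per_time(map, atlas, "BA1", minutes = 4)
  # pooled sample sd of {3,3,1,...,1}: reference unique so both modes agree
  pooled <- map[c(roi_idx, nb_idx)]
  expect_equal(res$mean, 2 / sd(pooled) / 2, tolerance = 1e-12)
  expect_equal(res$mean,
               cnr_per_time(map, atlas, "BA1", 4, "region_median")$mean,
               tolerance = 1e-12)
  # literal two-vertex arithmetic with the loop oracle
  expect_equal(loop_cnr(c(3, 3, 1, 1), 1:2, 3:4, c(1, 1), 4),
               c(2, 2) / sqrt(4 / 3) / 2, tolerance = 1e-12)
  expect_equal(loop_cnr(c(3, 3, 1, 1), 1:2, 3:4, c(1, 1), 4)[1],
               0.8660, tolerance = 1e-4)
  # scale invariance
  res2 <- cnr_per_time(5 * map, atlas, "BA1", 4, seed = 9)
  res1 <- cnr_per_time(map, atlas, "BA1", 4, seed = 9)
  expect_equal(res2$cnr, res1$cnr, tolerance = 1e-12)
  # degenerate contrast
  map[] <- 2
  expect_error(cnr_per_time(map, atlas, "BA1", 4), "degenerate")
})

test_that("random-vertex CNR references agree with the vectorized draw", {
  atlas <- small_atlas()
  set.seed(8)
  map <- rnorm(length(atlas$labels), 10)
  res <- cnr_per_time(map, atlas, "BA2", minutes = 8.55, seed = 31)
  # reproduce the seeded draw independently
  roi_idx <- roi_vertices(atlas, "BA2")
  nb_idx <- roi_vertices(atlas, "BG")
  ref <- myelinmapr:::with_seed(31,
    map[nb_idx[sample.int(length(nb_idx), length(roi_idx),
                          replace = TRUE)]])
  expect_equal(res$cnr[roi_idx],
               loop_cnr(map, roi_idx, nb_idx, ref, 8.55),
               tolerance = 1e-12)
  # determinism in the seed
  expect_equal(res$cnr,
               cnr_per_time(map, atlas, "BA2", 8.55, seed = 31)$cnr)
})

test_that("depthwise correlation handles self, negation and masks", {
  set.seed(4)
  m <- matrix(rnorm(20 * 11), 20, 11)
  dc <- depthwise_correlation(m, m)
  expect_equal(dc$by_depth, rep(1, 11), tolerance = 1e-12)
  expect_equal(dc$overall, 1, tolerance = 1e-12)
  expect_equal(depthwise_correlation(m, -m)$by_depth, rep(-1, 11),
               tolerance = 1e-12)
  # excluded vertices leave the computation
  mask <- c(rep(TRUE, 5), rep(FALSE, 15))
  expect_equal(depthwise_correlation(m, m, mask)$n, 15)
  # constant map: undefined-correlation marker
  cm <- matrix(1, 20, 11)
  expect_true(all(is.na(depthwise_correlation(m, cm)$by_depth)))
  expect_error(depthwise_correlation(m[1:2, ], m[1:2, ]), ">= 3")
})
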