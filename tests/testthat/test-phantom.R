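test_that("generators are pure functions of their seeds", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  pop <- population_params()
  g1 <- sample_ground_truth(mesh, atlas, pop, 17)
  g2 <- sample_ground_truth(mesh, atlas, pop, 17)
  expect_identical(g1, g2)
  g3 <- sample_ground_truth(mesh, atlas, pop, 18)
  expect_false(identical(g1$r1_true, g3$r1_true))
  acq <- acquisition_spec()
  s1 <- simulate_session(g1, acq, 99)
  s2 <- simulate_session(g1, acq, 99)
  expect_identical(s1, s2)
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(sample_ground_truth(mesh, atlas, pop, 17))
  expect_identical(rnorm(1), before)
})

test_that("zero subject-level variance collapses subjects onto one truth", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  pop <- frozen_population()
  ga <- sample_ground_truth(mesh, atlas, pop, 1)
  gb <- sample_ground_truth(mesh, atlas, pop, 2)
  for (lab in atlas$table$label) {
    idx <- which(atlas$labels == lab)
    expect_equal(mean(ga$r1_true[idx, ]), mean(gb$r1_true[idx, ]),
                 tolerance = 1e-12)
    expect_equal(mean(ga$t2s_true[idx, ]), mean(gb$t2s_true[idx, ]),
                 tolerance = 1e-12)
  }
})

test_that("myeloarchitecture class ordering holds in every subject", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  pop <- population_params()
  cls <- atlas$table$class[match(atlas$labels, atlas$table$label)]
  for (s in 1:10) {
    gt <- sample_ground_truth(mesh, atlas, pop, 400 + s)
    keep <- !gt$vein_flag
    r1 <- tapply(rowMeans(gt$r1_true)[keep], cls[keep], mean)
    t2 <- tapply(rowMeans(gt$t2s_true)[keep], cls[keep], mean)
    expect_true(r1["heavy"] > r1["moderate"] &&
                  r1["moderate"] > r1["light"])
    expect_true(t2["heavy"] < t2["moderate"] &&
                  t2["moderate"] < t2["light"])
  }
})

test_that("ground truth respects positivity, depth ordering and veins", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  gt <- sample_ground_truth(mesh, atlas, population_params(), 5)
  expect_true(all(gt$r1_true > 0) && all(gt$t2s_true > 0))
  # myelin decreases toward the pial surface
  expect_true(all(gt$r1_true[, 1] >= gt$r1_true[, 11]))
  expect_true(any(gt$vein_flag))
  expect_true(all(gt$t2s_true[gt$vein_flag, ] < 0.024))
  expect_error(
    sample_ground_truth(mesh, atlas,
                        population_params(r1_central = c(heavy = -1,
                                                         moderate = 1,
                                                         light = 1)), 1),
    "positive")
})

test_that("noiseless sessions reproduce the forward model exactly", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  gt <- sample_ground_truth(mesh, atlas, population_params(), 3)
  acq <- acquisition_spec(noise_sd_gre = 0, noise_sd_t1 = 0)
  ss <- simulate_session(gt, acq, 1)
  d <- 4
  clean <- gt$s0_true * exp(outer(-1 / gt$t2s_true[, d], acq$echo_times))
  expect_equal(ss$echoes[, , d], clean, tolerance = 1e-12)
  # closed-form round trip through the log-linear fit
  expect_equal(ss$maps[["T2s"]]$depths, gt$t2s_true, tolerance = 1e-10)
  expect_equal(ss$maps[["R1"]]$depths, gt$r1_true, tolerance = 1e-12)
  # depth-averaged map consistent with its per-depth values
  expect_equal(ss$maps[["T2s"]]$avg, depth_average(ss$maps[["T2s"]]$depths),
               tolerance = 1e-12)
})

test_that("session noise propagates at the configured variance", {
  mesh <- small_mesh()
  atlas <- small_atlas()
  gt <- sample_ground_truth(mesh, atlas, frozen_population(), 1)
  sd_t1 <- 0.008
  acq <- acquisition_spec(noise_sd_t1 = sd_t1)
  k <- 30
  reps <- vapply(seq_len(k), function(i) {
    simulate_session(gt, acq, 1000 + i)$maps[["R1"]]$depths[, 6]
  }, numeric(nrow(mesh$vertices)))
  v <- apply(reps, 1, var)
  # pooled variance across vertices with chi-square bounds on the pooled df
  pooled <- mean(v)
  df <- length(v) * (k - 1)
  lo <- qchisq(0.0005, df) / df
  hi <- qchisq(0.9995, df) / df
  expect_gt(pooled / sd_t1^2, lo)
  expect_lt(pooled / sd_t1^2, hi)
})

test_that("the weighted transform is monotone and spreads the center", {
  r1 <- seq(0.4, 0.8, by = 0.01)
  t1w <- weighted_transform(r1)
  expect_true(all(diff(t1w) > 0))
  expect_identical(weighted_transform(c(0.5, 0.5))[1],
                   weighted_transform(c(0.5, 0.5))[2])
  expect_error(weighted_transform(c(0.5, -0.1)), "positive")
  # optional multiplicative bias field
  pars <- weighted_transform_params(bias_field = rep(2, length(r1)))
  expect_equal(weighted_transform(r1, pars), 2 * t1w, tolerance = 1e-12)
})

test_that("rescaled T1w distribution is broader than R1 on the phantom", {
  cohort <- small_cohort()
  r1 <- rowMeans(vapply(cohort$sessions,
                        function(s) s$s1$maps[["R1"]]$avg,
                        numeric(length(cohort$atlas$labels))))
  t1w <- rowMeans(vapply(cohort$sessions,
                         function(s) s$s1$maps[["T1w"]]$avg,
                         numeric(length(cohort$atlas$labels))))
  expect_gt(estimate_fwhm(rescale_unit(t1w)),
            estimate_fwhm(rescale_unit(r1)))
})

test_that("scan minutes follow the source-sequence accounting", {
  acq <- acquisition_spec()
  expect_equal(scan_minutes_for("R1", acq), 8 + 2 / 60)
  expect_equal(scan_minutes_for("T2sw", acq), 8 + 33 / 60)
  expect_equal(scan_minutes_for("R1/T2s", acq), 16 + 35 / 60)
  expect_error(scan_minutes_for("Qx", acq), "unknown parameter")
})

test_that("anticorrelation weakens from deep to pial depths", {
  cohort <- small_cohort()
  n <- length(cohort$atlas$labels)
  acc_a <- acc_b <- 0
  for (s in cohort$sessions) {
    acc_a <- acc_a + s$s1$maps[["R1"]]$depths
    acc_b <- acc_b + s$s1$maps[["T2s"]]$depths
  }
  mask <- exclusion_mask(depth_average(acc_b / 4))
  dc <- depthwise_correlation(acc_a / 4, acc_b / 4, mask)
  expect_lt(dc$by_depth[3], dc$by_depth[10])  # depth 0.2 vs 0.9
  expect_lt(dc$overall, 0)
})
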