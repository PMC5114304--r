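test_that("noiseless mono-exponential fit recovers S0 and T2* exactly", {
  te <- paper_tes()
  sig <- matrix(100 * exp(-te / 0.05), nrow = 1)
  fit <- fit_t2star(echo_series(sig, te))
  expect_equal(fit$t2s, 0.05, tolerance = 1e-12)
  expect_equal(fit$s0, 100, tolerance = 1e-12)
  expect_false(fit$unfittable)
  # weighted variant is also exact in the noiseless limit
  fw <- fit_t2star(echo_series(sig, te), weighted = TRUE)
  expect_equal(fw$t2s, 0.05, tolerance = 1e-12)
})

test_that("degenerate echo series yield markers, not numbers", {
  te <- paper_tes()
  flat <- fit_t2star(echo_series(matrix(50, 1, 4), te))
  expect_identical(flat$t2s, Inf)
  bad <- fit_t2star(echo_series(rbind(c(10, 5, -1, 2), c(10, 8, 6, 5)), te))
  expect_true(bad$unfittable[1])
  expect_true(is.na(bad$t2s[1]))
  expect_false(bad$unfittable[2])
  expect_error(fit_t2star(echo_series(matrix(1, 1, 1), 0.01)),
               "one echo time per signal column|2 echoes")
})

test_that("log-linear fit agrees with a nonlinear least-squares oracle", {
  te <- paper_tes()
  set.seed(42)
  n <- 50
  truth <- 0.03
  sig <- 100 * exp(outer(rep(1, n), -te / truth)) +
    matrix(rnorm(n * 4, 0, 0.35), n, 4)  # per-echo SNR ~300
  fit <- fit_t2star(echo_series(sig, te))
  oracle <- vapply(seq_len(n), function(i) {
    df <- data.frame(te = te, s = sig[i, ])
    coef(nls(s ~ s0 * exp(-te / t2s), df,
             start = list(s0 = 90, t2s = 0.025)))["t2s"]
  }, numeric(1))
  expect_equal(fit$t2s, unname(oracle), tolerance = 0.01)
})

test_that("Monte-Carlo bias of the fit is below 2% at 1% noise", {
  te <- paper_tes()
  set.seed(7)
  n <- 10000
  truth <- 0.03
  sig <- 100 * exp(outer(rep(1, n), -te / truth)) +
    matrix(rnorm(n * 4, 0, 1), n, 4)
  fit <- fit_t2star(echo_series(sig, te))
  expect_lt(abs(mean(fit$t2s) - truth) / truth, 0.02)
})

test_that("T2*-weighted map is the last/first echo ratio", {
  te <- paper_tes()
  expect_equal(t2star_weighted(echo_series(matrix(c(100, 60, 45, 30), 1),
                                           te)), 0.3)
  expect_equal(t2star_weighted(echo_series(matrix(80, 1, 4), te)), 1)
  # noiseless closed form exp(-(TE4 - TE1)/T2*)
  sig <- matrix(100 * exp(-te / 0.05), nrow = 1)
  expect_equal(t2star_weighted(echo_series(sig, te)),
               exp(-(te[4] - te[1]) / 0.05), tolerance = 1e-12)
  expect_true(is.na(t2star_weighted(echo_series(
    matrix(c(0, 1, 1, 1), 1), te))))
})

test_that("reciprocal map relabels rates and times", {
  expect_equal(reciprocal_map(2.0), 0.5)
  expect_equal(reciprocal_map(0.04), 25)
  x <- c(0.5, 1.5, 3)
  expect_equal(reciprocal_map(reciprocal_map(x)), x)
  expect_true(is.na(reciprocal_map(-1)))
  expect_true(is.na(reciprocal_map(0)))
})

test_that("ratio maps divide elementwise and propagate masks", {
  r <- ratio_maps(t1w = 10, t2sw = 0.5, r1 = 0.5, t2s = 0.025)
  expect_equal(r$t1w_t2sw, 20)
  expect_equal(r$r1_t2s, 20)
  # linearity in the numerator
  a <- ratio_maps(c(2, 4), c(1, 2), c(1, 1), c(1, 1))$t1w_t2sw
  b <- ratio_maps(3 * c(2, 4), c(1, 2), c(1, 1), c(1, 1))$t1w_t2sw
  expect_equal(b, 3 * a)
  # unfittable parents poison the ratio
  r2 <- ratio_maps(c(NA, 1), c(1, 0), c(1, NA), c(1, 1))
  expect_true(all(is.na(r2$t1w_t2sw)))
  expect_true(is.na(r2$r1_t2s[2]))
})

test_that("exclusion mask applies the 0.024 s threshold", {
  expect_identical(exclusion_mask(c(0.023, 0.025, NA)),
                   c(TRUE, FALSE, TRUE))
  expect_false(any(exclusion_mask(seq(0.024, 0.05, by = 0.002))))
})
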