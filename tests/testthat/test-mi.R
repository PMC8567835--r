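test_that("z-scoring gives population mean 0 / SD 1 and is idempotent", {
  ts <- rbind(a = c(1, 2, 3), b = c(10, 20, 40))
  z <- zscore_timeseries(ts)
  expect_equal(rowMeans(z), c(a = 0, b = 0), tolerance = 1e-14)
  expect_equal(sqrt(rowMeans(z^2)), c(a = 1, b = 1), tolerance = 1e-14)
  expect_equal(zscore_timeseries(z), z, tolerance = 1e-12)

  set.seed(5)
  g <- matrix(rnorm(10 * 500), 10)
  expect_true(max(abs(rowMeans(zscore_timeseries(g)))) < 1e-12)

  bad <- rbind(ok = c(1, 2), flat = c(3, 3))
  expect_error(zscore_timeseries(bad), "flat")
})

test_that("discretization follows the half-open convention with clipping", {
  sch <- binning_scheme()
  expect_equal(sch$n_bins, 14L)
  x <- matrix(c(-3.5, 0, 5, -9, 0.49999, 3.5), 1)
  codes <- discretize_timeseries(x, sch)
  expect_identical(as.integer(codes), c(0L, 7L, 13L, 0L, 7L, 13L))
  expect_error(discretize_timeseries(matrix(NaN, 1, 2), sch), "NaN|NA")
})

test_that("binning scheme accepts the standard sensitivity widths", {
  expect_equal(binning_scheme(0.5)$n_bins, 14L)
  expect_equal(binning_scheme(0.75)$n_bins, 10L)
  expect_equal(binning_scheme(1)$n_bins, 7L)
  expect_equal(binning_scheme(2)$n_bins, 4L)
  expect_error(binning_scheme(-1), "positive")
})

test_that("MI of identical code streams equals the binned entropy exactly", {
  set.seed(7)
  codes <- matrix(sample(0:13, 2000, replace = TRUE), 1)
  fc <- pairwise_mi(rbind(codes, codes), binning_scheme())
  p <- tabulate(codes + 1L, 14) / length(codes)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_identical(fc$mi[1, 2], h)
  expect_identical(fc$mi[1, 1], h)  # diagonal stores H(i)
})

test_that("MI is exactly symmetric, nonnegative and bounded by marginal entropies", {
  set.seed(21)
  z <- zscore_timeseries(matrix(rnorm(6 * 800), 6))
  fc <- pairwise_mi(discretize_timeseries(z), binning_scheme())
  expect_identical(fc$mi, t(fc$mi))
  expect_true(all(fc$mi >= 0))
  h <- diag(fc$mi)
  bound <- outer(h, h, pmin) + 1e-12
  expect_true(all(fc$mi <= bound))
})

test_that("independent streams at large T give near-zero MI", {
  set.seed(31)
  z <- zscore_timeseries(matrix(rnorm(2 * 1e5), 2))
  fc <- pairwise_mi(discretize_timeseries(z), binning_scheme())
  expect_lt(fc$mi[1, 2], 0.01)
})

test_that("the estimator converges to the exact binned-Gaussian MI", {
  # the plug-in histogram estimator targets the MI of the DISCRETIZED pair;
  # binned_gaussian_mi() computes that quantity by numerical integration
  for (rho in c(0.3, 0.6, 0.9)) {
    ts <- synth_gaussian_timeseries(matrix(c(1, rho, rho, 1), 2), 1e5,
                                    seed = round(100 * rho))
    fc <- mi_connectome(ts)
    expect_lt(abs(fc$mi[1, 2] - binned_gaussian_mi(rho)), 0.02)
  }
})

test_that("estimation error against analytic Gaussian MI shrinks with T at moderate rho", {
  # mean absolute error over seeds, so sampling noise does not mask the
  # bias ordering; at moderate rho the plug-in bias dominates the
  # (T-independent) quantization bias and the error decays with T
  for (rho in c(0.2, 0.3, 0.4)) {
    errs <- vapply(c(500, 5000, 50000), function(tt) {
      mean(vapply(1:8, function(s) {
        ts <- synth_gaussian_timeseries(matrix(c(1, rho, rho, 1), 2), tt,
                                        seed = 10 * s + round(1000 * rho))
        abs(mi_connectome(ts)$mi[1, 2] - gaussian_mi(rho))
      }, 0))
    }, 0)
    expect_true(all(diff(errs) < 0))
  }
})

test_that("run averaging is the elementwise mean and checks binning", {
  mi <- random_fc_matrix(4, seed = 2)
  sch <- binning_scheme()
  fa <- functional_connectome(mi, binning = sch)
  fb <- functional_connectome(mi + 0.2 - diag(0.2, 4), binning = sch)
  avg <- average_runs(fa, fb)
  expect_equal(avg$mi[1, 2], mi[1, 2] + 0.1)
  expect_identical(average_runs(fa, fa)$mi, fa$mi)
  expect_identical(avg$mi, t(avg$mi))
  fb2 <- functional_connectome(mi, binning = binning_scheme(1))
  expect_error(average_runs(fa, fb2), "binning")
})

test_that("bin sensitivity reports per-width connectomes and their agreement", {
  corr <- synth_correlation(6, "block", rho = 0.7, block_size = 3)
  ts <- synth_gaussian_timeseries(corr, 4000, seed = 8)
  out <- bin_sensitivity(ts, widths = c(0.5, 0.75, 1, 2))
  expect_length(out$connectomes, 4)
  expect_equal(nrow(out$agreement), 16)
  self <- out$agreement[out$agreement$width_a == out$agreement$width_b, ]
  expect_true(all(self$correlation == 1))
  cross <- out$agreement[out$agreement$width_a != out$agreement$width_b, ]
  expect_true(all(cross$correlation > 0.9))
})

test_that("estimated MI respects the data processing inequality on 3-node chains", {
  ok <- vapply(1:100, function(s) {
    ts <- synth_markov_chain(3, hop_rho = 0.8, n_timepoints = 2000, seed = s)
    fc <- mi_connectome(ts)
    fc$mi[1, 2] >= fc$mi[1, 3]
  }, NA)
  expect_gte(mean(ok), 0.95)
})
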