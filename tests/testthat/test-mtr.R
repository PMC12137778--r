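# MTR maps, ROI statistics, histograms, reproducibility statistics.

test_that("MTR formula and masking behave as documented", {
  low <- array(100, c(4, 4, 2)); high <- array(77, c(4, 4, 2))
  r <- compute_mtr_map(low, high, threshold = 0)
  expect_true(all(r$mtr == 23))
  same <- compute_mtr_map(low, low, threshold = 0)
  expect_true(all(same$mtr == 0))
  # sub-threshold voxels become NA, never zero
  low[1, 1, 1] <- 0.5
  r2 <- compute_mtr_map(low, high, threshold = 1)
  expect_true(is.na(r2$mtr[1, 1, 1]))
  expect_false(r2$valid_mask[1, 1, 1])
  expect_equal(r2$provenance$n_valid, 31)
  expect_error(compute_mtr_map(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)),
                               threshold = 1), "threshold")
  expect_error(compute_mtr_map(low, array(1, c(2, 2, 2))), "shape")
})

test_that("recomputing any valid voxel from its inputs reproduces the map", {
  set.seed(5)
  low <- array(runif(60, 1, 10), c(5, 4, 3))
  high <- array(runif(60, 0, 9), c(5, 4, 3))
  r <- compute_mtr_map(low, high, threshold = 2)
  idx <- which(r$valid_mask)
  expect_identical(r$mtr[idx], (low[idx] - high[idx]) / low[idx] * 100)
  expect_true(all(is.na(r$mtr[-idx])))
})

test_that("ROI statistics: hand-checked mean/sd, explicit empty entries", {
  mtr <- array(NA_real_, c(4, 1, 1))
  lab <- array(c(1L, 1L, 2L, 3L), c(4, 1, 1))
  mtr[] <- c(20, 24, 5, NA)
  st <- roi_statistics(mtr, lab)
  r1 <- st[st$index == 1, ]
  expect_equal(r1$mean, 22)
  expect_equal(r1$sd, sqrt(8), tolerance = 1e-9)  # n-1 denominator: 2.828
  expect_equal(r1$n_voxels, 2L)
  r3 <- st[st$index == 3, ]  # all voxels invalid -> missing, not zero
  expect_true(is.na(r3$mean))
  expect_equal(r3$n_voxels, 0L)
})

test_that("ROI statistics agree with the per-vial ratio prediction", {
  maps <- fix_small_phantom()
  acq <- acquisition_sim(n_coils = 1, noise_sigma = 0, coil_mode = "uniform")
  low <- rss_combine(simulate_acquisition(maps, fix_protocol(60), acq = acq))
  high <- rss_combine(simulate_acquisition(maps, fix_protocol(300), acq = acq))
  st <- roi_statistics(compute_mtr_map(low, high, threshold = 0), maps)
  cond <- maps$tissues[["cond"]]
  expect_lt(abs(st$mean[st$label == "water"]), 0.01)
  expect_equal(st$mean[st$label == "cond"],
               predict_mtr(c(60, 300), fix_protocol(), cond),
               tolerance = 0.1 / 25)
})

test_that("histogram counts are conserved across bin widths and masks", {
  set.seed(9)
  mtr <- array(rnorm(200, 23, 4), c(10, 10, 2))
  h1 <- mtr_histogram(mtr, bin_width = 1)
  h2 <- mtr_histogram(mtr, bin_width = 2.5)
  expect_equal(sum(h1$count), 200)
  expect_equal(sum(h2$count), 200)
  one <- mtr_histogram(array(23.2, c(3, 3, 1)), bin_width = 1)
  expect_equal(sum(one$count > 0), 1)   # single occupied bin
  mask <- array(FALSE, dim(mtr)); mask[1:5, 1, 1] <- TRUE
  expect_equal(sum(mtr_histogram(mtr, mask = mask)$count), 5)
  expect_error(mtr_histogram(mtr, bin_width = 0), "bin_width")
})

test_that("identical same-seed simulations produce identical histograms", {
  maps <- fix_small_phantom()
  acq <- acquisition_sim(n_coils = 2, noise_sigma = 0.005, seed = 12)
  run <- function() {
    low <- rss_combine(simulate_acquisition(maps, fix_protocol(60),
                                            acq = acq, noise_seed = 101))
    high <- rss_combine(simulate_acquisition(maps, fix_protocol(300),
                                             acq = acq, noise_seed = 102))
    mtr_histogram(compute_mtr_map(low, high, threshold = 0.05))
  }
  expect_identical(run(), run())
})

test_that("scan-rescan CoV implements the bias-corrected two-scan formula", {
  expect_equal(cov_bias_factor(2), 1.125)
  expect_equal(scan_rescan_cov(23, 23), 0)
  # hand evaluation: sd = 0.2/sqrt(2), mean = 23.1
  expect_equal(scan_rescan_cov(23.0, 23.2),
               (0.2 / sqrt(2)) / 23.1 * 1.125 * 100, tolerance = 1e-12)
  expect_equal(scan_rescan_cov(23.0, 23.2), 0.689, tolerance = 1e-3)
  expect_equal(scan_rescan_cov(c(20, 30), c(22, 30)),
               c((2 / sqrt(2)) / 21 * 112.5, 0), tolerance = 1e-12)
  expect_error(scan_rescan_cov(1, c(1, 2)), "paired")
  expect_error(scan_rescan_cov(-1, 1), "zero")
})

test_that("Bland-Altman: hand-checked bias and limits, antisymmetry", {
  ba <- bland_altman(c(20, 22, 24), c(21, 21, 23))
  expect_equal(ba$bias, 1 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 1.1547, tolerance = 1e-4)
  expect_equal(ba$loa_high - ba$bias, 1.96 * ba$sd_diff)
  expect_equal(ba$loa_low + ba$loa_high, 2 * ba$bias, tolerance = 1e-12)
  swapped <- bland_altman(c(21, 21, 23), c(20, 22, 24))
  expect_equal(swapped$bias, -ba$bias)
  ident <- bland_altman(c(20, 25), c(20, 25))
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_low, 0)
  expect_error(bland_altman(1, 2), "2 pairs")
})
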