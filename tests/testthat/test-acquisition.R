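# Coil sensitivities, noisy acquisition, sweep datasets.

test_that("coil sensitivities: uniform mode, determinism, positive RSS", {
  u <- simulate_coil_sensitivities(c(8, 8, 4), 1, mode = "uniform")
  expect_true(all(u == 1 + 0i))
  s1 <- simulate_coil_sensitivities(c(8, 8, 4), 8, seed = 9)
  s2 <- simulate_coil_sensitivities(c(8, 8, 4), 8, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_coil_sensitivities(c(8, 8, 4), 8, seed = 10)
  expect_false(identical(s1, s3))
  rss <- sqrt(apply(Mod(s1)^2, 1:3, sum))
  expect_true(all(rss > 0))
  expect_equal(dim(s1), c(8, 8, 4, 8))
})

test_that("noise-free single uniform coil reproduces the signal map exactly", {
  maps <- fix_small_phantom()
  acq <- acquisition_sim(n_coils = 1, noise_sigma = 0, coil_mode = "uniform")
  img <- simulate_acquisition(maps, fix_protocol(60), acq = acq)
  sig <- attr(img, "signal_map")
  expect_equal(Mod(img[, , , 1]), sig, tolerance = 1e-15)
  expect_true(all(sig[maps$label == 0L] == 0))  # background exactly empty
  # water vial symmetric pair: equal means at 60 and 300 degrees
  img300 <- simulate_acquisition(maps, fix_protocol(300), acq = acq)
  m60 <- mean(Mod(img[, , , 1])[maps$label == 1L])
  m300 <- mean(Mod(img300[, , , 1])[maps$label == 1L])
  expect_lt(abs(m60 - m300) / m60, 1e-6)
})

test_that("multi-coil magnitudes match sensitivity-weighted analytic means", {
  maps <- fix_small_phantom()
  acq <- acquisition_sim(n_coils = 8, noise_sigma = 0, seed = 2)
  img <- rss_combine(simulate_acquisition(maps, fix_protocol(60), acq = acq))
  sens <- simulate_coil_sensitivities(dim(maps$label), 8, seed = 2)
  rss <- sqrt(apply(Mod(sens)^2, 1:3, sum))
  sig <- attr(simulate_acquisition(maps, fix_protocol(60), acq = acq),
              "signal_map")
  for (lab in 1:2) {
    sel <- maps$label == lab
    expect_equal(mean(img[sel]), mean((rss * sig)[sel]),
                 tolerance = 0.01)
  }
})

test_that("background magnitude after RSS follows the central-chi mean", {
  maps <- build_vial_phantom(phantom_definition(list(), fov = c(48, 48, 25),
                                                voxel = c(2, 2, 1)))
  n_coils <- 8; sigma <- 0.1
  acq <- acquisition_sim(n_coils = n_coils, noise_sigma = sigma, seed = 7)
  img <- rss_combine(simulate_acquisition(maps, fix_protocol(60), acq = acq))
  analytic <- sigma * sqrt(2) * gamma((2 * n_coils + 1) / 2) / gamma(n_coils)
  se <- stats::sd(as.vector(img)) / sqrt(length(img))
  expect_gt(length(img), 1e4)
  expect_lt(abs(mean(img) - analytic), 3 * se)
})

test_that("sweep datasets stack ascending angles and are seed-reproducible", {
  maps <- fix_small_phantom()
  angles <- c(300, 60, 180, 1)  # deliberately unsorted
  acq <- acquisition_sim(n_coils = 2, noise_sigma = 0.01, seed = 4)
  d1 <- simulate_sweep_dataset(maps, fix_protocol(), angles, acq)
  expect_equal(dim(d1$data)[4], 4L)
  expect_equal(d1$angles, c(1, 60, 180, 300))
  expect_equal(d1$provenance$acquisition_order, c(1, 300, 60, 180))
  d2 <- simulate_sweep_dataset(maps, fix_protocol(), angles, acq)
  expect_identical(d1$data, d2$data)  # bit-identical under the same seed
  acq2 <- acq; acq2$seed <- 5L
  d3 <- simulate_sweep_dataset(maps, fix_protocol(), angles, acq2)
  expect_false(identical(d1$data, d3$data))
})

test_that("interleaved acquisition order alternates extremes", {
  g <- default_flip_angles()
  ord <- make_interleaved_order(g)
  expect_equal(ord[1:4], c(1, 420, 10, 410))
  expect_equal(sort(ord), sort(g))  # a permutation, nothing lost
  expect_equal(make_interleaved_order(90), 90)
})
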