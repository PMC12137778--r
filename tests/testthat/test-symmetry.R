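# Symmetry analysis and flip-angle-pair selection.

test_that("exactly mirror-symmetric arrays locate their axis", {
  x <- seq(10, 350, by = 10)
  y <- exp(-((x - 180) / 90)^2)           # symmetric about 180
  expect_equal(find_symmetry_point(list(x = x, signal = y)), 180)
  y2 <- exp(-((x - 120) / 70)^2)          # symmetric about 120
  expect_equal(find_symmetry_point(list(x = x, signal = y2)), 120)
  expect_error(find_symmetry_point(list(x = 1:4, signal = 1:4)), "span")
})

test_that("simulated single-pool curves are symmetric about 180 degrees,
           even when the sweep passes one full turn", {
  tis <- fix_single_pool()
  curve <- flip_angle_sweep(seq(10, 350, 10), fix_protocol(), tis)
  expect_equal(find_symmetry_point(curve), 180)
  # the full default grid also contains the trivial 360-degree axis;
  # tied scores must resolve to the smaller angle
  full <- flip_angle_sweep(default_flip_angles(), fix_protocol(), tis)
  expect_equal(find_symmetry_point(full), 180)
})

test_that("a B1 miscalibration shifts the apparent axis to 180/s nominal", {
  tis <- fix_single_pool()
  curve <- flip_angle_sweep(seq(10, 350, 10), fix_protocol(),
                            tis, field_conditions(b1_scale = 180 / 190))
  expect_equal(find_symmetry_point(curve), 190)
})

test_that("asymmetry index: zero without MT, ordered by bound fraction", {
  grid <- seq(20, 340, by = 40)
  p <- fix_protocol()
  water <- flip_angle_sweep(grid, p, tissue_params(3000, 2000))
  expect_lt(abs(asymmetry_index(water, 180, 120)), 1e-6)
  cream <- flip_angle_sweep(grid, p,
                            tissue_params(500, 180, 0.05, 30, 500, 12))
  cond <- flip_angle_sweep(grid, p,
                           tissue_params(600, 120, 0.12, 30, 600, 12))
  ai_cream <- asymmetry_index(cream, 180, 120)
  ai_cond <- asymmetry_index(cond, 180, 120)
  expect_gt(ai_cream, 0)
  expect_gt(ai_cond, ai_cream)
  expect_error(asymmetry_index(water, 180, 125), "grid")
})

test_that("pair selection picks 60/300 when the reference peaks there", {
  x <- seq(10, 350, by = 10)
  # reference: symmetric trapezoid, maximal on [60, 300]
  ref <- pmin(x / 60, 1) * pmin((360 - x) / 60, 1)
  # MT curve: same shape depressed quadratically with angle
  mt <- ref * exp(-(x / 300)^2)
  sel <- choose_flip_angle_pair(list(x = x, signal = ref),
                                list(x = x, signal = mt),
                                signal_match_tol = 1e-6,
                                min_signal_frac = 0.999)
  expect_equal(unname(sel$pair), c(60, 300))
  expect_equal(sel$symmetry_point, 180)
})

test_that("pair selection equals a brute-force enumeration oracle", {
  tis_ref <- tissue_params(3000, 2000)
  tis_mt <- tissue_params(600, 120, 0.12, 30, 600, 12)
  grid <- default_flip_angles()
  p <- fix_protocol()
  ref <- flip_angle_sweep(grid, p, tis_ref)
  mt <- flip_angle_sweep(grid, p, tis_mt)
  tol <- 0.05; frac <- 0.9
  sel <- choose_flip_angle_pair(ref, mt, tol, frac)

  # oracle: independent nested-loop enumeration of every angle pair
  sp <- find_symmetry_point(ref)
  smax <- max(ref$signal)
  best <- NULL; best_mtr <- -Inf
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    if (grid[i] >= grid[j]) next
    if (abs((grid[i] + grid[j]) / 2 - sp) > 1e-6) next
    if (abs(ref$signal[i] - ref$signal[j]) / smax > tol) next
    if (ref$signal[i] < frac * smax) next
    m <- (mt$signal[i] - mt$signal[j]) / mt$signal[i] * 100
    if (m > best_mtr) { best_mtr <- m; best <- c(grid[i], grid[j]) }
  }
  expect_equal(unname(sel$pair), best)
  expect_equal(sel$predicted_mtr, best_mtr, tolerance = 1e-12)
})

test_that("infeasible tolerance settings fail loudly", {
  x <- seq(10, 350, 10)
  y <- exp(-((x - 180) / 90)^2)
  asym <- y * seq(1, 0.2, length.out = length(x))
  expect_error(
    choose_flip_angle_pair(list(x = x, signal = asym),
                           list(x = x, signal = y),
                           signal_match_tol = 1e-9,
                           min_signal_frac = 0.999),
    "feasible")
})
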