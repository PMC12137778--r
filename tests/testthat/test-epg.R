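# EPG primitive operators: RF mixing, saturation, relaxation/exchange,
# spoiler bookkeeping.

test_that("RF rotation: identity at 0, inversion at 180, bound pool inert", {
  tis <- fix_wm()
  st <- fix_random_state(tis, seed = 11)
  expect_equal(epg_rf_rotation(st, 0), st)

  eq <- epg_init(tis, 12)
  inv <- epg_rf_rotation(eq, 180)
  expect_equal(inv$z[1], -eq$z[1], tolerance = 1e-12)
  expect_true(all(Mod(inv$fp) < 1e-14) && all(Mod(inv$fm) < 1e-14))
  expect_equal(inv$zb, eq$zb)  # rotation never touches the bound pool
})

test_that("RF rotation matches an explicit rotation-matrix oracle per order", {
  # oracle: map each (F_k, F_-k*, Z_k) triple to Cartesian-like components,
  # apply the real 3x3 rotation about x by alpha, and map back
  alpha <- 37
  a <- alpha * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(a), -sin(a),
                0, sin(a), cos(a)), nrow = 3, byrow = TRUE)
  tis <- fix_wm()
  st <- fix_random_state(tis, n_states = 16, seed = 5)
  got <- epg_rf_rotation(st, alpha)
  for (k in seq_len(16)) {
    fp <- st$fp[k]; fmc <- Conj(st$fm[k]); z <- st$z[k]
    m <- c((fp + fmc) / 2, (fp - fmc) / (2i), z)
    mr <- as.vector(R %*% m)
    expect_equal(got$fp[k], mr[1] + 1i * mr[2], tolerance = 1e-12)
    expect_equal(Conj(got$fm[k]), mr[1] - 1i * mr[2], tolerance = 1e-12)
    expect_equal(got$z[k], mr[3], tolerance = 1e-12)
  }
})

test_that("saturation factor: unit at zero flip, quadratic in flip angle", {
  tis <- fix_wm()
  expect_identical(bound_pool_saturation_factor(0, 220, tis), 1)
  w1 <- -log(bound_pool_saturation_factor(90, 220, tis))
  w2 <- -log(bound_pool_saturation_factor(180, 220, tis))
  expect_equal(w2 / w1, 4, tolerance = 1e-12)
})

test_that("saturation factor equals the closed-form Gaussian-lineshape value", {
  tis <- tissue_params(600, 120, 0.12, 30, 600, t2_bound = 10)
  direct <- function(alpha_deg, tau_us, t2b_us) {
    tau <- tau_us * 1e-6
    omega1 <- alpha_deg * pi / 180 / tau
    exp(-pi * omega1^2 * (t2b_us * 1e-6 / sqrt(2 * pi)) * tau)
  }
  f300 <- bound_pool_saturation_factor(300, 220, tis)
  f60 <- bound_pool_saturation_factor(60, 220, tis)
  expect_equal(f300, direct(300, 220, 10), tolerance = 1e-12)
  expect_equal(f60, direct(60, 220, 10), tolerance = 1e-12)
  # strong saturation at 300 deg, mild at 60 deg
  expect_equal(f300, 0.21, tolerance = 0.01)
  expect_equal(f60, 0.94, tolerance = 0.01)
})

test_that("super-Lorentzian G(0) uses the cutoff rule and matches a
           quadrature oracle", {
  tis <- tissue_params(350, 90, 0.13, 35, 350, t2_bound = 11,
                       lineshape = "super_lorentzian")
  # oracle: midpoint-rule quadrature of the super-Lorentzian at the cutoff
  t2b <- 11e-6; delta <- 1000
  th <- seq(1e-7, pi / 2, length.out = 2e5)
  u <- abs(3 * cos(th)^2 - 1)
  g <- sin(th) * sqrt(2 / pi) * (t2b / u) *
    exp(-2 * (2 * pi * delta * t2b / u)^2)
  oracle <- mean(g) * (pi / 2)
  expect_equal(lineshape_g0(tis, cutoff_hz = 1000), oracle,
               tolerance = 1e-5)
  bad <- tis; bad$t2_bound <- -1
  expect_error(lineshape_g0(bad), "t2_bound")
})

test_that("relaxation/exchange: identity at dt = 0, equilibrium fixed point", {
  tis <- fix_wm()
  st <- fix_random_state(tis, seed = 3)
  expect_equal(relax_exchange_interval(st, 0, tis), st)
  expect_error(relax_exchange_interval(st, -1, tis), "dt")

  eq <- epg_init(tis, 10)
  for (dt in c(0.5, 5, 80)) {
    out <- relax_exchange_interval(eq, dt, tis)
    expect_equal(out$z[1], eq$z[1], tolerance = 1e-12)
    expect_equal(out$zb[1], eq$zb[1], tolerance = 1e-12)
  }
})

test_that("relaxation reduces to mono-exponential recovery without exchange", {
  tis <- tissue_params(500, 100, bound_fraction = 0, exchange_rate = 0)
  st <- epg_init(tis, 8)
  st$z[1] <- 0 + 0i  # fully saturated free pool
  for (dt in c(1, 12.03, 250)) {
    out <- relax_exchange_interval(st, dt, tis)
    expect_equal(Re(out$z[1]), 1 * (1 - exp(-dt / 500)), tolerance = 1e-12)
  }
})

test_that("spoiler shift moves the F_-1 pathway into F_0 and truncates", {
  tis <- fix_single_pool()
  st <- epg_init(tis, 6)
  st$fp <- complex(real = 1:6)
  st$fm <- complex(real = c(1, 10, 20, 30, 40, 50))
  st$fm[1] <- st$fp[1]
  out <- epg_spoiler_shift(st)
  expect_equal(out$fp, complex(real = c(10, 1, 2, 3, 4, 5)))  # F_-1 -> F_0
  expect_equal(out$fm, complex(real = c(10, 20, 30, 40, 50, 0)))
  expect_equal(out$z, st$z)  # longitudinal orders unaffected
})
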