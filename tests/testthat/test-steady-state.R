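# Steady-state solver behaviour and EPG-vs-isochromat validation.

test_that("no excitation gives zero signal on both pathways", {
  sig <- ssfp_steady_state(fix_protocol(0), fix_single_pool())
  expect_equal(sig$s_fid, 0)
  expect_equal(sig$s_echo, 0)
  expect_true(sig$converged)
})

test_that("single-pool echo response is mirror-symmetric about 180 degrees", {
  tis <- fix_single_pool()
  for (a in c(20, 60, 110, 150)) {
    s1 <- ssfp_steady_state(fix_protocol(a), tis)$s_echo
    s2 <- ssfp_steady_state(fix_protocol(360 - a), tis)$s_echo
    expect_lt(abs(s1 - s2) / max(s1, s2), 1e-6)
  }
})

test_that("single-pool echo signal nulls at 180 degrees under ideal B1", {
  tis <- fix_single_pool()
  s180 <- ssfp_steady_state(fix_protocol(180), tis)$s_echo
  s60 <- ssfp_steady_state(fix_protocol(60), tis)$s_echo
  expect_lt(s180, 1e-8 * s60)
})

test_that("two-pool EPG signal matches the isochromat oracle", {
  wm <- fix_wm()
  for (a in c(60, 300)) {
    e <- ssfp_steady_state(fix_protocol(a), wm)
    o <- isochromat_oracle(fix_protocol(a), wm, n_isochromats = 2000)
    expect_lt(abs(e$s_echo - o$s_echo) / max(o$s_echo), 1e-3)
    expect_lt(abs(e$s_fid - o$s_fid) / max(o$s_fid), 1e-3)
  }
})

test_that("oracle agreement improves as the isochromat count grows", {
  wm <- fix_wm()
  p <- fix_protocol(60)
  ref <- ssfp_steady_state(p, wm)$s_echo
  errs <- vapply(c(4, 8, 16, 64), function(n)
    abs(isochromat_oracle(p, wm, n_isochromats = n)$s_echo - ref),
    numeric(1))
  expect_true(all(diff(errs) <= 1e-12))  # non-increasing (ties at machine)
  expect_lt(errs[4], 1e-10)
})

test_that("a B1 scale error is an exact relabelling of the flip-angle axis", {
  wm <- fix_wm()
  aliased <- ssfp_steady_state(fix_protocol(100), wm,
                               field_conditions(b1_scale = 0.6))
  direct <- ssfp_steady_state(fix_protocol(60), wm)
  expect_equal(aliased$s_echo, direct$s_echo, tolerance = 1e-12)
  expect_equal(aliased$s_fid, direct$s_fid, tolerance = 1e-12)
})

test_that("the steady state is independent of the initial state", {
  wm <- fix_wm()
  p <- fix_protocol(60)
  ref <- ssfp_steady_state(p, wm)
  for (seed in 1:3) {
    alt <- ssfp_steady_state(p, wm,
                             init_state = fix_random_state(wm, seed = seed))
    expect_lt(abs(alt$s_echo - ref$s_echo) / ref$s_echo, 1e-9)
    expect_lt(abs(alt$s_fid - ref$s_fid) / ref$s_fid, 1e-9)
  }
})

test_that("hitting the iteration cap raises a diagnosable solver error", {
  err <- tryCatch(ssfp_steady_state(fix_protocol(60), fix_single_pool(),
                                    max_iter = 3),
                  condition = function(e) e)
  expect_s3_class(err, "ulfmt_convergence_error")
  expect_match(conditionMessage(err), "iterations")
})
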