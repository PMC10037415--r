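test_that("below-SLB curve with d = 0 reproduces the bare curve exactly", {
  cn <- giet_calibration("none")
  cb0 <- giet_calibration("below", 0)
  expect_lt(max(abs(cn$tau_ns - cb0$tau_ns)), 1e-12)
  fam <- giet_below_family(d_grid = c(0, 2, 4))
  expect_lt(max(abs(fam$curves[[1]]$tau_ns - cn$tau_ns)), 1e-12)
})

test_that("curves for dyes above an SLB coincide with the no-SLB curve", {
  cn <- giet_calibration("none")
  ca <- giet_calibration("above", 8, z_grid = seq(8, 30, by = 0.25))
  # lifetimes agree to a fraction of a percent everywhere (far below
  # single-bunch fit precision), so the bare curve serves for inversion
  tau_n <- approx(cn$z_nm, cn$tau_ns, xout = ca$z_nm)$y
  expect_lt(max(abs(ca$tau_ns - tau_n) / tau_n), 0.005)
  # and on the operating range of top-leaflet dyes the equivalent height
  # displacement is far below the method resolution
  lo <- which(ca$z_nm <= 12)
  zb <- invert_lifetime(cn, ca$tau_ns[lo])
  expect_lt(max(abs(zb - ca$z_nm[lo])), 0.15)
})

test_that("below-SLB curves shift left, monotonically in membrane thickness", {
  cn <- giet_calibration("none")
  shifts <- vapply(c(2, 4, 6, 8), function(d) {
    calibration_shift(cn, giet_calibration("below", d))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
  expect_gt(shifts[4], 0)
  expect_lte(shifts[4], 0.61)  # at most ~0.6 nm at d = 8 nm
  # family ordering: larger d never shifts the curve rightward
  fam <- giet_below_family(d_grid = c(0, 2, 4, 6, 8))
  lev <- seq(1.0, 2.2, length.out = 25)
  zs <- vapply(fam$curves, invert_lifetime, numeric(length(lev)), tau = lev)
  expect_true(all(apply(zs, 1, diff) <= 1e-9))
})

test_that("shift metric: identical and translated curves", {
  cn <- giet_calibration("none")
  expect_equal(calibration_shift(cn, cn), 0, tolerance = 1e-9)
  # translate the curve by +0.3 nm in z (same lifetimes at z + 0.3)
  shifted <- gietr:::new_calibration(cn$z_nm + 0.3, cn$S, cn$tau_ns, "none", 0)
  expect_equal(calibration_shift(cn, shifted), 0.3, tolerance = 1e-6)
  # disjoint lifetime ranges are an error
  fake <- gietr:::new_calibration(cn$z_nm, cn$S, cn$tau_ns + 10, "none", 0)
  expect_error(calibration_shift(cn, fake), class = "gietr_out_of_range")
})

test_that("lifetime inversion is the identity on the rising branch", {
  cu <- giet_calibration("none")
  ie <- gietr:::branch_end(cu$tau_ns)
  idx <- seq(5, ie - 5, by = 37)
  z_back <- invert_lifetime(cu, cu$tau_ns[idx])
  expect_lt(max(abs(z_back - cu$z_nm[idx])), 1e-3)
  # brute-force grid-scan oracle for random lifetimes
  set.seed(3)
  taus <- runif(20, cu$tau_ns[1] + 0.01, cu$tau_ns[ie] - 0.01)
  for (tt in taus) {
    z_fast <- invert_lifetime(cu, tt)
    z_scan <- cu$z_nm[which.min(abs(cu$tau_ns[seq_len(ie)] - tt))]
    expect_lt(abs(z_fast - z_scan), 0.05 + 1e-9)  # within one grid step
  }
  # out-of-range lifetimes are classed errors
  expect_error(invert_lifetime(cu, 1.05 * cu$tau_ns[ie]),
               class = "gietr_out_of_range")
  expect_error(invert_lifetime(cu, 0.5 * cu$tau_ns[1]),
               class = "gietr_out_of_range")
})

test_that("an optically invisible slab reduces to single-curve inversion", {
  st_inv <- giet_stack(slb_index = 1.333)  # slab index = medium index
  em <- giet_emitter()
  cv <- giet_curves(emitter = em, stack = st_inv, d_grid = seq(0, 10, 2.5),
                    z_grid = seq(0, 30, by = 0.1))
  tau_s <- cv$top$tau_ns[which.min(abs(cv$top$z_nm - 3))]
  tau_l <- cv$top$tau_ns[which.min(abs(cv$top$z_nm - 8))]
  est <- estimate_heights(tau_s, tau_l, cv)
  expect_true(est$converged)
  expect_equal(est$iterations, 1)
  expect_equal(est$z_bottom, invert_lifetime(cv$top, tau_s), tolerance = 0.02)
  expect_equal(est$z_top, invert_lifetime(cv$top, tau_l), tolerance = 1e-6)
})

test_that("forward-model round trips recover geometry within 0.02 nm", {
  st <- giet_stack(); em <- giet_emitter()
  cv <- giet_curves()
  cases <- rbind(c(1, 4), c(1, 5.4), c(2, 6), c(3, 7), c(11, 5))
  for (i in seq_len(nrow(cases))) {
    zb <- cases[i, 1]; d <- cases[i, 2]
    S_s <- spectrally_averaged_rate(st, em, zb, "above_emitter", d)
    S_l <- spectrally_averaged_rate(st, em, zb + d, "none")
    tau_s <- gietr:::tau_from_rate(S_s, em$tau0, em$phi)
    tau_l <- gietr:::tau_from_rate(S_l, em$tau0, em$phi)
    est <- estimate_heights(tau_s, tau_l, cv)
    expect_true(est$converged)
    expect_lte(est$iterations, 5)
    expect_lt(abs(est$z_bottom - zb), 0.02)
    expect_lt(abs(est$z_top - (zb + d)), 0.02)
    expect_lt(abs(est$d - d), 0.02)
    # the thickness identity holds exactly on converged estimates
    expect_equal(est$d, est$z_top - est$z_bottom, tolerance = 1e-12)
    # the fixed point is a contraction: |d updates| shrink monotonically
    dh <- attr(est, "d_history")
    if (length(dh) > 2) {
      steps <- abs(diff(dh))
      expect_true(all(diff(steps) <= 1e-9))
    }
  }
})

test_that("lifetime ordering and range violations are rejected", {
  cv <- giet_curves()
  expect_error(estimate_heights(2.0, 1.5, cv), "tau_short")
  expect_error(estimate_heights(0.1, 2.0, cv), class = "gietr_out_of_range")
})

test_that("calibration curves export and import losslessly", {
  cu <- giet_calibration("below", 4, z_grid = seq(0, 30, by = 0.5))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_calibration(cu, tf)
  back <- read_calibration(tf)
  expect_equal(back$z_nm, cu$z_nm)
  expect_equal(back$tau_ns, cu$tau_ns, tolerance = 1e-9)
  expect_equal(attr(back, "variant"), "below")
  expect_equal(attr(back, "slb_thickness"), 4)
})
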