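test_that("single-interface Fresnel coefficients match closed forms", {
  # identical media reflect nothing
  expect_equal(fresnel_reflection(1.5, 1.5, 0.7, "s"), 0 + 0i)
  expect_equal(fresnel_reflection(1.5, 1.5, 0.3, "p"), 0 + 0i)
  # normal incidence closed form
  expect_equal(fresnel_reflection(1, 1.5, 0, "s"), (1 - 1.5) / (1 + 1.5) + 0i,
               tolerance = 1e-12)
  # beyond the critical angle a lossless interface reflects with |r| = 1
  q_tir <- 1.1 / 1.33  # in-plane index 1.1, above n2 = 1.0
  for (pol in c("s", "p")) {
    r <- fresnel_reflection(1.33, 1.0, q_tir, pol)
    expect_equal(Mod(r), 1, tolerance = 1e-12)
  }
  expect_error(fresnel_reflection(1.5, 1.5, -0.1), ">= 0")
  expect_error(fresnel_reflection(1.5, 1.5, NaN), "finite")
})

test_that("stack reflection reduces to Airy and respects passivity", {
  # degenerate stack: zero-thickness layers between identical media
  st0 <- giet_stack(substrate_index = 1.333,
                    graphene = giet_layer(0, 1.7),
                    spacer = giet_layer(0, 1.46),
                    medium_index = 1.333)
  expect_equal(stack_reflection(st0, 680, c(0, 0.4, 0.9), "s"),
               rep(0 + 0i, 3), tolerance = 1e-14)
  # a single dielectric film agrees with the closed-form Airy summation
  st1 <- giet_stack(substrate_index = 1.52, graphene = NULL,
                    spacer = giet_layer(120, 1.46), medium_index = 1.333)
  for (pol in c("s", "p")) for (q in c(0, 0.35, 0.8, 1.4)) {
    got <- stack_reflection(st1, 680, q, pol)
    ref <- airy_reflection(1.333, 1.46, 1.52, 120, 680, q, pol)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # full absorbing stack: propagating waves never gain energy
  st <- giet_stack()
  for (lam in c(650, 700, 760)) for (pol in c("s", "p")) {
    r <- stack_reflection(st, lam, seq(0, 0.999, length.out = 101), pol)
    expect_true(all(Mod(r) <= 1 + 1e-12))
  }
})

test_that("free space and mirror limits of the decay rate are exact", {
  # all media equal to the top medium: S = 1 at every height
  free <- giet_stack(substrate_index = 1.333, graphene = NULL, spacer = NULL,
                     medium_index = 1.333)
  for (z in c(0, 3, 40)) {
    expect_equal(relative_decay_rate(free, z, 680, method = "adaptive"), 1,
                 tolerance = 1e-9)
    expect_equal(relative_decay_rate(free, z, 680, "vertical",
                                     method = "adaptive"), 1, tolerance = 1e-9)
  }
  # lossless perfect-mirror limit (r_s -> -1, r_p -> +1): the horizontal
  # dipole is cancelled by its image, the vertical dipole doubles
  mirror <- giet_stack(substrate_index = complex(real = 0, imaginary = 3000),
                       graphene = NULL, spacer = NULL, medium_index = 1.333)
  expect_equal(Mod(stack_reflection(mirror, 680, 0.3, "s")), 1, tolerance = 1e-3)
  Sh <- relative_decay_rate(mirror, 1e-4, 680, "horizontal", method = "adaptive")
  Sv <- relative_decay_rate(mirror, 1e-4, 680, "vertical", method = "adaptive")
  expect_lt(abs(Sh), 0.01)
  expect_equal(Sv, 2, tolerance = 0.01)
})

test_that("adaptive quadrature matches a brute-force trapezoid grid", {
  st <- giet_stack()
  set.seed(42)
  zs <- runif(5, 0.2, 40)
  lams <- runif(5, 655, 770)
  for (i in seq_along(zs)) {
    sa <- relative_decay_rate(st, zs[i], lams[i], method = "adaptive")
    sb <- trapezoid_decay_rate(st, zs[i], lams[i], n_nodes = 1e6)
    expect_equal(sa, sb, tolerance = 1e-6)
  }
  # and the fast fixed-grid path agrees with the adaptive one
  for (i in seq_along(zs)) {
    sg <- relative_decay_rate(st, zs[i], lams[i], method = "grid")
    sa <- relative_decay_rate(st, zs[i], lams[i], method = "adaptive")
    expect_equal(sg, sa, tolerance = 1e-6)
  }
})

test_that("isotropic emitters are the exact 2:1 horizontal:vertical mix", {
  st <- giet_stack()
  sp <- giet_spectrum(data.frame(wavelength_nm = c(680, 682), weight = c(1, 0)))
  z <- c(2, 8, 20)
  Sh <- spectrally_averaged_rate(st, giet_emitter(orientation = "horizontal",
                                                  spectrum = sp), z)
  Sv <- spectrally_averaged_rate(st, giet_emitter(orientation = "vertical",
                                                  spectrum = sp), z)
  Si <- spectrally_averaged_rate(st, giet_emitter(orientation = "isotropic",
                                                  spectrum = sp), z)
  expect_equal(Si, (2 * Sh + Sv) / 3, tolerance = 1e-12)
})

test_that("spectral averaging equals the explicit weighted sum", {
  st <- giet_stack()
  tab <- data.frame(wavelength_nm = c(660, 680, 700, 720),
                    weight = c(0.2, 1.0, 0.7, 0.1))
  em <- giet_emitter(spectrum = giet_spectrum(tab))
  z <- c(1, 6, 15)
  got <- spectrally_averaged_rate(st, em, z, spectral_step = 20)
  # direct summation oracle on the same 20 nm resampled grid
  wl <- seq(660, 720, by = 20)
  w <- approx(tab$wavelength_nm, tab$weight, xout = wl)$y
  ref <- Reduce(`+`, lapply(seq_along(wl), function(i) {
    w[i] * relative_decay_rate(st, z, wl[i])
  })) / sum(w)
  expect_equal(got, ref, tolerance = 1e-12)
  # a spectrum with a single nonzero weight is the single-wavelength rate
  em1 <- single_line_emitter(700)
  expect_equal(spectrally_averaged_rate(st, em1, z),
               relative_decay_rate(st, z, 700), tolerance = 1e-12)
})

test_that("lifetime curve limits: no radiative coupling and free space", {
  st <- giet_stack()
  em_dark <- giet_emitter(phi = 1e-12)
  cu <- lifetime_curve(st, em_dark, c(0, 5, 20))
  expect_equal(cu$tau_ns, rep(2.6, 3), tolerance = 1e-9)
  free <- giet_stack(substrate_index = 1.333, graphene = NULL, spacer = NULL,
                     medium_index = 1.333)
  cu2 <- lifetime_curve(free, giet_emitter(), c(0, 10))
  expect_equal(cu2$tau_ns, rep(2.6, 2), tolerance = 1e-7)
})

test_that("lifetime rises from strong quenching to its plateau within 25 nm", {
  cu <- giet_calibration("none")
  plateau <- spectrally_averaged_rate(giet_stack(), giet_emitter(), 100)
  tau_plateau <- gietr:::tau_from_rate(plateau, 2.6, 0.36)
  expect_lt(cu$tau_ns[1], 0.3 * tau_plateau)           # strong quenching at z = 0
  expect_true(all(diff(cu$tau_ns[cu$z_nm <= 20]) > 0)) # monotone GIET branch
  z90 <- min(cu$z_nm[cu$tau_ns >= 0.9 * tau_plateau])
  expect_lte(z90, 25)
  # far-field recovery: S within 2% of unity at 100 nm
  expect_lt(abs(plateau - 1), 0.02)
})
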