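test_that("decay model matches the closed-form convolved mono-exponential", {
  irf <- giet_irf(sigma = 0.12, shift = 2)
  edges <- seq(0, 40, by = 0.032)
  mu <- decay_model(tau = c(1.7, 3), amp = c(5e5, 0), background = 0,
                    irf = irf, bin_edges = edges)
  ref <- 5e5 * diff(emg_cdf_ref(edges, 1.7, 0.12, 2))
  expect_equal(mu, ref, tolerance = 1e-9)
})

test_that("decay model delta-IRF limit gives analytic bin integrals", {
  irf0 <- giet_irf(sigma = 0, shift = 1)
  edges <- seq(0, 30, by = 0.05)
  mu <- decay_model(tau = c(0.8, 2.4), amp = c(3e5, 7e5), background = 0,
                    irf = irf0, bin_edges = edges)
  ref <- 3e5 * diff(1 - exp(-pmax(edges - 1, 0) / 0.8)) +
    7e5 * diff(1 - exp(-pmax(edges - 1, 0) / 2.4))
  expect_equal(mu, ref, tolerance = 1e-12)
  # zero amplitudes leave the flat background
  flat <- decay_model(c(1, 2), c(0, 0), background = 3.5, irf = irf0,
                      bin_edges = edges)
  expect_equal(flat, rep(3.5, length(edges) - 1))
})

test_that("decay model conserves the total expectation up to truncation", {
  irf <- giet_irf(sigma = 0.1, shift = 2)
  edges <- seq(0, 50, by = 0.016)
  mu <- decay_model(c(1.2, 2.2), c(4e5, 6e5), background = 2, irf = irf,
                    bin_edges = edges)
  expect_equal(sum(mu), 4e5 + 6e5 + 2 * (length(edges) - 1),
               tolerance = 1e-3)
})

test_that("fit recovers exact parameters from noise-free expected counts", {
  irf <- giet_irf()
  edges <- seq(0, 50, by = 0.016)
  mu <- decay_model(c(0.9, 1.8), c(5e5, 5e5), background = 6, irf = irf,
                    bin_edges = edges)
  h <- decay_histogram(round(mu), edges)
  fit <- fit_biexponential(h, irf)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$tau_short - 0.9) / 0.9, 1e-3)
  expect_lt(abs(fit$tau_long - 1.8) / 1.8, 1e-3)
  expect_lt(abs(fit$amp_short - 5e5) / 5e5, 0.01)
  expect_lt(abs(fit$background - 6) / 6, 0.05)
})

test_that("relabeling: swapped initial lifetimes give the identical fit", {
  irf <- giet_irf()
  edges <- seq(0, 50, by = 0.064)
  set.seed(5)
  mu <- decay_model(c(1.0, 2.1), c(2e5, 2e5), background = 2, irf = irf,
                    bin_edges = edges)
  h <- decay_histogram(rpois(length(mu), mu), edges)
  f1 <- fit_biexponential(h, irf, init = list(tau = c(0.8, 2.5),
                                              amp = c(2e5, 2e5), background = 2))
  f2 <- fit_biexponential(h, irf, init = list(tau = c(2.5, 0.8),
                                              amp = c(2e5, 2e5), background = 2))
  expect_equal(f1$tau_short, f2$tau_short, tolerance = 1e-4)
  expect_equal(f1$tau_long, f2$tau_long, tolerance = 1e-4)
  expect_lte(f1$tau_short, f1$tau_long)
})

test_that("Monte-Carlo recovery is unbiased and deviance is calibrated", {
  irf <- giet_irf()
  edges <- seq(0, 50, by = 0.016)
  n_rep <- 50
  taus <- matrix(NA_real_, n_rep, 2)
  rdev <- numeric(n_rep)
  set.seed(2024)
  for (r in seq_len(n_rep)) {
    tt <- sample_biexp_direct(1e6, c(1.2, 2.2), frac_short = 0.5,
                              bg_frac = 0.02, irf = irf, window = 50)
    h <- bunch_photons(tt, 1e6, window = 50, bin_width = 0.016)[[1]]
    fit <- fit_biexponential(h, irf)
    taus[r, ] <- c(fit$tau_short, fit$tau_long)
    rdev[r] <- fit$deviance / (fit$n_bins - 5)
  }
  se <- apply(taus, 2, sd) / sqrt(n_rep)
  bias <- colMeans(taus) - c(1.2, 2.2)
  expect_lt(abs(bias[1]), 3 * se[1])
  expect_lt(abs(bias[2]), 3 * se[2])
  # reduced Poisson deviance of a correct model averages near 1
  expect_gt(mean(rdev), 0.9)
  expect_lt(mean(rdev), 1.1)
})

test_that("optimizer beats every node of a profile-likelihood grid scan", {
  irf <- giet_irf()
  edges <- seq(0, 25, by = 0.064)
  set.seed(77)
  mu <- decay_model(c(0.8, 2.0), c(1e5, 1e5), background = 1.5, irf = irf,
                    bin_edges = edges)
  cts <- rpois(length(mu), mu)
  h <- decay_histogram(cts, edges)
  fit <- fit_biexponential(h, irf)
  best_nll <- -fit$loglik
  grid1 <- seq(0.5, 1.5, length.out = 50)
  grid2 <- seq(1.5, 3.0, length.out = 50)
  node_nll <- outer(grid1, grid2,
                    Vectorize(function(t1, t2)
                      profile_poisson_nll(t1, t2, cts, edges, irf)))
  expect_lte(best_nll, min(node_nll) + 1e-4)
})

test_that("photon bunching is exact, order-preserving and conservative", {
  set.seed(9)
  tt <- runif(2e5, 0, 50)
  hs <- bunch_photons(tt, bunch_size = 1e5, window = 50, bin_width = 0.05)
  expect_length(hs, 2)
  expect_equal(attr(hs[[1]], "total_photons"), 1e5)
  expect_equal(attr(hs[[2]], "total_photons"), 1e5)
  # remainder photons are discarded
  hs2 <- bunch_photons(c(tt, runif(5, 0, 50)), bunch_size = 1e5, window = 50,
                       bin_width = 0.05)
  expect_length(hs2, 2)
  expect_equal(hs2[[1]]$counts, hs[[1]]$counts)
  # concatenation invariance: bunch histograms sum to the direct recount
  total <- hs[[1]]$counts + hs[[2]]$counts
  edges <- attr(hs[[1]], "bin_edges")
  direct <- as.integer(table(cut(tt, edges, right = FALSE)))
  expect_equal(total, direct)
  expect_equal(sum(total), 2e5)  # no photon lost or double-counted
  # empty stream gives an empty list
  expect_length(bunch_photons(numeric(0), 10), 0)
})

test_that("histogram constructor and low-count warning behave", {
  expect_error(decay_histogram(c(1, 2), c(0, 1)), "one more")
  expect_error(decay_histogram(c(1, -2), c(0, 1, 2)), "non-negative")
  h <- decay_histogram(rep(10, 100), seq(0, 10, by = 0.1))
  expect_warning(fit_biexponential(h), "photons")
})
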