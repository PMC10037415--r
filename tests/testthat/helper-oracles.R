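# shared fixtures and independent oracles used across test files

# emitter whose spectrum collapses to (almost) a single wavelength
single_line_emitter <- function(wavelength = 680, ...) {
  sp <- giet_spectrum(data.frame(wavelength_nm = c(wavelength, wavelength + 2),
                                 weight = c(1, 0)))
  giet_emitter(spectrum = sp, ...)
}

# brute-force fixed-grid trapezoid evaluation of the decay-rate integral on
# the same transformed branches the adaptive quadrature uses; only the
# integration rule is under test, so the integrand is taken from the package
trapezoid_decay_rate <- function(stack, z, wavelength, orientation = "horizontal",
                                 n_nodes = 5e5) {
  g <- gietr:::emitter_geometry(stack, wavelength, "none", 0, z)
  corefun <- function(q, w) {
    E <- exp(2i * g$k * w * g$gap)
    gietr:::core_integrand(q, w, 0 + 0i, 0 + 0i,
                           g$Rd(q, "s") * E, g$Rd(q, "p") * E, orientation)
  }
  trap <- function(f, a, b) {
    x <- seq(a, b, length.out = n_nodes)
    y <- f(x)
    sum((y[-1] + y[-n_nodes]) / 2) * (x[2] - x[1])
  }
  i1 <- trap(function(th) Re(corefun(sin(th), cos(th) + 0i)), 0, pi / 2)
  tmax <- acosh(gietr:::q_cutoff(g$k, z))
  i2 <- trap(function(t) Im(corefun(cosh(t), 1i * sinh(t))), 0, tmax)
  coef <- if (orientation == "vertical") 3 / 2 else 3 / 4
  1 + coef * (i1 + i2)
}

# closed-form Airy (two-interface) reflection of a single film, written out
# directly from the Fresnel coefficients
airy_reflection <- function(n1, n2, n3, thickness, wavelength, q, pol) {
  k0 <- 2 * pi / wavelength
  u2 <- (Re(n1) * q)^2 + 0i
  kz <- function(n) {
    r <- sqrt(as.complex(n^2 - u2))
    ifelse(Im(r) < 0, -r, r)
  }
  rr <- function(na, nb) {
    ka <- k0 * kz(na); kb <- k0 * kz(nb)
    if (pol == "s") (ka - kb) / (ka + kb)
    else (nb^2 * ka - na^2 * kb) / (nb^2 * ka + na^2 * kb)
  }
  r12 <- rr(n1, n2); r23 <- rr(n2, n3)
  ph <- exp(2i * k0 * kz(n2) * thickness)
  (r12 + r23 * ph) / (1 + r12 * r23 * ph)
}

# textbook exponentially-modified-Gaussian CDF (direct form, no log-scale
# guard), arranged independently of the package's implementation
emg_cdf_ref <- function(t, tau, sigma, mu) {
  pnorm((t - mu) / sigma) -
    exp(sigma^2 / (2 * tau^2) - (t - mu) / tau) *
    pnorm((t - mu) / sigma - sigma / tau)
}

# profile Poisson likelihood: best amplitudes/background for fixed lifetimes
profile_poisson_nll <- function(tau1, tau2, counts, edges, irf) {
  c1 <- diff(gietr:::emg_cdf(edges, tau1, irf$sigma, irf$shift))
  c2 <- diff(gietr:::emg_cdf(edges, tau2, irf$sigma, irf$shift))
  nll <- function(lp) {
    p <- exp(lp)
    mu <- pmax(p[1] * c1 + p[2] * c2 + p[3], 1e-300)
    sum(mu) - sum(counts * log(mu))
  }
  tot <- sum(counts)
  fit <- nlminb(log(c(tot / 2, tot / 2, 1)), nll,
                control = list(iter.max = 200))
  fit$objective
}

# direct rejection sampler for the window-truncated IRF-convolved
# biexponential mixture (independent of the package's inverse-CDF sampler)
sample_biexp_direct <- function(n, tau, frac_short, bg_frac, irf, window) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2 * (n - length(out)) + 100
    u <- runif(m)
    t <- ifelse(u < bg_frac, runif(m, 0, window),
                irf$shift + rnorm(m, 0, irf$sigma) +
                  rexp(m, 1 / ifelse(runif(m) < frac_short, tau[1], tau[2])))
    out <- c(out, t[t >= 0 & t < window])
  }
  out[seq_len(n)]
}
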