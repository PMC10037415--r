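#' Dipole electrodynamics above the layered GIET substrate
#'
#' The emission-rate model treats the dye as an ideal oscillating electric
#' dipole at height `z` above the stratified substrate and computes its total
#' dissipated power, normalized to the same dipole in the unbounded top
#' medium. The normalized rate `S(z)` follows from the classical
#' wavevector-resolved reflection integrals (CPS-type theory): `S` equals 1
#' plus a reflected-field correction integrated over the normalized in-plane
#' wavevector `q` from 0 through the evanescent region, with separate s- and
#' p-polarized integrands for horizontal and vertical dipoles. Near-field
#' (large `q`) components are absorbed by the graphene sheet; this
#' energy-transfer channel is what makes the total decay rate — and hence the
#' fluorescence lifetime — strongly distance dependent over roughly 25 nm.
#'
#' @name giet-optics
NULL

# principal square root with Im >= 0 (decaying evanescent waves)
msqrt <- function(x) {
  r <- sqrt(as.complex(x))
  ifelse(Im(r) < 0, -r, r)
}

#' Fresnel amplitude reflection coefficient of a single interface
#'
#' Reflection of a plane wave incident from medium 1 onto medium 2, with the
#' in-plane wavevector expressed as `q`, normalized to the wavenumber of
#' medium 1 (so `q = 1` is the grazing/evanescent boundary in medium 1).
#' Normal components of the wavevector take the square-root branch with
#' non-negative imaginary part. The sign convention makes a perfect mirror
#' give `r_s = -1` and `r_p = +1`.
#'
#' @param n1,n2 Complex refractive indices of the incidence and transmission
#'   media (passive: `Im >= 0`).
#' @param q Normalized in-plane wavevector(s), real and `>= 0`.
#' @param pol Polarization, `"s"` or `"p"`.
#' @return Complex reflection coefficient(s), same length as `q`.
#' @export
fresnel_reflection <- function(n1, n2, q, pol = c("s", "p")) {
  pol <- match.arg(pol)
  n1 <- complex_index(n1, "n1"); n2 <- complex_index(n2, "n2")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    abort("`q` must be finite, real and >= 0")
  }
  u2 <- (Re(n1) * q)^2 + 0i  # q normalized to medium 1
  kz1 <- msqrt(n1^2 - u2)
  kz2 <- msqrt(n2^2 - u2)
  if (pol == "s") (kz1 - kz2) / (kz1 + kz2)
  else (n2^2 * kz1 - n1^2 * kz2) / (n2^2 * kz1 + n1^2 * kz2)
}

# interface coefficient given precomputed normal wavevectors (units of k0)
r_interface <- function(kza, kzb, na, nb, pol) {
  if (pol == "s") (kza - kzb) / (kza + kzb)
  else (nb^2 * kza - na^2 * kzb) / (nb^2 * kza + na^2 * kzb)
}

# Parratt recursion through finite layers into a semi-infinite far medium.
# layers: list of list(n = complex, t = nm), ordered emitter-side first.
# q normalized to the emitter medium with real index n_top; vectorized in q.
parratt_reflection <- function(q, wavelength, n_top, layers, n_far, pol) {
  k0 <- 2 * pi / wavelength
  u2 <- (n_top * q)^2 + 0i
  ns <- c(n_top + 0i, vapply(layers, `[[`, complex(1), "n"), n_far)
  kz <- lapply(ns, function(n) k0 * msqrt(n^2 - u2))
  m <- length(layers)
  r <- r_interface(kz[[m + 1]], kz[[m + 2]], ns[m + 1], ns[m + 2], pol)
  if (m >= 1) {
    for (j in m:1) {
      ph <- exp(2i * kz[[j + 1]] * layers[[j]]$t)
      rj <- r_interface(kz[[j]], kz[[j + 1]], ns[j], ns[j + 1], pol)
      rp <- r * ph
      r <- (rj + rp) / (1 + rj * rp)
    }
  }
  r
}

# resolve stack layers below the emitter at one wavelength
resolved_below <- function(stack, wavelength) {
  lapply(stack$below_layers, function(ly) {
    list(n = resolve_index(ly$index, wavelength), t = ly$thickness)
  })
}

#' Reflection coefficient of the half-space on one side of the emitter
#'
#' Looking `"below"`, the wave crosses the spacer and graphene layers and is
#' transmitted into the substrate; looking `"above"`, it either sees the
#' unbounded top medium (no reflection) or, when `slb_thickness > 0`, a
#' membrane slab of index `stack$slb_index` backed by the top medium.
#'
#' @param stack A [giet_stack()].
#' @param wavelength Vacuum wavelength (nm); must lie inside every dispersion
#'   table used by the stack.
#' @param q Normalized in-plane wavevector(s) (relative to the top-medium
#'   wavenumber), real, `>= 0`.
#' @param pol `"s"` or `"p"`.
#' @param side `"below"` or `"above"`.
#' @param slb_thickness Thickness (nm) of the SLB slab above the emitter
#'   (only used for `side = "above"`).
#' @return Complex reflection coefficient(s).
#' @export
stack_reflection <- function(stack, wavelength, q, pol = c("s", "p"),
                             side = c("below", "above"), slb_thickness = 0) {
  pol <- match.arg(pol); side <- match.arg(side)
  stopifnot(inherits(stack, "giet_stack"))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    abort("`q` must be finite, real and >= 0")
  }
  n_top <- Re(stack$medium_index)
  if (side == "below") {
    parratt_reflection(q, wavelength, n_top, resolved_below(stack, wavelength),
                       stack$substrate_index, pol)
  } else {
    if (slb_thickness == 0) return(rep_len(0 + 0i, length(q)))
    layers <- list(list(n = stack$slb_index, t = slb_thickness))
    parratt_reflection(q, wavelength, n_top, layers, stack$medium_index, pol)
  }
}

# cavity correction term: ((1 + s R_u E_u)(1 + s R_d E_d))/(1 - R_u R_d E_u E_d) - 1
# with the upper-reflection product A = R_u * E_u and lower product B = R_d * E_d
cavity_term <- function(A, B, sgn) {
  ((1 + sgn * A) * (1 + sgn * B)) / (1 - A * B) - 1
}

# C(q) = w * F(q): the 1/w-free core of the CPS integrand.
# A_* are upper-side reflection products (vectors over q, or 0),
# B_* lower-side products (vectors or node-by-z matrices).
core_integrand <- function(q, w, A_s, A_p, B_s, B_p, orientation) {
  if (orientation == "vertical") {
    q^3 * cavity_term(A_p, B_p, +1)
  } else {
    q * (cavity_term(A_s, B_s, +1) + w^2 * cavity_term(A_p, B_p, -1))
  }
}

# geometry of the emitter's surroundings for one wavelength:
# returns reflection-coefficient functions for both sides.
# slb: "none", "above_emitter" (slab touches the emitter from above),
#      "below_emitter" (slab touches the emitter from below; needs z >= d).
emitter_geometry <- function(stack, wavelength, slb, d, z = NULL) {
  n_top <- Re(stack$medium_index)
  below <- resolved_below(stack, wavelength)
  if (slb == "below_emitter") {
    if (is.null(z)) abort("slab below the emitter requires `z`")
    if (d < 0) abort("`slb_thickness` must be >= 0")
    if (z < d) abort("emitter height `z` must be >= slab thickness for a slab below the emitter")
    below <- c(list(list(n = stack$slb_index, t = d),
                    list(n = stack$medium_index, t = z - d)), below)
    gap <- 0
  } else {
    gap <- z %||% NA_real_
  }
  Ru <- if (slb == "above_emitter" && d > 0) {
    layers <- list(list(n = stack$slb_index, t = d))
    function(q, pol) parratt_reflection(q, wavelength, n_top, layers,
                                        stack$medium_index, pol)
  } else {
    function(q, pol) rep_len(0 + 0i, length(q))
  }
  list(
    n_top = n_top,
    k = 2 * pi * n_top / wavelength,
    gap = gap,  # distance from emitter down to the first interface below
    Rd = function(q, pol) parratt_reflection(q, wavelength, n_top, below,
                                             stack$substrate_index, pol),
    Ru = Ru
  )
}

# evanescent cutoff: truncate where exp(-2 k z sqrt(q^2-1)) < 1e-12,
# hard cap q <= 50 (always binding for z below ~25 nm)
q_cutoff <- function(k, z) {
  if (z < 0.5) return(50)
  min(50, sqrt(1 + (log(1e12) / (2 * k * z))^2))
}

# adaptive quadrature of S for a single (z, wavelength)
decay_rate_adaptive <- function(stack, z, wavelength, orientation, slb, d,
                                rel_tol = 1e-10) {
  g <- emitter_geometry(stack, wavelength, slb, d, z)
  eval_core <- function(q, w) {
    A_s <- g$Ru(q, "s"); A_p <- g$Ru(q, "p")
    E <- exp(2i * g$k * w * g$gap)
    B_s <- g$Rd(q, "s") * E; B_p <- g$Rd(q, "p") * E
    core_integrand(q, w, A_s, A_p, B_s, B_p, orientation)
  }
  # q = sin(theta) on the propagating branch, q = cosh(t) on the evanescent
  # branch; both substitutions cancel the 1/w singularity at q = 1.
  f_prop <- function(th) Re(eval_core(sin(th), cos(th) + 0i))
  f_evan <- function(t) Im(eval_core(cosh(t), 1i * sinh(t)))
  tmax <- acosh(q_cutoff(g$k, z))
  i1 <- tryCatch(
    integrate(f_prop, 0, pi / 2, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) abort(sprintf("propagating-branch quadrature failed: %s",
                                      conditionMessage(e))))
  i2 <- tryCatch(
    integrate(f_evan, 0, tmax, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) abort(sprintf("evanescent-branch quadrature failed: %s",
                                      conditionMessage(e))))
  coef <- if (orientation == "vertical") 3 / 2 else 3 / 4
  1 + coef * (i1$value + i2$value)
}

# square-root branch points of the stack's lossless materials, expressed in
# the transformed integration variables: a real index n_c > n_top kinks the
# evanescent branch at t = acosh(n_c/n_top), one below n_top kinks the
# propagating branch at theta = asin(n_c/n_top). Gauss-Legendre panels are
# aligned with these points; absorbing materials (graphene) have no kink on
# the real path.
stack_branch_points <- function(stack) {
  n_top <- Re(stack$medium_index)
  cand <- c(stack$substrate_index, stack$slb_index,
            unlist(lapply(stack$below_layers, function(ly) {
              if (inherits(ly$index, "giet_dispersion")) NULL else ly$index
            })))
  cand <- Re(cand[Im(cand) < 1e-3])
  r <- cand / n_top
  list(theta = sort(unique(round(asin(r[r < 1 - 1e-9]), 10))),
       t = sort(unique(round(acosh(r[r > 1 + 1e-9 & r < 50]), 10))))
}

# fixed Gauss-Legendre node set on the transformed branches, with panel
# edges aligned to the stack's branch points (memoized per edge set)
gl_nodes <- function(breaks = list(theta = numeric(0), t = numeric(0))) {
  key <- paste("gl", paste(format(unlist(breaks), digits = 12), collapse = ","))
  if (!is.null(.giet_cache[[key]])) return(.giet_cache[[key]])
  panel <- function(n, a, b) pracma::gaussLegendre(n, a, b)
  th_edges <- sort(unique(c(0, breaks$theta, 1.2, pi / 2)))
  t_edges <- sort(unique(c(0, breaks$t[breaks$t < 1.6], 1.6, acosh(50))))
  th <- c(); thw <- c()
  for (i in seq_len(length(th_edges) - 1)) {
    g <- panel(64, th_edges[i], th_edges[i + 1])
    th <- c(th, g$x); thw <- c(thw, g$w)
  }
  tt <- c(); ttw <- c()
  nt <- length(t_edges) - 1
  for (i in seq_len(nt)) {
    g <- panel(if (i == nt) 96 else 48, t_edges[i], t_edges[i + 1])
    tt <- c(tt, g$x); ttw <- c(ttw, g$w)
  }
  out <- list(
    q = c(sin(th), cosh(tt)),
    w = c(cos(th) + 0i, 1i * sinh(tt)),
    # quadrature weights including the -i factor of the evanescent branch
    wt = c(thw + 0i, -1i * ttw)
  )
  .giet_cache[[key]] <- out
  out
}

# fixed-grid evaluation of S over a vector of heights at one wavelength,
# vectorized over z when the geometry below the emitter is z-independent
decay_rate_grid <- function(stack, z, wavelength, orientation, slb, d) {
  nd <- gl_nodes(stack_branch_points(stack))
  coef <- if (orientation == "vertical") 3 / 2 else 3 / 4
  if (slb == "below_emitter") {
    vapply(z, function(zi) {
      g <- emitter_geometry(stack, wavelength, slb, d, zi)
      C <- core_integrand(nd$q, nd$w, g$Ru(nd$q, "s"), g$Ru(nd$q, "p"),
                          g$Rd(nd$q, "s"), g$Rd(nd$q, "p"), orientation)
      1 + coef * Re(sum(nd$wt * C))
    }, numeric(1))
  } else {
    g <- emitter_geometry(stack, wavelength, slb, d, z = 0)
    A_s <- g$Ru(nd$q, "s"); A_p <- g$Ru(nd$q, "p")
    Rd_s <- g$Rd(nd$q, "s"); Rd_p <- g$Rd(nd$q, "p")
    E <- exp(outer(2i * g$k * nd$w, z))          # nodes x heights
    C <- core_integrand(nd$q, nd$w, A_s, A_p, Rd_s * E, Rd_p * E, orientation)
    1 + coef * Re(as.vector(crossprod(C, nd$wt)))
  }
}

#' Normalized total decay rate of a dipole above the stack
#'
#' Computes `S(z)`, the total dissipated power of an oscillating dipole at
#' height `z` (nm above the SiO2 surface) relative to the same dipole in the
#' unbounded top medium, at a single vacuum wavelength.
#'
#' @param stack A [giet_stack()].
#' @param z Height(s) above the SiO2 surface (nm, `>= 0`).
#' @param wavelength Vacuum wavelength (nm).
#' @param orientation Dipole orientation, `"horizontal"` or `"vertical"`
#'   (mix isotropic emitters yourself as `(2 S_h + S_v) / 3`).
#' @param slb Placement of the optional membrane slab relative to the
#'   emitter: `"none"`, `"above_emitter"` (slab touching the emitter from
#'   above, the geometry for dyes under a membrane), or `"below_emitter"`
#'   (slab directly under the emitter; requires `z >= slb_thickness`).
#' @param slb_thickness Slab thickness (nm).
#' @param method `"grid"` (fast fixed high-order quadrature, vectorized over
#'   `z`) or `"adaptive"` (adaptive quadrature to `rel_tol`).
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Numeric vector of rates `S >= 0`, one per `z`.
#' @export
relative_decay_rate <- function(stack, z, wavelength,
                                orientation = c("horizontal", "vertical"),
                                slb = c("none", "above_emitter", "below_emitter"),
                                slb_thickness = 0,
                                method = c("grid", "adaptive"),
                                rel_tol = 1e-10) {
  orientation <- match.arg(orientation)
  slb <- match.arg(slb)
  method <- match.arg(method)
  stopifnot(inherits(stack, "giet_stack"))
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < 0)) {
    abort("`z` must be finite and >= 0 (nm above the SiO2 surface)")
  }
  if (!is.numeric(wavelength) || length(wavelength) != 1 || !is.finite(wavelength)) {
    abort("`wavelength` must be a single finite number (nm)")
  }
  if (slb != "none" && slb_thickness < 0) abort("`slb_thickness` must be >= 0")
  if (method == "adaptive") {
    vapply(z, function(zi)
      decay_rate_adaptive(stack, zi, wavelength, orientation, slb,
                          slb_thickness, rel_tol), numeric(1))
  } else {
    decay_rate_grid(stack, z, wavelength, orientation, slb, slb_thickness)
  }
}

#' Spectrally averaged decay rate
#'
#' Averages [relative_decay_rate()] over the emitter's emission spectrum:
#' the rate is computed per wavelength on the spectrum resampled to a uniform
#' 2 nm grid and combined with weights normalized to unit sum. Isotropic
#' emitters are the 2:1 power mix of horizontal and vertical dipoles.
#'
#' @inheritParams relative_decay_rate
#' @param emitter A [giet_emitter()].
#' @param spectral_step Resampling step of the emission spectrum (nm).
#' @return Numeric vector of spectrally averaged rates, one per `z`.
#' @export
spectrally_averaged_rate <- function(stack, emitter, z,
                                     slb = c("none", "above_emitter", "below_emitter"),
                                     slb_thickness = 0,
                                     method = c("grid", "adaptive"),
                                     spectral_step = 2) {
  slb <- match.arg(slb); method <- match.arg(method)
  stopifnot(inherits(emitter, "giet_emitter"))
  sp <- resample_spectrum(emitter$spectrum, spectral_step)
  one <- function(orient) {
    acc <- numeric(length(z))
    for (i in seq_len(nrow(sp))) {
      acc <- acc + sp$weight[i] *
        relative_decay_rate(stack, z, sp$wavelength_nm[i], orient,
                            slb, slb_thickness, method)
    }
    acc
  }
  switch(emitter$orientation,
         horizontal = one("horizontal"),
         vertical = one("vertical"),
         isotropic = (2 * one("horizontal") + one("vertical")) / 3)
}

# lifetime from the normalized rate: only the radiative fraction phi of the
# free-space decay is modified by the environment
tau_from_rate <- function(S, tau0, phi) tau0 / (1 - phi + phi * S)

#' Lifetime-versus-distance curve
#'
#' Evaluates the spectrally averaged rate and the resulting fluorescence
#' lifetime `tau(z) = tau0 / (1 - phi + phi * S(z))` on a height grid.
#'
#' @inheritParams spectrally_averaged_rate
#' @param z_grid Strictly increasing heights (nm, `>= 0`).
#' @return A tibble of class `giet_rate_curve` with columns `z_nm`, `S`,
#'   `tau_ns`.
#' @export
lifetime_curve <- function(stack, emitter, z_grid,
                           slb = c("none", "above_emitter", "below_emitter"),
                           slb_thickness = 0,
                           method = c("grid", "adaptive")) {
  slb <- match.arg(slb); method <- match.arg(method)
  if (any(diff(z_grid) <= 0)) abort("`z_grid` must be strictly increasing")
  S <- spectrally_averaged_rate(stack, emitter, z_grid, slb, slb_thickness,
                                method)
  out <- tibble(z_nm = z_grid, S = S,
                tau_ns = tau_from_rate(S, emitter$tau0, emitter$phi))
  class(out) <- c("giet_rate_curve", class(out))
  attr(out, "slb") <- slb
  attr(out, "slb_thickness") <- slb_thickness
  out
}
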