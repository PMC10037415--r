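#' GIET calibration curves and height inversion
#'
#' A calibration curve samples the fluorescence lifetime tau(z) of the dye as
#' a function of its height above the SiO2 surface for one of three membrane
#' geometries: no membrane (`"none"`), dye above the SLB (`"above"`, slab
#' directly below the dye), or dye below the SLB (`"below"`, slab directly
#' above the dye; the geometry of bottom-leaflet labels). Lifetimes are
#' converted back into heights on the rising, invertible branch of the curve,
#' which ends at the first local lifetime maximum.
#'
#' @name giet-calibration
NULL

out_of_range <- function(msg) abort(msg, class = "gietr_out_of_range")

# index of the last point of the monotone rising branch (first local max)
branch_end <- function(tau) {
  drop <- which(diff(tau) <= 0)
  if (length(drop) == 0) length(tau) else drop[1]
}

new_calibration <- function(z, S, tau, variant, d) {
  out <- tibble(z_nm = z, S = S, tau_ns = tau)
  class(out) <- c("giet_calibration", "giet_rate_curve", class(tibble()))
  attr(out, "variant") <- variant
  attr(out, "slb_thickness") <- d
  attr(out, "monotone_limit") <- z[branch_end(tau)]
  out
}

#' Build a GIET calibration curve
#'
#' @param variant Geometry variant: `"none"` (bare substrate), `"above"`
#'   (dye above the SLB; indistinguishable from `"none"` in practice), or
#'   `"below"` (dye below an SLB of thickness `slb_thickness`).
#' @param slb_thickness SLB thickness `d` in nm (used by `"below"` and
#'   `"above"`; `d = 0` reproduces `"none"` exactly).
#' @param emitter A [giet_emitter()].
#' @param stack A [giet_stack()].
#' @param z_grid Strictly increasing heights (nm); the default covers
#'   0-30 nm at 0.05 nm spacing. For `"above"`, points with `z <
#'   slb_thickness` (dye inside the membrane) are dropped.
#' @param method Quadrature method passed to the rate computation.
#' @param use_cache Reuse identical curves computed earlier this session.
#' @return A tibble of class `giet_calibration` with columns `z_nm`, `S`,
#'   `tau_ns` and attributes `variant`, `slb_thickness`, `monotone_limit`.
#' @export
giet_calibration <- function(variant = c("none", "above", "below"),
                             slb_thickness = 0,
                             emitter = giet_emitter(),
                             stack = giet_stack(),
                             z_grid = seq(0, 30, by = 0.05),
                             method = c("grid", "adaptive"),
                             use_cache = TRUE) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  if (!is.numeric(slb_thickness) || length(slb_thickness) != 1 ||
      !is.finite(slb_thickness) || slb_thickness < 0) {
    abort("`slb_thickness` must be a single finite number >= 0 (nm)")
  }
  key <- stack_key(fn = "calibration", variant = variant, d = slb_thickness,
                   stack = unclass(stack), emitter = unclass(emitter),
                   z = range(z_grid), nz = length(z_grid), method = method)
  if (use_cache && !is.null(.giet_cache[[key]])) return(.giet_cache[[key]])
  slb <- switch(variant, none = "none", below = "above_emitter",
                above = "below_emitter")
  d <- if (variant == "none") 0 else slb_thickness
  zg <- z_grid
  if (variant == "above") zg <- zg[zg >= d]
  if (length(zg) < 2) abort("`z_grid` leaves fewer than 2 valid heights")
  cu <- lifetime_curve(stack, emitter, zg, slb = slb, slb_thickness = d,
                       method = method)
  out <- new_calibration(cu$z_nm, cu$S, cu$tau_ns, variant, d)
  if (use_cache) .giet_cache[[key]] <- out
  out
}

# monotone cubic interpolant of tau(z) on the rising branch
branch_spline <- function(curve) {
  ie <- branch_end(curve$tau_ns)
  splinefun(curve$z_nm[seq_len(ie)], curve$tau_ns[seq_len(ie)],
            method = "hyman")
}

#' Invert a lifetime into a height
#'
#' Solves `tau(z) = tau` on the rising branch of a calibration curve by
#' bisection on a monotone cubic interpolant of the sampled curve. Lifetimes
#' outside `[tau(0), tau(monotone_limit)]` signal a distance outside the
#' invertible GIET range and raise a classed error (`gietr_out_of_range`).
#'
#' @param curve A `giet_calibration`.
#' @param tau Lifetime value(s) in ns.
#' @return Height(s) `z` in nm.
#' @export
invert_lifetime <- function(curve, tau) {
  stopifnot(inherits(curve, "giet_calibration"))
  ie <- branch_end(curve$tau_ns)
  lo <- curve$z_nm[1]; hi <- curve$z_nm[ie]
  tlo <- curve$tau_ns[1]; thi <- curve$tau_ns[ie]
  f <- branch_spline(curve)
  vapply(tau, function(tt) {
    if (!is.finite(tt)) abort("`tau` must be finite")
    if (tt > thi) {
      out_of_range(sprintf(
        "tau = %.4f ns exceeds the branch maximum %.4f ns (beyond the GIET dynamic range)",
        tt, thi))
    }
    if (tt < tlo) {
      out_of_range(sprintf(
        "tau = %.4f ns is below tau(0) = %.4f ns", tt, tlo))
    }
    a <- lo; b <- hi
    for (i in 1:80) {
      m <- (a + b) / 2
      if (f(m) < tt) a <- m else b <- m
      if (b - a < 1e-9) break
    }
    (a + b) / 2
  }, numeric(1))
}

#' Maximum horizontal displacement between two calibration curves
#'
#' Measures how far curve `b` is displaced from curve `a` along the height
#' axis: the maximum over shared lifetime levels (on both rising branches)
#' of `|z_a(tau) - z_b(tau)|`. Levels are restricted to the sensitive part
#' of the branches — lifetimes up to `sensitivity_cap` times the smaller of
#' the two branch maxima — because on the approach to the lifetime plateau
#' the slope `d tau / d z` vanishes and horizontal displacement becomes an
#' ill-conditioned (and physically meaningless) ratio of two quantities
#' that both tend to zero.
#'
#' @param curve_a,curve_b `giet_calibration` curves.
#' @param n_levels Number of lifetime levels sampled across the shared range.
#' @param sensitivity_cap Upper lifetime cutoff as a fraction of the branch
#'   maximum (default 0.95, roughly the end of the usable GIET dynamic
#'   range).
#' @return Displacement in nm.
#' @export
calibration_shift <- function(curve_a, curve_b, n_levels = 200,
                              sensitivity_cap = 0.95) {
  rng <- function(cu) {
    ie <- branch_end(cu$tau_ns)
    c(cu$tau_ns[1], cu$tau_ns[ie])
  }
  ra <- rng(curve_a); rb <- rng(curve_b)
  lo <- max(ra[1], rb[1])
  hi <- sensitivity_cap * min(ra[2], rb[2])
  if (!(hi > lo)) out_of_range("the two curves share no lifetime range")
  eps <- (hi - lo) * 1e-6
  lev <- seq(lo + eps, hi - eps, length.out = n_levels)
  max(abs(invert_lifetime(curve_a, lev) - invert_lifetime(curve_b, lev)))
}

#' Precomputed family of below-SLB calibration curves
#'
#' Builds the below-SLB curve on a grid of membrane thicknesses `d` so the
#' iterative height inversion can interpolate in `(tau, d)` instead of
#' re-solving the electrodynamics at every iteration. Lower-half-space
#' reflections are shared across the family, so this is much faster than
#' building the curves one by one.
#'
#' @param d_grid Membrane thicknesses (nm), strictly increasing, starting
#'   at 0.
#' @inheritParams giet_calibration
#' @return A list of class `giet_curve_family` with elements `d_grid` and
#'   `curves` (one `giet_calibration` per `d`).
#' @export
giet_below_family <- function(d_grid = seq(0, 10, by = 0.25),
                              emitter = giet_emitter(),
                              stack = giet_stack(),
                              z_grid = seq(0, 30, by = 0.05),
                              use_cache = TRUE) {
  if (any(diff(d_grid) <= 0) || any(d_grid < 0)) {
    abort("`d_grid` must be non-negative and strictly increasing")
  }
  key <- stack_key(fn = "family", d = d_grid, stack = unclass(stack),
                   emitter = unclass(emitter), z = range(z_grid),
                   nz = length(z_grid))
  if (use_cache && !is.null(.giet_cache[[key]])) return(.giet_cache[[key]])
  Sbar <- below_family_rates(stack, emitter, z_grid, d_grid)
  curves <- lapply(seq_along(d_grid), function(j) {
    new_calibration(z_grid, Sbar[, j],
                    tau_from_rate(Sbar[, j], emitter$tau0, emitter$phi),
                    variant = "below", d = d_grid[j])
  })
  out <- structure(list(d_grid = d_grid, curves = curves),
                   class = "giet_curve_family")
  if (use_cache) .giet_cache[[key]] <- out
  out
}

# spectrally averaged rates for the whole below-SLB family at once:
# matrix length(z_grid) x length(d_grid)
below_family_rates <- function(stack, emitter, z_grid, d_grid,
                               spectral_step = 2) {
  sp <- resample_spectrum(emitter$spectrum, spectral_step)
  nd <- gl_nodes(stack_branch_points(stack))
  n_top <- Re(stack$medium_index)
  orients <- switch(emitter$orientation,
                    horizontal = list(c("horizontal", 1)),
                    vertical = list(c("vertical", 1)),
                    isotropic = list(c("horizontal", 2 / 3), c("vertical", 1 / 3)))
  acc <- matrix(0, nrow = length(z_grid), ncol = length(d_grid))
  for (i in seq_len(nrow(sp))) {
    lam <- sp$wavelength_nm[i]
    below <- resolved_below(stack, lam)
    k <- 2 * pi * n_top / lam
    Rd_s <- parratt_reflection(nd$q, lam, n_top, below, stack$substrate_index, "s")
    Rd_p <- parratt_reflection(nd$q, lam, n_top, below, stack$substrate_index, "p")
    E <- exp(outer(2i * k * nd$w, z_grid))
    B_s <- Rd_s * E; B_p <- Rd_p * E
    slb_layer <- function(d) list(list(n = stack$slb_index, t = d))
    for (j in seq_along(d_grid)) {
      d <- d_grid[j]
      if (d > 0) {
        A_s <- parratt_reflection(nd$q, lam, n_top, slb_layer(d),
                                  stack$medium_index, "s")
        A_p <- parratt_reflection(nd$q, lam, n_top, slb_layer(d),
                                  stack$medium_index, "p")
      } else {
        A_s <- A_p <- rep_len(0 + 0i, length(nd$q))
      }
      for (oo in orients) {
        coef <- if (oo[[1]] == "vertical") 3 / 2 else 3 / 4
        C <- core_integrand(nd$q, nd$w, A_s, A_p, B_s, B_p, oo[[1]])
        S <- 1 + coef * Re(as.vector(crossprod(C, nd$wt)))
        acc[, j] <- acc[, j] + sp$weight[i] * as.numeric(oo[[2]]) * S
      }
    }
  }
  acc
}

# height of the bottom-leaflet dye for a given short lifetime and membrane
# thickness, interpolated linearly in d across the precomputed family
g_bottom <- function(tau_short, d, family) {
  dg <- family$d_grid
  if (d < dg[1] - 1e-9 || d > dg[length(dg)] + 1e-9) {
    out_of_range(sprintf(
      "membrane thickness d = %.3f nm outside the precomputed family range [%g, %g] nm",
      d, dg[1], dg[length(dg)]))
  }
  d <- min(max(d, dg[1]), dg[length(dg)])
  j <- findInterval(d, dg, rightmost.closed = TRUE)
  if (j == length(dg)) j <- j - 1
  a <- (d - dg[j]) / (dg[j + 1] - dg[j])
  (1 - a) * invert_lifetime(family$curves[[j]], tau_short) +
    a * invert_lifetime(family$curves[[j + 1]], tau_short)
}

#' Default calibration curve set for the height inversion
#'
#' Convenience constructor bundling the top-leaflet curve (no-SLB geometry,
#' which is indistinguishable from the above-SLB geometry) and the
#' below-SLB curve family used by [estimate_heights()].
#'
#' @inheritParams giet_below_family
#' @return A list of class `giet_curves` with elements `top` and `family`.
#' @export
giet_curves <- function(emitter = giet_emitter(), stack = giet_stack(),
                        d_grid = seq(0, 10, by = 0.25),
                        z_grid = seq(0, 30, by = 0.05),
                        use_cache = TRUE) {
  structure(
    list(top = giet_calibration("none", emitter = emitter, stack = stack,
                                z_grid = z_grid, use_cache = use_cache),
         family = giet_below_family(d_grid, emitter, stack, z_grid,
                                    use_cache = use_cache)),
    class = "giet_curves")
}

#' Iterative thickness-consistent height estimation
#'
#' Converts a leaflet lifetime pair into heights and membrane thickness.
#' The long lifetime is inverted once on the top curve to give `z_top`. The
#' short lifetime is inverted on the below-SLB curve, whose shape depends on
#' the membrane thickness `d = z_top - z_bottom` itself, so `z_bottom`
#' solves an implicit equation: starting from `d = 0`, `z_bottom` is
#' re-inverted and `d` updated until the change in `d` falls below `tol`.
#'
#' @param tau_short,tau_long Leaflet lifetimes (ns), `tau_short <= tau_long`
#'   (bottom and top leaflet respectively).
#' @param curves A [giet_curves()] set (or pass `family` and `top`
#'   separately).
#' @param tol Convergence tolerance on `d` (nm).
#' @param max_iter Iteration cap.
#' @return A one-row tibble of class `giet_height` with columns `z_bottom`,
#'   `z_top`, `d`, `iterations`, `converged`.
#' @export
estimate_heights <- function(tau_short, tau_long, curves = giet_curves(),
                             tol = 0.01, max_iter = 20) {
  stopifnot(inherits(curves, "giet_curves"))
  if (!is.finite(tau_short) || !is.finite(tau_long)) {
    abort("lifetimes must be finite")
  }
  if (tau_short > tau_long + 1e-12) {
    abort("`tau_short` must not exceed `tau_long`")
  }
  z_top <- invert_lifetime(curves$top, tau_long)
  d <- 0
  converged <- FALSE
  evals <- 0
  d_hist <- numeric(0)
  while (evals <= max_iter) {
    evals <- evals + 1
    z_bottom <- g_bottom(tau_short, d, curves$family)
    d_new <- max(z_top - z_bottom, 0)
    d_hist <- c(d_hist, d_new)
    if (abs(d_new - d) < tol) {
      d <- d_new
      converged <- TRUE
      break
    }
    d <- d_new
  }
  # report the self-consistent pair (z_bottom, d = z_top - z_bottom);
  # iterations counts the corrective d updates after the initial d = 0 pass
  z_bottom <- z_top - d
  out <- tibble(z_bottom = z_bottom, z_top = z_top, d = d,
                iterations = max(evals - 1L, 1L), converged = converged)
  class(out) <- c("giet_height", class(out))
  attr(out, "d_history") <- d_hist
  out
}

#' @export
print.giet_curve_family <- function(x, ...) {
  cat(sprintf("<giet_curve_family> %d below-SLB curves, d = %g..%g nm\n",
              length(x$d_grid), min(x$d_grid), max(x$d_grid)))
  invisible(x)
}

#' @export
print.giet_curves <- function(x, ...) {
  cat("<giet_curves>\n  top: no-SLB calibration curve\n")
  print(x$family)
  invisible(x)
}
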