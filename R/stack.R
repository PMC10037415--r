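#' Optical layers, dispersion tables and emitters
#'
#' The GIET substrate is described as a stratified medium: a semi-infinite
#' glass substrate carrying a single graphene sheet and a thin SiO2 spacer,
#' bounded above by a semi-infinite aqueous medium that contains the dye.
#' Heights `z` are measured in nm from the top surface of the SiO2 spacer
#' upward; graphene and spacer lie below `z = 0`.
#'
#' @name giet-materials
NULL

complex_index <- function(x, what = "refractive index") {
  x <- as.complex(x)
  if (length(x) != 1 || !is.finite(Re(x)) || !is.finite(Im(x))) {
    abort(sprintf("`%s` must be a single finite (complex) number.", what))
  }
  if (Im(x) < 0) abort(sprintf("`%s` must have Im >= 0 (passive medium).", what))
  if (Re(x) < 0 || Mod(x) == 0) abort(sprintf("`%s` must have Re >= 0 and nonzero modulus.", what))
  x
}

#' Validate a dispersion table
#'
#' A dispersion table gives the complex refractive index n + ik of a material
#' on a strictly increasing wavelength grid (nm). Indices at intermediate
#' wavelengths are obtained by linear interpolation; requests outside the
#' tabulated range are an error.
#'
#' @param table Data frame with columns `wavelength_nm`, `n`, `k`.
#' @param name Label used in error messages.
#' @return A tibble of class `giet_dispersion`.
#' @export
giet_dispersion <- function(table, name = "dispersion") {
  table <- as_tibble(table)
  need <- c("wavelength_nm", "n", "k")
  if (!all(need %in% names(table))) {
    abort(sprintf("dispersion table `%s` needs columns %s",
                  name, paste(need, collapse = ", ")))
  }
  wl <- table$wavelength_nm
  if (anyNA(table[need]) || any(!is.finite(wl))) {
    abort(sprintf("dispersion table `%s` contains non-finite values", name))
  }
  if (any(diff(wl) <= 0)) {
    abort(sprintf("dispersion table `%s`: wavelengths must be strictly increasing", name))
  }
  if (any(table$n <= 0)) abort(sprintf("dispersion table `%s`: n must be > 0", name))
  if (any(table$k < 0)) abort(sprintf("dispersion table `%s`: k must be >= 0", name))
  structure(table[need], class = c("giet_dispersion", class(table)),
            material = name)
}

#' Read a dispersion table from a delimited file
#'
#' Expects one header line `wavelength_nm,n,k`.
#'
#' @param path File path.
#' @param name Material label (defaults to the file name).
#' @return A `giet_dispersion` tibble.
#' @export
read_dispersion <- function(path, name = basename(path)) {
  giet_dispersion(readr::read_csv(path, show_col_types = FALSE), name = name)
}

#' Packaged default graphene dispersion
#'
#' Complex refractive index of single-layer graphene represented as a
#' homogeneous 0.34 nm slab. The packaged default is computed from graphene's
#' universal optical sheet conductivity (the pi*alpha ~ 2.3% single-pass
#' absorption), i.e. eps(lambda) = 1 + i * alpha * lambda / (2 * t) with
#' t = 0.34 nm. Its absorptive part Im(eps) = 2 n k agrees with published
#' visible-range ellipsometry of graphene to within a few percent. Replace it
#' with a measured table via [read_dispersion()] when one is available.
#'
#' @return A `giet_dispersion` tibble covering 400-1000 nm.
#' @export
graphene_dispersion <- function() {
  path <- system.file("extdata", "graphene_dispersion_model.csv", package = "gietr")
  read_dispersion(path, name = "graphene")
}

#' Validate an emission spectrum
#'
#' @param table Data frame with columns `wavelength_nm` and non-negative
#'   `weight` on a strictly increasing wavelength grid.
#' @param name Label used in error messages.
#' @return A tibble of class `giet_spectrum`.
#' @export
giet_spectrum <- function(table, name = "emission") {
  table <- as_tibble(table)
  need <- c("wavelength_nm", "weight")
  if (!all(need %in% names(table))) {
    abort(sprintf("emission spectrum `%s` needs columns %s",
                  name, paste(need, collapse = ", ")))
  }
  if (anyNA(table[need])) abort("emission spectrum contains missing values")
  if (any(diff(table$wavelength_nm) <= 0)) {
    abort("emission spectrum: wavelengths must be strictly increasing")
  }
  if (any(table$weight < 0) || !any(table$weight > 0)) {
    abort("emission spectrum: weights must be >= 0 with at least one positive")
  }
  structure(table[need], class = c("giet_spectrum", class(table)), name = name)
}

#' Read an emission spectrum from a delimited file
#'
#' Expects one header line `wavelength_nm,weight`.
#'
#' @inheritParams read_dispersion
#' @return A `giet_spectrum` tibble.
#' @export
read_emission_spectrum <- function(path, name = basename(path)) {
  giet_spectrum(readr::read_csv(path, show_col_types = FALSE), name = name)
}

#' Packaged Atto655-like emission spectrum
#'
#' A smooth synthetic stand-in for the measured emission spectrum of the
#' red-emitting dye Atto655 (peak near 680 nm, red-shaded band over
#' 650-780 nm), used as the default spectral weight for calibration curves.
#'
#' @return A `giet_spectrum` tibble.
#' @export
atto655_spectrum <- function() {
  path <- system.file("extdata", "atto655_emission_synthetic.csv", package = "gietr")
  read_emission_spectrum(path, name = "Atto655 (synthetic)")
}

# resolve a (possibly dispersive) index at given wavelengths -> complex vector
resolve_index <- function(index, wavelength) {
  if (inherits(index, "giet_dispersion")) {
    wl <- index$wavelength_nm
    out <- wavelength < min(wl) | wavelength > max(wl)
    if (any(out)) {
      abort(sprintf(
        "wavelength %g nm outside the range [%g, %g] of dispersion table `%s`",
        wavelength[which(out)[1]], min(wl), max(wl), attr(index, "material")))
    }
    n <- approx(wl, index$n, xout = wavelength)$y
    k <- approx(wl, index$k, xout = wavelength)$y
    complex(real = n, imaginary = k)
  } else {
    rep_len(as.complex(index), length(wavelength))
  }
}

#' Describe a finite optical layer
#'
#' @param thickness Layer thickness in nm (finite, `>= 0`).
#' @param index Complex refractive index, or a [giet_dispersion()] table for
#'   wavelength-dependent materials.
#' @param name Optional label.
#' @return A list of class `giet_layer`.
#' @export
giet_layer <- function(thickness, index, name = "layer") {
  if (!is.numeric(thickness) || length(thickness) != 1 ||
      !is.finite(thickness) || thickness < 0) {
    abort("`thickness` must be a single finite number >= 0 (nm)")
  }
  if (!inherits(index, "giet_dispersion")) index <- complex_index(index, name)
  structure(list(thickness = thickness, index = index, name = name),
            class = "giet_layer")
}

#' The GIET layer stack
#'
#' Describes the stratified medium sensed by the emitting dipole: a
#' semi-infinite glass substrate, the graphene sheet, the SiO2 spacer, and the
#' semi-infinite aqueous medium above in which the emitter sits. An optional
#' membrane slab (the SLB) can be placed directly above or directly below the
#' emitter plane; calibration-curve geometry variants use this slot.
#'
#' @param substrate_index Complex index of the semi-infinite substrate
#'   (default glass, 1.52).
#' @param graphene Optional [giet_layer()] for the graphene sheet; default is
#'   a 0.34 nm slab with the packaged dispersion table. Use `NULL` to omit.
#' @param spacer Optional [giet_layer()] for the spacer (default 10 nm SiO2,
#'   index 1.46). Use `NULL` to omit.
#' @param medium_index Complex index of the semi-infinite top medium
#'   containing the emitter (default water, 1.333).
#' @param slb_index Complex index used for the SLB slab in calibration
#'   geometry variants (default 1.46).
#' @return A list of class `giet_stack`.
#' @export
giet_stack <- function(substrate_index = 1.52,
                       graphene = giet_layer(0.34, graphene_dispersion(), "graphene"),
                       spacer = giet_layer(10, 1.46, "SiO2"),
                       medium_index = 1.333,
                       slb_index = 1.46) {
  below <- list()
  if (!is.null(spacer)) below <- c(below, list(spacer))
  if (!is.null(graphene)) below <- c(below, list(graphene))
  for (ly in below) stopifnot(inherits(ly, "giet_layer"))
  structure(
    list(substrate_index = complex_index(substrate_index, "substrate_index"),
         below_layers = below,
         medium_index = complex_index(medium_index, "medium_index"),
         slb_index = complex_index(slb_index, "slb_index")),
    class = "giet_stack")
}

#' Dye photophysics
#'
#' Free-space lifetime, quantum yield, dipole orientation relative to the
#' substrate plane, and emission spectrum of the reporter dye. Defaults are
#' the Atto655 values used throughout: tau0 = 2.6 ns, phi = 0.36, and a
#' horizontal (in-plane) transition dipole, appropriate for a headgroup label
#' lying in the membrane plane.
#'
#' @param tau0 Free-space fluorescence lifetime (ns, > 0).
#' @param phi Free-space quantum yield in (0, 1].
#' @param orientation `"horizontal"`, `"vertical"`, or `"isotropic"`
#'   (isotropic is the 2:1 horizontal:vertical power mix).
#' @param spectrum A [giet_spectrum()]; default [atto655_spectrum()].
#' @return A list of class `giet_emitter`.
#' @export
giet_emitter <- function(tau0 = 2.6, phi = 0.36,
                         orientation = c("horizontal", "vertical", "isotropic"),
                         spectrum = atto655_spectrum()) {
  orientation <- match.arg(orientation)
  if (!is.numeric(tau0) || length(tau0) != 1 || !is.finite(tau0) || tau0 <= 0) {
    abort("`tau0` must be a single positive number (ns)")
  }
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0 || phi > 1) {
    abort("`phi` must be in (0, 1]")
  }
  stopifnot(inherits(spectrum, "giet_spectrum"))
  structure(list(tau0 = tau0, phi = phi, orientation = orientation,
                 spectrum = spectrum),
            class = "giet_emitter")
}

# resample an emission spectrum to a uniform step (nm) and normalize weights
resample_spectrum <- function(spectrum, step = 2) {
  wl <- spectrum$wavelength_nm
  grid <- seq(min(wl), max(wl), by = step)
  w <- approx(wl, spectrum$weight, xout = grid)$y
  w <- pmax(w, 0)
  tibble(wavelength_nm = grid, weight = w / sum(w))
}

# deterministic cache key for stack/emitter/geometry combinations
stack_key <- function(...) {
  parts <- list(...)
  ser <- rapply(parts, function(x) paste(format(x, digits = 15), collapse = ","),
                how = "unlist")
  rlang::hash(paste(names(ser), ser, collapse = ";"))
}

#' @export
print.giet_stack <- function(x, ...) {
  cat("<giet_stack>\n")
  cat(sprintf("  top medium        n = %s (semi-infinite, contains emitter)\n",
              format(x$medium_index)))
  for (ly in x$below_layers) {
    idx <- if (inherits(ly$index, "giet_dispersion")) {
      sprintf("dispersive [%g-%g nm]", min(ly$index$wavelength_nm),
              max(ly$index$wavelength_nm))
    } else format(ly$index)
    cat(sprintf("  %-10s %6.2f nm  n = %s\n", ly$name, ly$thickness, idx))
  }
  cat(sprintf("  substrate         n = %s (semi-infinite)\n",
              format(x$substrate_index)))
  cat(sprintf("  SLB slab index    n = %s\n", format(x$slb_index)))
  invisible(x)
}

#' @export
print.giet_emitter <- function(x, ...) {
  cat("<giet_emitter>\n")
  cat(sprintf("  tau0 = %g ns, phi = %g, orientation = %s\n",
              x$tau0, x$phi, x$orientation))
  cat(sprintf("  spectrum: %s, %d points over %g-%g nm\n",
              attr(x$spectrum, "name"), nrow(x$spectrum),
              min(x$spectrum$wavelength_nm), max(x$spectrum$wavelength_nm)))
  invisible(x)
}
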