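#' Full analysis pipeline
#'
#' Per-bunch biexponential fits, lifetime-to-height conversion, mean +/- SD
#' aggregation over bunches, and a descriptive parabolic trend of thickness
#' versus cholesterol content.
#'
#' @name giet-pipeline
NULL

#' Analyze a measurement (a set of per-bunch histograms)
#'
#' Fits every bunch with the IRF-convolved biexponential model, converts
#' each lifetime pair into heights and thickness with the iterative
#' inversion, and aggregates thickness over bunches. Bunches whose fit does
#' not converge, is degenerate (effectively mono-exponential), whose
#' lifetimes fall outside the invertible calibration branch, or whose
#' inversion does not converge are excluded from the aggregate and counted
#' in the diagnostics.
#'
#' @param histograms List of [decay_histogram()] objects (one per bunch).
#' @param irf A [giet_irf()].
#' @param curves A [giet_curves()] calibration set.
#' @param tol,max_iter Passed to [estimate_heights()].
#' @return An object of class `giet_thickness`: list with `mean_d`, `sd_d`
#'   (sample SD over retained bunches), `n_bunches`, `n_dropped`, and the
#'   `per_bunch` tibble (`tau_short`, `tau_long`, `z_bottom`, `z_top`, `d`,
#'   `converged`, `retained`).
#' @export
analyze_measurement <- function(histograms, irf = giet_irf(),
                                curves = giet_curves(), tol = 0.01,
                                max_iter = 20) {
  if (length(histograms) < 1) abort("need at least one histogram")
  rows <- purrr::map_dfr(seq_along(histograms), function(i) {
    fit <- fit_biexponential(histograms[[i]], irf)
    row <- tibble(bunch = i, tau_short = fit$tau_short,
                  tau_long = fit$tau_long,
                  fit_converged = fit$converged, degenerate = fit$degenerate,
                  z_bottom = NA_real_, z_top = NA_real_, d = NA_real_,
                  iterations = NA_integer_, converged = FALSE,
                  note = "")
    if (!fit$converged) { row$note <- "fit did not converge"; return(row) }
    if (fit$degenerate) { row$note <- "degenerate fit"; return(row) }
    est <- tryCatch(
      estimate_heights(fit$tau_short, fit$tau_long, curves, tol, max_iter),
      gietr_out_of_range = function(e) NULL)
    if (is.null(est)) { row$note <- "lifetime outside calibration range"; return(row) }
    row$z_bottom <- est$z_bottom; row$z_top <- est$z_top; row$d <- est$d
    row$iterations <- est$iterations; row$converged <- est$converged
    if (!est$converged) row$note <- "inversion did not converge"
    row
  })
  rows$retained <- rows$converged & rows$fit_converged & !rows$degenerate
  kept <- rows$d[rows$retained]
  if (length(kept) == 0) {
    abort(paste0("no bunch produced a converged thickness estimate; notes: ",
                 paste(unique(rows$note), collapse = "; ")))
  }
  structure(list(
    mean_d = mean(kept),
    sd_d = if (length(kept) > 1) sd(kept) else NA_real_,
    n_bunches = nrow(rows),
    n_dropped = sum(!rows$retained),
    per_bunch = rows
  ), class = "giet_thickness")
}

#' Simulate and analyze a scenario end to end
#'
#' Convenience wrapper chaining [simulate_measurement()], [bunch_photons()]
#' and [analyze_measurement()].
#'
#' @inheritParams simulate_measurement
#' @inheritParams analyze_measurement
#' @param bin_width Histogram bin width (ns).
#' @return A `giet_thickness` with the scenario truth attached as attribute
#'   `"truth"`.
#' @export
analyze_scenario <- function(design, emitter = giet_emitter(),
                             irf = giet_irf(), stack = giet_stack(),
                             curves = NULL, window = 50, bin_width = 0.016) {
  curves <- curves %||% giet_curves(emitter, stack)
  sim <- simulate_measurement(design, emitter, irf, stack, window)
  hs <- bunch_photons(sim$stream, design$photons_per_bunch, window, bin_width)
  out <- analyze_measurement(hs, irf, curves)
  attr(out, "truth") <- sim$truth
  out
}

#' Parabolic trend of thickness versus cholesterol content
#'
#' Ordinary least-squares fit of `d(x) = c0 + c1 x + c2 x^2` with `x` the
#' cholesterol content in mol %. The parabola is descriptive — a smooth
#' guide to the thickening/thinning trend — not a physical model. An
#' inverse-variance weighted fit (weights `1/sd^2`) is available.
#'
#' @param points Data frame with columns `chol_pct`, `mean_d` and (for the
#'   weighted fit) `sd_d`.
#' @param weighted Use weights `1/sd_d^2` instead of the default unweighted
#'   fit.
#' @return An object of class `giet_trend`: list with `coefficients`
#'   (`c0`, `c1`, `c2`), `residuals`, `fitted`, and the underlying `lm`.
#' @export
trend_fit <- function(points, weighted = FALSE) {
  points <- as_tibble(points)
  if (!all(c("chol_pct", "mean_d") %in% names(points))) {
    abort("`points` needs columns `chol_pct` and `mean_d`")
  }
  if (length(unique(points$chol_pct)) < 3) {
    abort("need at least 3 distinct cholesterol levels for a parabola")
  }
  w <- NULL
  if (weighted) {
    if (!"sd_d" %in% names(points)) abort("weighted fit needs an `sd_d` column")
    w <- 1 / points$sd_d^2
  }
  df <- data.frame(x = points$chol_pct, y = points$mean_d)
  fit <- if (weighted) lm(y ~ x + I(x^2), data = df, weights = w)
  else lm(y ~ x + I(x^2), data = df)
  structure(list(
    coefficients = setNames(coef(fit), c("c0", "c1", "c2")),
    residuals = as.numeric(resid(fit)),
    fitted = as.numeric(fit$fitted.values),
    weighted = weighted,
    lm = fit
  ), class = "giet_trend")
}

#' Write an aggregated thickness result table
#'
#' One row per (lipid, cholesterol) cell, ordered by lipid then cholesterol:
#' `lipid,chol_pct,mean_d_nm,sd_d_nm,n_bunches`.
#'
#' @param estimates Data frame with columns `lipid`, `chol_pct`,
#'   `mean_d_nm`, `sd_d_nm`, `n_bunches`, or a named list of
#'   `giet_thickness` objects keyed by `lipid:chol`.
#' @param path Output file.
#' @return Invisibly, the tibble that was written.
#' @export
write_results <- function(estimates, path) {
  if (is.data.frame(estimates)) {
    tab <- as_tibble(estimates)
  } else {
    tab <- purrr::imap_dfr(estimates, function(est, key) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      tibble(lipid = parts[1], chol_pct = as.numeric(parts[2]),
             mean_d_nm = est$mean_d, sd_d_nm = est$sd_d,
             n_bunches = est$n_bunches - est$n_dropped)
    })
  }
  need <- c("lipid", "chol_pct", "mean_d_nm", "sd_d_nm", "n_bunches")
  if (nrow(tab) == 0) {
    tab <- tibble(lipid = character(), chol_pct = numeric(),
                  mean_d_nm = numeric(), sd_d_nm = numeric(),
                  n_bunches = integer())
  }
  if (!all(need %in% names(tab))) {
    abort(paste("`estimates` needs columns", paste(need, collapse = ", ")))
  }
  tab <- dplyr::arrange(tab[need], .data$lipid, .data$chol_pct)
  readr::write_csv(tab, path)
  invisible(tab)
}

#' Read a thickness result table written by [write_results()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(lipid = readr::col_character()))
}

#' Export / import a calibration curve
#'
#' Curves are stored as a `z_nm,tau_ns` table preceded by `#`-prefixed
#' metadata lines (variant and SLB thickness) so a curve can be rebuilt
#' without re-running the electrodynamics.
#'
#' @param curve A `giet_calibration`.
#' @param path File path.
#' @return `write_calibration` invisibly returns `curve`;
#'   `read_calibration` returns a `giet_calibration`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "giet_calibration"))
  writeLines(c(sprintf("# variant: %s", attr(curve, "variant")),
               sprintf("# slb_thickness_nm: %g", attr(curve, "slb_thickness")),
               "z_nm,tau_ns",
               sprintf("%.10g,%.10g", curve$z_nm, curve$tau_ns)), path)
  invisible(curve)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  hdr <- readLines(path, n = 2)
  variant <- sub("^# variant: *", "", hdr[1])
  d <- as.numeric(sub("^# slb_thickness_nm: *", "", hdr[2]))
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  new_calibration(tab$z_nm, S = rep(NA_real_, nrow(tab)), tau = tab$tau_ns,
                  variant = variant, d = d)
}

#' @export
print.giet_thickness <- function(x, ...) {
  cat("<giet_thickness>\n")
  cat(sprintf("  mean d = %.3f nm, sd = %.3f nm over %d of %d bunches (%d dropped)\n",
              x$mean_d, x$sd_d, x$n_bunches - x$n_dropped, x$n_bunches,
              x$n_dropped))
  invisible(x)
}

#' @export
print.giet_trend <- function(x, ...) {
  cat("<giet_trend> d(x) = c0 + c1 x + c2 x^2,",
      if (x$weighted) "1/sd^2-weighted" else "unweighted", "\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}
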