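#' Broom-style and ggplot2 methods for gietr objects
#'
#' `tidy()` returns per-term or per-bunch tibbles, `glance()` one-row model
#' summaries, and `autoplot()` ggplot2 figures for each result type.
#'
#' @name giet-methods
NULL

#' @export
tidy.giet_biexp <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov), 0))
  tibble(term = c("tau_short", "tau_long", "amp_short", "amp_long",
                  "background"),
         estimate = c(x$tau_short, x$tau_long, x$amp_short, x$amp_long,
                      x$background),
         std.error = c(se[1], se[2], NA_real_, NA_real_, NA_real_))
}

#' @export
glance.giet_biexp <- function(x, ...) {
  tibble(logLik = x$loglik, deviance = x$deviance,
         df.residual = x$n_bins - 5L, n_photons = x$n_photons,
         converged = x$converged, degenerate = x$degenerate)
}

#' @export
tidy.giet_thickness <- function(x, ...) x$per_bunch

#' @export
glance.giet_thickness <- function(x, ...) {
  tibble(mean_d = x$mean_d, sd_d = x$sd_d, n_bunches = x$n_bunches,
         n_dropped = x$n_dropped)
}

#' @export
tidy.giet_trend <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = c("c0", "c1", "c2"),
         estimate = as.numeric(x$coefficients),
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.giet_trend <- function(x, ...) {
  s <- summary(x$lm)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$lm$df.residual, weighted = x$weighted)
}

#' @export
autoplot.giet_rate_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_nm, y = .data$tau_ns)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = "height above SiO2 surface z (nm)",
                  y = "fluorescence lifetime τ (ns)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.giet_curve_family <- function(object, ...) {
  df <- purrr::map2_dfr(object$curves, object$d_grid, function(cu, d) {
    tibble(z_nm = cu$z_nm, tau_ns = cu$tau_ns, d_nm = d)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_nm, y = .data$tau_ns,
                                   group = .data$d_nm,
                                   colour = .data$d_nm)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "SLB thickness d (nm)") +
    ggplot2::labs(x = "height above SiO2 surface z (nm)",
                  y = "fluorescence lifetime τ (ns)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.giet_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                            y = .data$counts)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "micro-time (ns)", y = "photon counts") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "giet_biexp"))
    mu <- decay_model(c(fit$tau_short, fit$tau_long),
                      c(fit$amp_short, fit$amp_long),
                      fit$background, fit$irf, attr(object, "bin_edges"))
    p <- p + ggplot2::geom_line(
      data = tibble(time_ns = object$time_ns, counts = mu),
      colour = "#d7301f", linewidth = 0.6)
  }
  p
}

#' @export
autoplot.giet_thickness <- function(object, ...) {
  df <- dplyr::filter(object$per_bunch, .data$retained)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bunch, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_d, colour = "#d7301f") +
    ggplot2::geom_hline(yintercept = object$mean_d + c(-1, 1) * object$sd_d,
                        colour = "#d7301f", linetype = 2) +
    ggplot2::labs(x = "bunch", y = "bilayer thickness d (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.giet_trend <- function(object, ...) {
  df <- data.frame(x = object$lm$model$x, y = object$lm$model$y)
  xs <- seq(min(df$x), max(df$x), length.out = 100)
  cf <- object$coefficients
  pred <- data.frame(x = xs, y = cf[1] + cf[2] * xs + cf[3] * xs^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = pred, colour = "#2c7fb8") +
    ggplot2::labs(x = "cholesterol content (mol %)",
                  y = "bilayer thickness d (nm)") +
    ggplot2::theme_minimal()
}
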