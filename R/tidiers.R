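#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_function
#'   scale_x_log10 labs theme_minimal geom_col
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy method for isotherm fits
#' @param x An `isotherm_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.isotherm_fit <- function(x, ...) {
  tibble(term = c("r_min", "r_max", "c50"),
         estimate = c(x$r_min, x$r_max, x$c50),
         std.error = unname(x$std_errors[c("r_min", "r_max", "c50")]))
}

#' Glance method for isotherm fits
#' @inheritParams tidy.isotherm_fit
#' @return One-row tibble: `dynamic_range`, `sse`, `n`, `flags`.
#' @export
glance.isotherm_fit <- function(x, ...) {
  tibble(dynamic_range = x$r_max / x$r_min, sse = x$residual_sse,
         n = nrow(x$data),
         flags = paste(x$flags, collapse = ";"))
}

#' @export
tidy.fp_direct_fit <- function(x, ...) {
  tibble(term = c("fp0", "fps", "kd"),
         estimate = c(x$fp0, x$fps, x$kd),
         std.error = unname(x$std_errors[c("fp0", "fps", "kd")]))
}

#' @export
glance.fp_direct_fit <- function(x, ...) {
  tibble(sse = x$residual_sse, n = nrow(x$data), tracer_uM = x$tracer_conc)
}

#' @export
tidy.fp_competition_fit <- function(x, ...) {
  tibble(term = c("fp0", "fps", "c50"),
         estimate = c(x$fp0, x$fps, x$c50),
         std.error = unname(x$std_errors[c("fp0", "fps", "c50")]))
}

#' @export
glance.fp_competition_fit <- function(x, ...) {
  tibble(sse = x$residual_sse, n = nrow(x$data))
}

#' @export
tidy.decay_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(), .before = 1)
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         tau_amplitude_weighted_ns = amplitude_weighted_lifetime(x),
         offset = x$offset, chi2_reduced = x$chi2_reduced,
         n_bins = x$n_used, method = x$method)
}

#' @export
tidy.lifetime_calibration <- function(x, ...) {
  tibble(term = c("tau_donor_ns", "e_min", "e_max", "c50_uM"),
         estimate = c(x$tau_donor_ns, x$e_min, x$e_max, x$c50_uM),
         std.error = c(NA_real_, unname(x$std_errors[c("e_min", "e_max", "c50")])))
}

#' @export
glance.lifetime_calibration <- function(x, ...) {
  tibble(tau_donor_ns = x$tau_donor_ns, e_min = x$e_min, e_max = x$e_max,
         c50_uM = x$c50_uM, n_points = if (is.null(x$points)) NA_integer_ else nrow(x$points),
         flags = paste(x$flags, collapse = ";"))
}

#' Plot a titration fit over its data
#' @param object An `isotherm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isotherm_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(conc_uM = 10^seq(log10(max(min(d$conc_uM[d$conc_uM > 0]), 1e-4)),
                                  log10(max(d$conc_uM)), length.out = 200))
  grid$ratio <- predict(object, grid$conc_uM)
  ggplot(d, aes(x = .data$conc_uM, y = .data$ratio)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, color = "steelblue") +
    scale_x_log10() +
    labs(x = "[analyte] (uM)", y = "emission ratio",
         title = sprintf("c50 = %.3g uM, dynamic range %.2f-fold",
                         object$c50, object$r_max / object$r_min)) +
    theme_minimal()
}

#' Plot an FP binding fit over its data
#' @param object An `fp_direct_fit` or `fp_competition_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fp_direct_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x_uM = 10^seq(log10(max(min(d$x_uM[d$x_uM > 0]), 1e-4)),
                               log10(max(d$x_uM)), length.out = 200))
  grid$fp <- predict(object, grid$x_uM)
  ggplot(d, aes(x = .data$x_uM, y = .data$fp)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, color = "steelblue") +
    scale_x_log10() +
    labs(x = "[protein] (uM)", y = "polarization",
         title = sprintf("Kd = %.3g uM", object$kd)) +
    theme_minimal()
}

#' @rdname autoplot.fp_direct_fit
#' @export
autoplot.fp_competition_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x_uM = 10^seq(log10(max(min(d$x_uM[d$x_uM > 0]), 1e-4)),
                               log10(max(d$x_uM)), length.out = 200))
  grid$fp <- predict(object, grid$x_uM)
  ggplot(d, aes(x = .data$x_uM, y = .data$fp)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, color = "steelblue") +
    scale_x_log10() +
    labs(x = "[competitor] (uM)", y = "polarization",
         title = sprintf("c50 = %.3g uM", object$c50)) +
    theme_minimal()
}

#' Plot a decay fit: counts, model and residuals
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot (log-count scale).
#' @export
autoplot.decay_fit <- function(object, ...) {
  d <- tibble(t_ns = object$t_used, counts = object$counts_used,
              fitted = object$fitted)
  ggplot(d, aes(x = .data$t_ns)) +
    geom_point(aes(y = .data$counts), size = 0.4, alpha = 0.5) +
    geom_line(aes(y = .data$fitted), color = "firebrick") +
    ggplot2::scale_y_log10() +
    labs(x = "time (ns)", y = "photons / bin",
         title = sprintf("amplitude-weighted tau = %.3g ns, chi2_red = %.3f",
                         amplitude_weighted_lifetime(object), object$chi2_reduced)) +
    theme_minimal()
}

#' Plot a lifetime calibration curve
#' @param object A `lifetime_calibration` with its per-point table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lifetime_calibration <- function(object, ...) {
  if (is.null(object$points)) {
    stop_fq("Calibration has no per-point table to plot (loaded from JSON?).",
            "fq_empty_error")
  }
  d <- object$points
  grid <- tibble(conc_uM = 10^seq(log10(max(min(d$conc_uM[d$conc_uM > 0]), 1e-4)),
                                  log10(max(d$conc_uM)), length.out = 200))
  grid$efficiency <- object$e_min + (object$e_max - object$e_min) /
    (1 + object$c50_uM / grid$conc_uM)
  ggplot(d, aes(x = .data$conc_uM, y = .data$efficiency)) +
    geom_point() +
    geom_line(data = grid, color = "steelblue") +
    scale_x_log10() +
    labs(x = "[analyte] (uM)", y = "FRET efficiency E",
         title = sprintf("tau_D = %.3g ns, c50 = %.3g uM",
                         object$tau_donor_ns, object$c50_uM)) +
    theme_minimal()
}

#' Display a net FRET raster
#' @param x A `net_fret_image`.
#' @param ... Unused.
#' @return A ggplot raster of net FRET, invalid pixels blank.
#' @export
plot_net_fret <- function(x, ...) {
  stopifnot(inherits(x, "net_fret_image"))
  d <- tidyr::expand_grid(row = seq_len(nrow(x$net)), col = seq_len(ncol(x$net)))
  d$net <- as.numeric(x$net)[(d$col - 1) * nrow(x$net) + d$row]
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$net)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    labs(fill = "net FRET") +
    theme_minimal()
}
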