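#' Hyperbolic sensor response to analyte concentration
#'
#' Forward model for a ratiometric FRET sensor: the emission ratio follows a
#' one-site hyperbola \eqn{R = R_{min} + (R_{max} - R_{min}) / (1 + c_{50}/c)},
#' where \eqn{c_{50}} is the analyte concentration of half-maximal ratio
#' change. At `conc = 0` the zero-analyte limit \eqn{R_{min}} is returned.
#'
#' @param conc Analyte concentration(s), uM, non-negative.
#' @param r_min Emission ratio in the absence of analyte.
#' @param r_max Emission ratio at analyte saturation.
#' @param c50 Concentration of half-maximal ratio change, uM (> 0).
#'
#' @return Numeric vector of predicted emission ratios.
#' @examples
#' isotherm_response(c(0, 13.9, 139), r_min = 1, r_max = 2.8, c50 = 13.9)
#' @export
isotherm_response <- function(conc, r_min, r_max, c50) {
  check_numeric(conc, "conc", nonneg = TRUE)
  check_numeric(c50, "c50", positive = TRUE)
  out <- r_min + (r_max - r_min) / (1 + c50 / conc)
  out[conc == 0] <- r_min
  out
}

#' Invert the sensor isotherm: emission ratio to concentration
#'
#' Algebraic inverse of [isotherm_response()]:
#' \eqn{c = c_{50} (R - R_{min}) / (R_{max} - R)}. Defined only for ratios
#' strictly between `r_min` and `r_max`; the saturated endpoint maps to an
#' infinite concentration and is rejected.
#'
#' @param ratio Observed emission ratio(s), strictly inside (`r_min`, `r_max`).
#' @param fit An `isotherm_fit` object, or `NULL` if the three parameters are
#'   given directly.
#' @inheritParams isotherm_response
#' @return Concentration(s), uM.
#' @export
isotherm_invert <- function(ratio, fit = NULL, r_min = NULL, r_max = NULL, c50 = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "isotherm_fit"))
    r_min <- fit$r_min; r_max <- fit$r_max; c50 <- fit$c50
  }
  check_numeric(ratio, "ratio")
  lo <- min(r_min, r_max); hi <- max(r_min, r_max)
  if (any(ratio <= lo)) {
    stop_fq(sprintf("ratio <= %.6g (the zero-analyte bound r_min/r_max floor); no finite concentration maps there.", lo),
            "fq_range_error")
  }
  if (any(ratio >= hi)) {
    stop_fq(sprintf("ratio >= %.6g (the saturation bound); concentration diverges at saturation.", hi),
            "fq_range_error")
  }
  c50 * (ratio - r_min) / (r_max - ratio)
}

#' Sensor dynamic range
#'
#' The fold change of the emission ratio between saturation and zero analyte,
#' \eqn{\Delta R = R_{max} / R_{min}}.
#'
#' @param fit An `isotherm_fit`, or `NULL` when `r_min`/`r_max` are supplied.
#' @inheritParams isotherm_response
#' @return Fold change (dimensionless).
#' @examples
#' dynamic_range(r_min = 1, r_max = 2.8)
#' @export
dynamic_range <- function(fit = NULL, r_min = NULL, r_max = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "isotherm_fit"))
    r_min <- fit$r_min; r_max <- fit$r_max
  }
  if (!is.numeric(r_min) || r_min <= 0) {
    stop_fq("`r_min` must be > 0 to define a dynamic range.", "fq_domain_error")
  }
  r_max / r_min
}

#' Selectivity of a sensor between two analytes
#'
#' Fold difference between the half-maximal concentration for an off-target
#' analyte and that for the target analyte. Values well above 1 indicate a
#' selective sensor.
#'
#' @param c50_other c50 for the competing analyte, uM (> 0).
#' @param c50_analyte c50 for the target analyte, uM (> 0).
#' @return `c50_other / c50_analyte`.
#' @export
selectivity_fold <- function(c50_other, c50_analyte) {
  check_numeric(c50_other, "c50_other", positive = TRUE)
  check_numeric(c50_analyte, "c50_analyte", positive = TRUE)
  c50_other / c50_analyte
}

validate_titration <- function(conc, ratio) {
  check_numeric(conc, "conc", nonneg = TRUE)
  check_numeric(ratio, "ratio", positive = TRUE)
  if (length(conc) != length(ratio)) {
    stop_fq("Concentration and ratio vectors must have equal length.", "fq_shape_error")
  }
  if (length(unique(conc)) < 5) {
    stop_fq("At least 5 distinct concentrations are required to fit the isotherm.",
            "fq_design_error")
  }
  invisible(NULL)
}

#' Fit the sensor titration isotherm
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) fit of the
#' hyperbolic response [isotherm_response()] to a concentration-ratio series,
#' with free parameters `r_min`, `r_max` and `c50`. `c50` is log-parameterized
#' internally so positivity is structural; standard errors are mapped back to
#' the linear scale by the delta method. Replicates are pooled: every row is
#' one observation.
#'
#' Starting values are data-driven: `r_min`/`r_max` from the 5th/95th
#' percentiles of the observed ratios (orientation chosen by the low- vs
#' high-concentration means) and `c50` from the concentration whose mean ratio
#' lies nearest the midpoint.
#'
#' @param data A data frame of the titration, e.g. from [read_titration_csv()]
#'   or [sim_titration()].
#' @param conc,ratio Columns holding concentration (uM) and emission ratio;
#'   tidy-eval, defaults `conc_uM` and `ratio`.
#' @return An object of class `isotherm_fit` with fields `r_min`, `r_max`,
#'   `c50` (uM), `std_errors`, `residual_sse`, `flags` (character; may contain
#'   `"extrapolated"` or `"unidentifiable_c50"`), and the data used. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], `predict()`.
#' @examples
#' d <- tibble::tibble(conc_uM = 10^seq(-2, 3, length.out = 9),
#'                     ratio   = isotherm_response(10^seq(-2, 3, length.out = 9), 1, 2.8, 13.9))
#' fit <- fit_isotherm(d)
#' fit$c50
#' @export
fit_isotherm <- function(data, conc = conc_uM, ratio = ratio) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ conc }})
  y <- dplyr::pull(data, {{ ratio }})
  validate_titration(x, y)

  flags <- character()

  # Data-driven starts
  ord <- order(x)
  lo_mean <- mean(y[ord][seq_len(max(2L, length(y) %/% 4L))])
  hi_mean <- mean(rev(y[ord])[seq_len(max(2L, length(y) %/% 4L))])
  q <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  if (hi_mean >= lo_mean) { r_min0 <- q[1]; r_max0 <- q[2] } else { r_min0 <- q[2]; r_max0 <- q[1] }
  mid <- (r_min0 + r_max0) / 2
  pos <- x[x > 0]
  c50_0 <- if (length(pos)) pos[which.min(abs(y[x > 0] - mid))] else 1
  if (!is.finite(c50_0) || c50_0 <= 0) c50_0 <- stats::median(pos)

  env <- new.env()
  env$x <- x; env$y <- y
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ r_min + (r_max - r_min) / (1 + exp(lc50) / ifelse(x == 0, Inf, x)) * ifelse(x == 0, 0, 1),
      data = env,
      start = list(r_min = r_min0, r_max = r_max0, lc50 = log(c50_0)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    # Degenerate series (e.g. flat response): report the mean level, flag c50.
    if (stats::sd(y) < 1e-8 * abs(mean(y)) + 1e-12) {
      return(new_isotherm_fit(
        r_min = mean(y), r_max = mean(y), c50 = NA_real_,
        std_errors = c(r_min = NA, r_max = NA, c50 = NA),
        residual_sse = sum((y - mean(y))^2),
        flags = "unidentifiable_c50", data = tibble(conc_uM = x, ratio = y)
      ))
    }
    stop_fq(paste0("Isotherm fit failed to converge: ", conditionMessage(fit)),
            "fq_fit_error")
  }

  cf <- stats::coef(fit)
  c50 <- exp(cf[["lc50"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(cf)
  se_c50 <- c50 * se[["lc50"]]  # delta method for exp()

  if (abs(cf[["r_max"]] - cf[["r_min"]]) < 1e-6 * (abs(cf[["r_min"]]) + 1e-12)) {
    flags <- c(flags, "unidentifiable_c50")
  }
  pos_rng <- range(x[x > 0])
  if (is.finite(c50) && (c50 > pos_rng[2] * 10 || c50 < pos_rng[1] / 10)) {
    flags <- c(flags, "extrapolated")
    warn_fq("Fitted c50 lies >10x outside the sampled concentration range; treat as extrapolated.",
            "fq_extrapolated_warning")
  }

  new_isotherm_fit(
    r_min = unname(cf[["r_min"]]), r_max = unname(cf[["r_max"]]), c50 = unname(c50),
    std_errors = c(r_min = unname(se[["r_min"]]), r_max = unname(se[["r_max"]]), c50 = unname(se_c50)),
    residual_sse = sum(stats::resid(fit)^2),
    flags = flags, data = tibble(conc_uM = x, ratio = y)
  )
}

new_isotherm_fit <- function(r_min, r_max, c50, std_errors, residual_sse, flags, data) {
  structure(
    list(r_min = r_min, r_max = r_max, c50 = c50,
         std_errors = std_errors, residual_sse = residual_sse,
         flags = flags, data = data),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("<isotherm_fit>\n")
  cat(sprintf("  r_min = %.4g (SE %.3g)\n", x$r_min, x$std_errors[["r_min"]]))
  cat(sprintf("  r_max = %.4g (SE %.3g)\n", x$r_max, x$std_errors[["r_max"]]))
  cat(sprintf("  c50   = %.4g uM (SE %.3g)\n", x$c50, x$std_errors[["c50"]]))
  cat(sprintf("  dynamic range = %.3g-fold; SSE = %.4g\n",
              x$r_max / x$r_min, x$residual_sse))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.isotherm_fit <- function(object, conc, ...) {
  isotherm_response(conc, object$r_min, object$r_max, object$c50)
}

#' Fluorescence polarization from polarized intensity components
#'
#' \eqn{FP = (I_\parallel - G I_\perp) / (I_\parallel + G I_\perp)}, where `G`
#' is the instrument grating factor correcting the detection efficiency of the
#' two polarization channels. The result is dimensionless and lies in
#' \[-1, 1\]; multiply by 1000 for mFP units.
#'
#' @param i_parallel Intensity parallel to the excitation polarization (>= 0).
#' @param i_perpendicular Perpendicular intensity (>= 0).
#' @param g_factor Grating factor (> 0), default 1.
#' @return Polarization value(s) in \[-1, 1\].
#' @examples
#' fp_polarization(3, 1, g_factor = 2)
#' @export
fp_polarization <- function(i_parallel, i_perpendicular, g_factor = 1) {
  check_numeric(i_parallel, "i_parallel", nonneg = TRUE)
  check_numeric(i_perpendicular, "i_perpendicular", nonneg = TRUE)
  check_numeric(g_factor, "g_factor", positive = TRUE)
  denom <- i_parallel + i_perpendicular * g_factor
  if (any(denom == 0)) {
    stop_fq("Both polarization components are zero; FP undefined.", "fq_domain_error")
  }
  (i_parallel - i_perpendicular * g_factor) / denom
}

# Bound fraction of tracer under ligand depletion (exact quadratic solution
# of the 1:1 binding equilibrium at tracer concentration L).
quadratic_bound_fraction <- function(protein, kd, tracer) {
  s <- protein + tracer + kd
  (s - sqrt(pmax(s^2 - 4 * tracer * protein, 0))) / (2 * tracer)
}

#' Fit a direct (quadratic, ligand-depletion) polarization binding curve
#'
#' Fits the exact 1:1 binding solution for a fluorescent tracer at fixed
#' concentration titrated with protein:
#' \deqn{FP = FP_0 + (FP_s - FP_0) \frac{(L + K_d + P) - \sqrt{(L + P + K_d)^2 - 4 L P}}{2L}}
#' with free parameters `fp0` (free tracer), `fps` (bound tracer) and `kd`.
#' Unlike the simple hyperbola, this form remains correct when the tracer
#' concentration is comparable to `kd` (ligand depletion).
#'
#' @param data Data frame with protein concentrations and FP readings.
#' @param x,fp Columns holding protein concentration (uM) and polarization;
#'   defaults `x_uM`, `fp`.
#' @param tracer_conc Labeled tracer concentration, uM (e.g. 0.05 for a 50 nM
#'   tracer).
#' @return An `fp_direct_fit` with `fp0`, `fps`, `kd` (uM), `std_errors`,
#'   `residual_sse`, `tracer_conc`.
#' @export
fit_fp_direct <- function(data, x = x_uM, fp = fp, tracer_conc) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ fp }})
  check_numeric(xv, "x", nonneg = TRUE)
  check_numeric(yv, "fp")
  if (length(xv) != length(yv)) stop_fq("x and fp lengths differ.", "fq_shape_error")
  check_numeric(tracer_conc, "tracer_conc", positive = TRUE)

  fp0_0 <- yv[which.min(xv)]
  fps_0 <- yv[which.max(xv)]
  mid <- (fp0_0 + fps_0) / 2
  kd_0 <- max(xv[which.min(abs(yv - mid))], min(xv[xv > 0], na.rm = TRUE))

  env <- new.env(); env$xv <- xv; env$yv <- yv; env$L <- tracer_conc
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ fp0 + (fps - fp0) * ((xv + exp(lkd) + L) -
        sqrt((xv + exp(lkd) + L)^2 - 4 * L * xv)) / (2 * L),
      data = env,
      start = list(fp0 = fp0_0, fps = fps_0, lkd = log(kd_0)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      stop_fq(paste0("Direct FP fit failed to converge: ", conditionMessage(e),
                     sprintf(" (last starts fp0=%.4g fps=%.4g kd=%.4g)", fp0_0, fps_0, kd_0)),
              "fq_fit_error")
    }
  )
  cf <- stats::coef(fit)
  kd <- exp(cf[["lkd"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(vc), 0)); names(se) <- names(cf)
  structure(
    list(fp0 = unname(cf[["fp0"]]), fps = unname(cf[["fps"]]), kd = unname(kd),
         std_errors = c(fp0 = unname(se[["fp0"]]), fps = unname(se[["fps"]]),
                        kd = unname(kd * se[["lkd"]])),
         residual_sse = sum(stats::resid(fit)^2),
         tracer_conc = tracer_conc,
         data = tibble(x_uM = xv, fp = yv)),
    class = "fp_direct_fit"
  )
}

#' @export
print.fp_direct_fit <- function(x, ...) {
  cat("<fp_direct_fit>\n")
  cat(sprintf("  fp0 = %.4g, fps = %.4g, Kd = %.4g uM (SE %.3g)\n",
              x$fp0, x$fps, x$kd, x$std_errors[["kd"]]))
  cat(sprintf("  tracer = %.4g uM; SSE = %.4g\n", x$tracer_conc, x$residual_sse))
  invisible(x)
}

#' @export
predict.fp_direct_fit <- function(object, x, ...) {
  object$fp0 + (object$fps - object$fp0) *
    quadratic_bound_fraction(x, object$kd, object$tracer_conc)
}

#' Fit a competition polarization curve
#'
#' Fits the hyperbolic displacement model
#' \eqn{FP = FP_0 + (FP_s - FP_0) / (1 + c_{50}/c)} to FP readings against
#' competitor concentration `c`. `fp0` is the polarization at zero competitor
#' (tracer fully bound), `fps` the polarization at saturating competitor
#' (tracer displaced, free), and `c50` the half-displacement concentration.
#'
#' @param data Data frame of competitor concentration vs polarization.
#' @param x,fp Columns; defaults `x_uM`, `fp`.
#' @return An `fp_competition_fit` with `fp0`, `fps`, `c50` (uM),
#'   `std_errors`, `residual_sse`.
#' @export
fit_fp_competition <- function(data, x = x_uM, fp = fp) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ fp }})
  check_numeric(xv, "x", nonneg = TRUE)
  check_numeric(yv, "fp")
  if (length(xv) != length(yv)) stop_fq("x and fp lengths differ.", "fq_shape_error")

  fp0_0 <- yv[which.min(xv)]
  fps_0 <- yv[which.max(xv)]
  mid <- (fp0_0 + fps_0) / 2
  pos <- xv[xv > 0]
  c50_0 <- max(xv[which.min(abs(yv - mid))], min(pos))

  env <- new.env(); env$xv <- xv; env$yv <- yv
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ fp0 + (fps - fp0) / (1 + exp(lc50) / ifelse(xv == 0, Inf, xv)) * ifelse(xv == 0, 0, 1),
      data = env,
      start = list(fp0 = fp0_0, fps = fps_0, lc50 = log(c50_0)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      stop_fq(paste0("Competition FP fit failed to converge: ", conditionMessage(e),
                     sprintf(" (last starts fp0=%.4g fps=%.4g c50=%.4g)", fp0_0, fps_0, c50_0)),
              "fq_fit_error")
    }
  )
  cf <- stats::coef(fit)
  c50 <- exp(cf[["lc50"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(vc), 0)); names(se) <- names(cf)
  structure(
    list(fp0 = unname(cf[["fp0"]]), fps = unname(cf[["fps"]]), c50 = unname(c50),
         std_errors = c(fp0 = unname(se[["fp0"]]), fps = unname(se[["fps"]]),
                        c50 = unname(c50 * se[["lc50"]])),
         residual_sse = sum(stats::resid(fit)^2),
         data = tibble(x_uM = xv, fp = yv)),
    class = "fp_competition_fit"
  )
}

#' @export
print.fp_competition_fit <- function(x, ...) {
  cat("<fp_competition_fit>\n")
  cat(sprintf("  fp0 = %.4g, fps = %.4g, c50 = %.4g uM (SE %.3g)\n",
              x$fp0, x$fps, x$c50, x$std_errors[["c50"]]))
  cat(sprintf("  SSE = %.4g\n", x$residual_sse))
  invisible(x)
}

#' @export
predict.fp_competition_fit <- function(object, x, ...) {
  out <- object$fp0 + (object$fps - object$fp0) / (1 + object$c50 / x)
  out[x == 0] <- object$fp0
  out
}
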