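#' TCSPC decay histogram
#'
#' A time-correlated single-photon-counting decay: photon counts per uniform
#' time bin, with an optional instrument-response histogram on the same bins.
#'
#' @param t_ns Left edges of the time bins, ns, uniformly spaced.
#' @param counts Non-negative integer photon counts per bin.
#' @param irf Optional instrument-response counts on the same bins.
#' @return A `decay_histogram` with derived fields `bin_width_ns` and
#'   `total_photons`.
#' @export
decay_histogram <- function(t_ns, counts, irf = NULL) {
  check_numeric(t_ns, "t_ns")
  check_numeric(counts, "counts", nonneg = TRUE)
  if (length(t_ns) != length(counts)) {
    stop_fq("`t_ns` and `counts` must have equal length.", "fq_shape_error")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_fq("`counts` must be integers (photon counts).", "fq_domain_error")
  }
  dt <- diff(t_ns)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * stats::median(dt)) {
    stop_fq("Time bins must be uniform.", "fq_domain_error")
  }
  if (!is.null(irf)) {
    check_numeric(irf, "irf", nonneg = TRUE)
    if (length(irf) != length(counts)) {
      stop_fq("`irf` must be on the same bins as `counts`.", "fq_shape_error")
    }
  }
  structure(
    list(t_ns = t_ns, counts = round(counts), irf = irf,
         bin_width_ns = if (length(dt)) stats::median(dt) else NA_real_,
         total_photons = sum(counts)),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins x %.4g ns, %s photons%s\n",
              length(x$counts), x$bin_width_ns,
              format(x$total_photons, big.mark = ","),
              if (is.null(x$irf)) "" else ", with IRF"))
  invisible(x)
}

# Model curve: sum_i a_i exp(-t/tau_i) + offset, evaluated at bin centers,
# optionally convolved with a normalized IRF (discrete, causal).
multiexp_model <- function(t_centers, amplitudes, lifetimes, offset = 0, irf_p = NULL) {
  dec <- rowSums(vapply(seq_along(amplitudes),
                        function(i) amplitudes[i] * exp(-t_centers / lifetimes[i]),
                        numeric(length(t_centers))))
  if (!is.null(irf_p)) {
    n <- length(dec)
    conv <- stats::convolve(dec, rev(irf_p), type = "open")[seq_len(n)]
    dec <- pmax(conv, 0)
  }
  dec + offset
}

#' Fit a multi-exponential model to a photon-count decay
#'
#' Fits \eqn{I(t) = \sum_i \alpha_i e^{-t/\tau_i} + b} to a TCSPC histogram by
#' Poisson maximum likelihood (default, correct at low counts) or
#' Neyman-weighted least squares. Amplitudes and lifetimes are
#' log-parameterized, so positivity is structural; components are reported
#' sorted by descending lifetime. Goodness of fit is the reduced Pearson
#' chi-square against the fitted expectation; values near 1 indicate the
#' model accounts for the decay at shot-noise level (the conventional
#' acceptance bound for lifetime fits is chi2 < 1.2).
#'
#' Without an IRF the fit is a tail fit: bins before the peak-count bin are
#' dropped and time is re-referenced to the peak. With `use_irf = TRUE` the
#' model is numerically convolved with the decay's IRF histogram
#' (reconvolution fit) and all bins are used.
#'
#' Components whose lifetimes collapse onto each other (within 1% relative)
#' are merged, with a warning, into a single component carrying the summed
#' amplitude.
#'
#' @param decay A [decay_histogram()] with at least 1000 photons.
#' @param n_components Number of exponential components, 1-3 (default 3).
#' @param method `"mle"` (Poisson likelihood) or `"wls"` (Neyman weights).
#' @param use_irf Convolve with the stored IRF (requires `decay$irf`).
#' @param fit_offset Also fit a constant background term (default TRUE).
#' @return A `decay_fit`: tibble `components` (`amplitude`, `lifetime_ns`,
#'   `fraction`), `offset`, `chi2_reduced`, `fitted` curve, `n_used` bins,
#'   `t_used`, `counts_used`, `method`, `convergence` diagnostics.
#' @export
fit_decay <- function(decay, n_components = 3, method = c("mle", "wls"),
                      use_irf = FALSE, fit_offset = TRUE) {
  stopifnot(inherits(decay, "decay_histogram"))
  method <- match.arg(method)
  if (!n_components %in% 1:3) {
    stop_fq("`n_components` must be 1, 2 or 3.", "fq_design_error")
  }
  if (decay$total_photons < 1000) {
    stop_fq("At least 1000 photons are required for a stable decay fit.",
            "fq_design_error")
  }
  if (use_irf && is.null(decay$irf)) {
    stop_fq("`use_irf = TRUE` but the histogram carries no IRF.", "fq_design_error")
  }

  counts <- decay$counts
  t_ns <- decay$t_ns
  dt <- decay$bin_width_ns
  irf_p <- NULL
  if (use_irf) {
    irf_p <- decay$irf / sum(decay$irf)
    t_fit <- t_ns - t_ns[1] + dt / 2
    c_fit <- counts
  } else {
    peak <- which.max(counts)
    t_fit <- t_ns[peak:length(t_ns)]
    t_fit <- t_fit - t_fit[1] + dt / 2
    c_fit <- counts[peak:length(counts)]
  }
  n <- length(c_fit)

  t_span <- max(t_fit)
  b0 <- if (fit_offset) max(mean(utils::tail(c_fit, max(3, n %/% 20))), 1e-3) else 0

  # Amplitude starts by linear least squares on the (convolved) exponential
  # basis of a trial lifetime set; keeps the optimizer on the right scale.
  init_amps <- function(taus) {
    B <- vapply(taus, function(tt) {
      b <- exp(-t_fit / tt)
      if (!is.null(irf_p)) {
        b <- pmax(stats::convolve(b, rev(irf_p), type = "open")[seq_len(n)], 0)
      }
      b
    }, numeric(n))
    a <- tryCatch(as.numeric(qr.solve(B, c_fit)),
                  error = function(e) rep(max(c_fit) / length(taus), length(taus)))
    pmax(a, max(c_fit) * 1e-4)
  }
  # Tail slope gives a data-driven longest-lifetime estimate
  tail_idx <- which(t_fit > t_span / 3 & c_fit > 0)
  tau_tail <- if (length(tail_idx) > 5) {
    sl <- stats::coef(stats::lm(log(c_fit[tail_idx]) ~ t_fit[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) min(-1 / sl, t_span) else t_span / 3
  } else t_span / 3
  spread <- function(hi, ratio) hi / ratio^(rev(seq_len(n_components)) - 1)
  tau_starts <- unique(list(
    spread(tau_tail, 4),
    spread(t_span / 3, 4),
    spread(max(tau_tail / 2, 4 * dt), 3)
  ))

  unpack <- function(p) {
    a <- exp(p[seq_len(n_components)])
    tau <- exp(p[n_components + seq_len(n_components)])
    b <- if (fit_offset) exp(p[2 * n_components + 1]) else 0
    list(a = a, tau = tau, b = b)
  }
  objective <- function(p) {
    q <- unpack(p)
    mu <- multiexp_model(t_fit, q$a, q$tau, q$b, irf_p)
    mu <- pmax(mu, 1e-12)
    if (method == "mle") {
      sum(mu - c_fit * log(mu))          # Poisson negative log-likelihood (up to const)
    } else {
      sum((c_fit - mu)^2 / pmax(c_fit, 1))
    }
  }
  # Multi-start over lifetime configurations; multi-exponential likelihoods
  # are multimodal and a single bad start can falsely converge.
  # Lifetimes below one bin width are unresolvable; bound them away.
  lower <- rep(-Inf, 2 * n_components + as.integer(fit_offset))
  lower[n_components + seq_len(n_components)] <- log(dt)
  opt <- NULL
  for (tau0 in tau_starts) {
    par0 <- c(log(init_amps(tau0)), log(pmax(tau0, dt * 1.01)),
              if (fit_offset) log(b0))
    o <- stats::nlminb(par0, objective, lower = lower,
                       control = list(iter.max = 2000, eval.max = 4000,
                                      rel.tol = 1e-14, x.tol = 1e-14))
    if (is.null(opt) || (is.finite(o$objective) && o$objective < opt$objective)) opt <- o
  }
  # Polish from the best optimum; the surface is flat near the solution and
  # a restart tightens noiseless recovery.
  opt2 <- stats::nlminb(opt$par, objective, lower = lower,
                        control = list(iter.max = 2000, eval.max = 4000,
                                       rel.tol = 1e-15, x.tol = 1e-15))
  if (opt2$objective <= opt$objective) opt <- opt2
  if (!is.finite(opt$objective)) {
    stop_fq(sprintf("Decay fit failed: non-finite objective (convergence code %d, %s).",
                    opt$convergence, opt$message), "fq_fit_error")
  }

  q <- unpack(opt$par)
  a <- q$a; tau <- q$tau; b <- q$b

  # Prune over-parameterization: components carrying a negligible share of
  # the photons (< 0.5% of alpha_i * tau_i) are unidentifiable noise-chasers.
  if (length(tau) > 1) {
    share <- a * tau / sum(a * tau)
    drop <- share < 0.005
    if (any(drop) && !all(drop)) {
      warn_fq(sprintf("Dropped %d component(s) with <0.5%% photon share (over-parameterized fit).",
                      sum(drop)), "fq_collapse_warning")
      a <- a[!drop]; tau <- tau[!drop]
    }
  }

  # Merge collapsed components
  ordt <- order(tau, decreasing = TRUE)
  a <- a[ordt]; tau <- tau[ordt]
  if (n_components > 1) {
    i <- 1
    while (i < length(tau)) {
      if (abs(tau[i] - tau[i + 1]) < 0.01 * tau[i]) {
        warn_fq(sprintf("Components with lifetimes %.4g and %.4g ns collapsed; merged.",
                        tau[i], tau[i + 1]), "fq_collapse_warning")
        wa <- a[i] + a[i + 1]
        tau[i] <- (a[i] * tau[i] + a[i + 1] * tau[i + 1]) / wa
        a[i] <- wa
        a <- a[-(i + 1)]; tau <- tau[-(i + 1)]
      } else i <- i + 1
    }
  }

  mu <- multiexp_model(t_fit, a, tau, b, irf_p)
  n_par <- 2 * length(a) + as.integer(fit_offset)
  chi2 <- sum((c_fit - mu)^2 / pmax(mu, 1e-12)) / max(n - n_par, 1)

  structure(
    list(components = tibble(amplitude = a, lifetime_ns = tau,
                             fraction = a / sum(a)),
         offset = b,
         chi2_reduced = chi2,
         fitted = mu, t_used = t_fit, counts_used = c_fit, n_used = n,
         method = method, use_irf = use_irf,
         convergence = list(code = opt$convergence, message = opt$message,
                            objective = opt$objective)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s), %s objective, chi2_red = %.3f\n",
              nrow(x$components), x$method, x$chi2_reduced))
  print(x$components)
  cat(sprintf("  offset = %.4g; amplitude-weighted tau = %.4g ns\n",
              x$offset, amplitude_weighted_lifetime(x)))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' \eqn{\tau = \sum_i \alpha_i \tau_i / \sum_i \alpha_i}, the standard
#' amplitude-weighted average over fitted decay components. This is the
#' lifetime statistic that enters the FRET-efficiency formula; it is bounded
#' by the component lifetimes and invariant to a common rescaling of all
#' amplitudes.
#'
#' @param fit A `decay_fit`, or `NULL` if `amplitudes`/`lifetimes` are given.
#' @param amplitudes,lifetimes Component vectors (amplitudes >= 0, not all
#'   zero; lifetimes > 0).
#' @return Mean lifetime, ns.
#' @examples
#' amplitude_weighted_lifetime(amplitudes = c(2, 1), lifetimes = c(1, 4))
#' @export
amplitude_weighted_lifetime <- function(fit = NULL, amplitudes = NULL, lifetimes = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "decay_fit"))
    amplitudes <- fit$components$amplitude
    lifetimes <- fit$components$lifetime_ns
  }
  check_numeric(amplitudes, "amplitudes", nonneg = TRUE)
  check_numeric(lifetimes, "lifetimes", positive = TRUE)
  if (sum(amplitudes) == 0) {
    stop_fq("Amplitudes sum to zero; mean lifetime undefined.", "fq_domain_error")
  }
  sum(amplitudes * lifetimes) / sum(amplitudes)
}

#' FRET efficiency from donor lifetimes
#'
#' \eqn{E = 1 - \tau_{FRET} / \tau_D}: the fractional shortening of the donor
#' lifetime in the presence of the acceptor, relative to the donor-only
#' lifetime. Values are not clipped; a negative E (lifetime longer than the
#' donor reference) is returned as-is so the caller can flag it.
#'
#' @param tau_fret Amplitude-weighted lifetime of the FRET sample, ns (> 0).
#' @param tau_donor Amplitude-weighted lifetime of the donor-only sample, ns
#'   (> 0).
#' @return FRET efficiency (dimensionless).
#' @export
fret_efficiency <- function(tau_fret, tau_donor) {
  check_numeric(tau_fret, "tau_fret", positive = TRUE)
  check_numeric(tau_donor, "tau_donor", positive = TRUE)
  1 - tau_fret / tau_donor
}

#' Build a lifetime-based concentration calibration
#'
#' From an in vitro lifetime titration (one summed decay per analyte
#' concentration) plus a donor-only decay, fits each histogram, converts
#' amplitude-weighted lifetimes to FRET efficiencies, and fits the hyperbola
#' \eqn{E(c) = E_{min} + (E_{max} - E_{min}) / (1 + c_{50}/c)}. The resulting
#' calibration inverts a measured in-cell efficiency to an absolute analyte
#' concentration via [coa_concentration()].
#'
#' @param titration A data frame/tibble with a numeric `conc_uM` column and a
#'   `decay` list-column of [decay_histogram()] objects (>= 5 concentrations).
#' @param donor_only A [decay_histogram()] of the donor-only sample.
#' @param n_components Components per decay fit (default 3).
#' @param method,use_irf Passed to [fit_decay()].
#' @param temperature_note Free-text label recording the calibration
#'   temperature.
#' @return A `lifetime_calibration` with `tau_donor_ns`, `e_min`, `e_max`,
#'   `c50_uM`, per-point table `points`, hyperbola `std_errors` and `flags`
#'   (may include `"extrapolated"`).
#' @export
build_lifetime_calibration <- function(titration, donor_only, n_components = 3,
                                       method = "mle", use_irf = FALSE,
                                       temperature_note = NA_character_) {
  stopifnot(is.data.frame(titration), inherits(donor_only, "decay_histogram"))
  if (!all(c("conc_uM", "decay") %in% names(titration))) {
    stop_fq("`titration` needs columns `conc_uM` and `decay`.", "fq_shape_error")
  }
  if (length(unique(titration$conc_uM)) < 5) {
    stop_fq("At least 5 distinct concentrations are required for calibration.",
            "fq_design_error")
  }
  fit_d <- fit_decay(donor_only, n_components = n_components, method = method,
                     use_irf = use_irf)
  tau_d <- amplitude_weighted_lifetime(fit_d)

  pts <- purrr::map2_dfr(titration$conc_uM, titration$decay, function(conc, dec) {
    f <- fit_decay(dec, n_components = n_components, method = method, use_irf = use_irf)
    tau <- amplitude_weighted_lifetime(f)
    tibble(conc_uM = conc, tau_ns = tau,
           efficiency = fret_efficiency(tau, tau_d),
           chi2_reduced = f$chi2_reduced)
  })

  env <- new.env(); env$x <- pts$conc_uM; env$y <- pts$efficiency
  e_min0 <- min(pts$efficiency); e_max0 <- max(pts$efficiency)
  midc <- pts$conc_uM[which.min(abs(pts$efficiency - (e_min0 + e_max0) / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ e_min + (e_max - e_min) / (1 + exp(lc50) / ifelse(x == 0, Inf, x)) * ifelse(x == 0, 0, 1),
    data = env,
    start = list(e_min = e_min0, e_max = e_max0, lc50 = log(max(midc, 1e-6))),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  c50 <- exp(cf[["lc50"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(vc), 0)); names(se) <- names(cf)

  flags <- character()
  pos <- pts$conc_uM[pts$conc_uM > 0]
  if (c50 > max(pos) || c50 < min(pos)) {
    flags <- c(flags, "extrapolated")
    warn_fq("Calibration c50 lies outside the sampled concentration range.",
            "fq_extrapolated_warning")
  }

  structure(
    list(tau_donor_ns = tau_d,
         e_min = unname(cf[["e_min"]]), e_max = unname(cf[["e_max"]]),
         c50_uM = unname(c50),
         std_errors = c(e_min = unname(se[["e_min"]]), e_max = unname(se[["e_max"]]),
                        c50 = unname(c50 * se[["lc50"]])),
         points = pts, flags = flags,
         temperature_note = temperature_note),
    class = "lifetime_calibration"
  )
}

#' @export
print.lifetime_calibration <- function(x, ...) {
  cat("<lifetime_calibration>\n")
  cat(sprintf("  tau_donor = %.4g ns; E in [%.4g, %.4g]; c50 = %.4g uM\n",
              x$tau_donor_ns, x$e_min, x$e_max, x$c50_uM))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Absolute analyte concentration from a FRET efficiency
#'
#' Inverts the calibration hyperbola:
#' \eqn{[analyte] = c_{50} (E - E_{min}) / (E_{max} - E)}. Efficiencies at or
#' below `e_min` map to 0 uM with a `below_range` flag; efficiencies at or
#' above `e_max` are saturated (the inverse diverges) and yield `NA` with a
#' `saturated` flag, never an extrapolated number.
#'
#' @param efficiency FRET efficiency value(s), typically in-cell basal-state
#'   measurements.
#' @param calib A `lifetime_calibration`, or `NULL` with `e_min`, `e_max`,
#'   `c50` supplied directly.
#' @param e_min,e_max,c50 Calibration parameters when `calib` is `NULL`.
#' @return A tibble with `efficiency`, `coa_uM` and `flag`
#'   (`"ok"`, `"below_range"`, `"saturated"`).
#' @export
coa_concentration <- function(efficiency, calib = NULL,
                              e_min = NULL, e_max = NULL, c50 = NULL) {
  if (!is.null(calib)) {
    stopifnot(inherits(calib, "lifetime_calibration"))
    e_min <- calib$e_min; e_max <- calib$e_max; c50 <- calib$c50_uM
  }
  check_numeric(efficiency, "efficiency")
  check_numeric(c50, "c50", positive = TRUE)
  if (!(e_min < e_max)) stop_fq("Calibration requires e_min < e_max.", "fq_domain_error")
  flag <- dplyr::case_when(
    efficiency <= e_min ~ "below_range",
    efficiency >= e_max ~ "saturated",
    TRUE ~ "ok"
  )
  conc <- dplyr::case_when(
    flag == "below_range" ~ 0,
    flag == "saturated" ~ NA_real_,
    TRUE ~ c50 * (efficiency - e_min) / (e_max - efficiency)
  )
  tibble(efficiency = efficiency, coa_uM = conc, flag = flag)
}
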