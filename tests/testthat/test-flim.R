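test_that("decay histogram validates its invariants", {
  expect_error(decay_histogram(c(0, 1, 3), c(5, 4, 3)), class = "fq_domain_error")  # non-uniform
  expect_error(decay_histogram(0:3, c(5, 4, -1, 2)), class = "fq_domain_error")
  expect_error(decay_histogram(0:2, c(1, 2)), class = "fq_shape_error")
  d <- decay_histogram(seq(0, 24.9, length.out = 250), rep(10L, 250))
  expect_equal(d$total_photons, 2500)
})

test_that("noiseless biexponential decays are recovered essentially exactly", {
  sc <- small_scenario(seed = 1)
  d0 <- sim_decay(sc, amplitudes = c(1, 2), lifetimes = c(0.8, 3.0),
                  photons = 1e6, noise = FALSE)
  f0 <- fit_decay(d0, n_components = 2, fit_offset = FALSE)
  taus <- sort(f0$components$lifetime_ns)
  # noiseless counts are rounded to integers in the histogram container,
  # which limits agreement to ~1e-4 relative
  expect_equal(taus[1], 0.8, tolerance = 1e-3)
  expect_equal(taus[2], 3.0, tolerance = 1e-3)
  fr <- f0$components$fraction[order(f0$components$lifetime_ns)]
  expect_equal(fr, c(1, 2) / 3, tolerance = 1e-3)
})

test_that("a seeded monoexponential megacount decay meets the chi-square bound", {
  sc <- small_scenario(seed = 12)
  d <- sim_decay(sc, amplitudes = 1, lifetimes = 2.6, photons = 1e6)
  f <- fit_decay(d, n_components = 1, fit_offset = FALSE)
  expect_lt(abs(f$components$lifetime_ns - 2.6), 0.02)
  expect_lt(f$chi2_reduced, 1.2)
})

test_that("decay fitting rejects empty input and merges collapsed components", {
  sc <- small_scenario(seed = 12)
  zero <- decay_histogram(seq(0, 24.9, length.out = 250), rep(0L, 250))
  expect_error(fit_decay(zero, 1), class = "fq_design_error")

  mono <- sim_decay(sc, amplitudes = 1, lifetimes = 2.6, photons = 1e6,
                    stream = "mono")
  expect_warning(f <- fit_decay(mono, n_components = 2, fit_offset = FALSE),
                 class = "fq_collapse_warning")
  expect_equal(nrow(f$components), 1)
  expect_lt(abs(f$components$lifetime_ns - 2.6), 0.02)
})

test_that("reconvolution fitting recovers lifetimes under a finite IRF", {
  # Gaussian IRF (FWHM ~0.5 ns) convolved decay, tail heavy enough to fit
  sc <- small_scenario(seed = 30)
  nb <- 256; edges <- seq(0, 25, length.out = nb + 1); lo <- edges[-(nb + 1)]
  tc <- lo + diff(edges)[1] / 2
  irf <- exp(-(tc - 2)^2 / (2 * 0.2^2)); irf_p <- irf / sum(irf)
  model <- 1000 * exp(-tc / 2.6)
  mu <- pmax(stats::convolve(model, rev(irf_p), type = "open")[seq_len(nb)], 0)
  counts <- withr::with_seed(30, rpois(nb, mu * 50))
  d <- decay_histogram(lo, counts, irf = round(irf * 1000))
  f <- fit_decay(d, n_components = 1, use_irf = TRUE, fit_offset = FALSE)
  expect_lt(abs(f$components$lifetime_ns - 2.6) / 2.6, 0.02)
})

test_that("amplitude-weighted lifetime is the normalized mean with its invariances", {
  expect_equal(amplitude_weighted_lifetime(amplitudes = 5, lifetimes = 2.7), 2.7)
  expect_equal(amplitude_weighted_lifetime(amplitudes = c(1, 1), lifetimes = c(1, 3)), 2)
  expect_equal(amplitude_weighted_lifetime(amplitudes = c(2, 1), lifetimes = c(1, 4)), 2)
  # scale invariance and boundedness
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- runif(3, 0.1, 5); tau <- runif(3, 0.3, 5)
      v <- amplitude_weighted_lifetime(amplitudes = a, lifetimes = tau)
      expect_equal(amplitude_weighted_lifetime(amplitudes = 7.3 * a, lifetimes = tau), v)
      expect_true(v >= min(tau) && v <= max(tau))
    }
  })
  expect_error(amplitude_weighted_lifetime(amplitudes = c(0, 0), lifetimes = c(1, 2)),
               class = "fq_domain_error")
})

test_that("FRET efficiency is the fractional lifetime shortening, unclipped", {
  expect_equal(fret_efficiency(2.4, 2.4), 0)
  expect_equal(fret_efficiency(1.2, 2.4), 0.5)
  expect_equal(fret_efficiency(1.8, 2.4), 0.25)
  expect_lt(fret_efficiency(2.6, 2.4), 0)  # reported, not clipped
  expect_error(fret_efficiency(1, -2), class = "fq_domain_error")
})

test_that("efficiency falls when any component lifetime of the FRET fit rises", {
  a <- c(1, 2); tau <- c(0.8, 3.0); tau_d <- 3.2
  e0 <- fret_efficiency(amplitude_weighted_lifetime(amplitudes = a, lifetimes = tau), tau_d)
  for (i in 1:2) {
    tau2 <- tau; tau2[i] <- tau[i] * 1.2
    e1 <- fret_efficiency(amplitude_weighted_lifetime(amplitudes = a, lifetimes = tau2), tau_d)
    expect_lt(e1, e0)
  }
})

test_that("lifetime calibration recovers the efficiency hyperbola from decays", {
  sc <- small_scenario(seed = 19)
  donor <- sim_decay(sc, stream = "don")
  ladder <- sc$decay$c50_uM * c(0.1, 0.3, 1, 3, 10)
  titr <- tibble::tibble(
    conc_uM = ladder,
    decay = lapply(ladder, function(cc) sim_decay_for_conc(sc, cc, noise = FALSE)))
  cal <- build_lifetime_calibration(titr, donor, n_components = 2)
  expect_equal(cal$tau_donor_ns, 2.6, tolerance = 0.01)
  expect_equal(cal$c50_uM, 58.9, tolerance = 0.02 * 58.9)
  expect_lt(abs(cal$e_min - 0.05), 0.005)
  expect_lt(abs(cal$e_max - 0.45), 0.005)
  # donor-only decay sits at E = 0 against the calibration's own tau_D
  f_d <- fit_decay(donor, n_components = 1, fit_offset = FALSE)
  expect_equal(fret_efficiency(amplitude_weighted_lifetime(f_d), cal$tau_donor_ns),
               0, tolerance = 0.01)
  expect_error(build_lifetime_calibration(titr[1:3, ], donor),
               class = "fq_design_error")
})

test_that("concentration inversion is exact, with midpoint and saturation flags", {
  e_min <- 0.05; e_max <- 0.45; c50 <- 58.9
  est <- coa_concentration((e_min + e_max) / 2, e_min = e_min, e_max = e_max, c50 = c50)
  expect_equal(est$coa_uM, c50)
  # round trip through the forward hyperbola
  conc <- c(0.2, 1, 5) * c50
  e <- e_min + (e_max - e_min) / (1 + c50 / conc)
  back <- coa_concentration(e, e_min = e_min, e_max = e_max, c50 = c50)
  expect_equal(back$coa_uM, conc, tolerance = 1e-9)
  expect_true(all(back$flag == "ok"))

  hi <- coa_concentration(e_max + 1e-6, e_min = e_min, e_max = e_max, c50 = c50)
  expect_equal(hi$flag, "saturated"); expect_true(is.na(hi$coa_uM))
  lo <- coa_concentration(e_min - 0.01, e_min = e_min, e_max = e_max, c50 = c50)
  expect_equal(lo$flag, "below_range"); expect_equal(lo$coa_uM, 0)
})
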