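test_that("isotherm forward model honors limits, midpoint and hand-computed values", {
  expect_identical(isotherm_response(0, 1, 2.8, 14), 1)
  expect_equal(isotherm_response(14, 1, 2.8, 14), (1 + 2.8) / 2)
  # hand evaluation at conc = 10*c50, r_min = 1, r_max = 3:
  # 1 + 2 / (1 + 1/10) = 1 + 20/11
  expect_equal(isotherm_response(10 * 14, 1, 3, 14), 1 + 20 / 11, tolerance = 1e-12)
  expect_error(isotherm_response(-1, 1, 2.8, 14), class = "fq_domain_error")
})

test_that("isotherm forward model is monotone with the sign of r_max - r_min", {
  conc <- 10^seq(-2, 3, length.out = 50)
  up <- isotherm_response(conc, 1, 2.8, 13.9)
  down <- isotherm_response(conc, 2.8, 1, 13.9)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
})

test_that("isotherm inversion is the exact inverse and rejects out-of-range ratios", {
  fitlike <- list(r_min = 1, r_max = 2.8, c50 = 13.9)
  conc <- c(0.1, 1, 10) * 13.9
  r <- isotherm_response(conc, 1, 2.8, 13.9)
  back <- isotherm_invert(r, r_min = 1, r_max = 2.8, c50 = 13.9)
  expect_equal(back, conc, tolerance = 1e-9)
  expect_equal(isotherm_invert((1 + 2.8) / 2, r_min = 1, r_max = 2.8, c50 = 13.9), 13.9)
  expect_error(isotherm_invert(2.8, r_min = 1, r_max = 2.8, c50 = 13.9),
               class = "fq_range_error")
  expect_error(isotherm_invert(0.9, r_min = 1, r_max = 2.8, c50 = 13.9),
               class = "fq_range_error")
})

test_that("noiseless titrations are recovered exactly and flat series are flagged", {
  sc <- small_scenario(seed = 5)
  d0 <- sim_titration(sc, noise = FALSE)
  f0 <- fit_isotherm(d0)
  expect_equal(f0$c50, 13.9, tolerance = 1e-6)
  expect_equal(f0$r_min, 1, tolerance = 1e-6)
  expect_equal(f0$r_max, 2.8, tolerance = 1e-6)
  expect_equal(dynamic_range(f0), 2.8, tolerance = 1e-6)

  flat <- tibble::tibble(conc_uM = c(0, 1, 10, 100, 1000), ratio = rep(1.5, 5))
  ff <- fit_isotherm(flat)
  expect_true("unidentifiable_c50" %in% ff$flags)
  expect_equal(dynamic_range(ff), 1)

  expect_error(fit_isotherm(tibble::tibble(conc_uM = c(0, 1, 10, 10),
                                           ratio = c(1, 1.2, 2, 2))),
               class = "fq_design_error")
})

test_that("noisy titration fits stay near truth for a fixed seed", {
  sc <- small_scenario(seed = 42)
  f <- fit_isotherm(sim_titration(sc))
  # tolerance from the 500-rep ensemble: median |error| 1.7%, SD ~2.6%
  expect_lt(abs(f$c50 - 13.9) / 13.9, 0.10)
  expect_gt(f$std_errors[["c50"]], 0)
})

test_that("dynamic range is r_max / r_min with a positivity guard", {
  expect_equal(dynamic_range(r_min = 1, r_max = 2.8), 2.8)
  expect_equal(dynamic_range(r_min = 2, r_max = 2), 1)
  expect_equal(dynamic_range(r_min = 0.5, r_max = 2), 4)
  expect_error(dynamic_range(r_min = 0, r_max = 2), class = "fq_domain_error")
})

test_that("selectivity fold is a guarded ratio", {
  expect_equal(selectivity_fold(163, 13.9), 163 / 13.9)
  expect_equal(round(selectivity_fold(163, 13.9), 1), 11.7)
  expect_equal(selectivity_fold(7, 7), 1)
  expect_equal(selectivity_fold(100, 10), 10)
  expect_error(selectivity_fold(-1, 10), class = "fq_domain_error")
})

test_that("polarization from intensities matches hand arithmetic and stays bounded", {
  expect_equal(fp_polarization(5, 5, 1), 0)
  expect_equal(fp_polarization(3, 0, 1), 1)
  expect_equal(fp_polarization(3, 1, 2), 0.2)
  expect_error(fp_polarization(0, 0, 1), class = "fq_domain_error")
  withr::with_seed(9, {
    for (i in 1:50) {
      v <- fp_polarization(runif(1, 0, 100), runif(1, 0, 100), runif(1, 0.5, 2))
      expect_true(v >= -1 && v <= 1)
    }
  })
})

test_that("direct FP fit recovers the quadratic binding model", {
  sc <- small_scenario(seed = 2)
  d0 <- sim_fp_series(sc, "direct", noise = FALSE)
  f0 <- fit_fp_direct(d0, tracer_conc = 0.05)
  expect_equal(f0$kd, 1.2, tolerance = 1e-6)
  expect_equal(f0$fp0, 0.05, tolerance = 1e-6)
  expect_equal(f0$fps, 0.25, tolerance = 1e-6)
  # zero-protein limit: the fitted curve passes through fp0
  expect_equal(predict(f0, 0), f0$fp0, tolerance = 1e-12)

  f1 <- fit_fp_direct(sim_fp_series(sc, "direct"), tracer_conc = 0.05)
  expect_lt(abs(f1$kd - 1.2) / 1.2, 0.15)  # 100-rep ensemble max ~9.4%
})

test_that("competition FP fit recovers the displacement hyperbola", {
  sc <- small_scenario(seed = 3)
  d0 <- sim_fp_series(sc, "competition", noise = FALSE)
  f0 <- fit_fp_competition(d0)
  expect_equal(f0$c50, 13.9, tolerance = 1e-6)
  # at competitor = c50 the curve sits midway between bound and free FP
  expect_equal(predict(f0, f0$c50), (f0$fp0 + f0$fps) / 2, tolerance = 1e-9)

  f1 <- fit_fp_competition(sim_fp_series(sc, "competition"))
  expect_lt(abs(f1$c50 - 13.9) / 13.9, 0.15)
})

test_that("ligand-depletion fit reduces to the hyperbola when tracer << Kd", {
  # generate from the simple hyperbola; the depleting form must agree within 1%
  kd <- 1.2
  x <- 10^seq(-2, 2, length.out = 15)
  d <- tibble::tibble(x_uM = x, fp = 0.05 + 0.2 * x / (x + kd))
  f <- fit_fp_direct(d, tracer_conc = 0.01 * kd)
  expect_lt(abs(f$kd - kd) / kd, 0.01)
})
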