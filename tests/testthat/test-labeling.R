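test_that("labeling efficiency follows the band-ratio arithmetic with flags", {
  d <- tibble::tibble(s_a488 = c(0, 2, 1), s_sir = c(3, 4, 4),
                      c_a488 = c(1, 1, 1), c_sir = c(2, 2, 2))
  le <- labeling_efficiency(d)
  expect_equal(le$le_percent[1], 100)   # no free tag left
  expect_equal(le$le_percent[2], 0)     # sample ratio equals control ratio
  expect_equal(le$le_percent[3], 50)    # hand arithmetic: 1 - (1/4)/(1/2)
  expect_true(all(le$flag == "ok"))

  noisy <- labeling_efficiency(tibble::tibble(s_a488 = 3, s_sir = 4,
                                              c_a488 = 1, c_sir = 2))
  expect_equal(noisy$flag, "out_of_range")
  expect_lt(noisy$le_percent, 0)

  expect_error(labeling_efficiency(tibble::tibble(s_a488 = 1, s_sir = 0,
                                                  c_a488 = 1, c_sir = 2)),
               class = "fq_domain_error")
})

test_that("labeling efficiency is scale invariant and monotone in free tag", {
  base <- tibble::tibble(s_a488 = 1, s_sir = 4, c_a488 = 1, c_sir = 2)
  v0 <- labeling_efficiency(base)$le_percent
  scaled <- labeling_efficiency(dplyr::mutate(base, s_a488 = s_a488 * 7, s_sir = s_sir * 7))
  expect_equal(scaled$le_percent, v0)
  more_free <- labeling_efficiency(dplyr::mutate(base, s_a488 = 2))
  expect_lt(more_free$le_percent, v0)
})

test_that("plateau detection finds saturation, constants and non-plateaus", {
  t_h <- seq(2, 12, by = 2)
  sat <- tibble::tibble(time_h = t_h, ratio = 1 - exp(-t_h / 2))
  res <- labeling_timecourse(sat)
  expect_true(res$plateaued)
  # successive relative steps of 1 - exp(-t/2) at 2 h spacing drop below
  # the 2% tolerance from the t = 8 h point onward
  expect_equal(res$plateau_time_h, 8)

  const <- labeling_timecourse(tibble::tibble(time_h = t_h, ratio = rep(1.4, 6)))
  expect_equal(const$plateau_time_h, 2)

  lin <- labeling_timecourse(tibble::tibble(time_h = t_h, ratio = t_h))
  expect_false(lin$plateaued)
  expect_error(labeling_timecourse(tibble::tibble(time_h = 1:3, ratio = 1:3)),
               class = "fq_design_error")
})
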