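test_that("net FRET matches hand arithmetic on a toy image and guards zero pixels", {
  d <- matrix(c(4, 2, 0, 5), 2, 2)
  a <- matrix(c(9, 2, 3, 5), 2, 2)
  f <- matrix(c(10, 3, 1, 6), 2, 2)
  im <- image_set(d, a, f)
  nf <- net_fret_image(im, 0.5, 0.5)
  # pixel (1,1): (10 - 0.5*4 - 0.5*9) / sqrt(36) = 3.5/6
  expect_equal(nf$net[1, 1], 3.5 / 6)
  # donor = 0 pixel is masked, not NaN
  expect_false(nf$valid[1, 2])
  expect_true(is.na(nf$net[1, 2]))
  expect_error(net_fret_image(image_set(d, a, f), -0.1, 0.5),
               class = "fq_domain_error")
})

test_that("vectorized net FRET equals a scalar per-pixel reference loop bitwise", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      nr <- sample(8:64, 1); nc <- sample(8:64, 1)
      d <- matrix(runif(nr * nc, 0, 500), nr, nc)
      a <- matrix(runif(nr * nc, 0, 500), nr, nc)
      f <- matrix(runif(nr * nc, 0, 500), nr, nc)
      btd <- runif(1, 0, 0.3); bta <- runif(1, 0, 0.3)
      nf <- net_fret_image(image_set(d, a, f), btd, bta)
      ref <- matrix(NA_real_, nr, nc)
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (d[i, j] * a[i, j] > 0) {
          ref[i, j] <- (f[i, j] - d[i, j] * btd - a[i, j] * bta) /
            sqrt(d[i, j] * a[i, j])
        }
      }
      expect_identical(nf$net, ref)
    }
  })
})

test_that("bleedthrough is exact on noiseless controls and errors on blank input", {
  sc <- small_scenario(seed = 8)
  ctrl <- sim_control_images(sc, "donor", noise = FALSE)
  bt <- estimate_bleedthrough(ctrl, "donor", background_floor = 20)
  expect_equal(as.numeric(bt), sc$bleedthrough$donor, tolerance = 1e-12)

  blank <- image_set(matrix(1, 8, 8), matrix(1, 8, 8), matrix(1, 8, 8))
  expect_error(estimate_bleedthrough(blank, "donor", background_floor = 10),
               class = "fq_empty_error")
})

test_that("bleedthrough from noisy controls lands within 0.005 with >= 1e4 pixels", {
  sc <- synthetic_scenario(seed = 21)  # full 512 px field, 55 cells
  for (ch in c("donor", "acceptor")) {
    bt <- estimate_bleedthrough(sim_control_images(sc, ch), ch)
    expect_gte(attr(bt, "n_pixels"), 1e4)
    expect_lt(abs(as.numeric(bt) - sc$bleedthrough[[ch]]), 0.005)
  }
})

test_that("self-estimated bleedthrough cancels single-fluorophore images", {
  sc <- small_scenario(seed = 4)
  for (ch in c("donor", "acceptor")) {
    ctrl <- sim_control_images(sc, ch)
    bt <- estimate_bleedthrough(ctrl, ch)
    args <- list(imgs = ctrl, intensity_floor = 20)
    nf <- if (ch == "donor") {
      net_fret_image(ctrl, bt, 0, intensity_floor = 20)
    } else {
      net_fret_image(ctrl, 0, bt, intensity_floor = 20)
    }
    labs <- segment_rois(ctrl[[ch]], min_pixels = 30)
    vals <- roi_table(nf, labs)$mean_net_fret
    # Poisson noise floor of the FRET channel relative to sqrt(Id*Ia)
    expect_lt(abs(mean(vals)), 0.05)
  }
})

test_that("segmentation counts constructed discs and merges touching ones", {
  centers <- as.matrix(expand.grid(seq(10, 120, by = 18), seq(10, 120, by = 18)))
  img <- draw_discs(c(128L, 128L), centers, radius = 5)
  labs <- segment_rois(img, min_pixels = 20)
  expect_equal(attr(labs, "n_rois"), nrow(centers))

  # move the second disc adjacent to the first: the two merge (8-connectivity)
  centers2 <- centers
  centers2[2, ] <- centers[1, ] + c(10, 0)
  img2 <- draw_discs(c(128L, 128L), centers2, radius = 5)
  labs2 <- segment_rois(img2, min_pixels = 20)
  expect_equal(attr(labs2, "n_rois"), nrow(centers) - 1L)

  expect_warning(labs0 <- segment_rois(matrix(0, 32, 32)), class = "fq_empty_warning")
  expect_equal(attr(labs0, "n_rois"), 0L)
})

test_that("segmentation is deterministic and diagonal touching counts as connected", {
  img <- matrix(0, 16, 16)
  img[4, 4] <- 100; img[5, 5] <- 100   # touch only diagonally
  labs <- segment_rois(img, min_pixels = 1, threshold = 50)
  expect_equal(attr(labs, "n_rois"), 1L)

  sc <- small_scenario(seed = 13)
  im <- sim_image_set(sc, "control", "TAZ")
  expect_identical(segment_rois(im$donor), segment_rois(im$donor))
})

test_that("normalized FRET supports both orientations and guards zeros", {
  expect_equal(normalized_fret(1, 1), 100)
  expect_equal(normalized_fret(1.0, 0.5), 50)
  expect_equal(normalized_fret(1.0, 0.5, orientation = "inverted"), 200)
  expect_error(normalized_fret(0, 0.5), class = "fq_domain_error")
})

test_that("ratio change and condition comparison behave on fixtures", {
  same <- c(1, 1.02, 0.98, 1)
  rc0 <- ratio_change(same, same)
  expect_equal(rc0$percent_change, 0)
  expect_equal(rc0$p_value, 1, tolerance = 1e-12)

  rc <- ratio_change(c(1.1, 1.1, 1.1), c(1.0, 1.0, 1.0))
  expect_equal(rc$percent_change, 10)
  expect_error(ratio_change(1.1, c(1, 1)), class = "fq_design_error")

  # Welch t statistic computed from explicit sums
  a <- c(10, 12, 14); b <- c(15, 17, 19, 21)
  va <- var(a) / 3; vb <- var(b) / 4
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 2 + vb^2 / 3)
  p_ref <- 2 * pt(-abs(tstat), df)
  expect_equal(compare_conditions(a, b), p_ref, tolerance = 1e-12)
  expect_error(compare_conditions(1, b), class = "fq_design_error")
})

test_that("increasing analyte lowers net FRET through the whole imaging chain", {
  sc <- small_scenario(seed = 6)
  coas <- c(2, 13.9, 80)
  means <- vapply(coas, function(cc) {
    im <- sim_image_set(sc, cc, "TAZ", noise = FALSE)
    nf <- net_fret_image(im, sc$bleedthrough$donor, sc$bleedthrough$acceptor,
                         intensity_floor = 20)
    mean(roi_table(nf, segment_rois(im$donor))$mean_net_fret)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # printed-orientation normalized FRET rises as net FRET falls
  norm <- normalized_fret(means, 0.2)
  expect_true(all(diff(norm) > 0))
})
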