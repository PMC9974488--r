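test_that("generators are deterministic for a fixed scenario and seed", {
  sc1 <- small_scenario(seed = 77)
  sc2 <- small_scenario(seed = 77)
  expect_identical(sim_titration(sc1), sim_titration(sc2))
  expect_identical(sim_fp_series(sc1, "direct"), sim_fp_series(sc2, "direct"))
  expect_identical(sim_decay(sc1)$counts, sim_decay(sc2)$counts)
  im1 <- sim_image_set(sc1, "control", "TAZ")
  im2 <- sim_image_set(sc2, "control", "TAZ")
  expect_identical(im1$fret, im2$fret)
  # different seeds diverge
  expect_false(identical(sim_titration(small_scenario(seed = 78)), sim_titration(sc1)))
})

test_that("noiseless generators reproduce their forward models exactly", {
  sc <- small_scenario(seed = 1)
  d0 <- sim_titration(sc, noise = FALSE)
  expect_equal(d0$ratio, isotherm_response(d0$conc_uM, 1, 2.8, 13.9))
  fp0 <- sim_fp_series(sc, "competition", noise = FALSE)
  expect_equal(fp0$fp[fp0$x_uM == max(fp0$x_uM)],
               0.25 + (0.05 - 0.25) / (1 + 13.9 / max(fp0$x_uM)))
})

test_that("titration noise is calibrated to the stated multiplicative model", {
  sc <- synthetic_scenario(seed = 55, noise_cv = 0.01, n_replicates = 50)
  d <- sim_titration(sc)
  mu <- isotherm_response(d$conc_uM, 1, 2.8, 13.9)
  rel <- d$ratio / mu - 1
  # 600 draws of N(0, 0.01): sd within sampling error, mean near zero
  expect_lt(abs(sd(rel) - 0.01) / 0.01, 0.15)
  expect_lt(abs(mean(rel)), 0.002)
})

test_that("decay sampling matches the analytic bin masses at large photon counts", {
  sc <- small_scenario(seed = 9)
  d <- sim_decay(sc, amplitudes = c(1, 2), lifetimes = c(0.8, 3.0), photons = 2e6)
  tr <- attr(d, "truth")
  edges <- c(d$t_ns, d$t_ns[length(d$t_ns)] + d$bin_width_ns)
  mass <- sapply(1:2, function(i) {
    tr$amplitudes[i] * tr$lifetimes[i] *
      (exp(-edges[-length(edges)] / tr$lifetimes[i]) - exp(-edges[-1] / tr$lifetimes[i]))
  })
  p <- rowSums(mass) / sum(mass)
  expected <- 2e6 * p
  # Pearson GOF: statistic should be near its dof
  keep <- expected > 5
  x2 <- sum((d$counts[keep] - expected[keep])^2 / expected[keep])
  dof <- sum(keep) - 1
  expect_lt(x2, dof + 5 * sqrt(2 * dof))
  expect_gt(x2, dof - 5 * sqrt(2 * dof))
})

test_that("synthetic fields carry exact truth in the noiseless limit", {
  sc <- small_scenario(seed = 2)
  im <- sim_image_set(sc, "treated", "TAZ", noise = FALSE)
  tr <- attr(im, "truth")
  nf <- net_fret_image(im, sc$bleedthrough$donor, sc$bleedthrough$acceptor,
                       intensity_floor = 20)
  rt <- roi_table(nf, segment_rois(im$donor, min_pixels = 30))
  expect_equal(nrow(rt), sc$image$n_cells)
  expect_equal(rt$mean_net_fret, rep(tr$net_fret, nrow(rt)), tolerance = 1e-9)
})

test_that("the constructed condition pair encodes the stated normalized-FRET change", {
  sc <- small_scenario(seed = 3)
  nf <- vapply(sc$conditions, function(cc) {
    im <- sim_image_set(sc, cc, "TAZ", noise = FALSE)
    attr(im, "truth")$net_fret
  }, numeric(1))
  norm <- 100 * sc$netfret$open / nf   # printed orientation, against Me level
  expect_equal(100 * (norm[["treated"]] - norm[["control"]]) / norm[["control"]],
               20, tolerance = 1e-9)
})

test_that("cell placement respects bounds and non-overlap", {
  sc <- small_scenario(seed = 31)
  im <- sim_image_set(sc, "control", "TAZ", noise = FALSE)
  tr <- attr(im, "truth")
  n <- nrow(tr$centers)
  expect_equal(n, sc$image$n_cells)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt(sum((tr$centers[i, ] - tr$centers[j, ])^2))
      expect_gt(dd, tr$radii[i] + tr$radii[j])
    }
  }
  expect_error(
    sim_image_set(small_scenario(
      seed = 1, image = list(dim = c(48L, 48L), n_cells = 40L,
                             radius_px = c(6, 9), background = 5,
                             amplitude = 600, edge_px = 2)), "control"),
    class = "fq_placement_error")
})

test_that("a full experiment bundle round-trips through the disk formats", {
  sc <- small_scenario(seed = 23)
  out <- withr::local_tempdir()
  man <- sim_experiment(sc, out, n_fov = 2)
  expect_true(file.exists(file.path(out, "titration.csv")))
  expect_true(file.exists(file.path(out, "truth.json")))
  expect_equal(nrow(man), 2 * 2 * 2 + 2)  # cond x probe x fov + 2 controls

  man2 <- read_image_manifest(file.path(out, "manifest.csv"))
  im <- image_set(
    read_channel_tiff(man2$donor_path[1]),
    read_channel_tiff(man2$acceptor_path[1]),
    read_channel_tiff(man2$fret_path[1]))
  expect_equal(dim(im$donor), c(128L, 128L))

  d <- read_titration_csv(file.path(out, "titration.csv"))
  f <- fit_isotherm(d)
  expect_lt(abs(f$c50 - 13.9) / 13.9, 0.15)

  truth <- jsonlite::read_json(file.path(out, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$sensor$c50_uM, 13.9)
})
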