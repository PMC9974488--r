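#' Define a synthetic experiment scenario with known ground truth
#'
#' A `synthetic_scenario` collects every ground-truth parameter the seeded
#' generators need: the sensor's hyperbolic response, the concentration
#' ladder and plate-reader noise, the imaging geometry and bleedthrough
#' truth, the net-FRET levels of the closed/open sensor states, the decay
#' model and photon budget for lifetime experiments, and the true analyte
#' concentration per experimental condition. Identical scenario + seed means
#' byte-identical generated data.
#'
#' Defaults emulate the study design of a CoA FRET biosensor: a 12-point
#' log-spaced ladder from 12.8 nM to 1 mM in triplicate with 1% multiplicative
#' readout noise; sensor response `r_min = 1`, `r_max = 2.8`, `c50 = 13.9` uM;
#' 512 x 512 px fields with >50 cells and Poisson photon noise; a 50 nM FP
#' tracer with `Kd = 1.2` uM; 25 ns / 256-bin TCSPC histograms (40 MHz pulse
#' period) with ~1e6 photons per ROI; a lifetime calibration with
#' `c50 = 58.9` uM. The two default imaging conditions (`control`, `treated`)
#' are constructed so the treated condition's true normalized FRET differs by
#' `norm_change_pct` (+20%) from control.
#'
#' @param seed Integer master seed; every generator derives its own stream
#'   from it.
#' @param sensor List: `r_min`, `r_max`, `c50_uM`.
#' @param ladder Concentration ladder, uM.
#' @param noise_cv Multiplicative Gaussian SD on plate-reader ratios.
#' @param n_replicates Independent titration replicates.
#' @param fp List: `tracer_uM`, `kd_uM`, `fp_free`, `fp_bound`,
#'   `competition_c50_uM`, `noise_sd` (polarization units; 0.002 = 2 mFP).
#' @param image List: `dim`, `n_cells`, `radius_px` (range), `background`,
#'   `amplitude`, `edge_px`.
#' @param bleedthrough List: `donor`, `acceptor` true factors.
#' @param netfret List: `closed`, `open` net FRET of the sensor's two states;
#'   the non-responsive control probe sits at the open level.
#' @param decay List: `window_ns`, `n_bins`, `tau_donor_ns`, `tau_fret_ns`,
#'   `photons`, `offset_fraction`, and the efficiency calibration
#'   `e_min`, `e_max`, `c50_uM`.
#' @param conditions Named numeric vector of true analyte concentrations (uM)
#'   per imaging condition, or `NULL` to derive a control/treated pair from
#'   `norm_change_pct`.
#' @param norm_change_pct Constructed true difference in normalized FRET
#'   between `treated` and `control` when `conditions` is `NULL`.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    seed = 1L,
    sensor = list(r_min = 1, r_max = 2.8, c50_uM = 13.9),
    ladder = 10^seq(log10(0.0128), log10(1000), length.out = 12),
    noise_cv = 0.01,
    n_replicates = 3,
    fp = list(tracer_uM = 0.05, kd_uM = 1.2, fp_free = 0.05, fp_bound = 0.25,
              competition_c50_uM = 13.9, noise_sd = 0.002),
    image = list(dim = c(512L, 512L), n_cells = 55L, radius_px = c(8, 14),
                 background = 5, amplitude = 600, edge_px = 2),
    bleedthrough = list(donor = 0.15, acceptor = 0.10),
    netfret = list(closed = 0.6, open = 0.2),
    decay = list(window_ns = 25, n_bins = 256L, tau_donor_ns = 2.6,
                 tau_fret_ns = 0.8, photons = 1e6, offset_fraction = 0,
                 e_min = 0.05, e_max = 0.45, c50_uM = 58.9),
    conditions = NULL,
    norm_change_pct = 20) {
  check_numeric(seed, "seed")
  stopifnot(sensor$c50_uM > 0, sensor$r_max != sensor$r_min,
            all(ladder >= 0), noise_cv >= 0, n_replicates >= 1,
            netfret$closed > netfret$open, netfret$open > 0,
            decay$e_min < decay$e_max, decay$c50_uM > 0)

  sc <- list(seed = as.integer(seed), sensor = sensor, ladder = ladder,
             noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
             fp = fp, image = image, bleedthrough = bleedthrough,
             netfret = netfret, decay = decay,
             norm_change_pct = norm_change_pct)
  class(sc) <- "synthetic_scenario"

  if (is.null(conditions)) {
    # Basal state: sensor midway through its closed->open swing.
    nf_ctrl <- netfret$open + 0.625 * (netfret$closed - netfret$open)
    # Printed normalized FRET is control/sensor, so a +x% change needs the
    # treated net FRET lowered by the factor 1/(1 + x/100).
    nf_trt <- nf_ctrl / (1 + norm_change_pct / 100)
    conditions <- c(control = coa_from_netfret(sc, nf_ctrl),
                    treated = coa_from_netfret(sc, nf_trt))
  }
  sc$conditions <- conditions
  sc
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> seed =", x$seed, "\n")
  cat(sprintf("  sensor: r_min %.3g, r_max %.3g, c50 %.4g uM; ladder %d pts x %d reps @ %.2g%% noise\n",
              x$sensor$r_min, x$sensor$r_max, x$sensor$c50_uM,
              length(x$ladder), x$n_replicates, 100 * x$noise_cv))
  cat(sprintf("  image: %dx%d px, %d cells; BT donor %.3g / acceptor %.3g\n",
              x$image$dim[1], x$image$dim[2], x$image$n_cells,
              x$bleedthrough$donor, x$bleedthrough$acceptor))
  cat("  conditions [uM]:",
      paste(sprintf("%s = %.4g", names(x$conditions), x$conditions), collapse = ", "), "\n")
  invisible(x)
}

# True net FRET of the responsive probe at analyte concentration `coa`:
# the closed-state signal decays linearly with the fraction of open sensor,
# which follows the binding isotherm.
netfret_from_coa <- function(scenario, coa) {
  s <- scenario$sensor
  r <- isotherm_response(coa, s$r_min, s$r_max, s$c50_uM)
  f_open <- (r - s$r_min) / (s$r_max - s$r_min)
  scenario$netfret$closed - (scenario$netfret$closed - scenario$netfret$open) * f_open
}

coa_from_netfret <- function(scenario, nf) {
  s <- scenario$sensor
  f_open <- (scenario$netfret$closed - nf) /
    (scenario$netfret$closed - scenario$netfret$open)
  r <- s$r_min + f_open * (s$r_max - s$r_min)
  s$c50_uM * (r - s$r_min) / (s$r_max - r)
}

#' Generate a seeded sensor titration series
#'
#' Draws emission ratios from the scenario's hyperbolic truth with
#' multiplicative Gaussian readout noise, `ratio = R(c) (1 + eps)`,
#' `eps ~ N(0, noise_cv^2)`, independently per replicate.
#'
#' @param scenario A [synthetic_scenario()].
#' @param noise Set `FALSE` for the noiseless truth curve.
#' @param stream Seed-stream label; vary it to draw an independent repeat of
#'   the same design (used by Monte-Carlo studies).
#' @return Tibble `analyte`, `conc_uM`, `ratio`, `replicate`, with the truth
#'   parameters in `attr(, "truth")`.
#' @export
sim_titration <- function(scenario, noise = TRUE, stream = "titration") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario$sensor
  d <- tidyr::expand_grid(replicate = seq_len(scenario$n_replicates),
                          conc_uM = scenario$ladder) |>
    dplyr::mutate(mean_ratio = isotherm_response(conc_uM, s$r_min, s$r_max, s$c50_uM))
  eps <- if (noise) {
    withr::with_seed(derive_seed(scenario$seed, stream),
                     stats::rnorm(nrow(d), 0, scenario$noise_cv))
  } else 0
  out <- d |>
    dplyr::transmute(analyte = "CoA", conc_uM,
                     ratio = mean_ratio * (1 + eps), replicate)
  attr(out, "truth") <- s
  out
}

#' Generate a seeded fluorescence-polarization series
#'
#' Direct mode titrates protein against the fixed tracer and draws FP values
#' from the exact ligand-depletion quadratic; competition mode titrates a
#' competitor and uses the hyperbolic displacement model. Additive Gaussian
#' noise of SD `fp$noise_sd` polarization units.
#'
#' @inheritParams sim_titration
#' @param mode `"direct"` or `"competition"`.
#' @return Tibble `x_uM`, `fp`, `mode`, `tracer_uM`, truth in
#'   `attr(, "truth")`.
#' @export
sim_fp_series <- function(scenario, mode = c("direct", "competition"),
                          noise = TRUE, stream = "fp") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  mode <- match.arg(mode)
  p <- scenario$fp
  if (mode == "direct") {
    x <- 10^seq(-2, 2, length.out = 12)   # protein ladder around Kd, uM
    mu <- p$fp_free + (p$fp_bound - p$fp_free) *
      quadratic_bound_fraction(x, p$kd_uM, p$tracer_uM)
  } else {
    x <- 10^seq(log10(0.064), log10(5000), length.out = 12)  # competitor, uM
    mu <- p$fp_bound + (p$fp_free - p$fp_bound) / (1 + p$competition_c50_uM / x)
  }
  eps <- if (noise) {
    withr::with_seed(derive_seed(scenario$seed, paste0(stream, "-", mode)),
                     stats::rnorm(length(x), 0, p$noise_sd))
  } else 0
  out <- tibble(x_uM = x, fp = mu + eps, mode = mode, tracer_uM = p$tracer_uM)
  attr(out, "truth") <- p
  out
}

# Place n non-overlapping disc centers by rejection sampling. Bounded
# retries: regenerating a failing placement is preferred over overlap.
place_cells <- function(dim, n_cells, radius_range, max_tries = 5000) {
  centers <- matrix(NA_real_, n_cells, 2)
  radii <- numeric(n_cells)
  placed <- 0
  tries <- 0
  while (placed < n_cells) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop_fq("Could not place non-overlapping cells; lower n_cells or radius.",
              "fq_placement_error")
    }
    r <- stats::runif(1, radius_range[1], radius_range[2])
    cx <- stats::runif(1, r + 2, dim[1] - r - 2)
    cy <- stats::runif(1, r + 2, dim[2] - r - 2)
    if (placed > 0) {
      dd <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                 (centers[seq_len(placed), 2] - cy)^2)
      if (any(dd < radii[seq_len(placed)] + r + 3)) next
    }
    placed <- placed + 1
    centers[placed, ] <- c(cx, cy)
    radii[placed] <- r
  }
  list(centers = centers, radii = radii)
}

# Render soft-edged discs; returns the per-pixel sum of weights * values.
render_discs <- function(dim, centers, radii, values, edge) {
  out <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    x0 <- max(1L, floor(centers[i, 1] - r - edge)); x1 <- min(dim[1], ceiling(centers[i, 1] + r + edge))
    y0 <- max(1L, floor(centers[i, 2] - r - edge)); y1 <- min(dim[2], ceiling(centers[i, 2] + r + edge))
    xs <- x0:x1; ys <- y0:y1
    d <- sqrt(outer((xs - centers[i, 1])^2, (ys - centers[i, 2])^2, "+"))
    w <- pmin(pmax((r - d) / edge, 0), 1)
    out[xs, ys] <- out[xs, ys] + w * values[i]
  }
  out
}

#' Generate a three-channel synthetic field of view
#'
#' Renders soft-edged, non-overlapping disc "cells" whose donor/acceptor
#' brightness split encodes the sensor's emission ratio at the condition's
#' true analyte concentration (via the scenario's isotherm), composes the
#' FRET channel as true sensitized emission plus the two bleedthrough
#' contributions, and applies Poisson photon noise per channel.
#'
#' The sensitized-emission term is constructed as
#' `netFRET_true * sqrt(I_donor * I_acceptor)` per pixel, so the net-FRET
#' estimator inverts the construction exactly in the noiseless limit.
#'
#' @inheritParams sim_titration
#' @param condition Name of a condition in `scenario$conditions`, or a number
#'   (true analyte concentration, uM).
#' @param probe `"TAZ"` (responsive sensor) or `"Me"` (non-responsive
#'   fully-open control probe).
#' @param fov Field-of-view index; part of the seed stream.
#' @return An `image_set` with a `truth` attribute (true net FRET, analyte
#'   concentration, cell placement).
#' @export
sim_image_set <- function(scenario, condition = "control", probe = c("TAZ", "Me"),
                          fov = 1, noise = TRUE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  probe <- match.arg(probe)
  coa <- if (is.numeric(condition)) condition else {
    if (!condition %in% names(scenario$conditions)) {
      stop_fq(sprintf("Unknown condition '%s'.", condition), "fq_design_error")
    }
    scenario$conditions[[condition]]
  }
  cond_label <- if (is.numeric(condition)) sprintf("coa_%.4g", condition) else condition
  img <- scenario$image
  s <- scenario$sensor
  nf_true <- if (probe == "TAZ") netfret_from_coa(scenario, coa) else scenario$netfret$open
  r_ratio <- if (probe == "TAZ") {
    isotherm_response(coa, s$r_min, s$r_max, s$c50_uM)
  } else {
    s$r_max  # fully open probe sits at the open-state emission ratio
  }

  seed <- derive_seed(scenario$seed, paste("img", cond_label, probe, fov, sep = "-"))
  withr::with_seed(seed, {
    pl <- place_cells(img$dim, img$n_cells, img$radius_px)
    amp <- rep(img$amplitude, img$n_cells)
    w <- render_discs(img$dim, pl$centers, pl$radii, amp, img$edge_px)
    donor_clean <- img$background + w * r_ratio / (1 + r_ratio)
    acceptor_clean <- img$background + w / (1 + r_ratio)
    sens <- nf_true * sqrt(donor_clean * acceptor_clean)
    sens[w == 0] <- 0
    fret_clean <- sens + scenario$bleedthrough$donor * donor_clean +
      scenario$bleedthrough$acceptor * acceptor_clean
    if (noise) {
      donor <- matrix(stats::rpois(length(donor_clean), donor_clean), img$dim[1])
      acceptor <- matrix(stats::rpois(length(acceptor_clean), acceptor_clean), img$dim[1])
      fret <- matrix(stats::rpois(length(fret_clean), fret_clean), img$dim[1])
    } else {
      donor <- donor_clean; acceptor <- acceptor_clean; fret <- fret_clean
    }
  })
  out <- image_set(donor * 1.0, acceptor * 1.0, fret * 1.0,
                   fov_id = sprintf("%s_%s_fov%02d", cond_label, probe, fov),
                   condition = cond_label)
  attr(out, "truth") <- list(net_fret = nf_true, coa_uM = coa, probe = probe,
                             emission_ratio = r_ratio,
                             centers = pl$centers, radii = pl$radii,
                             bleedthrough = scenario$bleedthrough)
  out
}

#' Generate a single-fluorophore bleedthrough control field
#'
#' Same cell geometry engine as [sim_image_set()], but the sample carries one
#' fluorophore only: the named channel holds the cells, the other direct
#' channel holds background, and the FRET channel is exactly the bleedthrough
#' fraction of the source (plus noise).
#'
#' @inheritParams sim_image_set
#' @param channel `"donor"` or `"acceptor"`.
#' @return An `image_set`; truth attribute carries the bleedthrough factor.
#' @export
sim_control_images <- function(scenario, channel = c("donor", "acceptor"),
                               fov = 1, noise = TRUE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  channel <- match.arg(channel)
  img <- scenario$image
  bt <- scenario$bleedthrough[[channel]]
  seed <- derive_seed(scenario$seed, paste("ctrl", channel, fov, sep = "-"))
  withr::with_seed(seed, {
    pl <- place_cells(img$dim, img$n_cells, img$radius_px)
    w <- render_discs(img$dim, pl$centers, pl$radii,
                      rep(img$amplitude, img$n_cells), img$edge_px)
    src_clean <- img$background + w
    # detector background is channel-independent: the silent channel still
    # carries the background level
    other_clean <- matrix(img$background, img$dim[1], img$dim[2])
    fret_clean <- bt * src_clean
    if (noise) {
      src <- matrix(stats::rpois(length(src_clean), src_clean), img$dim[1])
      other <- matrix(stats::rpois(length(other_clean), other_clean), img$dim[1])
      fret <- matrix(stats::rpois(length(fret_clean), fret_clean), img$dim[1])
    } else {
      src <- src_clean; other <- other_clean; fret <- fret_clean
    }
  })
  chans <- if (channel == "donor") {
    list(donor = src, acceptor = other)
  } else {
    list(donor = other, acceptor = src)
  }
  out <- image_set(chans$donor * 1.0, chans$acceptor * 1.0, fret * 1.0,
                   fov_id = sprintf("%s_only_fov%02d", channel, fov),
                   condition = paste0(channel, "_only"))
  attr(out, "truth") <- list(bleedthrough = bt, channel = channel)
  out
}

#' Generate a seeded TCSPC decay histogram
#'
#' Samples photon arrival-time bins from the bin-integrated probabilities of
#' a multi-exponential decay (optionally with a uniform background fraction)
#' by multinomial sampling of the photon budget.
#'
#' @inheritParams sim_titration
#' @param amplitudes,lifetimes Component amplitudes (relative) and lifetimes
#'   (ns). Defaults: the scenario's donor-only monoexponential.
#' @param photons Photon budget (default from the scenario; >= 100).
#' @param offset_fraction Fraction of photons from uniform background.
#' @return A [decay_histogram()]; `attr(, "truth")` stores the generating
#'   parameters.
#' @export
sim_decay <- function(scenario, amplitudes = 1,
                      lifetimes = scenario$decay$tau_donor_ns,
                      photons = scenario$decay$photons,
                      offset_fraction = scenario$decay$offset_fraction,
                      noise = TRUE, stream = "decay") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  check_numeric(amplitudes, "amplitudes", positive = TRUE)
  check_numeric(lifetimes, "lifetimes", positive = TRUE)
  if (photons < 100) stop_fq("At least 100 photons are required.", "fq_design_error")
  dc <- scenario$decay
  edges <- seq(0, dc$window_ns, length.out = dc$n_bins + 1)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  # Exact bin-integrated decay mass per component
  mass <- rowSums(vapply(seq_along(amplitudes), function(i) {
    amplitudes[i] * lifetimes[i] * (exp(-lo / lifetimes[i]) - exp(-hi / lifetimes[i]))
  }, numeric(length(lo))))
  p <- (1 - offset_fraction) * mass / sum(mass) + offset_fraction / length(lo)
  counts <- if (noise) {
    withr::with_seed(derive_seed(scenario$seed, stream),
                     as.numeric(stats::rmultinom(1, size = round(photons), prob = p)))
  } else {
    round(photons) * p
  }
  out <- decay_histogram(lo, round(counts))
  attr(out, "truth") <- list(amplitudes = amplitudes / sum(amplitudes),
                             lifetimes = lifetimes, photons = photons,
                             offset_fraction = offset_fraction)
  out
}

#' Generate a decay whose mean lifetime encodes an analyte concentration
#'
#' Computes the true FRET efficiency at `coa_uM` from the scenario's
#' efficiency hyperbola, converts it to a target amplitude-weighted lifetime
#' `tau = tau_D (1 - E)`, and mixes the FRET (short) and donor (long)
#' components in the amplitude ratio that realizes it. The photon histogram
#' is then sampled as in [sim_decay()].
#'
#' @inheritParams sim_decay
#' @param coa_uM True analyte concentration, uM.
#' @return A [decay_histogram()] with generating truth (including
#'   `efficiency` and `coa_uM`) attached.
#' @export
sim_decay_for_conc <- function(scenario, coa_uM, photons = scenario$decay$photons,
                               noise = TRUE, stream = "flim") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  check_numeric(coa_uM, "coa_uM", nonneg = TRUE)
  dc <- scenario$decay
  e_true <- dc$e_min + (dc$e_max - dc$e_min) / (1 + dc$c50_uM / coa_uM)
  if (coa_uM == 0) e_true <- dc$e_min
  tau_target <- dc$tau_donor_ns * (1 - e_true)
  a_fret <- (dc$tau_donor_ns - tau_target) / (dc$tau_donor_ns - dc$tau_fret_ns)
  a_fret <- min(max(a_fret, 0), 1)
  amps <- c(a_fret, 1 - a_fret)
  taus <- c(dc$tau_fret_ns, dc$tau_donor_ns)
  keep <- amps > 1e-12
  out <- sim_decay(scenario, amplitudes = amps[keep], lifetimes = taus[keep],
                   photons = photons, noise = noise,
                   stream = paste0(stream, "-", signif(coa_uM, 8)))
  tr <- attr(out, "truth")
  tr$efficiency <- e_true
  tr$coa_uM <- coa_uM
  tr$tau_target_ns <- tau_target
  attr(out, "truth") <- tr
  out
}

#' Write a complete synthetic experiment bundle to disk
#'
#' Emits every input class the pipeline consumes, in the package's CSV/TIFF
#' dialects, plus a manifest and a ground-truth JSON for assertions:
#' titration and FP tables, per-FOV three-channel TIFFs with single-
#' fluorophore controls, decay histograms for a concentration ladder and the
#' donor-only reference, and a gel-lane table.
#'
#' @param scenario A [synthetic_scenario()].
#' @param out_dir Output directory (created if missing).
#' @param n_fov Fields of view per condition and probe (default 6).
#' @param ladder_flim Analyte ladder for the lifetime calibration decays;
#'   default 5 points spanning the efficiency c50.
#' @return Invisibly, the manifest tibble. Files written: `titration.csv`,
#'   `fp_direct.csv`, `fp_competition.csv`, `manifest.csv`, per-FOV TIFFs
#'   under `images/`, decay CSVs under `decays/`, `gel_lanes.csv`,
#'   `truth.json`.
#' @export
sim_experiment <- function(scenario, out_dir, n_fov = 6,
                           ladder_flim = scenario$decay$c50_uM * c(0.2, 0.5, 1, 2, 5)) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "decays"), showWarnings = FALSE)

  readr::write_csv(sim_titration(scenario), file.path(out_dir, "titration.csv"))
  readr::write_csv(sim_fp_series(scenario, "direct"), file.path(out_dir, "fp_direct.csv"))
  readr::write_csv(sim_fp_series(scenario, "competition"),
                   file.path(out_dir, "fp_competition.csv"))

  rows <- list()
  write_set <- function(im, base) {
    paths <- file.path("images", paste0(base, c("_donor.tif", "_acceptor.tif", "_fret.tif")))
    write_channel_tiff(im$donor, file.path(out_dir, paths[1]))
    write_channel_tiff(im$acceptor, file.path(out_dir, paths[2]))
    write_channel_tiff(im$fret, file.path(out_dir, paths[3]))
    paths
  }
  for (cond in names(scenario$conditions)) {
    for (probe in c("TAZ", "Me")) {
      for (fv in seq_len(n_fov)) {
        im <- sim_image_set(scenario, cond, probe, fov = fv)
        base <- sprintf("%s_%s_fov%02d", cond, probe, fv)
        p <- write_set(im, base)
        rows[[length(rows) + 1]] <- tibble(
          fov_id = im$fov_id, condition = cond, probe = probe,
          donor_path = p[1], acceptor_path = p[2], fret_path = p[3])
      }
    }
  }
  for (ch in c("donor", "acceptor")) {
    im <- sim_control_images(scenario, ch)
    p <- write_set(im, paste0(ch, "_only"))
    rows[[length(rows) + 1]] <- tibble(
      fov_id = im$fov_id, condition = paste0(ch, "_only"), probe = "control",
      donor_path = p[1], acceptor_path = p[2], fret_path = p[3])
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  donor_decay <- sim_decay(scenario, stream = "decay-donor")
  write_decay_csv(donor_decay, file.path(out_dir, "decays", "donor_only.csv"))
  for (conc in ladder_flim) {
    d <- sim_decay_for_conc(scenario, conc)
    write_decay_csv(d, file.path(out_dir, "decays",
                                 sprintf("calib_%.6g_uM.csv", conc)))
  }

  # Gel lanes: fully labeled, unlabeled, and a 50% lane
  gel <- tibble(sample_id = c("labeled", "unlabeled", "half"),
                s_a488 = c(0, 1, 1), s_sir = c(2, 2, 4),
                c_a488 = c(1, 1, 1), c_sir = c(2, 2, 2))
  readr::write_csv(gel, file.path(out_dir, "gel_lanes.csv"))

  truth <- list(
    seed = scenario$seed, sensor = scenario$sensor,
    bleedthrough = scenario$bleedthrough, netfret = scenario$netfret,
    conditions = as.list(scenario$conditions),
    netfret_by_condition = lapply(as.list(scenario$conditions),
                                  function(c) netfret_from_coa(scenario, c)),
    norm_change_pct = scenario$norm_change_pct,
    decay = scenario$decay, flim_ladder_uM = ladder_flim)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
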