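#' Read a titration CSV
#'
#' Expected columns: `analyte`, `conc_uM`, `ratio`, optional `replicate`.
#' Header required; decimal point; UTF-8.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_titration_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("analyte", "conc_uM", "ratio")
  if (!all(need %in% names(d))) {
    stop_fq(paste0("Titration CSV must have columns: ", paste(need, collapse = ", ")),
            "fq_format_error")
  }
  d
}

#' Read a fluorescence-polarization CSV
#'
#' Expected columns: `x_uM`, `mode`, `tracer_uM`, and either `fp` directly or
#' the raw components `i_par`, `i_perp`, `g` from which FP is computed via
#' [fp_polarization()].
#'
#' @param path CSV file path.
#' @return A tibble with an `fp` column guaranteed.
#' @export
read_fp_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!"x_uM" %in% names(d)) {
    stop_fq("FP CSV must have an `x_uM` column.", "fq_format_error")
  }
  if (!"fp" %in% names(d)) {
    if (!all(c("i_par", "i_perp", "g") %in% names(d))) {
      stop_fq("FP CSV needs `fp` or the raw columns `i_par`, `i_perp`, `g`.",
              "fq_format_error")
    }
    d <- dplyr::mutate(d, fp = fp_polarization(.data$i_par, .data$i_perp, .data$g))
  }
  d
}

#' Read a TCSPC decay CSV
#'
#' Expected columns: `t_ns`, `counts`, optional `irf_counts`.
#'
#' @param path CSV file path.
#' @return A [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t_ns", "counts") %in% names(d))) {
    stop_fq("Decay CSV must have columns `t_ns`, `counts`.", "fq_format_error")
  }
  decay_histogram(d$t_ns, d$counts,
                  irf = if ("irf_counts" %in% names(d)) d$irf_counts else NULL)
}

#' Write a decay histogram to CSV
#' @param decay A [decay_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "decay_histogram"))
  d <- tibble(t_ns = decay$t_ns, counts = decay$counts)
  if (!is.null(decay$irf)) d$irf_counts <- decay$irf
  readr::write_csv(d, path)
  invisible(path)
}

#' Read/write a single-channel grayscale TIFF
#'
#' Images are stored as 16-bit grayscale; intensities are rounded to integers
#' on write and must lie in \[0, 65535\].
#'
#' @param path TIFF path.
#' @return `read_channel_tiff`: a numeric matrix.
#' @export
read_channel_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_channel_tiff
#' @param img Numeric matrix, values in \[0, 65535\].
#' @export
write_channel_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  if (any(img < 0) || any(img > 65535)) {
    stop_fq("Image intensities must lie in [0, 65535] for the 16-bit container.",
            "fq_range_error")
  }
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read an imaging manifest CSV
#'
#' Maps each field of view to its three channel files. Columns: `fov_id`,
#' `condition`, `probe` (`TAZ`, `Me`, or `control`), `donor_path`,
#' `acceptor_path`, `fret_path`; paths are relative to the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with paths resolved to absolute.
#' @export
read_image_manifest <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("fov_id", "condition", "probe", "donor_path", "acceptor_path", "fret_path")
  if (!all(need %in% names(d))) {
    stop_fq(paste0("Manifest must have columns: ", paste(need, collapse = ", ")),
            "fq_format_error")
  }
  if (nrow(d) == 0) stop_fq("Manifest is empty.", "fq_empty_error")
  base <- dirname(normalizePath(path))
  for (col in c("donor_path", "acceptor_path", "fret_path")) {
    d[[col]] <- ifelse(grepl("^/", d[[col]]), d[[col]], file.path(base, d[[col]]))
  }
  d
}

load_image_set <- function(row) {
  image_set(read_channel_tiff(row$donor_path),
            read_channel_tiff(row$acceptor_path),
            read_channel_tiff(row$fret_path),
            fov_id = row$fov_id, condition = row$condition)
}

#' Serialize a fit object to a flat JSON report
#'
#' @param fit An `isotherm_fit`, `fp_direct_fit`, `fp_competition_fit`,
#'   `decay_fit` or `lifetime_calibration`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  rep <- if (inherits(fit, "isotherm_fit")) {
    list(type = "isotherm", r_min = fit$r_min, r_max = fit$r_max, c50_uM = fit$c50,
         dynamic_range = fit$r_max / fit$r_min,
         std_errors = as.list(fit$std_errors), sse = fit$residual_sse,
         flags = fit$flags)
  } else if (inherits(fit, "fp_direct_fit")) {
    list(type = "fp_direct", fp0 = fit$fp0, fps = fit$fps, kd_uM = fit$kd,
         tracer_uM = fit$tracer_conc, std_errors = as.list(fit$std_errors),
         sse = fit$residual_sse)
  } else if (inherits(fit, "fp_competition_fit")) {
    list(type = "fp_competition", fp0 = fit$fp0, fps = fit$fps, c50_uM = fit$c50,
         std_errors = as.list(fit$std_errors), sse = fit$residual_sse)
  } else if (inherits(fit, "decay_fit")) {
    list(type = "decay", amplitudes = fit$components$amplitude,
         lifetimes_ns = fit$components$lifetime_ns, offset = fit$offset,
         chi2_reduced = fit$chi2_reduced,
         tau_amplitude_weighted_ns = amplitude_weighted_lifetime(fit))
  } else if (inherits(fit, "lifetime_calibration")) {
    list(type = "lifetime_calibration", tau_donor_ns = fit$tau_donor_ns,
         e_min = fit$e_min, e_max = fit$e_max, c50_uM = fit$c50_uM,
         std_errors = as.list(fit$std_errors), flags = fit$flags,
         temperature_note = fit$temperature_note)
  } else {
    stop_fq("Unsupported fit object.", "fq_type_error")
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a lifetime calibration back from its JSON report
#' @param path JSON written by [write_fit_json()] for a calibration.
#' @return A `lifetime_calibration` (without the per-point table).
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "lifetime_calibration")) {
    stop_fq("JSON is not a lifetime_calibration report.", "fq_format_error")
  }
  structure(
    list(tau_donor_ns = j$tau_donor_ns, e_min = j$e_min, e_max = j$e_max,
         c50_uM = j$c50_uM, std_errors = unlist(j$std_errors),
         points = NULL, flags = j$flags %||% character(),
         temperature_note = j$temperature_note),
    class = "lifetime_calibration"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named analysis workflow from a configuration
#'
#' Binds the pipeline stages into the study's workflows. The configuration is
#' a named list (or path to a JSON file); `overrides` (e.g. parsed CLI flags)
#' take precedence over config keys. Every run writes a
#' `run_provenance.json` (inputs, seed, package version, config hash) into
#' the output directory, sufficient to reproduce deterministic stages.
#'
#' Workflows and their main keys:
#' * `simulate`: `seed`, optional scenario overrides, `out` — writes a full
#'   synthetic bundle via [sim_experiment()].
#' * `fit-titration`: `input` (titration CSV), `out`.
#' * `fit-fp`: `input` (FP CSV), `mode`, `tracer_uM`, `out`.
#' * `fret-image`: `manifest`, optional `bt_donor`/`bt_acceptor` (otherwise
#'   estimated from the manifest's `*_only` control rows), `min_pixels`,
#'   `eq6_orientation` (`printed`/`inverted`), `control_condition`, `out`.
#' * `flim-fit`: `input` (decay CSV), `n_components`, `out`.
#' * `flim-calibrate`: `decay_manifest` (CSV `conc_uM`, `path`),
#'   `donor_decay`, `n_components`, `out`.
#' * `flim-quantify`: `input` (decay CSV), `calibration` (JSON),
#'   `n_components`, `out`.
#' * `labeling`: `input` (gel-lane CSV), `out`.
#'
#' @param config Named list or path to a JSON config. Must contain
#'   `workflow`.
#' @param overrides Named list merged over `config`.
#' @return A list of result objects (workflow-dependent), invisibly; files
#'   are written under `config$out`.
#' @export
run_workflow <- function(config, overrides = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides
  wf <- config$workflow
  if (is.null(wf)) stop_fq("Config must name a `workflow`.", "fq_config_error")
  out_dir <- config$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  res <- switch(
    wf,
    "simulate" = {
      sc_args <- config[intersect(names(config),
                                  names(formals(synthetic_scenario)))]
      sc_args$seed <- config$seed %||% 1L
      sc <- do.call(synthetic_scenario, sc_args)
      manifest <- sim_experiment(sc, out_dir,
                                 n_fov = config$n_fov %||% 6)
      list(scenario = sc, manifest = manifest)
    },
    "fit-titration" = {
      fit <- fit_isotherm(read_titration_csv(config$input))
      write_fit_json(fit, file.path(out_dir, "isotherm_fit.json"))
      list(fit = fit)
    },
    "fit-fp" = {
      d <- read_fp_csv(config$input)
      mode <- config$mode %||% (if ("mode" %in% names(d)) d$mode[1] else "direct")
      fit <- if (mode == "direct") {
        tracer <- config$tracer_uM %||%
          (if ("tracer_uM" %in% names(d)) d$tracer_uM[1] else
            stop_fq("Direct FP fit needs `tracer_uM`.", "fq_config_error"))
        fit_fp_direct(d, tracer_conc = tracer)
      } else {
        fit_fp_competition(d)
      }
      write_fit_json(fit, file.path(out_dir, sprintf("fp_%s_fit.json", mode)))
      list(fit = fit)
    },
    "fret-image" = run_fret_image_workflow(config, out_dir),
    "flim-fit" = {
      fit <- fit_decay(read_decay_csv(config$input),
                       n_components = config$n_components %||% 3,
                       use_irf = isTRUE(config$use_irf))
      write_fit_json(fit, file.path(out_dir, "decay_fit.json"))
      list(fit = fit)
    },
    "flim-calibrate" = {
      man <- readr::read_csv(config$decay_manifest, show_col_types = FALSE)
      base <- dirname(normalizePath(config$decay_manifest))
      paths <- ifelse(grepl("^/", man$path), man$path, file.path(base, man$path))
      titr <- tibble(conc_uM = man$conc_uM,
                     decay = purrr::map(paths, read_decay_csv))
      calib <- build_lifetime_calibration(
        titr, read_decay_csv(config$donor_decay),
        n_components = config$n_components %||% 3)
      write_fit_json(calib, file.path(out_dir, "lifetime_calibration.json"))
      list(calibration = calib)
    },
    "flim-quantify" = {
      calib <- read_calibration_json(config$calibration)
      fit <- fit_decay(read_decay_csv(config$input),
                       n_components = config$n_components %||% 3)
      e <- fret_efficiency(amplitude_weighted_lifetime(fit), calib$tau_donor_ns)
      est <- coa_concentration(e, calib)
      readr::write_csv(est, file.path(out_dir, "coa_estimate.csv"))
      list(fit = fit, estimate = est)
    },
    "labeling" = {
      le <- labeling_efficiency(readr::read_csv(config$input, show_col_types = FALSE))
      readr::write_csv(le, file.path(out_dir, "labeling_efficiency.csv"))
      list(table = le)
    },
    stop_fq(sprintf("Unknown workflow '%s'.", wf), "fq_config_error")
  )

  prov <- list(workflow = wf, config = config, seed = config$seed %||% NA,
               package_version = as.character(utils::packageVersion("fretquant")),
               config_hash = rlang::hash(config), timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "run_provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(res)
}

# fret-image workflow: bleedthrough -> per-FOV net FRET -> ROI tables ->
# per-FOV normalized FRET (TAZ against matched Me control) -> condition
# comparison against the control condition.
run_fret_image_workflow <- function(config, out_dir) {
  man <- read_image_manifest(config$manifest)
  orientation <- config$eq6_orientation %||% "printed"
  min_pixels <- config$min_pixels %||% 50

  bt_d <- config$bt_donor
  bt_a <- config$bt_acceptor
  if (is.null(bt_d)) {
    rows <- man[man$condition == "donor_only", ]
    if (nrow(rows) == 0) stop_fq("No `bt_donor` given and no donor_only control in manifest.",
                                 "fq_config_error")
    bt_d <- estimate_bleedthrough(purrr::map(seq_len(nrow(rows)),
                                             ~ load_image_set(rows[.x, ])), "donor")
  }
  if (is.null(bt_a)) {
    rows <- man[man$condition == "acceptor_only", ]
    if (nrow(rows) == 0) stop_fq("No `bt_acceptor` given and no acceptor_only control in manifest.",
                                 "fq_config_error")
    bt_a <- estimate_bleedthrough(purrr::map(seq_len(nrow(rows)),
                                             ~ load_image_set(rows[.x, ])), "acceptor")
  }

  sample_rows <- man[man$probe %in% c("TAZ", "Me"), ]
  fov_results <- purrr::map(seq_len(nrow(sample_rows)), function(i) {
    row <- sample_rows[i, ]
    im <- load_image_set(row)
    nf <- net_fret_image(im, bt_d, bt_a,
                         intensity_floor = config$intensity_floor %||% 0)
    labs <- segment_rois(im$donor, min_pixels = min_pixels)
    list(row = row, rois = roi_table(nf, labs))
  })

  # Per-FOV mean net FRET of the Me control, matched by condition + order.
  rois_all <- purrr::map_dfr(fov_results, function(fr) {
    dplyr::mutate(fr$rois, probe = fr$row$probe)
  })
  me_means <- rois_all |>
    dplyr::filter(.data$probe == "Me") |>
    dplyr::group_by(.data$condition, .data$fov_id) |>
    dplyr::summarise(me_net = mean(.data$mean_net_fret), .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(pair_idx = dplyr::row_number()) |>
    dplyr::ungroup()

  taz <- rois_all |>
    dplyr::filter(.data$probe == "TAZ") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(pair_idx = dplyr::dense_rank(.data$fov_id)) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(me_means, "condition", "pair_idx", "me_net"),
                     by = c("condition", "pair_idx"))
  if (any(is.na(taz$me_net))) {
    stop_fq("Could not match every TAZ FOV to a Me control FOV of the same condition.",
            "fq_design_error")
  }
  taz <- dplyr::mutate(taz, norm_fret_pct = normalized_fret(
    .data$mean_net_fret, .data$me_net, orientation = orientation))
  readr::write_csv(taz, file.path(out_dir, "roi_table.csv"))

  fov_norm <- taz |>
    dplyr::group_by(.data$condition, .data$fov_id) |>
    dplyr::summarise(norm_fret_pct = mean(.data$norm_fret_pct), .groups = "drop")

  ctrl <- config$control_condition %||% "control"
  ctrl_vals <- fov_norm$norm_fret_pct[fov_norm$condition == ctrl]
  comparisons <- purrr::map_dfr(setdiff(unique(fov_norm$condition), ctrl), function(cc) {
    dplyr::mutate(
      ratio_change(fov_norm$norm_fret_pct[fov_norm$condition == cc], ctrl_vals),
      condition = cc, control = ctrl, .before = 1)
  })
  readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))

  list(bt_donor = as.numeric(bt_d), bt_acceptor = as.numeric(bt_a),
       roi_table = taz, fov_norm = fov_norm, comparisons = comparisons)
}
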