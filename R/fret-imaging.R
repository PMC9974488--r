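#' Bundle the three acquisition channels of one field of view
#'
#' A sensitized-emission experiment acquires each field under three settings:
#' donor excitation/donor emission (`donor`), acceptor excitation/acceptor
#' emission (`acceptor`), and donor excitation/acceptor emission (`fret`).
#' All three must be single-channel non-negative matrices of identical shape.
#'
#' @param donor,acceptor,fret Numeric matrices (intensity rasters).
#' @param fov_id,condition Optional labels carried into downstream tables.
#' @param pixel_size_um Optional pixel edge length, um.
#' @return An `image_set` object.
#' @export
image_set <- function(donor, acceptor, fret, fov_id = NA_character_,
                      condition = NA_character_, pixel_size_um = NA_real_) {
  chans <- list(donor = donor, acceptor = acceptor, fret = fret)
  for (nm in names(chans)) {
    m <- chans[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop_fq(sprintf("Channel `%s` must be a numeric matrix.", nm), "fq_type_error")
    }
    if (any(!is.finite(m)) || any(m < 0)) {
      stop_fq(sprintf("Channel `%s` must be finite and non-negative.", nm), "fq_domain_error")
    }
  }
  dims <- vapply(chans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_fq("All channels of an image_set must share the same dimensions.", "fq_shape_error")
  }
  structure(
    list(donor = donor, acceptor = acceptor, fret = fret,
         fov_id = fov_id, condition = condition, pixel_size_um = pixel_size_um),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %dx%d px, fov = %s, condition = %s\n",
              nrow(x$donor), ncol(x$donor), x$fov_id, x$condition))
  invisible(x)
}

#' Estimate a spectral bleedthrough factor from single-fluorophore controls
#'
#' With a sample carrying only the donor (or only the acceptor), any signal in
#' the FRET channel is bleedthrough. The factor is the median, over pixels
#' whose source-channel intensity exceeds `background_floor`, of the
#' FRET-channel to source-channel intensity ratio. The median makes the
#' estimate robust to hot pixels and residual autofluorescence.
#'
#' @param control_images A single `image_set` or a list of them, acquired on a
#'   donor-only or acceptor-only sample.
#' @param channel Which fluorophore the control carries: `"donor"` or
#'   `"acceptor"`.
#' @param background_floor Pixels with source intensity at or below this value
#'   are excluded. `NULL` (default) uses median + 3 MAD of the pooled source
#'   pixels — a robust "3 SD above background" rule when most pixels are
#'   background.
#' @return A single bleedthrough factor (dimensionless) with attributes
#'   `n_pixels` (qualifying pixels) and `background_floor`.
#' @export
estimate_bleedthrough <- function(control_images, channel = c("donor", "acceptor"),
                                  background_floor = NULL) {
  channel <- match.arg(channel)
  if (inherits(control_images, "image_set")) control_images <- list(control_images)
  stopifnot(length(control_images) >= 1,
            all(vapply(control_images, inherits, logical(1), "image_set")))

  src <- unlist(lapply(control_images, function(im) as.numeric(im[[channel]])))
  frt <- unlist(lapply(control_images, function(im) as.numeric(im$fret)))

  if (is.null(background_floor)) {
    background_floor <- stats::median(src) + 3 * stats::mad(src)
    if (!is.finite(background_floor)) background_floor <- 0
  }
  keep <- src > background_floor
  if (!any(keep)) {
    stop_fq("No pixels above the background floor; cannot estimate bleedthrough.",
            "fq_empty_error")
  }
  out <- stats::median(frt[keep] / src[keep])
  attr(out, "n_pixels") <- sum(keep)
  attr(out, "background_floor") <- background_floor
  out
}

#' Pixel-wise bleedthrough-corrected net FRET
#'
#' Computes, per pixel,
#' \deqn{netFRET = \frac{I_{FRET} - I_{donor} BT_d - I_{acceptor} BT_a}{\sqrt{I_{donor} I_{acceptor}}}}
#' the sensitized emission remaining after subtracting the fraction of donor
#' and acceptor signal that bleeds into the FRET channel, normalized by the
#' geometric mean of the two direct channels so the statistic is insensitive
#' to probe amount. Pixels whose donor-acceptor intensity product is at or
#' below `intensity_floor^2` are masked invalid (excluded, never NaN).
#'
#' @param imgs An `image_set`.
#' @param bt_donor,bt_acceptor Bleedthrough factors, typically from
#'   [estimate_bleedthrough()].
#' @param intensity_floor Per-channel intensity floor (>= 0); default 0 masks
#'   only pixels where a direct channel is exactly zero.
#' @return A `net_fret_image`: list with `net` (numeric matrix, `NA` where
#'   invalid), `valid` (logical matrix), and the inputs' labels.
#' @export
net_fret_image <- function(imgs, bt_donor, bt_acceptor, intensity_floor = 0) {
  stopifnot(inherits(imgs, "image_set"))
  check_numeric(bt_donor, "bt_donor", nonneg = TRUE)
  check_numeric(bt_acceptor, "bt_acceptor", nonneg = TRUE)
  check_numeric(intensity_floor, "intensity_floor", nonneg = TRUE)

  prod_da <- imgs$donor * imgs$acceptor
  valid <- prod_da > intensity_floor^2
  net <- matrix(NA_real_, nrow(imgs$donor), ncol(imgs$donor))
  num <- imgs$fret - imgs$donor * bt_donor - imgs$acceptor * bt_acceptor
  net[valid] <- num[valid] / sqrt(prod_da[valid])
  structure(
    list(net = net, valid = valid, fov_id = imgs$fov_id, condition = imgs$condition),
    class = "net_fret_image"
  )
}

#' @export
print.net_fret_image <- function(x, ...) {
  cat(sprintf("<net_fret_image> %dx%d px, %d valid (%.1f%%), mean net FRET %.4g\n",
              nrow(x$net), ncol(x$net), sum(x$valid),
              100 * mean(x$valid), mean(x$net[x$valid])))
  invisible(x)
}

# Merge 4-connected labels that touch diagonally, yielding 8-connected
# components. Union-find over label pairs collected from the two diagonal
# shifts of the label raster.
merge_diagonal_labels <- function(lab) {
  n <- max(lab)
  if (n < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right neighbors
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left neighbors
  pick1 <- a1 > 0 & b1 > 0 & a1 != b1
  pick2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[pick1], b1[pick1]), cbind(a2[pick2], b2[pick2]))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment cell ROIs by intensity thresholding
#'
#' Thresholds a single fluorescence channel (Otsu's method on a 256-level
#' histogram) and labels 8-connected components, discarding regions smaller
#' than `min_pixels`. Deterministic for fixed input; labels are assigned in
#' raster order.
#'
#' @param img Numeric matrix, e.g. the GFP/donor channel.
#' @param min_pixels Minimum component size kept (default 50).
#' @param threshold Optional fixed threshold overriding Otsu.
#' @return Integer label matrix (0 = background) with attributes `threshold`
#'   and `n_rois`. Zero ROIs triggers a warning, not an error.
#' @export
segment_rois <- function(img, min_pixels = 50, threshold = NULL) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_fq("`img` must be a numeric matrix.", "fq_type_error")
  }
  rng <- range(img)
  if (is.null(threshold)) {
    if (rng[2] > rng[1]) {
      scaled <- (img - rng[1]) / (rng[2] - rng[1])
      th01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
      threshold <- rng[1] + th01 * (rng[2] - rng[1])
    } else {
      threshold <- rng[2]  # flat image: nothing above threshold
    }
  }
  mask <- img > threshold
  if (!any(mask)) {
    warn_fq("No pixels above threshold; returning zero ROIs.", "fq_empty_warning")
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "threshold") <- threshold
    attr(out, "n_rois") <- 0L
    class(out) <- c("roi_labels", class(out))
    return(out)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- merge_diagonal_labels(matrix(as.integer(EBImage::imageData(lab)),
                                      nrow(img), ncol(img)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_pixels)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out <- matrix(as.integer(out), nrow(img), ncol(img))
  if (max(out) == 0) {
    warn_fq("All components below `min_pixels`; returning zero ROIs.", "fq_empty_warning")
  }
  attr(out, "threshold") <- threshold
  attr(out, "n_rois") <- max(out)
  class(out) <- c("roi_labels", class(out))
  out
}

#' Per-ROI net FRET summary table
#'
#' Averages a net FRET raster over each labeled ROI, using valid pixels only,
#' and optionally attaches the normalized FRET percentage against a matched
#' fully-open control value.
#'
#' @param nf A `net_fret_image`.
#' @param labels An ROI label matrix from [segment_rois()].
#' @param control_net Optional scalar: the mean net FRET of the matched
#'   non-responsive (fully open) control probe for this field of view. When
#'   given, a `norm_fret_pct` column is added via [normalized_fret()].
#' @param orientation Passed to [normalized_fret()].
#' @return A tibble with one row per ROI: `roi_id`, `pixel_count`,
#'   `mean_net_fret`, and optionally `norm_fret_pct`, plus `fov_id` and
#'   `condition` labels.
#' @export
roi_table <- function(nf, labels, control_net = NULL,
                      orientation = c("printed", "inverted")) {
  stopifnot(inherits(nf, "net_fret_image"))
  orientation <- match.arg(orientation)
  lab <- as.integer(labels)
  ok <- lab > 0 & as.logical(nf$valid)
  if (!any(ok)) {
    return(tibble(roi_id = integer(), pixel_count = integer(),
                  mean_net_fret = double(), fov_id = character(),
                  condition = character()))
  }
  d <- tibble(roi_id = lab[ok], net = as.numeric(nf$net)[ok]) |>
    dplyr::group_by(roi_id) |>
    dplyr::summarise(pixel_count = dplyr::n(),
                     mean_net_fret = mean(net), .groups = "drop") |>
    dplyr::mutate(fov_id = nf$fov_id, condition = nf$condition)
  if (!is.null(control_net)) {
    d <- dplyr::mutate(
      d, norm_fret_pct = normalized_fret(mean_net_fret, control_net,
                                         orientation = orientation))
  }
  d
}

#' Normalized FRET against the fully-open control probe
#'
#' Expresses a ROI's bleedthrough-corrected net FRET relative to that of a
#' matched control probe whose tethered ligand cannot rebind (fully open
#' state, no ratiometric response). The default orientation divides the
#' control by the sensor value (`control / sensor x 100%`); `"inverted"`
#' divides the sensor by the control (`sensor / control x 100%`). Both
#' conventions appear in the sensitized-emission literature; choose one and
#' keep it fixed across an experiment.
#'
#' @param net_sensor Net FRET of the responsive sensor (per ROI; vectorized).
#' @param net_control Net FRET of the matched fully-open control (scalar or
#'   vector).
#' @param orientation `"printed"` (default): `control / sensor`;
#'   `"inverted"`: `sensor / control`.
#' @return Normalized FRET, percent.
#' @export
normalized_fret <- function(net_sensor, net_control,
                            orientation = c("printed", "inverted")) {
  orientation <- match.arg(orientation)
  check_numeric(net_sensor, "net_sensor")
  check_numeric(net_control, "net_control")
  denom <- if (orientation == "printed") net_sensor else net_control
  if (any(denom == 0)) {
    stop_fq("Zero denominator in normalized FRET.", "fq_domain_error")
  }
  if (orientation == "printed") {
    100 * net_control / net_sensor
  } else {
    100 * net_sensor / net_control
  }
}

#' Relative change of normalized FRET between two conditions
#'
#' Computes `100 * (mean(condition) - mean(control)) / mean(control)` on
#' field-of-view level means (the FOV is the statistical unit), with the
#' standard error propagated by the delta method for a ratio of independent
#' means.
#'
#' @param fov_means_cond,fov_means_ctrl Numeric vectors of per-FOV mean
#'   normalized FRET, one value per field of view; each needs >= 2 FOVs.
#' @return A tibble with `percent_change`, `sem`, `n_cond`, `n_ctrl`, and the
#'   two-tailed unpaired t-test `p_value` from [compare_conditions()].
#' @export
ratio_change <- function(fov_means_cond, fov_means_ctrl) {
  check_numeric(fov_means_cond, "fov_means_cond")
  check_numeric(fov_means_ctrl, "fov_means_ctrl")
  if (length(fov_means_cond) < 2 || length(fov_means_ctrl) < 2) {
    stop_fq("At least 2 FOVs per group are required.", "fq_design_error")
  }
  mc <- mean(fov_means_cond); m0 <- mean(fov_means_ctrl)
  if (m0 == 0) stop_fq("Control mean is zero; relative change undefined.", "fq_domain_error")
  vc <- stats::var(fov_means_cond) / length(fov_means_cond)
  v0 <- stats::var(fov_means_ctrl) / length(fov_means_ctrl)
  # Delta method for r = mc/m0: var(r) ~ vc/m0^2 + mc^2 v0/m0^4
  sem <- 100 * sqrt(vc / m0^2 + mc^2 * v0 / m0^4)
  tibble(
    percent_change = 100 * (mc - m0) / m0,
    sem = sem,
    n_cond = length(fov_means_cond),
    n_ctrl = length(fov_means_ctrl),
    p_value = compare_conditions(fov_means_cond, fov_means_ctrl)
  )
}

#' Two-tailed unpaired t-test between FOV-level means
#'
#' Thin wrapper around [stats::t.test()] (Welch, two-sided) on per-FOV means.
#' Degenerate zero-variance input yields `NaN` with a warning rather than an
#' error.
#'
#' @param group_a,group_b Numeric vectors of per-FOV means, each length >= 2.
#' @return The p-value.
#' @export
compare_conditions <- function(group_a, group_b) {
  check_numeric(group_a, "group_a")
  check_numeric(group_b, "group_b")
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_fq("Each group needs at least 2 FOVs for a t-test.", "fq_design_error")
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) return(1)
    warn_fq("Zero variance in both groups; p-value undefined.", "fq_degenerate_warning")
    return(NaN)
  }
  out <- tryCatch(stats::t.test(group_a, group_b, var.equal = FALSE)$p.value,
                  error = function(e) {
                    warn_fq(paste0("t-test degenerate: ", conditionMessage(e)),
                            "fq_degenerate_warning")
                    NaN
                  })
  out
}
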