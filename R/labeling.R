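#' Labeling efficiency from dual-channel gel band intensities
#'
#' Quantifies how completely an intracellular self-labeling protein was
#' conjugated with its probe. After lysis, the unreacted fraction is labeled
#' with a second dye (Alexa488) and a loading reference (SiR) marks total
#' protein. With `S` the sample and `C` the fully-unreacted control band
#' intensities (background-corrected), the labeled fraction is
#' \deqn{LE = 100 (1 - \frac{S_{A488}/S_{SiR}}{C_{A488}/C_{SiR}})}
#' Noise can push individual lanes below 0% or above 100%; such values are
#' reported as computed with an `out_of_range` flag rather than clipped.
#'
#' @param data A data frame with one row per gel lane and columns `s_a488`,
#'   `s_sir` (sample bands, >= 0, `s_sir` > 0) and `c_a488`, `c_sir` (control
#'   bands, > 0). Extra columns (e.g. `sample_id`) are carried through.
#' @return The input tibble with `le_percent` and `flag` columns added.
#' @examples
#' labeling_efficiency(tibble::tibble(s_a488 = 1, s_sir = 4, c_a488 = 1, c_sir = 2))
#' @export
labeling_efficiency <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("s_a488", "s_sir", "c_a488", "c_sir")
  if (!all(need %in% names(data))) {
    stop_fq(paste0("Missing columns: ", paste(setdiff(need, names(data)), collapse = ", ")),
            "fq_shape_error")
  }
  check_numeric(data$s_a488, "s_a488", nonneg = TRUE)
  check_numeric(data$c_a488, "c_a488", positive = TRUE)
  check_numeric(data$c_sir, "c_sir", positive = TRUE)
  if (any(data$s_sir <= 0)) {
    stop_fq("`s_sir` must be strictly positive (loading reference band).",
            "fq_domain_error")
  }
  as_tibble(data) |>
    dplyr::mutate(
      le_percent = 100 * (1 - (.data$s_a488 / .data$s_sir) / (.data$c_a488 / .data$c_sir)),
      flag = ifelse(.data$le_percent < 0 | .data$le_percent > 100, "out_of_range", "ok")
    )
}

#' Detect the plateau of a labeling time-course
#'
#' Finds the earliest time after which every successive probe/protein
#' fluorescence ratio changes by less than `tol` (relative), i.e. labeling
#' has saturated. A constant series plateaus at its first point; a series
#' still rising at its end is flagged not plateaued.
#'
#' @param data Data frame of the time course.
#' @param time,ratio Columns; defaults `time_h` and `ratio`.
#' @param tol Relative tolerance between consecutive ratios (default 0.02).
#' @return A tibble with `plateaued` (logical), `plateau_time_h` (`NA` if not
#'   plateaued), `plateau_ratio` (mean over the plateau) and `n_points`.
#' @export
labeling_timecourse <- function(data, time = time_h, ratio = ratio, tol = 0.02) {
  stopifnot(is.data.frame(data))
  tv <- dplyr::pull(data, {{ time }})
  rv <- dplyr::pull(data, {{ ratio }})
  check_numeric(tv, "time"); check_numeric(rv, "ratio")
  if (length(tv) < 4) {
    stop_fq("At least 4 time points are required for plateau detection.",
            "fq_design_error")
  }
  ord <- order(tv); tv <- tv[ord]; rv <- rv[ord]
  rel <- abs(diff(rv)) / pmax(abs(rv[-length(rv)]), .Machine$double.eps)
  # plateau start = earliest i such that all steps from i on are below tol
  flat_from <- rev(cumprod(rev(rel < tol))) == 1
  if (!any(flat_from)) {
    return(tibble(plateaued = FALSE, plateau_time_h = NA_real_,
                  plateau_ratio = NA_real_, n_points = length(tv)))
  }
  i0 <- which(flat_from)[1]
  tibble(plateaued = TRUE,
         plateau_time_h = tv[i0],
         plateau_ratio = mean(rv[i0:length(rv)]),
         n_points = length(tv))
}
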