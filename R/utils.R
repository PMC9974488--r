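#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats median mad nlminb optimHess pt qnorm quantile rnorm rpois
#'   rmultinom runif sd setNames t.test var convolve
NULL

# Internal: stop with a classed condition so callers can test on class.
stop_fq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fretquant_error"))
}

warn_fq <- function(msg, class) {
  rlang::warn(msg, class = c(class, "fretquant_warning"))
}

check_numeric <- function(x, name, finite = TRUE, nonneg = FALSE, positive = FALSE) {
  if (!is.numeric(x)) stop_fq(sprintf("`%s` must be numeric.", name), "fq_type_error")
  if (finite && any(!is.finite(x))) {
    stop_fq(sprintf("`%s` contains non-finite values.", name), "fq_domain_error")
  }
  if (positive && any(x <= 0)) {
    stop_fq(sprintf("`%s` must be strictly positive.", name), "fq_domain_error")
  }
  if (nonneg && any(x < 0)) {
    stop_fq(sprintf("`%s` must be non-negative.", name), "fq_domain_error")
  }
  invisible(x)
}

# Derive a stream-specific 32-bit seed from a base seed. Keeps independent
# generators decoupled when one scenario feeds several modalities.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
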