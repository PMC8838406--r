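## Multi-Scale Retinex (MSR) illumination correction and green-channel
## extraction. Fundus photographs suffer smooth vignetting and uneven
## illumination; MSR estimates log-reflectance as a weighted sum over scales
## of log(S) - log(S * F_n), where F_n is a normalized Gaussian surround.

#' Multi-Scale Retinex configuration
#'
#' @param scales Surround-Gaussian standard deviations in pixels. The default
#'   small/medium/large triple (15, 80, 250) is standard MSR practice: the
#'   small scale preserves local contrast, the large scale flattens global
#'   illumination; surround kernels are truncated to fit the image.
#' @param weights Per-scale weights, non-negative, summing to 1.
#' @param epsilon Positive stabilizer: intensities are clamped from below at
#'   `epsilon` before taking logarithms, so true zeros do not produce
#'   `log(0)` while strictly positive images are left untouched (keeping MSR
#'   exactly invariant to global multiplicative gain).
#' @return Object of class `msr_config`.
#' @export
msr_config <- function(scales = c(15, 80, 250),
                       weights = rep(1 / length(scales), length(scales)),
                       epsilon = 1 / 255) {
  if (length(scales) != length(weights))
    stop("scales and weights must have equal length", call. = FALSE)
  if (any(scales <= 0)) stop("all MSR scales must be > 0", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("MSR weights must be >= 0 and sum to 1", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  structure(list(scales = scales, weights = weights, epsilon = epsilon),
            class = "msr_config")
}

#' Multi-Scale Retinex illumination correction
#'
#' Computes, per channel, `sum_n w_n * (log(S) - log(S * F_n))` where `F_n` is
#' a normalized Gaussian surround of standard deviation `scales[n]` and `*` is
#' 2-D convolution with reflective boundary handling (identical across
#' scales). A constant image therefore yields an identically zero raw
#' response, and the raw response is invariant to global multiplicative gain.
#'
#' @param image Grayscale matrix or `h x w x 3` array, values in `[0, 1]`.
#' @param config An [msr_config()].
#' @param rescale If `TRUE` (default), min-max rescale each channel of the
#'   output to `[0, 1]`; if `FALSE`, return the raw log-ratio response.
#' @return Same shape as `image`.
#' @export
msr <- function(image, config = msr_config(), rescale = TRUE) {
  stopifnot(inherits(config, "msr_config"))
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  one <- function(ch) {
    S <- pmax(ch, config$epsilon)
    radius_limit <- (min(dim(S)) - 1) / 2
    out <- 0
    for (n in seq_along(config$scales)) {
      Fk <- gaussian_kernel(config$scales[n], radius_limit)
      out <- out + config$weights[n] * (log(S) - log(conv2_reflect(S, Fk)))
    }
    if (rescale) rescale01(out) else out
  }
  if (length(dim(image)) == 3L) {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- one(image[, , c])
    out
  } else one(image)
}

#' Extract the green channel of a color image
#'
#' In fundus photography the green channel carries the highest
#' vessel/background contrast (red is over-saturated and low contrast, blue
#' is dim and noisy), so it is the working grayscale image of the pipeline.
#'
#' @param image `h x w x 3` array (red, green, blue).
#' @return Grayscale matrix: channel 2, unchanged.
#' @export
extract_green_channel <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("extract_green_channel requires a 3-channel color image", call. = FALSE)
  image[, , 2L]
}
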