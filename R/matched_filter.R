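## Rotated Gaussian matched filters for curvilinear (vessel) structures.
## A vessel cross-section is approximately an inverted Gaussian, so the
## template is -exp(-u^2 / 2 sigma^2) along the cross-vessel coordinate u,
## extended L pixels along the vessel, rotated over a bank of orientations.
## The in-support mean is subtracted (classical matched-filter practice) so
## a constant background produces exactly zero response; dark vessels then
## produce positive responses.

#' Matched-filter kernel specification
#'
#' @param sigma Kernel scale (px): the cross-sectional spread of vessels the
#'   filter is tuned to.
#' @param length Template length `L` along the vessel (default 9 px: short
#'   enough that vessel segments are approximately straight).
#' @param n_orientations Number of orientations covering `[0, 180)` degrees
#'   (default 12, i.e. one kernel every 15 degrees).
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma, length = 9, n_orientations = 12L) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length <= 0) stop("length must be > 0", call. = FALSE)
  n_orientations <- as.integer(n_orientations)
  angle_step <- 180 / n_orientations
  if (n_orientations < 1L || abs(n_orientations * angle_step - 180) > 1e-9)
    stop("n_orientations x angle_step must equal 180 degrees", call. = FALSE)
  structure(list(sigma = sigma, length = length,
                 n_orientations = n_orientations, angle_step = angle_step),
            class = "kernel_spec")
}

#' Build one rotated matched-filter kernel
#'
#' Grid points `p = (x, y)` (x = column offset, y = row offset) are rotated to
#' `(u, v) = p %*% t(r)` with `r = [[cos, -sin], [sin, cos]]`; the support is
#' `|u| <= 3 sigma, |v| <= L/2`. In-support values are `-exp(-u^2/2 sigma^2)`
#' minus their mean (zero-mean kernel); out-of-support entries are 0. The
#' kernel at angle `theta` responds maximally to a vessel running along
#' direction `(sin theta, cos theta)` in (column, row) coordinates.
#'
#' For very small `sigma` (e.g. 0.13, where `3 sigma < 1` px) the support
#' collapses to the `u = 0` line; at angles where every in-support grid point
#' has exactly `u = 0` (0 and 90 degrees) mean subtraction yields the zero
#' kernel. This degeneracy is kept as the support rule dictates.
#'
#' @param spec A [kernel_spec()].
#' @param theta Orientation in degrees, in `[0, 180)`.
#' @return Zero-mean kernel matrix (odd dimensions) with attributes `sigma`
#'   and `theta`.
#' @export
build_kernel <- function(spec, theta) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.numeric(theta) || theta < 0 || theta >= 180)
    stop("theta must lie in [0, 180) degrees", call. = FALSE)
  sigma <- spec$sigma; L <- spec$length
  R <- ceiling(sqrt((3 * sigma)^2 + (L / 2)^2))
  xs <- matrix(seq.int(-R, R), 2 * R + 1, 2 * R + 1, byrow = TRUE) # columns
  ys <- matrix(seq.int(-R, R), 2 * R + 1, 2 * R + 1)               # rows
  th <- theta * pi / 180
  u <- cos(th) * xs - sin(th) * ys
  v <- sin(th) * xs + cos(th) * ys
  insup <- abs(u) <= 3 * sigma & abs(v) <= L / 2
  k <- matrix(0, 2 * R + 1, 2 * R + 1)
  vals <- -exp(-u[insup]^2 / (2 * sigma^2))
  k[insup] <- vals - mean(vals)
  # crop all-zero border (support is centrosymmetric, so crop symmetrically)
  nz_r <- which(apply(insup, 1, any)); nz_c <- which(apply(insup, 2, any))
  mr <- max(abs(nz_r - (R + 1))); mc <- max(abs(nz_c - (R + 1)))
  k <- k[seq.int(R + 1 - mr, R + 1 + mr), seq.int(R + 1 - mc, R + 1 + mc),
         drop = FALSE]
  attr(k, "sigma") <- sigma; attr(k, "theta") <- theta
  k
}

#' Build the full orientation bank for one scale
#'
#' @param spec A [kernel_spec()].
#' @return Named list of kernels at `theta = 0, step, ..., 180 - step`.
#' @export
filter_bank <- function(spec) {
  thetas <- (seq_len(spec$n_orientations) - 1L) * spec$angle_step
  stats::setNames(lapply(thetas, function(th) build_kernel(spec, th)),
                  sprintf("theta_%g", thetas))
}

#' Maximum orientation response of the matched filter
#'
#' Convolves the image with every kernel of the orientation bank (reflective
#' boundary) and keeps the pixel-wise maximum response. Because kernels are
#' zero-mean, a constant image gives an identically zero response.
#'
#' @param image Grayscale matrix (finite values).
#' @param spec A [kernel_spec()].
#' @param return_argmax If `TRUE`, attach attribute `argmax_theta`: the
#'   orientation (degrees) attaining the maximum at each pixel.
#' @return Matrix of maximum responses (not clamped; clamping at zero happens
#'   in [fuse_scales()]).
#' @export
max_response <- function(image, spec, return_argmax = FALSE) {
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  bank <- filter_bank(spec)
  best <- NULL; arg <- NULL
  for (k in bank) {
    r <- conv2_reflect(image, k)
    if (is.null(best)) {
      best <- r
      if (return_argmax) arg <- matrix(attr(k, "theta"), nrow(r), ncol(r))
    } else {
      if (return_argmax) arg[r > best] <- attr(k, "theta")
      best <- pmax(best, r)
    }
  }
  if (return_argmax) attr(best, "argmax_theta") <- arg
  best
}

#' Scale-fusion configuration
#'
#' @param sigmas Three kernel scales; the defaults (1.9, 0.5, 0.13) target the
#'   main vessel contours, intermediate calibers, and the finest details.
#' @param weights Non-negative fusion weights summing to 1 (default uniform).
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(sigmas = c(1.9, 0.5, 0.13),
                          weights = rep(1 / 3, 3)) {
  if (length(sigmas) != length(weights))
    stop("sigmas and weights must have equal length", call. = FALSE)
  if (any(sigmas <= 0)) stop("all sigmas must be > 0", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("fusion weights must be >= 0 and sum to 1", call. = FALSE)
  structure(list(sigmas = sigmas, weights = weights), class = "fusion_config")
}

#' Fuse per-scale maximum responses
#'
#' Responses are clamped at zero from below (vessels are dark, so genuine
#' vessel responses are positive) and combined as a weighted pixel-wise sum
#' `G = w1 G1 + w2 G2 + w3 G3`, then min-max rescaled to `[0, 1]` (single
#' rescaling after fusion; per-scale maps are not individually rescaled).
#'
#' @param responses List of per-scale response matrices, equal dimensions.
#' @param config A [fusion_config()] (its `weights` are used).
#' @param clamp Clamp responses at 0 from below before fusing (default `TRUE`).
#' @param rescale Min-max rescale the fused map to `[0,1]` (default `TRUE`).
#' @return Fused response matrix.
#' @export
fuse_scales <- function(responses, config = fusion_config(), clamp = TRUE,
                        rescale = TRUE) {
  stopifnot(inherits(config, "fusion_config"),
            length(responses) == length(config$weights))
  for (i in seq_along(responses)[-1])
    stop_if_dim_mismatch(responses[[1]], responses[[i]], "scale responses")
  out <- 0
  for (i in seq_along(responses)) {
    g <- responses[[i]]
    if (clamp) g <- pmax(g, 0)
    out <- out + config$weights[i] * g
  }
  if (rescale) rescale01(out) else out
}

#' Multiscale matched-filter vessel enhancement
#'
#' Convenience wrapper: maximum orientation response at each scale of
#' `config$sigmas`, fused by [fuse_scales()].
#'
#' @param image Grayscale matrix.
#' @param config A [fusion_config()].
#' @param length,n_orientations Passed to [kernel_spec()].
#' @return Fused vessel-enhancement map in `[0, 1]`.
#' @export
multiscale_response <- function(image, config = fusion_config(),
                                length = 9, n_orientations = 12L) {
  responses <- lapply(config$sigmas, function(s)
    max_response(image, kernel_spec(s, length, n_orientations)))
  fuse_scales(responses, config)
}
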