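## Synthetic fundus phantoms: dark Gaussian-profile vessels on a bright,
## unevenly illuminated disc (the camera field of view), with pixel-exact
## ground truth. Every downstream stage of the pipeline is testable against
## these without external datasets.

#' Specify a synthetic fundus phantom
#'
#' A phantom is a bright circular field of view (FOV) on a dark surround,
#' crossed by dark vessels with Gaussian cross-sections, modulated by a smooth
#' illumination field and additive Gaussian noise. Vessel cross-section
#' standard deviation is `width / 2.355`, i.e. `width` is the full width at
#' half maximum (FWHM) of the intensity dip, which makes the half-peak-depth
#' ground-truth rule mark a band of approximately `width` pixels.
#'
#' @param height,width Image dimensions in pixels.
#' @param vessels `data.frame` with one row per vessel segment and columns
#'   `r0, c0, r1, c1` (endpoints, row/column pixel coordinates), `width`
#'   (FWHM in px, `> 0` and `<= min(height, width)/4`) and `depth` (contrast
#'   depth in gray units, `> 0`; vessels are darker than background). May have
#'   zero rows.
#' @param fov_radius_fraction FOV radius as a fraction of `min(height, width)/2`,
#'   in `(0, 1]`.
#' @param background_level Background gray level inside the FOV, in `[0, 1]`.
#' @param illumination_amplitude Peak-to-trough amplitude of the smooth
#'   illumination field (a broad off-center Gaussian hotspot, zero-mean).
#' @param noise_sigma Standard deviation of additive Gaussian noise (`>= 0`).
#' @param seed Integer seed controlling the noise; phantoms are bit-identical
#'   for identical spec and seed.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [random_phantom_spec()]
#' @export
phantom_spec <- function(height, width, vessels = empty_vessels(),
                         fov_radius_fraction = 0.92,
                         background_level = 0.78,
                         illumination_amplitude = 0.12,
                         noise_sigma = 0.02,
                         seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 8L || width < 8L)
    stop("phantom dimensions must be integers >= 8", call. = FALSE)
  if (!is.data.frame(vessels) ||
      !all(c("r0", "c0", "r1", "c1", "width", "depth") %in% names(vessels)))
    stop("vessels must be a data.frame with columns r0,c0,r1,c1,width,depth",
         call. = FALSE)
  if (nrow(vessels) > 0) {
    if (any(vessels$width <= 0) || any(vessels$width > min(height, width) / 4))
      stop("vessel widths must be in (0, min(height,width)/4]", call. = FALSE)
    if (any(vessels$depth <= 0))
      stop("vessel contrast depth must be > 0 (vessels are darker than background)",
           call. = FALSE)
  }
  if (fov_radius_fraction <= 0 || fov_radius_fraction > 1)
    stop("fov_radius_fraction must be in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (background_level < 0 || background_level > 1)
    stop("background_level must be in [0, 1]", call. = FALSE)
  structure(list(height = height, width = width, vessels = vessels,
                 fov_radius_fraction = fov_radius_fraction,
                 background_level = background_level,
                 illumination_amplitude = illumination_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Empty vessel table (helper for degenerate phantoms)
#' @return Zero-row `data.frame` with the vessel columns.
#' @export
empty_vessels <- function() {
  data.frame(r0 = numeric(0), c0 = numeric(0), r1 = numeric(0),
             c1 = numeric(0), width = numeric(0), depth = numeric(0))
}

# Noise-free per-segment vessel field: depth * exp(-d^2 / (2 sigma_v^2)) with
# d the distance from each pixel to the segment. Fields of multiple segments
# combine by pixel-wise maximum (crossing vessels do not darken additively).
vessel_field <- function(height, width, seg) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  ar <- seg$r0; ac <- seg$c0
  dr <- seg$r1 - ar; dc <- seg$c1 - ac
  len2 <- dr^2 + dc^2
  t <- if (len2 > 0) ((rr - ar) * dr + (cc - ac) * dc) / len2 else rr * 0
  t <- pmin(pmax(t, 0), 1)
  d2 <- (rr - (ar + t * dr))^2 + (cc - (ac + t * dc))^2
  sigma_v <- seg$width / 2.355
  seg$depth * exp(-d2 / (2 * sigma_v^2))
}

#' Generate a synthetic fundus phantom
#'
#' Renders the phantom described by a [phantom_spec()]: a constant background
#' inside the circular FOV minus the vessel field (pixel-wise maximum over
#' per-segment inverted-Gaussian profiles), multiplied by a smooth unit-mean
#' illumination field (illumination acts multiplicatively on reflectance, so
#' shading also scales local vessel contrast), plus Gaussian noise, clipped to
#' `[0, 1]`. The surround outside the FOV sits
#' near black. The ground-truth mask marks pixels whose noiseless contribution
#' from some segment exceeds half that segment's depth, intersected with the
#' FOV.
#'
#' @param spec A [phantom_spec()].
#' @param color If `TRUE`, return a 3-channel image: the vessel signal lives
#'   predominantly in the green channel, the red channel is bright with low
#'   vessel contrast, and the blue channel is dim and noisy — mimicking the
#'   channel statistics of real fundus photographs.
#' @return An object of class `phantom`: list with `image` (matrix or
#'   `h x w x 3` array in `[0,1]`), `truth` (0/1 matrix, 1 = vessel),
#'   `fov` (0/1 matrix, 1 = inside field of view) and `spec`.
#' @examples
#' sp <- random_phantom_spec(height = 128, width = 128, n_vessels = 4, seed = 7)
#' ph <- generate_phantom(sp)
#' mean(ph$truth)  # vessel pixel fraction
#' @export
generate_phantom <- function(spec, color = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ctr_r <- (h + 1) / 2; ctr_c <- (w + 1) / 2
  radius <- spec$fov_radius_fraction * min(h, w) / 2
  fov <- (((rr - ctr_r)^2 + (cc - ctr_c)^2) <= radius^2) * 1

  V <- matrix(0, h, w)
  truth <- matrix(0, h, w)
  if (nrow(spec$vessels) > 0) {
    for (i in seq_len(nrow(spec$vessels))) {
      seg <- spec$vessels[i, ]
      f <- vessel_field(h, w, seg)
      V <- pmax(V, f)
      truth <- pmax(truth, (f > seg$depth / 2) * 1)
    }
  }
  truth <- truth * fov

  # smooth uneven illumination: broad off-center Gaussian hotspot, zero-mean,
  # applied multiplicatively (images form as illumination x reflectance, so
  # shading scales vessel contrast along with the background)
  si <- 0.45 * min(h, w)
  g <- exp(-((rr - 0.35 * h)^2 + (cc - 0.35 * w)^2) / (2 * si^2))
  illum <- 1 + spec$illumination_amplitude * (g - mean(g[fov == 1]))

  base <- (spec$background_level - V) * illum * fov + 0.02 * (1 - fov)
  img <- with_seed(spec$seed, {
    noise <- if (spec$noise_sigma > 0)
      matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w) else 0
    if (color) {
      # red: brighter, only 25% of the vessel dip; blue: dim, faint dip, 3x noise
      red   <- pmin(pmax(base + (0.12 + 0.75 * V) * fov + noise * 0.7, 0), 1)
      blue  <- pmin(pmax((0.25 - 0.25 * V) * fov + 0.02 * (1 - fov) + 3 * noise, 0), 1)
      green <- pmin(pmax(base + noise, 0), 1)
      array(c(red, green, blue), dim = c(h, w, 3L))
    } else {
      pmin(pmax(base + noise, 0), 1)
    }
  })
  structure(list(image = img, truth = truth, fov = fov, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("fundus phantom: %dx%d %s, %d vessel segment(s), %.1f%% vessel pixels\n",
              d[1], d[2], if (length(d) == 3) "color" else "grayscale",
              nrow(x$spec$vessels), 100 * mean(x$truth)))
  invisible(x)
}

#' Random phantom specification at DRIVE-like conditions
#'
#' Draws a set of straight vessel chords through the FOV with widths spanning
#' 1-6 px (the caliber range of retinal vessels at DRIVE resolution), a smooth
#' illumination gradient and noise, reproducibly from a seed. Contrast depth
#' scales with the square root of caliber (`0.28-0.35` for the widest
#' vessels): a vessel narrower than the imaging point-spread width loses peak
#' contrast to partial-volume averaging, so the finest capillaries are also
#' the faintest — the regime in which multilevel thresholding earns its keep.
#'
#' @param height,width Image dimensions (defaults: DRIVE-like 565 x 585).
#' @param n_vessels Number of vessel segments.
#' @param noise_sigma Additive noise standard deviation.
#' @param illumination_amplitude Illumination field amplitude.
#' @param seed Integer seed (drives both layout and rendering noise).
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(height = 565L, width = 585L, n_vessels = 10L,
                                noise_sigma = 0.02,
                                illumination_amplitude = 0.12,
                                seed = 1L) {
  with_seed(seed, {
    ctr_r <- (height + 1) / 2; ctr_c <- (width + 1) / 2
    radius <- 0.92 * min(height, width) / 2
    widths <- rep_len(1:6, n_vessels)[sample.int(n_vessels)]
    segs <- lapply(seq_len(n_vessels), function(i) {
      phi <- stats::runif(1, 0, pi)           # chord direction
      off <- stats::runif(1, -0.55, 0.55) * radius  # perpendicular offset
      half <- 0.85 * sqrt(max(radius^2 - off^2, 1)) # stay inside the FOV
      pr <- ctr_r + off * cos(phi + pi / 2); pc <- ctr_c + off * sin(phi + pi / 2)
      data.frame(r0 = pr - half * cos(phi), c0 = pc - half * sin(phi),
                 r1 = pr + half * cos(phi), c1 = pc + half * sin(phi),
                 width = widths[i],
                 depth = stats::runif(1, 0.28, 0.35) * sqrt(widths[i] / 6))
    })
    phantom_spec(height, width, vessels = do.call(rbind, segs),
                 noise_sigma = noise_sigma,
                 illumination_amplitude = illumination_amplitude,
                 seed = as.integer(seed))
  })
}

#' Mixture-of-Gaussians gray-level histogram fixture
#'
#' Builds a normalized histogram with `n_modes` well-separated Gaussian modes
#' over `n_levels` gray levels — a controlled input for the multilevel Otsu
#' objective and its optimizers. Mode centers are evenly spaced with a small
#' seeded jitter; mode widths scale with the level range.
#'
#' @param n_modes Number of modes, between 1 and 6.
#' @param seed Integer seed.
#' @param n_levels Number of gray levels (default 256).
#' @return A [gray_histogram()] whose probabilities sum to 1.
#' @export
generate_histogram_fixture <- function(n_modes, seed = 1L, n_levels = 256L) {
  if (!is.numeric(n_modes) || n_modes < 1 || n_modes > 6)
    stop("n_modes must be between 1 and 6", call. = FALSE)
  n_modes <- as.integer(n_modes); n_levels <- as.integer(n_levels)
  with_seed(seed, {
    centers <- (seq_len(n_modes) - 0.5) / n_modes * (n_levels - 1) +
      stats::runif(n_modes, -0.02, 0.02) * n_levels
    sds <- stats::runif(n_modes, 0.020, 0.032) * n_levels
    wts <- stats::runif(n_modes, 0.6, 1.4); wts <- wts / sum(wts)
    lv <- 0:(n_levels - 1)
    p <- numeric(n_levels)
    for (k in seq_len(n_modes))
      p <- p + wts[k] * stats::dnorm(lv, centers[k], sds[k])
    gray_histogram(p / sum(p))
  })
}
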