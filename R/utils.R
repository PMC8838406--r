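#' @keywords internal
"_PACKAGE"

## Internal numerics shared across modules: reflective padding, FFT
## convolution with controlled boundary semantics, and seeded evaluation
## that does not disturb the caller's RNG stream.

#' Reflect an index vector into 1..n (half-sample symmetric reflection)
#' @noRd
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # triangular wave with period 2n mapping Z -> 1..n, edges repeated
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' Pad a matrix by symmetric (reflective) boundary extension
#' @noRd
pad_reflect <- function(x, py, px = py) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- reflect_index(seq.int(1L - py, nr + py), nr)
  ci <- reflect_index(seq.int(1L - px, nc + px), nc)
  x[ri, ci, drop = FALSE]
}

#' 2-D convolution with reflective padding
#'
#' Convolves `x` with kernel `k` (odd dimensions) using FFT convolution on a
#' reflect-padded copy so every stage of the pipeline shares the same boundary
#' semantics. Kernels used in this package are centrosymmetric, so convolution
#' and correlation coincide.
#' @noRd
conv2_reflect <- function(x, k) {
  stopifnot(nrow(k) %% 2L == 1L, ncol(k) %% 2L == 1L)
  py <- (nrow(k) - 1L) %/% 2L
  px <- (ncol(k) - 1L) %/% 2L
  if (py == 0L && px == 0L) return(x * k[1L, 1L])
  xp <- pad_reflect(x, py, px)
  out <- EBImage::filter2(xp, k, boundary = "circular")
  out[seq.int(py + 1L, py + nrow(x)), seq.int(px + 1L, px + ncol(x)), drop = FALSE]
}

#' Normalized isotropic Gaussian kernel, truncation radius capped by limit
#' @noRd
gaussian_kernel <- function(sigma, radius_limit = Inf) {
  r <- min(ceiling(3 * sigma), floor(radius_limit))
  r <- max(r, 1L)
  g1 <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Evaluate an expression under a temporary RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage seed from the pipeline seed (kept below 2^31)
#' @noRd
fanout_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + stage * 16807) %% 2147483647)
}

#' Min-max rescale a matrix to [0, 1]; a constant matrix maps to all zeros
#' @noRd
rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else x * 0
}

is_binary <- function(x) all(x %in% c(0, 1))

stop_if_dim_mismatch <- function(a, b, what = "images") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("%s must share dimensions (%s vs %s)", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Structuring element: binary disc of given radius (odd square for radius 0)
#' @noRd
disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}
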