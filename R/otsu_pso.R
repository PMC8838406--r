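## Multilevel Otsu thresholding and its particle swarm optimizer.
## The between-class variance objective sigma_B^2 = sum_k w_k (u_k - u_T)^2
## over the m+1 classes induced by an ordered threshold tuple is maximized
## either exhaustively (single threshold) or by PSO (m >= 2), where an
## exhaustive scan over all ordered tuples would be too expensive at
## image-processing time.

#' Gray-level histogram
#'
#' @param p Probability vector over gray levels (non-negative, sums to 1
#'   within 1e-8; renormalized exactly).
#' @param counts Optional integer counts the probabilities derive from.
#' @return Object of class `gray_histogram` with fields `p`, `counts`,
#'   `n_levels`.
#' @export
gray_histogram <- function(p, counts = NULL) {
  if (any(p < 0) || !all(is.finite(p)))
    stop("histogram probabilities must be finite and >= 0", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("histogram probabilities must sum to 1", call. = FALSE)
  structure(list(p = p / s, counts = counts, n_levels = length(p)),
            class = "gray_histogram")
}

#' 256-level histogram of a unit-range image
#'
#' Quantizes values in `[0, 1]` to integer levels `floor(v * (n_levels - 1))`
#' and tabulates them, optionally restricted to a mask (e.g. the camera field
#' of view, so the black surround does not dominate the lowest class).
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param mask Optional 0/1 matrix; only pixels with `mask == 1` are counted.
#' @param n_levels Number of gray levels (default 256).
#' @return A [gray_histogram()].
#' @export
histogram256 <- function(image, mask = NULL, n_levels = 256L) {
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  v <- if (!is.null(mask)) {
    stop_if_dim_mismatch(image, mask, "image and mask")
    image[mask == 1]
  } else as.vector(image)
  if (length(v) == 0) stop("empty mask: no pixels to histogram", call. = FALSE)
  lev <- pmin(floor(v * (n_levels - 1) + 1e-12), n_levels - 1L)
  counts <- tabulate(lev + 1L, nbins = n_levels)
  gray_histogram(counts / sum(counts), counts = counts)
}

# cumulative zeroth/first moments: P[t+1] = sum_{i<=t} p_i, S[t+1] = sum i p_i
hist_cumulants <- function(hist) {
  p <- hist$p
  lv <- seq_along(p) - 1
  list(P = cumsum(p), S = cumsum(lv * p), uT = sum(lv * p))
}

validate_thresholds <- function(thresholds, n_levels) {
  t <- as.integer(round(thresholds))
  if (length(t) < 1L) stop("need at least one threshold", call. = FALSE)
  if (any(t < 0L) || any(t > n_levels - 2L))
    stop(sprintf("thresholds must lie in [0, %d]", n_levels - 2L), call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0L))
    stop("thresholds must be strictly increasing", call. = FALSE)
  t
}

#' Between-class variance of a threshold combination
#'
#' For ordered thresholds `(t1 < ... < tm)`, class `k` holds levels
#' `t_k < i <= t_{k+1}` (with `t_0 = -1`, `t_{m+1} = L-1`). Returns
#' `sigma_B^2 = sum_k w_k (u_k - u_T)^2` with class probabilities `w_k`, class
#' means `u_k`, and total mean `u_T`; empty classes contribute 0.
#'
#' @param hist A [gray_histogram()].
#' @param thresholds Strictly increasing integer gray levels in
#'   `[0, n_levels - 2]`.
#' @return Scalar between-class variance.
#' @export
between_class_variance <- function(hist, thresholds) {
  stopifnot(inherits(hist, "gray_histogram"))
  t <- validate_thresholds(thresholds, hist$n_levels)
  cm <- hist_cumulants(hist)
  bounds <- c(0L, t + 1L, hist$n_levels)   # indices into P/S, class k = [bounds[k], bounds[k+1])
  P <- c(0, cm$P); S <- c(0, cm$S)
  w <- P[bounds[-1] + 1L] - P[bounds[-length(bounds)] + 1L]
  su <- S[bounds[-1] + 1L] - S[bounds[-length(bounds)] + 1L]
  u <- ifelse(w > 0, su / w, 0)
  sum(ifelse(w > 0, w * (u - cm$uT)^2, 0))
}

# vectorized objective for a matrix of ordered integer threshold tuples
# (rows = candidates); used by the PSO fitness loop
bcv_batch <- function(cm, n_levels, T) {
  m <- ncol(T)
  P <- c(0, cm$P); S <- c(0, cm$S)
  B <- cbind(0L, T + 1L, n_levels)
  tot <- numeric(nrow(T))
  for (k in seq_len(m + 1L)) {
    w <- P[B[, k + 1L] + 1L] - P[B[, k] + 1L]
    su <- S[B[, k + 1L] + 1L] - S[B[, k] + 1L]
    u <- ifelse(w > 0, su / w, 0)
    tot <- tot + ifelse(w > 0, w * (u - cm$uT)^2, 0)
  }
  tot
}

#' Single-threshold Otsu by exhaustive scan
#'
#' Scans every threshold `t` in `[0, n_levels - 2]` and returns the argmax of
#' the between-class variance; ties resolve to the smallest `t`.
#'
#' @param hist A [gray_histogram()] with at least two occupied bins.
#' @return Integer threshold, with attribute `fitness` (the attained
#'   between-class variance).
#' @export
otsu_single <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (sum(hist$p > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied bins", call. = FALSE)
  cm <- hist_cumulants(hist)
  L <- hist$n_levels
  ts <- 0:(L - 2L)
  w0 <- cm$P[ts + 1L]; s0 <- cm$S[ts + 1L]
  w1 <- 1 - w0; s1 <- cm$uT - s0
  u0 <- ifelse(w0 > 0, s0 / w0, 0); u1 <- ifelse(w1 > 0, s1 / w1, 0)
  f <- ifelse(w0 > 0, w0 * (u0 - cm$uT)^2, 0) +
       ifelse(w1 > 0, w1 * (u1 - cm$uT)^2, 0)
  best <- which.max(f)   # which.max returns the first (smallest t) maximum
  structure(ts[best], fitness = f[best])
}

#' PSO configuration
#'
#' Defaults follow the standard swarm settings for this problem: population
#' `N = 40`, inertia `w = 0.5`, acceleration constants `c1 = c2 = 2`,
#' `M = 20` iterations.
#'
#' @param population Number of particles.
#' @param inertia Inertia weight `w`.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param iterations Number of update iterations `M`.
#' @param velocity_clamp Velocity limit as a fraction of the search range.
#' @param seed Integer seed for the swarm's RNG (required for reproducibility
#'   when used via [otsu_pso()]).
#' @return Object of class `pso_config`.
#' @export
pso_config <- function(population = 40L, inertia = 0.5, c1 = 2, c2 = 2,
                       iterations = 20L, velocity_clamp = 0.2, seed = NULL) {
  stopifnot(population >= 1, iterations >= 0, velocity_clamp > 0)
  structure(list(population = as.integer(population), inertia = inertia,
                 c1 = c1, c2 = c2, iterations = as.integer(iterations),
                 velocity_clamp = velocity_clamp,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pso_config")
}

# Repair a continuous position into a strictly ordered integer tuple in
# [0, upper]: round, clamp, sort, bump duplicates upward (+1), and if the top
# overflows, cascade downward. Feasible whenever m <= upper + 1.
repair_position <- function(x, upper) {
  v <- sort(pmin(pmax(round(x), 0), upper))
  m <- length(v)
  if (m > 1L) for (j in 2:m) if (v[j] <= v[j - 1L]) v[j] <- v[j - 1L] + 1L
  if (v[m] > upper) {
    v[m] <- upper
    if (m > 1L) for (j in (m - 1L):1L) if (v[j] >= v[j + 1L]) v[j] <- v[j + 1L] - 1L
  }
  as.integer(v)
}

# fresh uniform draws in the fixed order r1-then-r2, particle-major,
# dimension-minor: draw index ((i-1)*D + (d-1))*2 + {1,2}
draw_r1r2 <- function(N, D) {
  u <- stats::runif(2L * N * D)
  a <- array(u, dim = c(2L, D, N))
  list(r1 = t(matrix(a[1L, , ], D, N)), r2 = t(matrix(a[2L, , ], D, N)))
}

#' One PSO update step
#'
#' Velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' fresh per-particle, per-dimension uniform draws `r1, r2`; velocities are
#' clamped to `+/- velocity_clamp * range`; positions move by `x <- x + v` and
#' are reflected back into `[0, upper]`; fitness is evaluated on the repaired
#' (rounded, sorted, de-duplicated) integer projection; personal and global
#' bests are updated on strict improvement. Consumes the caller's RNG stream.
#'
#' @param state Swarm state as produced by [init_swarm()] or a previous
#'   `pso_step()`.
#' @param config A [pso_config()].
#' @param fitness Function mapping an ordered integer tuple to a scalar to be
#'   maximized.
#' @return Updated swarm state.
#' @export
pso_step <- function(state, config, fitness) {
  N <- nrow(state$X); D <- ncol(state$X)
  upper <- state$upper
  r <- draw_r1r2(N, D)
  V <- config$inertia * state$V +
    config$c1 * r$r1 * (state$Pb - state$X) +
    config$c2 * r$r2 * (matrix(state$gbest, N, D, byrow = TRUE) - state$X)
  vmax <- config$velocity_clamp * upper
  V <- pmin(pmax(V, -vmax), vmax)
  X <- state$X + V
  # reflect into [0, upper]: triangular fold with period 2*upper
  X <- upper - abs(upper - abs(X) %% (2 * upper))
  for (i in seq_len(N)) {
    xi <- repair_position(X[i, ], upper)
    fi <- fitness(xi)
    if (fi > state$pb_fit[i]) {
      state$pb_fit[i] <- fi
      state$Pb[i, ] <- X[i, ]
      state$pb_repaired[i, ] <- xi
      if (fi > state$gbest_fit) {
        state$gbest_fit <- fi
        state$gbest <- X[i, ]
        state$gbest_repaired <- xi
      }
    }
  }
  state$X <- X; state$V <- V
  state$iteration <- state$iteration + 1L
  state
}

#' Initialize a random swarm
#'
#' Positions uniform in `[0, upper]^D`, velocities uniform within the clamp,
#' personal bests at the initial positions, global best at the best particle.
#' Consumes the caller's RNG stream (seed management belongs to [otsu_pso()]).
#'
#' @param config A [pso_config()].
#' @param D Search dimension (number of thresholds).
#' @param upper Upper bound of each coordinate (`n_levels - 2`).
#' @param fitness Objective over ordered integer tuples.
#' @return Swarm state list.
#' @export
init_swarm <- function(config, D, upper, fitness) {
  N <- config$population
  u <- stats::runif(N * D, 0, upper)
  X <- matrix(u, N, D, byrow = TRUE)    # particle-major, dimension-minor
  vmax <- config$velocity_clamp * upper
  V <- matrix(stats::runif(N * D, -vmax, vmax), N, D, byrow = TRUE)
  pb_fit <- numeric(N)
  pb_repaired <- matrix(0L, N, D)
  for (i in seq_len(N)) {
    xi <- repair_position(X[i, ], upper)
    pb_repaired[i, ] <- xi
    pb_fit[i] <- fitness(xi)
  }
  g <- which.max(pb_fit)
  list(X = X, V = V, Pb = X, pb_fit = pb_fit, pb_repaired = pb_repaired,
       gbest = X[g, ], gbest_fit = pb_fit[g], gbest_repaired = pb_repaired[g, ],
       upper = upper, iteration = 0L)
}

#' Multilevel Otsu thresholds by particle swarm optimization
#'
#' Maximizes the m-threshold between-class variance over ordered integer
#' tuples: initialize a random swarm, evaluate fitness, update by the PSO
#' velocity/position rules, iterate `M` times, and return the repaired global
#' best. Deterministic for a fixed `config$seed`.
#'
#' @param hist A [gray_histogram()].
#' @param m Number of thresholds (default 3).
#' @param config A [pso_config()]; its `seed` drives all randomness.
#' @return Integer vector of `m` strictly increasing thresholds with
#'   attributes `fitness` (attained between-class variance) and `trace`
#'   (global-best fitness per iteration).
#' @export
otsu_pso <- function(hist, m = 3L, config = pso_config(seed = 1L)) {
  stopifnot(inherits(hist, "gray_histogram"), inherits(config, "pso_config"))
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  occ <- sum(hist$p > 0)
  if (m >= occ)
    stop(sprintf("infeasible: %d thresholds need more than %d occupied bins",
                 m, occ), call. = FALSE)
  upper <- hist$n_levels - 2L
  if (m > upper + 1L) stop("m too large for the gray-level range", call. = FALSE)
  cm <- hist_cumulants(hist)
  fitness <- function(t) bcv_batch(cm, hist$n_levels, matrix(t, 1L))
  with_seed(config$seed, {
    state <- init_swarm(config, m, upper, fitness)
    trace <- numeric(config$iterations)
    for (k in seq_len(config$iterations)) {
      state <- pso_step(state, config, fitness)
      trace[k] <- state$gbest_fit
    }
    structure(state$gbest_repaired, fitness = state$gbest_fit, trace = trace)
  })
}

#' Apply a threshold combination to an image
#'
#' Quantizes the image to gray levels and assigns each pixel the class `k`
#' with `t_k < level <= t_{k+1}` (`t_0 = -Inf`, `t_{m+1} = Inf`). The rendered
#' image places the `m + 1` classes at equally spaced gray levels in `[0, 1]`
#' (for `m = 3`: 0, 1/3, 2/3, 1, i.e. levels 0/85/170/255), preserving class
#' order for the subsequent single-threshold re-binarization.
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param thresholds Strictly increasing integer gray levels.
#' @param n_levels Quantization levels (default 256).
#' @return List of class `threshold_map`: `labels` (integer matrix, classes
#'   `0..m`) and `rendered` (gray image in `[0, 1]`).
#' @export
apply_thresholds <- function(image, thresholds, n_levels = 256L) {
  t <- validate_thresholds(thresholds, n_levels)
  lev <- pmin(floor(image * (n_levels - 1) + 1e-12), n_levels - 1L)
  lab <- matrix(findInterval(lev, t + 0.5), nrow(image), ncol(image))
  m <- length(t)
  rendered <- lab / m
  structure(list(labels = lab, rendered = rendered, thresholds = t),
            class = "threshold_map")
}
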