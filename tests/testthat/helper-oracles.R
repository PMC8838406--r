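# Independent oracles: brute-force / closed-form implementations kept separate
# from the package's computational paths.

# symmetric (edge-inclusive) reflected index, built from an explicit mirror
oracle_reflect <- function(i, n) {
  mirror <- c(seq_len(n), rev(seq_len(n)))
  mirror[((i - 1) %% (2 * n)) + 1]
}

# dense O(n^2 m^2) convolution with reflective boundary
oracle_conv <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(k) - 1) / 2; kc <- (ncol(k) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      ii <- oracle_reflect(i + a, nr); jj <- oracle_reflect(j + b, nc)
      acc <- acc + img[ii, jj] * k[kr + 1 + a, kc + 1 + b]
    }
    out[i, j] <- acc
  }
  out
}

# brute-force single-threshold Otsu: double loop straight from the class
# probability / class mean definitions
oracle_otsu_single <- function(p) {
  L <- length(p)
  lv <- 0:(L - 1)
  uT <- sum(lv * p)
  best_f <- -Inf; best_t <- NA
  for (t in 0:(L - 2)) {
    w0 <- 0; s0 <- 0
    for (i in 0:t) { w0 <- w0 + p[i + 1]; s0 <- s0 + i * p[i + 1] }
    w1 <- 1 - w0; s1 <- uT - s0
    f <- 0
    if (w0 > 0) f <- f + w0 * (s0 / w0 - uT)^2
    if (w1 > 0) f <- f + w1 * (s1 / w1 - uT)^2
    if (f > best_f + 1e-15) { best_f <- f; best_t <- t }
  }
  list(t = best_t, fitness = best_f)
}

# class probabilities and means for an ordered threshold tuple (definitional)
oracle_class_stats <- function(p, thresholds) {
  L <- length(p); lv <- 0:(L - 1)
  bounds <- c(-1, thresholds, L - 1)
  w <- numeric(length(thresholds) + 1); u <- w
  for (k in seq_along(w)) {
    sel <- lv > bounds[k] & lv <= bounds[k + 1]
    w[k] <- sum(p[sel])
    u[k] <- if (w[k] > 0) sum(lv[sel] * p[sel]) / w[k] else 0
  }
  list(w = w, u = u, uT = sum(lv * p))
}

oracle_bcv <- function(p, thresholds) {
  cs <- oracle_class_stats(p, thresholds)
  sum(ifelse(cs$w > 0, cs$w * (cs$u - cs$uT)^2, 0))
}

# exhaustive search over all ordered triples (t3 vectorized for speed; the
# objective itself comes from the definitional cumulative moments)
oracle_exhaustive3 <- function(p) {
  L <- length(p); lv <- 0:(L - 1)
  P <- cumsum(p); S <- cumsum(lv * p); uT <- S[L]
  seg <- function(wa, sa) ifelse(wa > 0, wa * (sa / wa - uT)^2, 0)
  best <- -Inf; bt <- NULL
  for (t1 in 0:(L - 4)) {
    w0 <- P[t1 + 1]; s0 <- S[t1 + 1]
    f0 <- seg(w0, s0)
    for (t2 in (t1 + 1):(L - 3)) {
      w1 <- P[t2 + 1] - P[t1 + 1]; s1 <- S[t2 + 1] - S[t1 + 1]
      t3 <- (t2 + 1):(L - 2)
      w2 <- P[t3 + 1] - P[t2 + 1]; s2 <- S[t3 + 1] - S[t2 + 1]
      w3 <- 1 - P[t3 + 1]; s3 <- uT - S[t3 + 1]
      f <- f0 + seg(w1, s1) + seg(w2, s2) + seg(w3, s3)
      i <- which.max(f)
      if (f[i] > best) { best <- f[i]; bt <- c(t1, t2, t3[i]) }
    }
  }
  list(fit = best, t = bt)
}

# sliding-window median with reflective boundary
oracle_median <- function(img, k) {
  r <- (k - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(0)
    for (a in -r:r) for (b in -r:r)
      vals <- c(vals, img[oracle_reflect(i + a, nr), oracle_reflect(j + b, nc)])
    out[i, j] <- stats::median(vals)
  }
  out
}

# flood-fill 8-connected component areas (small images only)
oracle_component_areas <- function(img) {
  lab <- matrix(0L, nrow(img), ncol(img))
  nxt <- 0L
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (img[i, j] == 1 && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        q <- queue[[1]]; queue <- queue[-1]
        for (a in -1:1) for (b in -1:1) {
          ii <- q[1] + a; jj <- q[2] + b
          if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img) &&
              img[ii, jj] == 1 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  if (nxt == 0L) integer(0) else tabulate(lab[lab > 0L])
}

# enumeration of the matched-filter support rule on the integer grid:
# in-support iff |u| <= 3 sigma and |v| <= L/2 after rotation
oracle_kernel_support <- function(sigma, L, theta_deg, Rr, Rc = Rr) {
  th <- theta_deg * pi / 180
  sup <- matrix(FALSE, 2 * Rr + 1, 2 * Rc + 1)
  for (y in -Rr:Rr) for (x in -Rc:Rc) {
    u <- cos(th) * x - sin(th) * y
    v <- sin(th) * x + cos(th) * y
    if (abs(u) <= 3 * sigma && abs(v) <= L / 2)
      sup[y + Rr + 1, x + Rc + 1] <- TRUE
  }
  sup
}

# straight Gaussian-profile vessel image built directly from the closed form
oracle_vessel_image <- function(n, theta_deg, width, depth, background = 0.8) {
  th <- theta_deg * pi / 180
  sigma_v <- width / 2.355
  ctr <- (n + 1) / 2
  img <- matrix(background, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    # signed distance from pixel to the line through the center with
    # direction (sin th, cos th) in (column, row) coordinates
    d <- cos(th) * (j - ctr) - sin(th) * (i - ctr)
    img[i, j] <- background - depth * exp(-d^2 / (2 * sigma_v^2))
  }
  img
}

random_histogram <- function(seed, n_levels = 256) {
  set.seed(seed)
  p <- stats::runif(n_levels)^3
  gray_histogram(p / sum(p))
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90ccw <- function(m) t(m)[nrow(t(m)):1, , drop = FALSE]
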