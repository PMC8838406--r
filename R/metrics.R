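## Segmentation evaluation: pixel-wise confusion counts and the derived
## accuracy / sensitivity / specificity, plus two structure-aware scores that
## do not assume pixel independence: SSIM (local luminance/contrast/structure
## comparison) and the S-measure (object-aware + region-aware similarity of a
## foreground map against binary ground truth).

#' Pixel-wise confusion counts
#'
#' @param pred Binary predicted vessel map.
#' @param truth Binary ground-truth vessel map.
#' @param fov Optional binary mask; only pixels with `fov == 1` are counted.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(pred, truth, fov = NULL) {
  stop_if_dim_mismatch(pred, truth, "pred and truth")
  if (!is_binary(pred) || !is_binary(truth))
    stop("pred and truth must be binary", call. = FALSE)
  if (!is.null(fov)) {
    stop_if_dim_mismatch(pred, fov, "pred and fov")
    sel <- fov == 1
    pred <- pred[sel]; truth <- truth[sel]
  }
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 TN = sum(pred == 0 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`, `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`.
#' A metric whose denominator is zero is undefined and reported as `NA`.
#'
#' @param c A [confusion()] result.
#' @return Named list `acc`, `se`, `sp` (each in `[0, 1]` or `NA`).
#' @export
acc_se_sp <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$FP + c$TN + c$FN
  if (total == 0) stop("no evaluated pixels", call. = FALSE)
  list(acc = (c$TP + c$TN) / total,
       se = if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_,
       sp = if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the reference formulation's defaults: 11x11 Gaussian
#' window with standard deviation 1.5 and stabilizers `C1 = (0.01 R)^2`,
#' `C2 = (0.03 R)^2` for dynamic range `R`. When `fov` is supplied, both
#' inputs are masked (set to 0 outside) before comparison, so FOV-restricted
#' SSIM equals SSIM of pre-masked inputs by construction.
#'
#' @param a,b Matrices of equal dimensions, values in `[0, data_range]`.
#' @param data_range Dynamic range `R` (default 1).
#' @param fov Optional binary mask applied to both inputs.
#' @return Scalar in `[-1, 1]`; `ssim(x, x) = 1`.
#' @export
ssim <- function(a, b, data_range = 1, fov = NULL) {
  stop_if_dim_mismatch(a, b, "ssim inputs")
  if (!is.null(fov)) {
    stop_if_dim_mismatch(a, fov, "ssim input and fov")
    a <- a * fov; b <- b * fov
  }
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  g1 <- exp(-(seq.int(-5, 5))^2 / (2 * 1.5^2))
  w <- outer(g1, g1); w <- w / sum(w)
  mu_a <- conv2_reflect(a, w); mu_b <- conv2_reflect(b, w)
  va <- conv2_reflect(a * a, w) - mu_a^2
  vb <- conv2_reflect(b * b, w) - mu_b^2
  vab <- conv2_reflect(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * vab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (va + vb + C2)
  mean(num / den)
}

# object-level similarity of a (masked) prediction against a region:
# 2 xbar / (xbar^2 + 1 + sd(x)), over the region's pixels
s_object_score <- function(x) {
  if (length(x) == 0) return(0)
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else 0
  2 * m / (m^2 + 1 + s + .Machine$double.eps)
}

# region-level SSIM-like score on one quadrant
s_region_score <- function(pred, gt) {
  n <- length(pred)
  if (n == 0) return(1)
  x <- mean(pred); y <- mean(gt)
  if (n == 1) { sx2 <- 0; sy2 <- 0; sxy <- 0 } else {
    sx2 <- stats::var(as.vector(pred)); sy2 <- stats::var(as.vector(gt))
    sxy <- stats::cov(as.vector(pred), as.vector(gt))
  }
  num <- 4 * x * y * sxy
  den <- (x^2 + y^2) * (sx2 + sy2)
  if (num != 0) num / (den + .Machine$double.eps)
  else if (den == 0) 1 else 0
}

#' Structure measure (S-measure) of a foreground map
#'
#' `S = alpha * S_object + (1 - alpha) * S_region` with `alpha = 0.5`.
#' `S_object` compares the prediction inside the ground-truth foreground and
#' its complement inside the background, weighted by foreground prevalence.
#' `S_region` splits both maps into four quadrants about the ground-truth
#' centroid and averages an SSIM-like score weighted by quadrant area.
#' Degenerate ground truth (all background / all foreground) falls back to
#' `1 - mean(pred)` / `mean(pred)` respectively.
#'
#' @param pred Prediction map with values in `[0, 1]`.
#' @param truth Binary ground-truth map.
#' @param alpha Object/region balance (default 0.5).
#' @return Scalar in `[0, 1]`; `s_measure(truth, truth) = 1` up to machine
#'   stabilizers.
#' @export
s_measure <- function(pred, truth, alpha = 0.5) {
  stop_if_dim_mismatch(pred, truth, "pred and truth")
  if (!is_binary(truth)) stop("truth must be binary", call. = FALSE)
  if (min(pred) < 0 || max(pred) > 1)
    stop("pred values must lie in [0, 1]", call. = FALSE)
  y <- mean(truth)
  if (y == 0) return(1 - mean(pred))
  if (y == 1) return(mean(pred))

  # object-aware term
  o_fg <- s_object_score(pred[truth == 1])
  o_bg <- s_object_score((1 - pred)[truth == 0])
  s_obj <- y * o_fg + (1 - y) * o_bg

  # region-aware term: quadrants about the truth centroid
  nr <- nrow(truth); nc <- ncol(truth)
  rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cr <- round(sum(rr * truth) / sum(truth)); ccol <- round(sum(cc * truth) / sum(truth))
  cr <- min(max(cr, 1L), nr); ccol <- min(max(ccol, 1L), nc)
  qr <- list(seq_len(cr), if (cr < nr) seq.int(cr + 1L, nr) else integer(0))
  qc <- list(seq_len(ccol), if (ccol < nc) seq.int(ccol + 1L, nc) else integer(0))
  s_reg <- 0
  for (i in 1:2) for (j in 1:2) {
    p <- pred[qr[[i]], qc[[j]], drop = FALSE]
    g <- truth[qr[[i]], qc[[j]], drop = FALSE]
    wq <- length(g) / (nr * nc)
    if (wq > 0) s_reg <- s_reg + wq * s_region_score(p, g)
  }
  max(alpha * s_obj + (1 - alpha) * s_reg, 0)
}

#' Full metrics report for one segmentation
#'
#' @param pred Binary predicted vessel map.
#' @param truth Binary ground truth.
#' @param fov Optional FOV mask (restricts confusion counts and SSIM).
#' @return Object of class `metrics_report`: list with `acc`, `se`, `sp`,
#'   `ssim`, `s_measure` and the underlying `confusion`.
#' @export
metrics_report <- function(pred, truth, fov = NULL) {
  cc <- confusion(pred, truth, fov)
  r <- acc_se_sp(cc)
  structure(list(acc = r$acc, se = r$se, sp = r$sp,
                 ssim = ssim(pred, truth, fov = fov),
                 s_measure = s_measure(pred, truth),
                 confusion = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc=%.4f Se=%.4f Sp=%.4f SSIM=%.4f S-measure=%.4f\n",
              x$acc, x$se, x$sp, x$ssim, x$s_measure))
  invisible(x)
}
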