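## Morphological post-processing of the binary vessel map: median smoothing
## (reconnecting sub-window breaks and removing speckle), closing + small
## object removal, and deletion of the spurious responses the matched filter
## produces at the bright rim of the camera field of view.

#' Post-processing configuration
#'
#' @param median_kernel Odd median window size in pixels (>= 3).
#' @param min_object_area Connected components (8-connectivity) smaller than
#'   this area (strict `<`) are removed.
#' @param edge_dilation_radius Dilation radius (px, disc) applied to the FOV
#'   boundary ring before subtracting it from the vessel map.
#' @param closing_radius Disc radius of the morphological closing used to
#'   reconnect nearby fragments before small-object removal.
#' @return Object of class `postprocess_config`.
#' @export
postprocess_config <- function(median_kernel = 3L, min_object_area = 30L,
                               edge_dilation_radius = 3L, closing_radius = 1L) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 3L || median_kernel %% 2L == 0L)
    stop("median_kernel must be odd and >= 3", call. = FALSE)
  if (min_object_area < 0) stop("min_object_area must be >= 0", call. = FALSE)
  structure(list(median_kernel = median_kernel,
                 min_object_area = as.integer(min_object_area),
                 edge_dilation_radius = as.integer(edge_dilation_radius),
                 closing_radius = as.integer(closing_radius)),
            class = "postprocess_config")
}

#' Median filter with reflective boundary
#'
#' For binary input the median over an odd window is the majority vote,
#' computed exactly by box convolution; grayscale input is median-filtered
#' on a reflect-padded copy so the boundary semantics match the rest of the
#' pipeline.
#'
#' @param image Binary (0/1) or grayscale (`[0,1]`) matrix.
#' @param kernel Odd window size (default 3).
#' @return Filtered matrix of the same type.
#' @export
median_denoise <- function(image, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("median window must be odd", call. = FALSE)
  if (kernel == 1L) return(image)
  if (is_binary(image)) {
    ones <- matrix(1, kernel, kernel)
    counts <- conv2_reflect(image, ones)
    (counts > kernel^2 / 2) * 1
  } else {
    r <- (kernel - 1L) %/% 2L
    xp <- pad_reflect(image, r, r)
    out <- EBImage::medianFilter(xp, r)
    out[seq.int(r + 1L, r + nrow(image)), seq.int(r + 1L, r + ncol(image))]
  }
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that touch
# diagonally are merged through a components pass on the small label graph.
label8 <- function(image) {
  lab <- EBImage::bwlabel(image)
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # NW-SE diagonal neighbors
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # NE-SW diagonal neighbors
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  up <- unique(pairs)
  g <- igraph::graph_from_edgelist(matrix(as.character(up), ncol = 2L),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  remap <- seq_len(n)
  remap[as.integer(names(memb))] <- n + memb  # merge groups to fresh ids
  remap <- match(remap, sort(unique(remap)))  # compact ids
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Remove small connected components
#'
#' Deletes 8-connected components with area strictly below
#' `config$min_object_area`.
#'
#' @param image Binary (0/1) matrix.
#' @param config A [postprocess_config()].
#' @return Binary matrix (subset of the input's foreground).
#' @export
remove_small_objects <- function(image, config = postprocess_config()) {
  if (!is_binary(image)) stop("input must be binary", call. = FALSE)
  if (config$min_object_area <= 0L) return(image)
  lab <- label8(image)
  if (max(lab) == 0L) return(image)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= config$min_object_area)
  (matrix(lab %in% keep, nrow(image), ncol(image))) * 1
}

#' Extract the camera field-of-view mask from a fundus image
#'
#' Thresholds the red channel (or the grayscale intensity) with
#' single-threshold Otsu, keeps the largest connected component and fills its
#' holes. The red channel is used because the FOV interior is uniformly bright
#' in it, giving the cleanest disc/surround separation.
#'
#' @param source Color array or grayscale matrix in `[0, 1]`.
#' @return Binary FOV mask (1 = inside the field of view).
#' @export
build_fov_mask <- function(source) {
  gray <- if (length(dim(source)) == 3L) source[, , 1L] else source
  hist <- tryCatch(histogram256(gray),
                   error = function(e) stop("mask extraction failed: ", conditionMessage(e),
                                            call. = FALSE))
  if (sum(hist$p > 0) < 2L)
    stop("mask extraction failed: image has no foreground/background contrast",
         call. = FALSE)
  t <- otsu_single(hist)
  lev <- pmin(floor(gray * 255 + 1e-12), 255)
  fg <- (lev > t) * 1
  if (sum(fg) == 0) stop("mask extraction failed: empty foreground", call. = FALSE)
  lab <- label8(fg)
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  mask <- (lab == biggest) * 1
  as.matrix(EBImage::fillHull(mask)) * 1
}

#' Remove false detections at the field-of-view rim
#'
#' The FOV boundary ring (mask minus its erosion) is dilated by
#' `edge_dilation_radius` and subtracted from the vessel map: any vessel pixel
#' inside the dilated ring is deleted. The ring construction is equivalent, on
#' a sharp-edged FOV, to Otsu-binarizing the difference between the source
#' image and its mask.
#'
#' @param vessels Binary vessel map.
#' @param source Source image from which to extract the FOV (ignored when
#'   `fov` is given).
#' @param config A [postprocess_config()].
#' @param fov Optional precomputed binary FOV mask (bypasses extraction).
#' @return Binary matrix (subset of the input's foreground).
#' @export
remove_fov_edge <- function(vessels, source = NULL,
                            config = postprocess_config(), fov = NULL) {
  if (is.null(fov)) {
    if (is.null(source)) stop("need either source or fov", call. = FALSE)
    stop_if_dim_mismatch(vessels, source, "vessels and source")
    fov <- build_fov_mask(source)
  }
  stop_if_dim_mismatch(vessels, fov, "vessels and fov")
  eroded <- as.matrix(EBImage::erode(fov, disc_brush(1)))
  ring <- pmax(fov - eroded, 0)
  if (config$edge_dilation_radius > 0)
    ring <- as.matrix(EBImage::dilate(ring, disc_brush(config$edge_dilation_radius)))
  vessels * (1 - ring)
}

#' Full post-processing chain
#'
#' Median smoothing, morphological closing, small-object removal, and
#' FOV-rim artifact removal, in that order, restricted to the FOV. A second
#' majority vote follows the closing: the closing adds pixels at concavities
#' that a majority vote disagrees with, and absorbing them immediately makes
#' the chain stable under re-application (a bare median-closing pair
#' oscillates). The chain is re-applied until it reaches its fixed point —
#' normally the second pass just confirms the first — so the cleaned map is
#' invariant under re-processing.
#'
#' @param vessels Binary vessel map from the thresholding stage.
#' @param source Source image (for FOV extraction when `fov` missing).
#' @param config A [postprocess_config()].
#' @param fov Optional precomputed FOV mask.
#' @param max_passes Safety cap on the number of stabilization passes.
#' @return Cleaned binary vessel map.
#' @export
postprocess <- function(vessels, source = NULL,
                        config = postprocess_config(), fov = NULL,
                        max_passes = 10L) {
  if (!is_binary(vessels)) stop("vessel map must be binary", call. = FALSE)
  if (is.null(fov) && !is.null(source)) fov <- build_fov_mask(source)
  pass <- function(x) {
    out <- median_denoise(x, config$median_kernel)
    if (config$closing_radius > 0) {
      out <- as.matrix(EBImage::closing(out, disc_brush(config$closing_radius))) * 1
      out <- median_denoise(out, config$median_kernel)
    }
    out <- remove_small_objects(out, config)
    if (!is.null(fov)) {
      out <- remove_fov_edge(out, config = config, fov = fov)
      out <- out * fov
    }
    out
  }
  out <- pass(vessels)
  for (i in seq_len(max_passes - 1L)) {
    nxt <- pass(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out
}
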