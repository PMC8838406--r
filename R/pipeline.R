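## End-to-end orchestration: MSR -> green channel -> multiscale matched
## filtering -> PSO-optimized three-threshold Otsu -> single-threshold
## re-binarization -> morphological post-processing.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with their published/standard
#' defaults: MSR scales (15, 80, 250) with uniform weights, matched-filter
#' scales (1.9, 0.5, 0.13) with L = 9 and 12 orientations, three Otsu
#' thresholds optimized by PSO (N = 40, w = 0.5, c1 = c2 = 2, M = 20), and
#' the post-processing sizes.
#'
#' @param msr An [msr_config()].
#' @param filter A [fusion_config()].
#' @param filter_length,n_orientations Matched-filter template length and
#'   orientation count.
#' @param n_thresholds Number of Otsu thresholds `m` (default 3; `1` gives
#'   the single-threshold ablation).
#' @param pso A [pso_config()] (its seed, if unset, is derived from `seed`).
#' @param post A [postprocess_config()].
#' @param seed Pipeline seed; per-stage seeds are derived from it so one
#'   integer reproduces the whole run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(msr = msr_config(),
                            filter = fusion_config(),
                            filter_length = 9,
                            n_orientations = 12L,
                            n_thresholds = 3L,
                            pso = pso_config(),
                            post = postprocess_config(),
                            seed = 1L) {
  stopifnot(inherits(msr, "msr_config"), inherits(filter, "fusion_config"),
            inherits(pso, "pso_config"), inherits(post, "postprocess_config"))
  structure(list(msr = msr, filter = filter, filter_length = filter_length,
                 n_orientations = as.integer(n_orientations),
                 n_thresholds = as.integer(n_thresholds), pso = pso,
                 post = post, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment retinal vessels in a fundus image
#'
#' Runs the full pipeline on a color fundus image (or a grayscale image, in
#' which case channel extraction is skipped): illumination correction,
#' green-channel extraction, multiscale matched filtering, three-threshold
#' Otsu segmentation optimized by PSO, single-threshold re-binarization of the
#' multilevel map, and morphological post-processing. Deterministic for a
#' fixed config and seed.
#'
#' @param image Color `h x w x 3` array or grayscale matrix, values `[0, 1]`.
#' @param config A [pipeline_config()].
#' @param fov Optional binary FOV mask; if `NULL` and the image has a dark
#'   surround it is extracted with [build_fov_mask()]; pass `fov = FALSE` to
#'   force whole-image processing.
#' @return Object of class `vessel_segmentation`: list with `mask` (binary
#'   vessel map), `fov`, `response` (fused filter map), `thresholds` (the
#'   PSO-optimized tuple), `binarization_threshold`, `provenance` (seed,
#'   config, per-stage timings).
#' @export
segment_image <- function(image, config = pipeline_config(), fov = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    timings[[name]] <<- now - t0
    t0 <<- now
  }

  enhanced <- msr(image, config$msr)
  gray <- if (length(dim(image)) == 3L) extract_green_channel(enhanced) else enhanced
  tick("preprocessing")

  if (is.null(fov)) {
    fov <- tryCatch(build_fov_mask(image), error = function(e) NULL)
  } else if (isFALSE(fov)) fov <- NULL
  if (is.null(fov)) fov <- matrix(1, nrow(gray), ncol(gray))
  tick("fov")

  response <- multiscale_response(gray, config$filter,
                                  length = config$filter_length,
                                  n_orientations = config$n_orientations)
  tick("filtering")

  pso_cfg <- config$pso
  if (is.null(pso_cfg$seed)) pso_cfg$seed <- fanout_seed(config$seed, 1L)
  hist <- histogram256(response, mask = fov)
  thresholds <- otsu_pso(hist, m = config$n_thresholds, config = pso_cfg)
  tmap <- apply_thresholds(response, thresholds)
  # re-binarize the multilevel rendering with single-threshold Otsu
  if (config$n_thresholds > 1L) {
    h2 <- histogram256(tmap$rendered, mask = fov)
    tbin <- otsu_single(h2)
  } else {
    tbin <- structure(0L, fitness = NA_real_)
  }
  lev <- pmin(floor(tmap$rendered * 255 + 1e-12), 255)
  binary <- (lev > as.integer(tbin)) * 1
  tick("thresholding")

  mask <- postprocess(binary, config = config$post, fov = fov)
  tick("postprocessing")

  structure(list(mask = mask, fov = fov, response = response,
                 thresholds = as.integer(thresholds),
                 binarization_threshold = as.integer(tbin),
                 provenance = list(seed = config$seed,
                                   pso_seed = pso_cfg$seed,
                                   n_thresholds = config$n_thresholds,
                                   pso_fitness = attr(thresholds, "fitness"),
                                   timings = timings)),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "vessel segmentation: %dx%d, %.2f%% vessel pixels, thresholds (%s), rebinarized at %d\n",
    nrow(x$mask), ncol(x$mask), 100 * mean(x$mask),
    paste(x$thresholds, collapse = ", "), x$binarization_threshold))
  invisible(x)
}

#' Discover a DRIVE/STARE-style dataset layout
#'
#' Looks for `images/`, ground truth in `1st_manual/` (or `labels/`,
#' `truth/`), and optional FOV masks in `mask/` (or `masks/`), pairing files
#' by shared numeric/stem prefix.
#'
#' @param dir Dataset root directory.
#' @return Data frame with columns `image`, `truth`, `mask` (NA if absent).
#' @export
discover_dataset <- function(dir) {
  pick_dir <- function(cands) {
    for (d in cands) if (dir.exists(file.path(dir, d))) return(file.path(dir, d))
    NULL
  }
  img_dir <- pick_dir(c("images", "image")); if (is.null(img_dir)) img_dir <- dir
  gt_dir <- pick_dir(c("1st_manual", "labels", "truth", "manual"))
  mask_dir <- pick_dir(c("mask", "masks", "fov"))
  exts <- "\\.(png|tif|tiff|ppm|pgm)$"
  imgs <- sort(list.files(img_dir, pattern = exts, full.names = TRUE))
  stem <- function(p) sub("[_.].*$", "", basename(p))
  find_match <- function(d, s) {
    if (is.null(d)) return(NA_character_)
    fs <- list.files(d, pattern = exts, full.names = TRUE)
    hit <- fs[vapply(fs, function(f) startsWith(basename(f), s), logical(1))]
    if (length(hit) >= 1) hit[1] else NA_character_
  }
  data.frame(image = imgs,
             truth = vapply(imgs, function(p) find_match(gt_dir, stem(p)), character(1)),
             mask = vapply(imgs, function(p) find_match(mask_dir, stem(p)), character(1)),
             row.names = NULL)
}

#' Segment and evaluate a batch of images
#'
#' Runs [segment_image()] on every image that has ground truth and tabulates
#' the per-image metrics plus a final mean row.
#'
#' @param dir Dataset directory in DRIVE/STARE-like layout (see
#'   [discover_dataset()]).
#' @param config A [pipeline_config()].
#' @return Data frame with columns `id`, `acc`, `se`, `sp`, `ssim`,
#'   `s_measure`; the last row (`id == "mean"`) holds the column means.
#' @export
evaluate_batch <- function(dir, config = pipeline_config()) {
  files <- discover_dataset(dir)
  rows <- list()
  for (i in seq_len(nrow(files))) {
    if (is.na(files$truth[i])) {
      warning("no ground truth for ", basename(files$image[i]), "; skipped")
      next
    }
    img <- read_image(files$image[i])
    truth <- (read_image(files$truth[i]) > 0.5) * 1
    if (length(dim(truth)) == 3L) truth <- truth[, , 1]
    fov <- if (!is.na(files$mask[i])) {
      m <- read_image(files$mask[i])
      if (length(dim(m)) == 3L) m <- m[, , 1]
      (m > 0.5) * 1
    } else NULL
    seg <- segment_image(img, config, fov = fov)
    rep <- metrics_report(seg$mask, truth, fov = seg$fov)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sub("\\.[^.]*$", "", basename(files$image[i])),
      acc = rep$acc, se = rep$se, sp = rep$sp,
      ssim = rep$ssim, s_measure = rep$s_measure)
  }
  if (length(rows) == 0) return(data.frame(id = character(0), acc = numeric(0),
                                           se = numeric(0), sp = numeric(0),
                                           ssim = numeric(0), s_measure = numeric(0)))
  out <- do.call(rbind, rows)
  mean_row <- data.frame(id = "mean", acc = mean(out$acc), se = mean(out$se),
                         sp = mean(out$sp), ssim = mean(out$ssim),
                         s_measure = mean(out$s_measure))
  rbind(out, mean_row)
}
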