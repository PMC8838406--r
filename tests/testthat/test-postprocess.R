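test_that("median filter handles constant, speckle and gap cases", {
  ones <- matrix(1, 10, 10)
  expect_identical(median_denoise(ones, 3), ones)

  speck <- matrix(0, 9, 9); speck[5, 5] <- 1
  expect_true(all(median_denoise(speck, 3) == 0))

  # 3-px-wide bar with a one-pixel gap: gap filled
  bar <- matrix(0, 11, 11); bar[5:7, ] <- 1; bar[6, 6] <- 0
  filled <- median_denoise(bar, 3)
  expect_equal(filled[6, 6], 1)
  expect_identical(filled, oracle_median(bar, 3))

  expect_error(median_denoise(bar, 4), "odd")
})

test_that("median filter matches the sliding-window oracle on gray images", {
  set.seed(6)
  img <- matrix(stats::runif(144), 12, 12)
  # EBImage's constant-time median quantizes intensities; allow that error
  expect_lt(max(abs(median_denoise(img, 3) - oracle_median(img, 3))), 1e-4)
})

test_that("median filter commutes with transposition", {
  set.seed(7)
  b <- (matrix(stats::runif(15 * 11), 15, 11) > 0.5) * 1
  expect_identical(t(median_denoise(b, 3)), median_denoise(t(b), 3))
})

test_that("small-object removal uses 8-connectivity and a strict area rule", {
  cfg0 <- postprocess_config(min_object_area = 0)
  set.seed(8)
  img <- (matrix(stats::runif(100), 10, 10) > 0.6) * 1
  expect_identical(remove_small_objects(img, cfg0), img)

  two <- matrix(0, 20, 20)
  two[2, 2:6] <- 1                      # area 5
  two[10:14, 10:19] <- 1                # area 50
  out <- remove_small_objects(two, postprocess_config(min_object_area = 10))
  expect_equal(sum(out), 50)
  expect_true(all(out[10:14, 10:19] == 1))

  # exactly at the threshold: kept (strict <)
  at <- matrix(0, 10, 10); at[3, 3:7] <- 1
  expect_identical(remove_small_objects(at, postprocess_config(min_object_area = 5)), at)

  # a diagonal staircase is one 8-connected component
  diag_img <- matrix(0, 12, 12)
  for (i in 1:8) diag_img[i, i] <- 1
  kept <- remove_small_objects(diag_img, postprocess_config(min_object_area = 8))
  expect_identical(kept, diag_img)
  expect_equal(length(oracle_component_areas(diag_img)), 1L)
})

test_that("8-connected labeling areas agree with a flood-fill oracle", {
  set.seed(9)
  for (i in 1:5) {
    img <- (matrix(stats::runif(15 * 15), 15, 15) > 0.65) * 1
    cfg <- postprocess_config(min_object_area = 4)
    out <- remove_small_objects(img, cfg)
    areas <- oracle_component_areas(img)
    expect_equal(sum(out), sum(areas[areas >= 4]))
    expect_true(all(out <= img))
  }
})

test_that("FOV mask extraction recovers the phantom field of view", {
  sp <- random_phantom_spec(height = 128, width = 128, n_vessels = 3, seed = 10)
  ph <- generate_phantom(sp, color = TRUE)
  mask <- build_fov_mask(ph$image)
  jacc <- sum(mask & ph$fov) / sum(mask | ph$fov)
  expect_gte(jacc, 0.99)
  expect_error(build_fov_mask(matrix(0, 16, 16)), "mask extraction")
})

test_that("FOV rim artifacts are removed, interior vessels untouched", {
  sp <- phantom_spec(100, 100, vessels = empty_vessels(), noise_sigma = 0)
  ph <- generate_phantom(sp)
  cfg <- postprocess_config(edge_dilation_radius = 2)

  # vessels strictly interior: unchanged
  inner <- matrix(0, 100, 100); inner[48:52, 30:70] <- 1
  expect_identical(remove_fov_edge(inner, config = cfg, fov = ph$fov), inner)

  # a 1-px circle traced exactly on the FOV boundary: fully removed
  eroded <- as.matrix(EBImage::erode(ph$fov, matrix(1, 3, 3)))
  ring <- (ph$fov - eroded) * 1
  expect_gt(sum(ring), 0)
  expect_true(all(remove_fov_edge(ring, config = cfg, fov = ph$fov) == 0))

  # radius 0: only ring-overlap pixels removed (set-difference oracle)
  cfg0 <- postprocess_config(edge_dilation_radius = 0)
  mixed <- pmax(inner, ring)
  out <- remove_fov_edge(mixed, config = cfg0, fov = ph$fov)
  expect_identical(out, mixed * (1 - ring))

  expect_error(remove_fov_edge(inner, config = cfg, fov = matrix(1, 5, 5)),
               "dimensions")
})

test_that("post-processing is anti-extensive on deletions and idempotent", {
  sp <- random_phantom_spec(height = 128, width = 128, n_vessels = 5, seed = 12)
  ph <- generate_phantom(sp, color = TRUE)
  seg <- segment_image(ph$image, pipeline_config(seed = 12))
  cfg <- postprocess_config()

  # anti-extensivity of the deleting stages
  set.seed(13)
  noisy <- pmax(seg$mask, (matrix(stats::runif(128 * 128), 128, 128) > 0.97) * 1)
  expect_true(all(remove_small_objects(noisy, cfg) <= noisy))
  expect_true(all(remove_fov_edge(noisy, config = cfg, fov = ph$fov) <= noisy))

  # idempotence of the full chain
  once <- postprocess(noisy, config = cfg, fov = ph$fov)
  twice <- postprocess(once, config = cfg, fov = ph$fov)
  expect_identical(once, twice)
})
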