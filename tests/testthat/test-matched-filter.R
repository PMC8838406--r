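test_that("kernel values and support follow the template-field rule", {
  spec <- kernel_spec(sigma = 1.9, length = 9)
  k <- build_kernel(spec, 0)
  # full kernel matches the enumeration oracle applying the rotated range
  # directly: raw value -exp(-u^2/2sigma^2) in support, minus in-support mean
  Rr <- (nrow(k) - 1) / 2; Rc <- (ncol(k) - 1) / 2
  sup_oracle <- oracle_kernel_support(1.9, 9, 0, Rr, Rc)
  xs <- matrix(-Rc:Rc, 2 * Rr + 1, 2 * Rc + 1, byrow = TRUE)
  raw <- -exp(-xs^2 / (2 * 1.9^2))
  expected <- matrix(0, 2 * Rr + 1, 2 * Rc + 1)
  expected[sup_oracle] <- raw[sup_oracle] - mean(raw[sup_oracle])
  expect_equal(unclass(k), expected, tolerance = 1e-12, ignore_attr = TRUE)
  # pre-mean-subtraction center value is -exp(0) = -1
  expect_equal(k[Rr + 1, Rc + 1], -1 - mean(raw[sup_oracle]), tolerance = 1e-12)
  # half-extent along the cross-section: integer |u| <= 3 sigma
  nz_cols <- which(apply(sup_oracle, 2, any))
  expect_equal(max(abs(nz_cols - (Rc + 1))), floor(3 * 1.9))
})

test_that("the 90-degree kernel is the transpose of the 0-degree kernel", {
  spec <- kernel_spec(sigma = 1.5, length = 9)
  k0 <- build_kernel(spec, 0)
  k90 <- build_kernel(spec, 90)
  expect_equal(t(k0), k90, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("every kernel in every bank is zero-mean", {
  for (sigma in c(1.9, 0.5, 0.13)) {
    bank <- filter_bank(kernel_spec(sigma))
    for (k in bank) expect_lt(abs(sum(k)), 1e-10)
  }
})

test_that("theta outside [0, 180) is rejected", {
  spec <- kernel_spec(1)
  expect_error(build_kernel(spec, 180), "theta")
  expect_error(build_kernel(spec, -5), "theta")
  expect_error(kernel_spec(-1), "sigma")
})

test_that("constant images produce identically zero maximum response", {
  img <- matrix(0.7, 40, 40)
  for (sigma in c(1.9, 0.5, 0.13))
    expect_lt(max(abs(max_response(img, kernel_spec(sigma)))), 1e-10)
})

test_that("argmax orientation equals the drawn vessel angle for all 12 angles", {
  spec <- kernel_spec(sigma = 1.9, length = 9)
  for (th in seq(0, 165, by = 15)) {
    img <- oracle_vessel_image(61, th, width = 1.9 * 2.355, depth = 0.3)
    r <- max_response(img, spec, return_argmax = TRUE)
    expect_equal(attr(r, "argmax_theta")[31, 31], th)
  }
})

test_that("vessel orientation response agrees with direct dense convolution", {
  spec <- kernel_spec(sigma = 1, length = 7, n_orientations = 4L)
  img <- oracle_vessel_image(25, 45, width = 2.4, depth = 0.3)
  responses <- sapply(c(0, 45, 90, 135), function(th)
    oracle_conv(img, build_kernel(spec, th))[13, 13])
  got <- max_response(img, spec, return_argmax = TRUE)
  expect_equal(got[13, 13], max(responses), tolerance = 1e-9)
  expect_equal(attr(got, "argmax_theta")[13, 13], c(0, 45, 90, 135)[which.max(responses)])
})

test_that("center-line response peaks when vessel width matches the kernel scale", {
  spec <- kernel_spec(sigma = 1.9, length = 9)
  resp_at_center <- function(sigma_v) {
    img <- oracle_vessel_image(61, 90, width = sigma_v * 2.355, depth = 0.3)
    max_response(img, spec)[31, 31]
  }
  matched <- resp_at_center(1.9)
  expect_gt(matched, resp_at_center(0.95))
  expect_gt(matched, resp_at_center(3.8))
})

test_that("max_response is equivariant under 90-degree rotation", {
  sp <- random_phantom_spec(height = 64, width = 64, n_vessels = 3, seed = 5)
  img <- generate_phantom(sp)$image
  spec <- kernel_spec(sigma = 1.9)
  a <- max_response(rot90cw(img), spec)
  b <- rot90cw(max_response(img, spec))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("fuse_scales degenerate weights and convexity identities hold", {
  set.seed(3)
  g1 <- matrix(stats::runif(100), 10, 10)
  g2 <- matrix(stats::runif(100), 10, 10)
  g3 <- matrix(stats::runif(100), 10, 10)
  f <- fuse_scales(list(g1, g2, g3), fusion_config(weights = c(1, 0, 0)))
  expect_equal(f, (g1 - min(g1)) / (max(g1) - min(g1)), tolerance = 1e-12)
  same <- fuse_scales(list(g1, g1, g1), fusion_config(), rescale = FALSE)
  expect_equal(same, g1, tolerance = 1e-12)
  expect_error(fuse_scales(list(g1, g2, matrix(0, 5, 5)), fusion_config()),
               "dimension")
})

test_that("fusion is monotone in each input before rescaling", {
  set.seed(4)
  gs <- lapply(1:3, function(i) matrix(stats::runif(64), 8, 8))
  base <- fuse_scales(gs, fusion_config(), rescale = FALSE)
  for (i in 1:3) {
    bumped <- gs
    bumped[[i]][4, 4] <- bumped[[i]][4, 4] + 0.5
    expect_true(all(fuse_scales(bumped, fusion_config(), rescale = FALSE) >= base))
  }
})

test_that("multiscale fusion recovers both thick and thin vessels better than single scales", {
  vessels <- data.frame(r0 = c(25, 65), c0 = c(5, 5), r1 = c(25, 65),
                        c1 = c(85, 85), width = c(5, 1), depth = c(0.3, 0.3))
  sp <- phantom_spec(90, 90, vessels = vessels, illumination_amplitude = 0,
                     noise_sigma = 0, fov_radius_fraction = 1)
  ph <- generate_phantom(sp)
  cfg <- fusion_config()
  single <- lapply(cfg$sigmas, function(s) max_response(ph$image, kernel_spec(s)))
  fused <- fuse_scales(single, cfg)
  resc <- lapply(single, function(g) {
    g <- pmax(g, 0); (g - min(g)) / (max(g) - min(g))
  })
  thick <- ph$truth == 1 & row(ph$truth) < 45
  thin <- ph$truth == 1 & row(ph$truth) >= 45
  expect_gt(mean(fused[thin]), mean(resc[[1]][thin]))   # coarse scale misses thin
  expect_gt(mean(fused[thick]), mean(resc[[3]][thick])) # fine scale misses thick
})
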