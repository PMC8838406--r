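test_that("histogram256 quantizes and normalizes correctly", {
  img <- matrix(0, 4, 4)
  h <- histogram256(img)
  expect_equal(h$p[1], 1)
  expect_true(all(h$p[-1] == 0))

  img2 <- matrix(c(0, 0, 128 / 255, 1), 2, 2)
  h2 <- histogram256(img2)
  expect_equal(h2$p[0 + 1], 0.5)
  expect_equal(h2$p[128 + 1], 0.25)
  expect_equal(h2$p[255 + 1], 0.25)

  set.seed(1)
  h3 <- histogram256(matrix(stats::runif(400), 20, 20))
  expect_lt(abs(sum(h3$p) - 1), 1e-12)

  expect_error(histogram256(matrix(0.5, 3, 3), mask = matrix(0, 3, 3)), "empty mask")
  expect_error(histogram256(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("between-class variance matches the hand-computed two-point case", {
  p <- numeric(256)
  p[50 + 1] <- 0.4
  p[200 + 1] <- 0.6
  h <- gray_histogram(p)
  # u_T = 0.4*50 + 0.6*200 = 140; sigma_B^2 = 0.4*90^2 + 0.6*60^2 = 5400
  expect_equal(between_class_variance(h, 100), 5400, tolerance = 1e-10)
  expect_error(between_class_variance(h, c(100, 100)), "strictly increasing")
  expect_error(between_class_variance(h, c(120, 80)), "strictly increasing")
})

test_that("a single-bin histogram has zero between-class variance everywhere", {
  p <- numeric(256); p[77] <- 1
  h <- gray_histogram(p)
  for (t in c(0, 50, 76, 200, 254))
    expect_equal(between_class_variance(h, t), 0)
})

test_that("the two-class moment identities hold for every threshold", {
  h <- random_histogram(13)
  for (t in 0:254) {
    cs <- oracle_class_stats(h$p, t)
    expect_lt(abs(sum(cs$w) - 1), 1e-12)
    expect_lt(abs(sum(cs$w * cs$u) - cs$uT), 1e-12)
    # and the package objective equals the definitional oracle
  }
  ts <- c(0, 13, 100, 254)
  for (t in ts)
    expect_equal(between_class_variance(h, t), oracle_bcv(h$p, t), tolerance = 1e-12)
})

test_that("the m-class moment identities hold for random ordered triples", {
  h <- random_histogram(29)
  set.seed(77)
  for (i in 1:200) {
    t <- sort(sample(0:254, 3))
    cs <- oracle_class_stats(h$p, t)
    expect_lt(abs(sum(cs$w) - 1), 1e-12)
    expect_lt(abs(sum(cs$w * cs$u) - cs$uT), 1e-12)
    expect_equal(between_class_variance(h, t), oracle_bcv(h$p, t),
                 tolerance = 1e-12)
  }
})

test_that("otsu_single matches the brute-force oracle and tie rules", {
  # two point masses: plateau [50, 199], smallest t wins
  p <- numeric(256); p[50 + 1] <- 0.4; p[200 + 1] <- 0.6
  expect_equal(as.integer(otsu_single(gray_histogram(p))), 50)
  # symmetric two-point case at 0 and 255: plateau [0, 254] -> 0
  q <- numeric(256); q[1] <- 0.5; q[256] <- 0.5
  expect_equal(as.integer(otsu_single(gray_histogram(q))), 0)
  # random histograms: exact argmax and fitness agreement
  for (s in 1:5) {
    h <- random_histogram(s)
    got <- otsu_single(h)
    ora <- oracle_otsu_single(h$p)
    expect_equal(as.integer(got), ora$t)
    expect_equal(attr(got, "fitness"), ora$fitness, tolerance = 1e-12)
  }
  single <- numeric(256); single[100] <- 1
  expect_error(otsu_single(gray_histogram(single)), "degenerate")
})

test_that("PSO null dynamics freeze the swarm", {
  h <- generate_histogram_fixture(2, seed = 1)
  cfg <- pso_config(population = 5, inertia = 0, c1 = 0, c2 = 0,
                    iterations = 1, seed = 3)
  cm_fit <- function(t) between_class_variance(h, t)
  set.seed(3)
  st <- init_swarm(cfg, 2L, 254, cm_fit)
  st$V <- st$V * 0
  st2 <- pso_step(st, cfg, cm_fit)
  expect_equal(st2$X, st$X)
  expect_true(all(st2$V == 0))
})

test_that("a particle at the global best with zero velocity is a fixed point", {
  h <- generate_histogram_fixture(2, seed = 2)
  fit <- function(t) between_class_variance(h, t)
  cfg <- pso_config(population = 3, iterations = 1, seed = 5)
  set.seed(9)
  st <- init_swarm(cfg, 2L, 254, fit)
  g <- which.max(st$pb_fit)
  st$X[g, ] <- st$gbest; st$Pb[g, ] <- st$gbest; st$V[g, ] <- 0
  st2 <- pso_step(st, cfg, fit)
  expect_equal(st2$X[g, ], st$gbest)
})

test_that("otsu_pso is deterministic and matches otsu_single for m = 1", {
  h <- random_histogram(17)
  cfg <- pso_config(seed = 11)
  a <- otsu_pso(h, 1, cfg)
  b <- otsu_pso(h, 1, cfg)
  expect_identical(as.integer(a), as.integer(b))
  expect_equal(attr(a, "fitness"), attr(otsu_single(h), "fitness"),
               tolerance = 1e-12)
  # Table-style default config
  d <- pso_config()
  expect_equal(d$population, 40L)
  expect_equal(d$inertia, 0.5)
  expect_equal(d$c1, 2); expect_equal(d$c2, 2)
  expect_equal(d$iterations, 20L)
})

test_that("otsu_pso m=3 determinism and feasibility contracts", {
  h <- generate_histogram_fixture(4, seed = 8)
  expect_identical(as.integer(otsu_pso(h, 3, pso_config(seed = 21))),
                   as.integer(otsu_pso(h, 3, pso_config(seed = 21))))
  sparse <- numeric(256); sparse[c(10, 200)] <- 0.5
  expect_error(otsu_pso(gray_histogram(sparse), 3, pso_config(seed = 1)),
               "infeasible")
})

test_that("global-best fitness never decreases across iterations", {
  h <- generate_histogram_fixture(3, seed = 31)
  t <- otsu_pso(h, 3, pso_config(seed = 4))
  expect_true(all(diff(attr(t, "trace")) >= 0))
})

test_that("apply_thresholds assigns interval classes and renders evenly", {
  ramp <- matrix(seq(0, 1, length.out = 256), 16, 16)
  tm <- apply_thresholds(ramp, 127)
  lev <- floor(ramp * 255 + 1e-12)
  expect_true(all((tm$labels == 1) == (lev > 127)))

  img <- matrix(c(0, 100, 150, 255) / 255, 2, 2)
  tm3 <- apply_thresholds(img, c(63, 127, 191))
  expect_equal(sort(as.vector(tm3$labels)), 0:3)
  expect_equal(sort(unique(as.vector(tm3$rendered))), c(0, 1, 2, 3) / 3)

  # re-binarizing a 2-class labeling with single-threshold Otsu reproduces it
  tm1 <- apply_thresholds(ramp, 127)
  h <- histogram256(tm1$rendered)
  tcut <- otsu_single(h)
  lev2 <- floor(tm1$rendered * 255 + 1e-12)
  expect_identical((lev2 > as.integer(tcut)) * 1, tm1$labels * 1)
})
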