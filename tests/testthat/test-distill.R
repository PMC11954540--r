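test_that("the feature distance matches hand-evaluated cases", {
  cfg <- distance_config()
  expect_equal(feature_distance(c(3, 4), c(3, 4), cfg), 0)
  expect_equal(feature_distance(c(1, 0), c(0, 1), cfg), 1 + sqrt(2),
               tolerance = 1e-6)
  expect_equal(feature_distance(c(2, 0), c(1, 0), cfg), 1)  # cosine term 0
  cfg05 <- distance_config(lambda_weight = 0.5)
  expect_equal(feature_distance(c(1, 2), c(2, 1), cfg05),
               0.5 * (1 - 4 / 5) + sqrt(2), tolerance = 1e-6)
  expect_error(feature_distance(c(1, 2), c(1, 2, 3)), "length")
  ## finite at zero vectors thanks to epsilon
  expect_true(is.finite(feature_distance(c(0, 0), c(0, 0))))
})

test_that("distance maps are local and agree with the scalar-loop oracle", {
  cfg <- distance_config()
  lv <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  expect_equal(distance_map(lv, lv, cfg), matrix(0, 2, 2))
  lv2 <- lv
  lv2[2, 1, ] <- lv2[2, 1, ] + 1
  M <- distance_map(lv, lv2, cfg)
  expect_equal(sum(M > 1e-9), 1L)  # untouched positions only carry rounding
  expect_gt(M[2, 1], 0.1)
  set.seed(42)
  for (rep in 1:5) {
    a <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
    b <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
    expect_lt(max(abs(distance_map(a, b, cfg) - distance_map_oracle(a, b, cfg))),
              1e-6)
  }
  expect_error(distance_map(array(0, c(2, 2, 3)), array(0, c(2, 3, 3))), "shape")
})

test_that("the loss sums per-level spatial means and is zero only at identity", {
  cfg <- distance_config()
  shapes <- list(c(4, 4, 3), c(2, 2, 5))
  pyr <- random_pyramids(shapes, seed = 7)
  expect_equal(distillation_loss(pyr$t, pyr$t, cfg), 0)
  ## uniform per-position distances 1 and 2: collinear vectors, L2 gap 1 and 2
  lvl1_t <- array(rep(c(2, 0), each = 16), dim = c(4, 4, 2))
  lvl1_s <- array(rep(c(1, 0), each = 16), dim = c(4, 4, 2))
  lvl2_t <- array(rep(c(3, 0), each = 4), dim = c(2, 2, 2))
  lvl2_s <- array(rep(c(1, 0), each = 4), dim = c(2, 2, 2))
  expect_equal(distillation_loss(list(lvl1_t, lvl2_t), list(lvl1_s, lvl2_s), cfg),
               3, tolerance = 1e-9)
  ## composition oracle
  L <- distillation_loss(pyr$t, pyr$s, cfg)
  by_maps <- sum(vapply(seq_along(shapes), function(n) {
    mean(distance_map(pyr$t[[n]], pyr$s[[n]], cfg))
  }, numeric(1)))
  expect_lt(abs(L - by_maps), 1e-6)
  expect_gte(L, 0)
  expect_error(distillation_loss(pyr$t, pyr$s[1]), "level count")
})

test_that("distance and loss are nonnegative over random draws", {
  cfg <- distance_config(lambda_weight = 0.7)
  set.seed(11)
  for (rep in 1:50) {
    f <- rnorm(5); g <- rnorm(5)
    expect_gte(feature_distance(f, g, cfg), 0)
  }
})

test_that("training reduces the loss, leaves the teacher untouched, and is reproducible", {
  cfg <- tiny_phantom(seed = 21)
  imgs <- unlist(lapply(1:8, function(i) {
    c2 <- cfg; c2$seed <- i
    generate_volume(c2)$images
  }), recursive = FALSE)
  imgs <- lapply(imgs, function(m) m[1:16, 1:16])
  b <- model_bundle(tiny_spec(), seed = 9)
  before <- teacher_checksum(b)
  tcfg <- train_config(epochs = 6L, batch_size = 8L, seed = 3L)
  fit <- train_student(b, imgs, tcfg)
  expect_lt(fit$history$mean_loss[6], fit$history$mean_loss[1])
  expect_identical(teacher_checksum(fit$bundle), before)
  expect_identical(fit$bundle$teacher, b$teacher)
  ## reproducible for a fixed seed
  fit2 <- train_student(b, imgs, tcfg)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
})

test_that("a zero learning rate is a null training step", {
  imgs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  b <- model_bundle(tiny_spec(), seed = 13)
  fit <- train_student(b, imgs, train_config(epochs = 3L, learning_rate = 0))
  expect_equal(fit$history$mean_loss, rep(fit$history$mean_loss[1], 3))
  expect_identical(fit$bundle$student, b$student)
  expect_identical(fit$bundle$bottleneck, b$bottleneck)
})

test_that("training refuses anomalous or empty inputs", {
  b <- model_bundle(tiny_spec(), seed = 1)
  expect_error(train_student(b, list()), "empty")
  cfg <- tiny_phantom(seed = 5)
  specs <- rep(list(list()), cfg$n_bscans)
  specs[[1]] <- list(lesion_spec("bump", c(16, 16), 40, 0.3))
  vol <- generate_volume(cfg, specs, volume_id = "bad")
  expect_error(train_student(b, list(vol)), "anomalous")
  imgs <- lapply(1:2, function(i) matrix(runif(256), 16, 16))
  expect_error(train_student(b, imgs, labels = c("normal", "anomalous")),
               "anomalous")
})
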