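test_that("train_step is deterministic given the RNG state", {
  cfg <- small_config(size = 32, steps = 1)
  cfg$image_size <- 32L
  state <- init_dualgan_state(cfg)
  batch <- phantom_batch(32, n = 2, width_range = c(4L, 6L))
  set.seed(99); o1 <- train_step(batch[c("s", "w", "m")], state, cfg)
  set.seed(99); o2 <- train_step(batch[c("s", "w", "m")], state, cfg)
  expect_identical(o1$record, o2$record)
  expect_identical(o1$state$ga$params, o2$state$ga$params)
  expect_equal(o1$record$total,
               sum(unlist(loss_weights()) *
                     unlist(o1$record[c("ssim", "frequency", "l1",
                                        "adversarial", "reconstruction")])))
})

test_that("ablation weights switch code paths without other changes", {
  cfg <- small_config(size = 32)
  cfg$image_size <- 32L
  cfg$weights <- loss_weights(adversarial = 0, reconstruction = 0)
  state <- init_dualgan_state(cfg)
  batch <- phantom_batch(32, n = 2, width_range = c(4L, 6L))
  set.seed(1)
  out <- train_step(batch[c("s", "w", "m")], state, cfg)
  # discriminators untouched in the supervised ablation
  expect_identical(out$state$da$params, state$da$params)
  expect_true(is.na(out$record$da_real))
  expect_equal(out$record$reconstruction, 0)
})

test_that("fitting runs end to end, checkpoints, and resumes bit-exactly", {
  dir <- withr::local_tempdir()
  build_dataset(6, 2, dir, params = phantom_params(32, 32),
                train_mask_params = mask_params(c(3L, 5L)),
                test_mask_params = mask_params(c(6L, 8L)), seed = 2)
  cfg <- small_config(size = 32, steps = 6, seed = 3)
  cfg$base_channels <- 8L
  fit <- dualgan(dir, cfg)
  expect_s3_class(fit, "dualgan")
  expect_equal(fit$state$step, 6L)
  expect_equal(nrow(fit$history), 6)
  expect_true(all(is.finite(fit$history$total)))

  ckpt <- file.path(dir, "ck.rds")
  save_checkpoint(fit, ckpt)
  fit2 <- load_checkpoint(ckpt)
  expect_identical(fit2$state$ga$params, fit$state$ga$params)

  # interrupted-at-3 + resume == uninterrupted 6 steps
  cfg3 <- cfg; cfg3$steps <- 3L
  fit3 <- dualgan(dir, cfg3)
  cfg6 <- cfg3; cfg6$steps <- 6L
  fit36 <- dualgan(dir, cfg6, resume_from = fit3)
  expect_equal(fit36$history, fit$history)
  expect_equal(fit36$state$ga$params, fit$state$ga$params, tolerance = 1e-15)

  # print/summary/plot/predict methods work on the fit
  expect_output(print(fit), "Dual-GAN")
  expect_output(summary(fit), "trajectory")
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  art <- load_image(file.path(dir, read_manifest(dir)$path_artifact[7]))
  msk <- load_mask(file.path(dir, read_manifest(dir)$path_mask[7]))
  expect_identical(predict(fit, art, msk), inpaint(art, msk, fit))
})

test_that("inpainting is bit-identical outside the mask for any model state", {
  cfg <- small_config(size = 64, seed = 5)
  state <- init_dualgan_state(cfg)   # untrained random weights
  sc <- tiny_phantom(64, seed = 11, speckle = 0.2)
  m <- sample_mask(mask_params(c(8L, 8L), c(40L, 40L)), c(64, 64))
  art <- corrupt(sc$image, m)$artifact_image
  out <- inpaint(art, m, state)
  expect_identical(out[m == 0], art[m == 0])
  expect_true(all(out >= 0 & out <= 1))
  # all-zero mask: output equals the input exactly
  expect_identical(inpaint(art, matrix(0, 64, 64), state), art)
  expect_error(inpaint(art[1:32, 1:32], m[1:32, 1:32], state), "divisible")
})

test_that("discriminators separate real from fake after a short warm-up", {
  cfg <- small_config(size = 32, steps = 30, seed = 4, log_every = 1L)
  cfg$image_size <- 32L
  cfg$base_channels <- 8L
  dir <- withr::local_tempdir()
  build_dataset(4, 1, dir, params = phantom_params(32, 32),
                train_mask_params = mask_params(c(3L, 5L)),
                test_mask_params = mask_params(c(6L, 8L)), seed = 6)
  fit <- dualgan(dir, cfg)
  late <- utils::tail(fit$history, 10)
  expect_gt(median(late$da_real - late$da_fake), 0)
  expect_gt(median(late$db_real - late$db_fake), 0)
})
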