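test_that("psnr follows its closed forms and is monotone in MSE", {
  x <- matrix(0, 8, 8)
  expect_equal(psnr(x, x), 100)                       # capped at zero MSE
  expect_equal(psnr(x, matrix(1, 8, 8)), 0)           # MSE 1, L = 1
  # halving the MSE raises PSNR by 10 log10(2)
  y1 <- matrix(c(rep(0.2, 32), rep(0, 32)), 8, 8)     # MSE 0.02
  y2 <- matrix(c(rep(0.2, 16), rep(0, 48)), 8, 8)     # MSE 0.01
  expect_equal(psnr(x, y2) - psnr(x, y1), 10 * log10(2))
  # masked region restriction
  m <- matrix(0, 8, 8); m[, 3:4] <- 1
  z <- x; z[, 3:4] <- 0.5
  expect_equal(psnr(x, z, region_spec("masked", m)), 10 * log10(1 / 0.25))
  expect_equal(psnr(x, z), 10 * log10(1 / (0.25 * 16 / 64)))
  expect_error(region_spec("masked", matrix(0, 8, 8)), "nonempty")
})

test_that("region ssim shares the loss-side implementation", {
  x <- tiny_phantom(64, seed = 2, speckle = 0.2)$image
  y <- tiny_phantom(64, seed = 3, tilt = 6, speckle = 0.2)$image
  expect_equal(ssim_metric(x, x), 1)
  expect_equal(ssim_metric(x, y), ssim(x, y))
  expect_equal(ssim_metric(x, y), ssim_metric(y, x))
  m <- matrix(0, 64, 64); m[, 20:40] <- 1
  reg <- region_spec("bbox", m)
  expect_equal(ssim_metric(x, y, reg), ssim(x[, 20:40], y[, 20:40]))
  # narrow stripe: windowed mode must refuse, global mode must work
  m2 <- matrix(0, 64, 64); m2[, 30:33] <- 1
  expect_error(ssim_metric(x, y, region_spec("bbox", m2)), "global")
  expect_true(is.finite(ssim_metric(x, y, region_spec("bbox", m2),
                                    ssim_params(type = "global"))))
})

test_that("confusion counts match a hand-counted 4x4 case", {
  pred <- matrix(0, 4, 4); truth <- matrix(0, 4, 4)
  pred[1, 1:4] <- 1                      # |X| = 4
  truth[1, 1:2] <- 1; truth[2, 1:2] <- 1 # |Y| = 4, overlap = 2
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2, TN = 10, FP = 2, FN = 2))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 16)
  expect_equal(dsc(pred, truth), 0.5)
  expect_equal(pixel_accuracy(cc), 12 / 16)
  expect_equal(f1_score(cc), 0.5)
  expect_equal(jaccard(pred, truth), 1 / 3)
  expect_error(confusion(pred, matrix(0.5, 4, 4)), "binary")

  x <- matrix(1, 3, 3)
  expect_equal(dsc(x, x), 1)
  expect_equal(dsc(x, 1 - x), 0)
  cc2 <- confusion(x, 1 - x)
  expect_equal(cc2$TP + cc2$TN, 0)
  expect_equal(pixel_accuracy(cc2), 0)
})

test_that("dice equals F1 and the dice-jaccard identity holds exactly", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    d <- dsc(a, b); j <- jaccard(a, b)
    expect_identical(d, f1_score(confusion(a, b)))
    expect_equal(d, 2 * j / (1 + j))
  }
  # empty-mask convention
  e <- matrix(0, 4, 4)
  expect_equal(dsc(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  expect_equal(f1_score(confusion(e, e)), 1)
})

test_that("threshold boundary recovery traces the anterior surface of a phantom", {
  sc <- tiny_phantom(64, seed = 6, speckle = 0)
  b <- boundary_from_image(sc$image, threshold = 0.3, from = "top")
  expect_true(all(colSums(b) <= 1))
  sm <- segmentation_metrics(b, sc$boundaries$EP, tolerance = 1)
  expect_gt(sm$dsc, 0.7)
  expect_gt(sm$pa, 0.95)
  # a one-row shift: strict comparison scores 0, while a tolerance-t band
  # overlaps in (2t + 1 - shift) of (2t + 1) rows per column
  shifted <- rbind(matrix(0, 1, 64), sc$boundaries$EP[-64, ])
  expect_equal(segmentation_metrics(shifted, sc$boundaries$EP, 0)$dsc, 0)
  expect_equal(segmentation_metrics(shifted, sc$boundaries$EP, 2)$dsc, 4 / 5)
})

test_that("evaluate ranks oracle > identity on every corrupted phantom", {
  dir <- withr::local_tempdir()
  build_dataset(1, 3, dir, params = phantom_params(64, 64),
                train_mask_params = mask_params(c(4L, 6L)),
                test_mask_params = mask_params(c(8L, 12L)), seed = 9)
  rep_or <- evaluate(dir, "oracle")
  rep_id <- evaluate(dir, "identity")
  expect_equal(rep_or$psnr, rep(100, 3))
  expect_equal(rep_or$ssim, rep(1, 3))
  expect_true(all(rep_or$psnr > rep_id$psnr))
  expect_true(all(rep_or$ssim > rep_id$ssim))
  # identity inpainter reproduces the before-inpainting baseline
  expect_equal(rep_id$psnr, rep_id$psnr_before)
  expect_equal(rep_id$ssim, rep_id$ssim_before)
  # report means are the arithmetic means of per-image values
  expect_equal(unname(attr(rep_id, "means")["psnr"]), mean(rep_id$psnr))
})
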