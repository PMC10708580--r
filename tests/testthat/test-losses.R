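test_that("ssim is 1 on identical images, symmetric, and range-rescalable", {
  x <- tiny_phantom(64, seed = 1, speckle = 0.2)$image
  y <- tiny_phantom(64, seed = 2, tilt = 5, speckle = 0.2)$image
  for (tp in c("gaussian", "global")) {
    sp <- ssim_params(type = tp)
    expect_equal(ssim(x, x, sp), 1)
    expect_equal(ssim(x, y, sp), ssim(y, x, sp))
  }
  # dynamic-range rescaling: ssim(a x, a y | a L) = ssim(x, y | L)
  a <- 2.5
  expect_equal(ssim(a * x, a * y, ssim_params(dynamic_range = a)),
               ssim(x, y, ssim_params(dynamic_range = 1)))
})

test_that("global-window ssim of constant 0 vs constant 1 is C1/(1+C1)", {
  v <- ssim(matrix(0, 16, 16), matrix(1, 16, 16), ssim_params(type = "global"))
  expect_equal(v, 1e-4 / (1 + 1e-4))
})

test_that("ssim_loss is zero for perfect generators and additive by direction", {
  w <- tiny_phantom(32, seed = 1, speckle = 0.2)$image
  s <- corrupt(w, sample_mask(mask_params(c(4L, 4L), c(16L, 16L)), c(32, 32)))$artifact_image
  sp <- ssim_params(window = 7)
  expect_equal(ssim_loss(w, w, s, s, sp), 0)
  # one direction perfect, the other contributing 1 - SSIM(s, gb)
  gb <- 0.9 * s + 0.05
  expect_equal(ssim_loss(w, w, s, gb, sp), 1 - ssim(s, gb, sp))
  expect_gte(ssim_loss(w, s, s, w, sp), 0)
})

test_that("fft2 matches the naive DFT oracle and its closed forms", {
  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  expect_lt(max(Mod(fft2(x) - naive_dft(x))), 1e-10)
  # constant image: c * n^2 at DC, zero elsewhere
  cst <- matrix(0.4, 8, 8)
  sp <- fft2(cst)
  expect_equal(Re(sp[1, 1]), 0.4 * 64)
  expect_lt(max(Mod(sp[-1])), 1e-10)
  # Hermitian symmetry of a real image's spectrum: F[u,v] = conj(F[-u,-v])
  n <- 8
  idx <- function(i) ((n - i) %% n) + 1
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    expect_equal(fft2(x)[u + 1, v + 1], Conj(fft2(x)[idx(u), idx(v)]))
  }
})

test_that("frequency loss is zero at equality, 1-homogeneous, and matches its oracle", {
  set.seed(12)
  w <- matrix(runif(64), 8, 8); s <- matrix(runif(64), 8, 8)
  expect_equal(frequency_loss(w, w, s, s), 0)
  # scaling the perturbation by 2 scales the term by 2
  d <- matrix(rnorm(64, sd = 0.1), 8, 8)
  l1x <- frequency_loss(w, w + d, s, s)
  l2x <- frequency_loss(w, w + 2 * d, s, s)
  expect_equal(l2x, 2 * l1x, tolerance = 1e-12)
  # oracle equivalence on random pairs
  ga <- matrix(runif(64), 8, 8); gb <- matrix(runif(64), 8, 8)
  expect_lt(abs(frequency_loss(w, ga, s, gb) -
                naive_frequency_loss(w, ga, s, gb)), 1e-8)
})

test_that("l1 loss takes its analytic values and is permutation-invariant", {
  set.seed(13)
  w <- matrix(runif(64), 8, 8); s <- matrix(runif(64), 8, 8)
  expect_equal(l1_loss(w, w, s, s), 0)
  expect_equal(l1_loss(w, w + 0.5, s, s), 0.5)
  p <- sample(64)
  wp <- matrix(w[p], 8, 8); gp <- matrix((w + 0.3)[p], 8, 8)
  expect_equal(l1_loss(w, w + 0.3, s, s), l1_loss(wp, gp, s, s))
})

test_that("adversarial loss takes its analytic values and rejects bad scores", {
  half <- matrix(0.5, 3, 3)
  expect_equal(adversarial_loss(half, half, half, half), 4 * log(0.5))
  # invariant to patch-map size at constant scores
  big <- matrix(0.5, 30, 30)
  expect_equal(adversarial_loss(big, big, big, big), 4 * log(0.5))
  # perfect discriminators drive the value toward 0 from below
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    r <- matrix(1 - eps, 3, 3); f <- matrix(eps, 3, 3)
    v <- adversarial_loss(r, f, r, f)
    expect_lt(v, 0)
    expect_gt(v, -8 * eps)
  }
  expect_error(adversarial_loss(matrix(1, 2, 2), half, half, half), "sigmoid")
  expect_error(adversarial_loss(half, matrix(0, 2, 2), half, half), "sigmoid")
})

test_that("reconstruction loss measures cycle error symmetrically", {
  set.seed(14)
  s <- matrix(runif(64), 8, 8); w <- matrix(runif(64), 8, 8)
  expect_equal(reconstruction_loss(s, s, w, w), 0)
  expect_equal(reconstruction_loss(s, s + 0.1, w, w), 0.1)
  expect_equal(reconstruction_loss(s, s + 0.1, w, w + 0.2),
               reconstruction_loss(w, w + 0.2, s, s + 0.1))
})

test_that("total loss applies the default weights and names bad terms", {
  tl <- total_loss(list(ssim = 1, frequency = 1, l1 = 1, adversarial = 1,
                        reconstruction = 1))
  expect_equal(tl$total, 153)
  expect_equal(total_loss(list(ssim = 0, frequency = 0, l1 = 0,
                               adversarial = 0, reconstruction = 0))$total, 0)
  # lambda_F = 0 reproduces the no-frequency ablation weighting:
  # 50*1 + 0*5 + 100*1 + 1 + 1
  wts <- loss_weights(frequency = 0)
  tl2 <- total_loss(list(ssim = 1, frequency = 5, l1 = 1, adversarial = 1,
                         reconstruction = 1), wts)
  expect_equal(tl2$total, 152)
  expect_error(total_loss(list(ssim = 1, frequency = NaN, l1 = 1,
                               adversarial = 1, reconstruction = 1)),
               "frequency")
})

test_that("analytic loss gradients match finite differences", {
  set.seed(15)
  w <- matrix(runif(64), 8, 8); s <- matrix(runif(64), 8, 8)
  ga <- matrix(runif(64), 8, 8); gb <- matrix(runif(64), 8, 8)
  idx <- sample(64, 12)
  sp <- ssim_params(window = 5)

  sg <- ssim_loss_grad(w, ga, s, gb, sp)
  num <- numeric_grad(function(z) ssim_loss(w, z, s, gb, sp), ga, idx)
  expect_lt(max_rel_err(num, sg$g_ga[[1]][idx]), 1e-4)
  num <- numeric_grad(function(z) ssim_loss(w, ga, s, z, sp), gb, idx)
  expect_lt(max_rel_err(num, sg$g_gb[[1]][idx]), 1e-4)

  fg <- frequency_loss_grad(w, ga, s, gb)
  num <- numeric_grad(function(z) frequency_loss(w, z, s, gb), ga, idx)
  expect_lt(max_rel_err(num, fg$g_ga[[1]][idx]), 1e-4)

  lg <- l1_loss_grad(w, ga, s, gb)
  num <- numeric_grad(function(z) l1_loss(w, z, s, gb), ga, idx)
  expect_lt(max_rel_err(num, lg$g_ga[[1]][idx]), 1e-4)
})
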