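# Loss terms of the dual-GAN objective: structural similarity, spectral
# (FFT) L1 frequency distance, pixel L1, adversarial log-likelihood and
# cycle reconstruction, plus their weighted total.  Every term also has an
# analytic gradient used by the training loop and checked against finite
# differences in the test suite.

#' SSIM parameters
#'
#' Stabilization constants follow the standard convention
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the declared intensity
#' dynamic range.  The default window is the classic 11x11 Gaussian
#' (sigma 1.5); `type = "global"` uses a single window spanning the whole
#' image, i.e. the literal global-statistics form of the index.
#'
#' @param window Odd window side length in pixels (ignored for global).
#' @param sigma Gaussian window standard deviation in pixels.
#' @param type `"gaussian"`, `"uniform"` or `"global"`.
#' @param dynamic_range Intensity span `L` (1 for `[0,1]` storage space).
#' @return An object of class `"ssim_params"`.
#' @export
ssim_params <- function(window = 11L, sigma = 1.5,
                        type = c("gaussian", "uniform", "global"),
                        dynamic_range = 1) {
  type <- match.arg(type)
  window <- as.integer(window)
  if (type != "global" && window %% 2L == 0L) stop("SSIM window side must be odd")
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  structure(list(window = window, sigma = sigma, type = type,
                 dynamic_range = dynamic_range,
                 C1 = (0.01 * dynamic_range)^2,
                 C2 = (0.03 * dynamic_range)^2),
            class = "ssim_params")
}

ssim_kernel <- function(params, h, w) {
  if (params$type == "global") {
    k <- matrix(1 / (h * w), h, w)
  } else {
    n <- params$window
    if (n > min(h, w))
      stop("SSIM window (", n, ") larger than image (", h, "x", w,
           "); use a smaller window or type = \"global\"")
    if (params$type == "uniform") {
      k <- matrix(1 / n^2, n, n)
    } else {
      r <- seq_len(n) - (n + 1) / 2
      g <- exp(-r^2 / (2 * params$sigma^2))
      k <- outer(g, g)
      k <- k / sum(k)
    }
  }
  array(k, dim = c(1L, 1L, nrow(k), ncol(k)))
}

ssim_conv <- function(img, kern) {
  x <- array(img, dim = c(1L, 1L, nrow(img), ncol(img)))
  y <- conv_fwd(x, kern, numeric(0), 1L, 0L)
  array(y[1, 1, , ], dim = dim(y)[3:4])
}

ssim_conv_t <- function(m, kern, h, w) {
  g <- array(m, dim = c(1L, 1L, nrow(m), ncol(m)))
  y <- conv_grad_input(g, kern, 1L, 0L, h, w)
  array(y[1, 1, , ], dim = c(h, w))
}

ssim_stats <- function(x, y, params) {
  kern <- ssim_kernel(params, nrow(x), ncol(x))
  mx <- ssim_conv(x, kern); my <- ssim_conv(y, kern)
  vx <- ssim_conv(x * x, kern) - mx^2
  vy <- ssim_conv(y * y, kern) - my^2
  cxy <- ssim_conv(x * y, kern) - mx * my
  A1 <- 2 * mx * my + params$C1
  A2 <- 2 * cxy + params$C2
  B1 <- mx^2 + my^2 + params$C1
  B2 <- vx + vy + params$C2
  list(kern = kern, mx = mx, my = my, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       map = (A1 * A2) / (B1 * B2))
}

#' Structural similarity index
#'
#' Mean of the per-window SSIM map of two images.  Symmetric in its
#' arguments and equal to 1 exactly when the images are identical.
#'
#' @param x,y Images (matrices of the same shape).
#' @param params An [ssim_params()].
#' @return A scalar in (-1, 1].
#' @export
ssim <- function(x, y, params = ssim_params()) {
  check_same_shape(x, y, "ssim")
  mean(ssim_stats(x, y, params)$map)
}

#' SSIM value and gradient
#'
#' Analytic gradient of `mean(SSIM map)` with respect to both images.
#'
#' @inheritParams ssim
#' @return A list with elements `value`, `gx`, `gy`.
#' @export
ssim_grad <- function(x, y, params = ssim_params()) {
  check_same_shape(x, y, "ssim_grad")
  st <- ssim_stats(x, y, params)
  P <- length(st$map)
  D <- st$B1 * st$B2
  S <- st$map
  dmx <- (2 * st$my * st$A2) / D - S * (2 * st$mx) / st$B1
  dmy <- (2 * st$mx * st$A2) / D - S * (2 * st$my) / st$B1
  dvx <- -S / st$B2
  dvy <- -S / st$B2
  dcxy <- 2 * st$A1 / D
  h <- nrow(x); w <- ncol(x)
  tb <- ssim_conv_t(dvx, st$kern, h, w)
  tby <- ssim_conv_t(dvy, st$kern, h, w)
  tc <- ssim_conv_t(dcxy, st$kern, h, w)
  gx <- (ssim_conv_t(dmx - 2 * st$mx * dvx - st$my * dcxy, st$kern, h, w) +
           2 * x * tb + y * tc) / P
  gy <- (ssim_conv_t(dmy - 2 * st$my * dvy - st$mx * dcxy, st$kern, h, w) +
           2 * y * tby + x * tc) / P
  list(value = mean(S), gx = gx, gy = gy)
}

loss_pair_mean <- function(targets, generated, f, what) {
  targets <- as_image_list(targets, what)
  generated <- as_image_list(generated, what)
  if (length(targets) != length(generated))
    stop("batch length mismatch in ", what)
  vals <- mapply(f, targets, generated)
  mean(vals)
}

#' Structural-similarity loss
#'
#' `E_W[1 - SSIM(w, GA(s))] + E_S[1 - SSIM(s, GB(w))]`: one minus the SSIM
#' between target and generated image, batch-averaged over both translation
#' directions.  Zero exactly when both generators reproduce their targets.
#'
#' @param w Clean-domain targets (matrix, list, or `[N,1,H,W]` array).
#' @param ga_s Generator-A outputs paired with `w`.
#' @param s Artifact-domain targets.
#' @param gb_w Generator-B outputs paired with `s`.
#' @param params An [ssim_params()].
#' @return Nonnegative scalar.
#' @export
ssim_loss <- function(w, ga_s, s, gb_w, params = ssim_params()) {
  loss_pair_mean(w, ga_s, function(a, b) 1 - ssim(a, b, params), "ssim_loss") +
    loss_pair_mean(s, gb_w, function(a, b) 1 - ssim(a, b, params), "ssim_loss")
}

#' @rdname ssim_loss
#' @return For `ssim_loss_grad()`: list with `value` and gradients `g_ga`
#'   and `g_gb` (lists of matrices) with respect to the generated images.
#' @export
ssim_loss_grad <- function(w, ga_s, s, gb_w, params = ssim_params()) {
  w <- as_image_list(w); ga_s <- as_image_list(ga_s)
  s <- as_image_list(s); gb_w <- as_image_list(gb_w)
  na <- length(w); nb <- length(s)
  val <- 0
  g_ga <- vector("list", na); g_gb <- vector("list", nb)
  for (i in seq_len(na)) {
    sg <- ssim_grad(w[[i]], ga_s[[i]], params)
    val <- val + (1 - sg$value) / na
    g_ga[[i]] <- -sg$gy / na
  }
  for (i in seq_len(nb)) {
    sg <- ssim_grad(s[[i]], gb_w[[i]], params)
    val <- val + (1 - sg$value) / nb
    g_gb[[i]] <- -sg$gy / nb
  }
  list(value = val, g_ga = g_ga, g_gb = g_gb)
}

#' Two-dimensional discrete Fourier transform
#'
#' Unnormalized forward DFT of an image (no `1/N` factor), as used by the
#' frequency loss.
#'
#' @param x A real or complex matrix.
#' @return A complex matrix of the same shape.
#' @export
fft2 <- function(x) stats::fft(x)

freq_pair <- function(target, generated) {
  D <- stats::fft(generated) - stats::fft(target)
  mean(Mod(D))
}

freq_pair_grad <- function(target, generated) {
  D <- stats::fft(generated) - stats::fft(target)
  md <- Mod(D)
  u <- ifelse(md == 0, 0 + 0i, Conj(D) / md)
  list(value = mean(md), g = Re(stats::fft(u)) / length(D))
}

#' Frequency-domain L1 loss
#'
#' Mean over frequency bins of the complex modulus of the difference between
#' the 2D FFT spectra of generated and target images, batch-averaged over
#' both translation directions.
#'
#' @inheritParams ssim_loss
#' @return Nonnegative scalar; zero iff the images are equal.
#' @export
frequency_loss <- function(w, ga_s, s, gb_w) {
  loss_pair_mean(w, ga_s, freq_pair, "frequency_loss") +
    loss_pair_mean(s, gb_w, freq_pair, "frequency_loss")
}

#' @rdname frequency_loss
#' @export
frequency_loss_grad <- function(w, ga_s, s, gb_w) {
  w <- as_image_list(w); ga_s <- as_image_list(ga_s)
  s <- as_image_list(s); gb_w <- as_image_list(gb_w)
  na <- length(w); nb <- length(s)
  val <- 0
  g_ga <- vector("list", na); g_gb <- vector("list", nb)
  for (i in seq_len(na)) {
    fg <- freq_pair_grad(w[[i]], ga_s[[i]])
    val <- val + fg$value / na
    g_ga[[i]] <- fg$g / na
  }
  for (i in seq_len(nb)) {
    fg <- freq_pair_grad(s[[i]], gb_w[[i]])
    val <- val + fg$value / nb
    g_gb[[i]] <- fg$g / nb
  }
  list(value = val, g_ga = g_ga, g_gb = g_gb)
}

#' Pixel L1 loss
#'
#' Mean absolute pixel difference between generated and target images,
#' batch-averaged over both translation directions.
#'
#' @inheritParams ssim_loss
#' @return Nonnegative scalar.
#' @export
l1_loss <- function(w, ga_s, s, gb_w) {
  loss_pair_mean(w, ga_s, function(a, b) mean(abs(b - a)), "l1_loss") +
    loss_pair_mean(s, gb_w, function(a, b) mean(abs(b - a)), "l1_loss")
}

#' @rdname l1_loss
#' @export
l1_loss_grad <- function(w, ga_s, s, gb_w) {
  w <- as_image_list(w); ga_s <- as_image_list(ga_s)
  s <- as_image_list(s); gb_w <- as_image_list(gb_w)
  na <- length(w); nb <- length(s)
  val <- 0
  g_ga <- vector("list", na); g_gb <- vector("list", nb)
  for (i in seq_len(na)) {
    d <- ga_s[[i]] - w[[i]]
    val <- val + mean(abs(d)) / na
    g_ga[[i]] <- sign(d) / (length(d) * na)
  }
  for (i in seq_len(nb)) {
    d <- gb_w[[i]] - s[[i]]
    val <- val + mean(abs(d)) / nb
    g_gb[[i]] <- sign(d) / (length(d) * nb)
  }
  list(value = val, g_ga = g_ga, g_gb = g_gb)
}

check_scores <- function(x, what) {
  v <- unlist(lapply(as_image_list(x, what), as.numeric))
  if (any(v <= 0 | v >= 1))
    stop(what, " contains scores outside (0,1); ",
         "discriminator outputs must pass through a sigmoid")
  v
}

#' Adversarial log-likelihood
#'
#' The GAN minimax value
#' `E[log DA(w)] + E[log(1 - DA(GA(s)))] + E[log DB(s)] + E[log(1 - DB(GB(w)))]`,
#' each expectation taken as the mean over patch-score maps and batch.
#' Discriminators ascend this value; generators are trained with the
#' non-saturating surrogate (see the training loop), while this quantity is
#' the reported adversarial term.
#'
#' @param da_real,da_fake Discriminator-A patch scores on real clean images
#'   and on generator-A outputs (matrices, lists, or arrays, values in (0,1)).
#' @param db_real,db_fake Discriminator-B patch scores on real artifact
#'   images and on generator-B outputs.
#' @return A scalar in `(-Inf, 0)`.
#' @export
adversarial_loss <- function(da_real, da_fake, db_real, db_fake) {
  mean(log(check_scores(da_real, "da_real"))) +
    mean(log1p(-check_scores(da_fake, "da_fake"))) +
    mean(log(check_scores(db_real, "db_real"))) +
    mean(log1p(-check_scores(db_fake, "db_fake")))
}

#' Cycle-reconstruction loss
#'
#' `E_S[|GB(GA(s)) - s|] + E_W[|GA(GB(w)) - w|]`: mean absolute error of the
#' round-trip translations.
#'
#' @param s Artifact-domain originals.
#' @param gb_ga_s Round trip `GB(GA(s))`.
#' @param w Clean-domain originals.
#' @param ga_gb_w Round trip `GA(GB(w))`.
#' @return Nonnegative scalar; zero iff both cycles are identities.
#' @export
reconstruction_loss <- function(s, gb_ga_s, w, ga_gb_w) {
  loss_pair_mean(s, gb_ga_s, function(a, b) mean(abs(b - a)), "reconstruction_loss") +
    loss_pair_mean(w, ga_gb_w, function(a, b) mean(abs(b - a)), "reconstruction_loss")
}

#' Loss weights
#'
#' Tradeoff parameters of the total objective; the defaults are
#' (SSIM, frequency, L1, adversarial, reconstruction) = (50, 1, 100, 1, 1).
#' Setting a weight to 0 reproduces the corresponding ablation (e.g.
#' `frequency = 0` trains without the frequency term).
#'
#' @param ssim,frequency,l1,adversarial,reconstruction Nonnegative weights.
#' @return An object of class `"loss_weights"`.
#' @export
loss_weights <- function(ssim = 50, frequency = 1, l1 = 100,
                         adversarial = 1, reconstruction = 1) {
  w <- c(ssim = ssim, frequency = frequency, l1 = l1,
         adversarial = adversarial, reconstruction = reconstruction)
  if (any(w < 0) || any(!is.finite(w))) stop("loss weights must be finite and >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Weighted total loss
#'
#' Combines the five loss terms into the training objective
#' `total = sum(lambda_i * term_i)` and retains each term for logging and
#' ablation analysis.
#'
#' @param terms Named list (or individual arguments) with elements `ssim`,
#'   `frequency`, `l1`, `adversarial`, `reconstruction`.
#' @param weights A [loss_weights()].
#' @return An object of class `"loss_report"`: the per-term values, the
#'   weights, and `total`.
#' @export
total_loss <- function(terms, weights = loss_weights()) {
  need <- c("ssim", "frequency", "l1", "adversarial", "reconstruction")
  if (!all(need %in% names(terms)))
    stop("terms must contain: ", paste(need, collapse = ", "))
  for (nm in need) {
    if (!is.finite(terms[[nm]]))
      stop("non-finite loss term: ", nm, " = ", terms[[nm]])
  }
  total <- sum(vapply(need, function(nm) weights[[nm]] * terms[[nm]], 0))
  structure(list(terms = terms[need], weights = weights, total = total),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat("Loss report\n")
  for (nm in names(x$terms))
    cat(sprintf("  %-15s %12.6f  (weight %g)\n", nm, x$terms[[nm]],
                x$weights[[nm]]))
  cat(sprintf("  %-15s %12.6f\n", "total", x$total))
  invisible(x)
}
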