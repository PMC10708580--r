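# Shared fixtures and independent oracles used across the suite.

# Naive O(N^4) double-sum DFT, the independent oracle for fft2().
naive_dft <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0 + 0i, n, m)
  for (u in 0:(n - 1)) {
    for (v in 0:(m - 1)) {
      acc <- 0 + 0i
      for (p in 0:(n - 1)) {
        for (q in 0:(m - 1)) {
          acc <- acc + x[p + 1, q + 1] *
            exp(-2i * pi * (u * p / n + v * q / m))
        }
      }
      out[u + 1, v + 1] <- acc
    }
  }
  out
}

# From-scratch frequency-loss reimplementation (naive DFT + per-bin modulus).
naive_frequency_loss <- function(w, ga_s, s, gb_w) {
  mean(Mod(naive_dft(ga_s) - naive_dft(w))) +
    mean(Mod(naive_dft(gb_w) - naive_dft(s)))
}

# Central finite-difference gradient of f at x (matrix), at selected indices.
numeric_grad <- function(f, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}

# A small noiseless phantom for deterministic image fixtures.
tiny_phantom <- function(size = 64, tilt = 0, seed = 0, speckle = 0) {
  generate_phantom(phantom_params(size, size, tilt_deg = tilt, seed = seed,
                                  speckle_strength = speckle))
}

# A 4-image paired batch at the given size (used by training tests).
phantom_batch <- function(size = 64, n = 4, width_range = c(6L, 12L),
                          seed = 0) {
  scenes <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_params(size, size, tilt_deg = (i - (n + 1) / 2) * 4,
                                    seed = seed + i)))
  masks <- lapply(seq_len(n), function(i)
    sample_mask(mask_params(width_range, seed = seed + 100L + i), c(size, size)))
  list(s = mapply(function(sc, m) corrupt(sc$image, m)$artifact_image,
                  scenes, masks, SIMPLIFY = FALSE),
       w = lapply(scenes, `[[`, "image"),
       m = masks,
       scenes = scenes)
}

# Small train config used by training and acceptance tests.
small_config <- function(size = 64, steps = 10, seed = 1, ...) {
  train_config(image_size = size, base_channels = 16, max_channels = 128,
               disc_base_channels = 16, steps = steps, seed = seed, ...)
}
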