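# Dual-GAN network definitions: two U-Net generators mapping between the
# artifact (S) and artifact-free (W) image domains, and two 70x70 PatchGAN
# discriminators.  Generators use a pre-activation block layout: the encoder
# is Conv, then Relu-Conv-LayerNorm blocks, then a Relu-Conv bottleneck; the
# decoder is Relu-ConvTranspose-BatchNorm-Dropout blocks followed by a
# Relu-ConvTranspose-Tanh head, with skip connections pairing encoder stage k
# to decoder stage depth - k.

#' Generator architecture specification
#'
#' Describes a U-Net generator: `depth` encoder stages (4x4 convolutions with
#' stride 2, so each stage halves the spatial size) mirrored by `depth`
#' transposed-convolution decoder stages with skip connections.  The default
#' depth of 8 bottoms out at 1x1 for 256x256 inputs.  For smaller test images
#' of side `2^d < 256` the depth is auto-reduced to `d` so the bottleneck is
#' still 1x1 (`auto_depth = TRUE`).
#'
#' @param size Input image side length in pixels (a power of two, >= 32).
#' @param base_channels Channel count of the first encoder stage; later
#'   stages double it, capped at `max_channels`.
#' @param max_channels Channel cap for deep stages.
#' @param depth Number of encoder (= decoder) stages; `NULL` picks
#'   `min(8, log2(size))`.
#' @param dropout Dropout rate applied in every decoder
#'   Relu-ConvTranspose-BatchNorm-Dropout block.
#' @param auto_depth Reduce depth automatically for small images.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(size = 256, base_channels = 64, max_channels = 512,
                           depth = NULL, dropout = 0.5, auto_depth = TRUE) {
  if (size < 32 || bitwAnd(size, size - 1L) != 0)
    stop("image size must be a power of two >= 32")
  d_max <- as.integer(round(log2(size)))
  if (is.null(depth)) depth <- min(8L, d_max)
  depth <- as.integer(depth)
  if (2^depth > size) {
    if (auto_depth) depth <- d_max
    else stop("image of side ", size, " is smaller than 2^depth; ",
              "enable auto_depth or reduce depth")
  }
  channels <- pmin(base_channels * 2^(seq_len(depth) - 1), max_channels)
  structure(list(size = as.integer(size), depth = depth,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 channels = as.integer(channels), kernel = 4L,
                 dropout = dropout),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A PatchGAN: five 4x4 convolution stages (Conv-LeakyRelu, three
#' Conv-BatchNorm-LeakyRelu, Conv-Sigmoid).  With the default stride
#' schedule (2, 2, 2, 1, 1) and padding 1 the receptive field of one output
#' unit is 70x70 input pixels.
#'
#' @param base_channels Channels of the first stage; stages double up to 8x.
#' @param kernel Square kernel side (default 4).
#' @param strides Integer vector of per-layer strides.
#' @param padding Zero padding applied by every layer.
#' @param lrelu_slope Negative slope of the LeakyReLU activations.
#' @return An object of class `"discriminator_spec"`.
#' @export
discriminator_spec <- function(base_channels = 64, kernel = 4L,
                               strides = c(2L, 2L, 2L, 1L, 1L), padding = 1L,
                               lrelu_slope = 0.2) {
  n <- length(strides)
  mult <- pmin(2^(seq_len(n - 1) - 1), 8L)
  channels <- c(as.integer(base_channels * mult), 1L)
  structure(list(base_channels = as.integer(base_channels),
                 kernel = as.integer(kernel), strides = as.integer(strides),
                 padding = as.integer(padding), channels = channels,
                 lrelu_slope = lrelu_slope),
            class = "discriminator_spec")
}

#' Receptive field of a patch discriminator
#'
#' Side length in input pixels of the region influencing one output unit,
#' by the standard recursion `r_k = r_{k-1} + (kernel - 1) * prod(strides
#' before layer k)`.
#'
#' @param spec A [discriminator_spec()].
#' @return Receptive-field side length in pixels.
#' @export
receptive_field <- function(spec) {
  r <- 1
  jump <- 1
  for (s in spec$strides) {
    r <- r + (spec$kernel - 1) * jump
    jump <- jump * s
  }
  as.integer(r)
}

#' Build a U-Net generator
#'
#' Initializes all convolution weights from a zero-mean Gaussian (sd 0.02)
#' under the given seed; two builds with the same seed are identical.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"dg_generator"`; apply it to images with
#'   [generator_apply()].
#' @export
build_generator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth; ch <- spec$channels; k <- spec$kernel
  params <- with_seed(seed, {
    enc <- vector("list", d)
    enc[[1]] <- init_conv(ch[1], 1L, k)
    for (i in 2:d) {
      enc[[i]] <- init_conv(ch[i], ch[i - 1], k)
      if (i < d) enc[[i]]$ln <- init_norm_params(ch[i])
    }
    dec <- vector("list", d)
    for (i in seq_len(d)) {
      c_in <- if (i == 1) ch[d] else 2L * ch[d - i + 1]
      c_out <- if (i == d) 1L else ch[d - i]
      dec[[i]] <- init_convt(c_in, c_out, k)
      if (i < d) dec[[i]]$bn <- init_norm_params(c_out)
    }
    list(enc = enc, dec = dec)
  })
  structure(list(spec = spec, params = params, seed = seed),
            class = "dg_generator")
}

# Forward pass over an [N,1,H,W] array in network space [-1,1].
# Returns list(y, cache); cache = NULL computation is not retained when
# retain = FALSE (inference).
unet_forward <- function(gen, x, train = FALSE, retain = train) {
  spec <- gen$spec; p <- gen$params
  d <- spec$depth
  e <- vector("list", d)
  caches <- list(enc = vector("list", d), dec = vector("list", d))
  cf <- conv_forward(x, p$enc[[1]], 2L, 1L)
  e[[1]] <- cf$y
  caches$enc[[1]] <- list(conv = cf$cache)
  for (i in 2:d) {
    rf <- relu_forward(e[[i - 1]])
    cf <- conv_forward(rf$y, p$enc[[i]], 2L, 1L)
    st <- list(relu = rf$cache, conv = cf$cache)
    h <- cf$y
    if (i < d) {
      lf <- layernorm_forward(h, p$enc[[i]]$ln)
      h <- lf$y
      st$ln <- lf$cache
    }
    e[[i]] <- h
    caches$enc[[i]] <- st
  }
  h <- e[[d]]
  bn_updates <- vector("list", d)
  for (i in seq_len(d)) {
    rf <- relu_forward(h)
    cf <- convt_forward(rf$y, p$dec[[i]], 2L, 1L)
    st <- list(relu = rf$cache, conv = cf$cache)
    h <- cf$y
    if (i < d) {
      bf <- batchnorm_forward(h, p$dec[[i]]$bn, train)
      h <- bf$y
      st$bn <- bf$cache
      bn_updates[[i]] <- bf$p
      df <- dropout_forward(h, spec$dropout, train)
      h <- df$y
      st$drop <- df$cache
      st$skip_channels <- dim(h)[2]
      h <- concat_channels(h, e[[d - i]])
    } else {
      tf <- tanh_forward(h)
      h <- tf$y
      st$tanh <- tf$cache
    }
    caches$dec[[i]] <- st
  }
  list(y = h,
       cache = if (retain) caches else NULL,
       bn_updates = bn_updates)
}

# Backward pass; returns list(gx, grads) with grads mirroring gen$params.
unet_backward <- function(gen, cache, gy) {
  spec <- gen$spec; p <- gen$params
  d <- spec$depth
  genc <- vector("list", d)  # grads flowing into encoder outputs e[[k]]
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  g <- gy
  for (i in rev(seq_len(d))) {
    st <- cache$dec[[i]]
    if (i < d) {
      sp <- split_channels(g, st$skip_channels)
      g <- sp$a
      genc[[d - i]] <- if (is.null(genc[[d - i]])) sp$b else genc[[d - i]] + sp$b
      g <- dropout_backward(st$drop, g)
      bb <- batchnorm_backward(p$dec[[i]]$bn, st$bn, g)
      g <- bb$gx
      grads$dec[[i]]$bn <- bb$grads
    } else {
      g <- tanh_backward(st$tanh, g)
    }
    cb <- convt_backward(p$dec[[i]], st$conv, g)
    grads$dec[[i]]$W <- cb$grads$W
    grads$dec[[i]]$b <- cb$grads$b
    g <- relu_backward(st$relu, cb$gx)
    if (i == 1) genc[[d]] <- if (is.null(genc[[d]])) g else genc[[d]] + g
  }
  g <- genc[[d]]
  for (i in rev(seq_len(d))) {
    st <- cache$enc[[i]]
    if (i > 1 && i < d) {
      lb <- layernorm_backward(p$enc[[i]]$ln, st$ln, g)
      g <- lb$gx
      grads$enc[[i]]$ln <- lb$grads
    }
    cb <- conv_backward(p$enc[[i]], st$conv, g)
    grads$enc[[i]]$W <- cb$grads$W
    grads$enc[[i]]$b <- cb$grads$b
    g <- cb$gx
    if (i > 1) {
      g <- relu_backward(st$relu, g)
      if (!is.null(genc[[i - 1]])) g <- g + genc[[i - 1]]
    }
  }
  list(gx = g, grads = grads)
}

#' Apply a generator to images
#'
#' Maps images in network space `[-1, 1]` to images in `[-1, 1]` of the same
#' shape (inference mode: dropout off, batch-norm running statistics).
#'
#' @param gen A generator from [build_generator()].
#' @param x A matrix, list of matrices, or `[N,1,H,W]` array in `[-1, 1]`.
#' @return Same container shape as the input.
#' @export
generator_apply <- function(gen, x) {
  was_matrix <- is.matrix(x)
  xb <- if (is.matrix(x) || is.list(x)) stack_batch(if (is.list(x)) x else list(x)) else x
  if (dim(xb)[3] %% 2^gen$spec$depth != 0)
    stop("input side must be divisible by 2^depth = ", 2^gen$spec$depth)
  y <- unet_forward(gen, xb, train = FALSE, retain = FALSE)$y
  if (was_matrix) unstack_batch(y)[[1]] else if (is.list(x)) unstack_batch(y) else y
}

#' Build a PatchGAN discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `"dg_discriminator"`.
#' @export
build_discriminator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  nl <- length(spec$strides)
  ch <- spec$channels; k <- spec$kernel
  params <- with_seed(seed, {
    layers <- vector("list", nl)
    c_prev <- 1L
    for (i in seq_len(nl)) {
      layers[[i]] <- init_conv(ch[i], c_prev, k)
      if (i > 1 && i < nl) layers[[i]]$bn <- init_norm_params(ch[i])
      c_prev <- ch[i]
    }
    layers
  })
  structure(list(spec = spec, params = params, seed = seed),
            class = "dg_discriminator")
}

# Forward pass to patch logits; scores = sigmoid(logits) in (0,1).
disc_forward <- function(disc, x, train = FALSE, retain = train) {
  spec <- disc$spec; p <- disc$params
  nl <- length(spec$strides)
  caches <- vector("list", nl)
  h <- x
  bn_updates <- vector("list", nl)
  for (i in seq_len(nl)) {
    cf <- conv_forward(h, p[[i]], spec$strides[i], spec$padding)
    st <- list(conv = cf$cache)
    h <- cf$y
    if (i < nl) {
      if (i > 1) {
        bf <- batchnorm_forward(h, p[[i]]$bn, train)
        h <- bf$y
        st$bn <- bf$cache
        bn_updates[[i]] <- bf$p
      }
      lf <- lrelu_forward(h, spec$lrelu_slope)
      h <- lf$y
      st$lrelu <- lf$cache
    }
    caches[[i]] <- st
  }
  list(logits = h, scores = sigmoid(h),
       cache = if (retain) caches else NULL,
       bn_updates = bn_updates)
}

# Backward from a gradient w.r.t. logits.
disc_backward <- function(disc, cache, glogits) {
  spec <- disc$spec; p <- disc$params
  nl <- length(spec$strides)
  grads <- vector("list", nl)
  g <- glogits
  for (i in rev(seq_len(nl))) {
    st <- cache[[i]]
    if (i < nl) {
      g <- lrelu_backward(st$lrelu, g)
      if (i > 1) {
        bb <- batchnorm_backward(p[[i]]$bn, st$bn, g)
        g <- bb$gx
        grads[[i]]$bn <- bb$grads
      }
    }
    cb <- conv_backward(p[[i]], st$conv, g)
    grads[[i]]$W <- cb$grads$W
    grads[[i]]$b <- cb$grads$b
    g <- cb$gx
  }
  list(gx = g, grads = grads)
}

#' Apply a discriminator to images
#'
#' @param disc A discriminator from [build_discriminator()].
#' @param x A matrix, list of matrices, or `[N,1,H,W]` array in `[-1, 1]`.
#' @return Patch score map(s) with values in (0, 1), same container shape.
#' @export
discriminator_apply <- function(disc, x) {
  was_matrix <- is.matrix(x)
  xb <- if (is.matrix(x) || is.list(x)) stack_batch(if (is.list(x)) x else list(x)) else x
  s <- disc_forward(disc, xb, train = FALSE, retain = FALSE)$scores
  if (was_matrix) unstack_batch(s)[[1]] else if (is.list(x)) unstack_batch(s) else s
}

#' Mask-composite of a generated image into the artifact image
#'
#' `composite(s, m, s_hat) = s * (1 - m) + s_hat * m`: the artifact image is
#' replaced by the generated content only inside the repair region, so every
#' pixel with `m = 0` is bit-identical to `s`.
#'
#' @param s Artifact image (matrix).
#' @param m Binary artifact mask (matrix, 1 = repair region).
#' @param s_hat Generated image (matrix, same shape).
#' @return The composited image.
#' @export
composite <- function(s, m, s_hat) {
  check_same_shape(s, m, "composite(s, m)")
  check_same_shape(s, s_hat, "composite(s, s_hat)")
  s * (1 - m) + s_hat * m
}

#' Empirical receptive field by gradient footprint
#'
#' Builds a discriminator with strictly positive weights, backpropagates a
#' unit gradient from one central output unit, and measures the side length
#' of the input region with a nonzero gradient.  Agrees with
#' [receptive_field()] whenever the input is large enough to contain the
#' full footprint.
#'
#' @param spec A [discriminator_spec()].
#' @param input_size Input side length in pixels.
#' @param seed Seed for the probe weights.
#' @return Footprint side length in pixels (max over rows/columns).
#' @export
receptive_field_empirical <- function(spec, input_size = 128L, seed = 0L) {
  disc <- build_discriminator(spec, seed)
  # strictly positive weights so contributions cannot cancel
  for (i in seq_along(disc$params)) {
    disc$params[[i]]$W <- abs(disc$params[[i]]$W) + 1e-3
  }
  x <- array(0.1, dim = c(1L, 1L, input_size, input_size))
  fw <- disc_forward(disc, x, train = FALSE, retain = TRUE)
  d <- dim(fw$logits)
  g <- array(0, dim = d)
  g[1, 1, (d[3] + 1) %/% 2, (d[4] + 1) %/% 2] <- 1
  gx <- disc_backward(disc, fw$cache, g)$gx
  support <- abs(gx[1, 1, , ]) > 0
  rows <- which(apply(support, 1, any))
  cols <- which(apply(support, 2, any))
  as.integer(max(diff(range(rows)), diff(range(cols))) + 1L)
}
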