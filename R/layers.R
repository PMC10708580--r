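# Primitive network layers with explicit forward/backward passes.
# Each forward returns list(y, cache); each backward takes (cache, gy) and
# returns list(gx, grads) where grads mirrors the layer's parameter list.
# Convolutions run through the compiled kernels in src/conv_ops.cpp.

conv_out_size <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

init_conv <- function(c_out, c_in, k, sd = 0.02) {
  list(W = array(stats::rnorm(c_out * c_in * k * k, 0, sd),
                 dim = c(c_out, c_in, k, k)),
       b = numeric(c_out))
}

# Transposed-conv weights are stored [C_in, C_out, k, k].
init_convt <- function(c_in, c_out, k, sd = 0.02) {
  list(W = array(stats::rnorm(c_in * c_out * k * k, 0, sd),
                 dim = c(c_in, c_out, k, k)),
       b = numeric(c_out))
}

conv_forward <- function(x, p, stride, pad) {
  y <- conv_fwd(x, p$W, p$b, stride, pad)
  list(y = y, cache = list(x = x, stride = stride, pad = pad,
                           kh = dim(p$W)[3], kw = dim(p$W)[4]))
}

conv_backward <- function(p, cache, gy) {
  gwb <- conv_grad_wb(cache$x, gy, cache$kh, cache$kw, cache$stride, cache$pad)
  gx <- conv_grad_input(gy, p$W, cache$stride, cache$pad,
                        dim(cache$x)[3], dim(cache$x)[4])
  list(gx = gx, grads = list(W = gwb$gw, b = gwb$gb))
}

convt_forward <- function(x, p, stride, pad) {
  d <- dim(x); k <- dim(p$W)[3]
  h_out <- (d[3] - 1) * stride - 2 * pad + k
  w_out <- (d[4] - 1) * stride - 2 * pad + k
  y <- conv_grad_input(x, p$W, stride, pad, h_out, w_out)
  c_out <- dim(p$W)[2]
  y <- y + array(rep(p$b, each = d[1]), dim = c(d[1], c_out, h_out, w_out))
  list(y = y, cache = list(x = x, stride = stride, pad = pad, k = k))
}

convt_backward <- function(p, cache, gy) {
  # input grad: correlate gy with W read as [C_in -> out channels]
  gx <- conv_fwd(gy, p$W, numeric(0), cache$stride, cache$pad)
  gwb <- conv_grad_wb(gy, cache$x, cache$k, cache$k, cache$stride, cache$pad)
  gb <- channel_sums(gy, dim(gy))
  list(gx = gx, grads = list(W = gwb$gw, b = gb))
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}
relu_backward <- function(cache, gy) gy * cache

lrelu_forward <- function(x, slope = 0.2) {
  mask <- (x > 0) * 1
  scale <- mask + slope * (1 - mask)
  list(y = x * scale, cache = scale)
}
lrelu_backward <- function(cache, gy) gy * cache

tanh_forward <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}
tanh_backward <- function(cache, gy) gy * (1 - cache^2)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-sample means over (C,H,W): length-N vector.
sample_means <- function(x, d) .rowMeans(x, d[1], d[2] * d[3] * d[4])

# Per-channel sums over (N,H,W): length-C vector.
channel_sums <- function(x, d) {
  rs <- .rowSums(x, d[1] * d[2], d[3] * d[4])
  .colSums(rs, d[1], d[2])
}

# Broadcast a per-sample vector (length N) over an [N,C,H,W] shape.
bcast_n <- function(v, d) array(v, dim = d)

# Broadcast a per-channel vector (length C) over an [N,C,H,W] shape.
bcast_c <- function(v, d) array(rep(v, each = d[1]), dim = d)

# Layer normalization over (C, H, W) per sample, per-channel affine.
layernorm_forward <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  mu <- sample_means(x, d)
  xc <- x - bcast_n(mu, d)
  sd_ <- sqrt(sample_means(xc * xc, d) + eps)
  xhat <- xc / bcast_n(sd_, d)
  list(y = xhat * bcast_c(p$gamma, d) + bcast_c(p$beta, d),
       cache = list(xhat = xhat, sd = sd_, d = d))
}

layernorm_backward <- function(p, cache, gy) {
  d <- cache$d
  xhat <- cache$xhat
  gxhat <- gy * bcast_c(p$gamma, d)
  m1 <- sample_means(gxhat, d)
  m2 <- sample_means(gxhat * xhat, d)
  gx <- (gxhat - bcast_n(m1, d) - xhat * bcast_n(m2, d)) / bcast_n(cache$sd, d)
  list(gx = gx, grads = list(gamma = channel_sums(gy * xhat, d),
                             beta = channel_sums(gy, d)))
}

# Batch normalization per channel over (N, H, W); running stats for eval.
batchnorm_forward <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[3] * d[4]
  if (train) {
    mu <- channel_sums(x, d) / m
    xc <- x - bcast_c(mu, d)
    v <- channel_sums(xc * xc, d) / m
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * v
  } else {
    mu <- p$run_mean
    v <- p$run_var
    xc <- x - bcast_c(mu, d)
  }
  sd_ <- sqrt(v + eps)
  xhat <- xc / bcast_c(sd_, d)
  list(y = xhat * bcast_c(p$gamma, d) + bcast_c(p$beta, d),
       cache = list(xhat = xhat, sd = sd_, d = d, train = train),
       p = p)
}

batchnorm_backward <- function(p, cache, gy) {
  d <- cache$d
  m <- d[1] * d[3] * d[4]
  xhat <- cache$xhat
  gxhat <- gy * bcast_c(p$gamma, d)
  if (cache$train) {
    m1 <- channel_sums(gxhat, d) / m
    m2 <- channel_sums(gxhat * xhat, d) / m
    gx <- (gxhat - bcast_c(m1, d) - xhat * bcast_c(m2, d)) / bcast_c(cache$sd, d)
  } else {
    gx <- gxhat / bcast_c(cache$sd, d)
  }
  list(gx = gx, grads = list(gamma = channel_sums(gy * xhat, d),
                             beta = channel_sums(gy, d)))
}

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  mask <- array(as.numeric(stats::runif(length(x)) < keep) / keep, dim = dim(x))
  list(y = x * mask, cache = mask)
}
dropout_backward <- function(cache, gy) if (is.null(cache)) gy else gy * cache

init_norm_params <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}
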