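# Internal tensor plumbing.  Batches are 4D arrays dim c(N, C, H, W);
# single images are H x W matrices with values in [0, 1] (storage space)
# or [-1, 1] (network space).

#' @useDynLib stripefill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# storage [0,1] <-> network [-1,1]
to_net <- function(x) 2 * x - 1
to_store <- function(x) (x + 1) / 2

# Stack a list of H x W matrices into an [N, 1, H, W] array.
stack_batch <- function(imgs) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  n <- length(imgs)
  out <- array(0, dim = c(n, 1L, h, w))
  for (i in seq_len(n)) {
    m <- imgs[[i]]
    if (nrow(m) != h || ncol(m) != w) stop("images in a batch must share a shape")
    out[i, 1, , ] <- m
  }
  out
}

# Split an [N, 1, H, W] array back into a list of matrices.
unstack_batch <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[1]), function(i) array(x[i, 1, , ], dim = d[3:4]))
}

# Accept a matrix, a 4D array, or a list of matrices; return list of matrices.
as_image_list <- function(x, what = "image") {
  if (is.list(x)) return(x)
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 4L) return(unstack_batch(x))
  stop(what, " must be a matrix, a list of matrices, or an [N,1,H,W] array")
}

check_same_shape <- function(x, y, ctx = "inputs") {
  if (!identical(dim(x), dim(y)))
    stop("shape mismatch in ", ctx, ": ", paste(dim(x), collapse = "x"),
         " vs ", paste(dim(y), collapse = "x"))
  invisible(TRUE)
}

# Channel-wise concatenation of two [N,C,H,W] arrays.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- a
  out[, da[2] + seq_len(db[2]), , ] <- b
  out
}

split_channels <- function(g, c1) {
  d <- dim(g)
  list(a = array(g[, seq_len(c1), , ], dim = c(d[1], c1, d[3], d[4])),
       b = array(g[, c1 + seq_len(d[2] - c1), , ], dim = c(d[1], d[2] - c1, d[3], d[4])))
}
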