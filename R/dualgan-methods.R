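# S3 methods for fitted dual-GAN models.

#' @export
print.dualgan <- function(x, ...) {
  cfg <- x$config
  cat("Dual-GAN saturation-artifact inpainting model\n")
  cat(sprintf("  image size    : %dx%d\n", cfg$image_size, cfg$image_size))
  cat(sprintf("  generators    : U-Net depth %d, base channels %d\n",
              x$state$ga$spec$depth, cfg$base_channels))
  cat(sprintf("  discriminators: PatchGAN, receptive field %d px\n",
              receptive_field(x$state$da$spec)))
  cat(sprintf("  trained steps : %d (batch %d, seed %d)\n",
              x$state$step, cfg$batch_size, cfg$seed))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last total loss: %.4f (l1 %.4f, ssim %.4f)\n",
                last$total, last$l1, last$ssim))
  }
  invisible(x)
}

#' @export
summary.dualgan <- function(object, ...) {
  h <- object$history
  cat("Dual-GAN fit summary\n")
  print(object)
  if (!is.null(h) && nrow(h) > 1) {
    cat("\nLoss trajectory (first vs last logged step):\n")
    for (nm in c("total", "ssim", "frequency", "l1", "reconstruction")) {
      cat(sprintf("  %-15s %10.4f -> %10.4f\n", nm, h[[nm]][1],
                  h[[nm]][nrow(h)]))
    }
    if (!all(is.na(h$da_real))) {
      cat(sprintf("\n  D_A scores (real/fake): %.3f / %.3f\n",
                  h$da_real[nrow(h)], h$da_fake[nrow(h)]))
      cat(sprintf("  D_B scores (real/fake): %.3f / %.3f\n",
                  h$db_real[nrow(h)], h$db_fake[nrow(h)]))
    }
  }
  invisible(object)
}

#' Inpaint with a fitted model
#'
#' `predict(fit, image, mask)` is equivalent to [inpaint()].
#'
#' @param object A fitted [dualgan()] model.
#' @param image Artifact image (matrix in `[0, 1]`).
#' @param mask Binary artifact mask.
#' @param ... Unused.
#' @return The inpainted image.
#' @export
predict.dualgan <- function(object, image, mask, ...) {
  inpaint(image, mask, object)
}

#' @export
coef.dualgan <- function(object, ...) {
  list(ga = object$state$ga$params, gb = object$state$gb$params,
       da = object$state$da$params, db = object$state$db$params)
}

#' Plot the training loss trajectory
#'
#' @param x A fitted [dualgan()] model.
#' @param terms Which logged loss columns to draw.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dualgan <- function(x, terms = c("total", "l1", "ssim"), ...) {
  h <- x$history
  if (is.null(h) || nrow(h) < 2) stop("no training history to plot")
  y <- as.matrix(h[, terms, drop = FALSE])
  graphics::matplot(h$step, y, type = "l", lty = 1,
                    col = seq_along(terms) + 1,
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", legend = terms, lty = 1,
                   col = seq_along(terms) + 1, bty = "n")
  invisible(x)
}
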