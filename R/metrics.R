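# Inpainting quality metrics restricted to the repaired region, and
# segmentation overlap metrics (Dice, pixel accuracy, F1, Jaccard).

#' Region specification for inpainting metrics
#'
#' `"masked"` restricts the comparison to the pixels with mask = 1;
#' `"bbox"` to the bounding box of the mask (needed by windowed SSIM, which
#' requires a 2D neighborhood); `"full"` uses the whole image.
#'
#' @param mode One of `"masked"`, `"bbox"`, `"full"`.
#' @param mask Binary artifact mask (required for the masked modes).
#' @return An object of class `"region_spec"`.
#' @export
region_spec <- function(mode = c("masked", "bbox", "full"), mask = NULL) {
  mode <- match.arg(mode)
  if (mode != "full") {
    if (is.null(mask)) stop("region mode '", mode, "' requires a mask")
    if (sum(mask) == 0) stop("region mode '", mode, "' requires a nonempty mask")
  }
  structure(list(mode = mode, mask = mask), class = "region_spec")
}

region_values <- function(x, region) {
  switch(region$mode,
         full = as.numeric(x),
         masked = x[region$mask == 1],
         bbox = as.numeric(region_crop(x, region)))
}

region_crop <- function(x, region) {
  idx <- which(region$mask == 1, arr.ind = TRUE)
  x[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
}

#' Peak signal-to-noise ratio over a region
#'
#' `10 log10(L^2 / MSE)` over the region's pixels.  A zero MSE (identical
#' inputs) is reported as the cap `cap` dB rather than infinity.
#'
#' @param x,y Images (matrices of the same shape).
#' @param region A [region_spec()] (default: full image).
#' @param dynamic_range Intensity span `L`.
#' @param cap Value reported when MSE = 0.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, region = region_spec("full"), dynamic_range = 1,
                 cap = 100) {
  check_same_shape(x, y, "psnr")
  vx <- region_values(x, region); vy <- region_values(y, region)
  if (length(vx) == 0) stop("empty region in psnr")
  mse <- mean((vx - vy)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(dynamic_range^2 / mse))
}

#' SSIM over a region
#'
#' Reuses the loss-side SSIM machinery.  In `"bbox"` mode the images are
#' cropped to the mask bounding box first; the crop must be at least the
#' window size (use `type = "global"` in `params` for narrow stripes).
#' `"masked"` mode is not defined for a windowed index and is treated as
#' `"bbox"`.
#'
#' @inheritParams psnr
#' @param params An [ssim_params()].
#' @return SSIM scalar.
#' @export
ssim_metric <- function(x, y, region = region_spec("full"),
                        params = ssim_params()) {
  check_same_shape(x, y, "ssim_metric")
  if (region$mode != "full") {
    x <- region_crop(x, region)
    y <- region_crop(y, region)
  }
  ssim(x, y, params)
}

#' Confusion counts of a binary mask pair
#'
#' @param pred,truth Binary matrices of the same shape.
#' @return An object of class `"confusion_counts"`: list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  check_same_shape(pred, truth, "confusion")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("confusion requires binary masks")
  structure(list(TP = sum(pred == 1 & truth == 1),
                 TN = sum(pred == 0 & truth == 0),
                 FP = sum(pred == 1 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Dice similarity coefficient
#'
#' `DSC = 2|X ∩ Y| / (|X| + |Y|)`; defined as 1 when both masks are empty.
#'
#' @inheritParams confusion
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(pred, truth) {
  check_same_shape(pred, truth, "dsc")
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / denom
}

#' Pixel accuracy
#'
#' `PA = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion()] result.
#' @return Scalar in `[0, 1]`.
#' @export
pixel_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("pixel_accuracy of an empty confusion table")
  (counts$TP + counts$TN) / total
}

#' F1 score
#'
#' `F1 = 2 TP / (2 TP + FN + FP)`; algebraically identical to the Dice
#' coefficient of the same mask pair.  Defined as 1 when TP = FP = FN = 0.
#'
#' @inheritParams pixel_accuracy
#' @return Scalar in `[0, 1]`.
#' @export
f1_score <- function(counts) {
  denom <- 2 * counts$TP + counts$FN + counts$FP
  if (denom == 0) return(1)
  2 * counts$TP / denom
}

#' Jaccard index
#'
#' `J = |X ∩ Y| / |X ∪ Y|`; defined as 1 when both masks are empty.
#' Related to Dice by `DSC = 2J / (1 + J)`.
#'
#' @inheritParams confusion
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) {
  check_same_shape(pred, truth, "jaccard")
  uni <- sum(pmax(pred, truth))
  if (uni == 0) return(1)
  sum(pred * truth) / uni
}

#' Recover a boundary curve from an image by thresholding
#'
#' Per column, marks the first (top-down) or last pixel whose intensity
#' exceeds `threshold` — a deliberately simple surface-recovery rule used to
#' probe whether inpainting restores a traceable corneal boundary.
#'
#' @param image Matrix in `[0, 1]`.
#' @param threshold Intensity threshold.
#' @param from `"top"` (anterior surface) or `"bottom"` (posterior surface).
#' @return A binary matrix with at most one marked pixel per column.
#' @export
boundary_from_image <- function(image, threshold = 0.3,
                                from = c("top", "bottom")) {
  from <- match.arg(from)
  m <- matrix(0, nrow(image), ncol(image))
  for (j in seq_len(ncol(image))) {
    hits <- which(image[, j] > threshold)
    if (length(hits) == 0) next
    r <- if (from == "top") hits[1] else hits[length(hits)]
    m[r, j] <- 1
  }
  m
}

# Dilate a binary mask vertically by `tol` pixels (tolerance band around a
# 1-pixel boundary curve).
dilate_rows <- function(mask, tol) {
  if (tol <= 0) return(mask)
  out <- mask
  for (k in seq_len(tol)) {
    h <- nrow(mask)
    up <- rbind(mask[-seq_len(k), , drop = FALSE],
                matrix(0, k, ncol(mask)))
    dn <- rbind(matrix(0, k, ncol(mask)),
                mask[seq_len(h - k), , drop = FALSE])
    out <- pmax(out, up, dn)
  }
  out
}

#' Boundary-curve overlap metrics with a row tolerance
#'
#' Compares two 1-pixel-wide boundary curves after dilating both vertically
#' by `tolerance` pixels, then computes Dice, pixel accuracy, F1 and
#' Jaccard.  `tolerance = 0` is the strict pixel-wise comparison.
#'
#' @param pred,truth Binary boundary masks.
#' @param tolerance Vertical dilation in pixels applied to both masks.
#' @return Named list with `dsc`, `pa`, `f1`, `jaccard`.
#' @export
segmentation_metrics <- function(pred, truth, tolerance = 0) {
  p <- dilate_rows(pred, tolerance)
  t <- dilate_rows(truth, tolerance)
  cc <- confusion(p, t)
  list(dsc = dsc(p, t), pa = pixel_accuracy(cc), f1 = f1_score(cc),
       jaccard = jaccard(p, t))
}

#' Evaluate an inpainter over the test split of a dataset
#'
#' Inpaints every test image and reports per-image and mean masked-region
#' PSNR and mask-bounding-box SSIM.  `model` may be a fitted [dualgan()]
#' object, a checkpoint path, `"identity"` (returns the artifact image —
#' the before-inpainting baseline) or `"oracle"` (returns the clean image).
#'
#' @param manifest Dataset directory or manifest from [read_manifest()].
#' @param model Inpainting model or baseline name.
#' @param split Manifest split to evaluate (default `"test"`).
#' @param ssim_type SSIM window type for the region SSIM (`"global"` is
#'   robust to narrow stripes).
#' @return An object of class `"metrics_report"`: data frame of per-image
#'   metrics with the means as attribute `"means"`.
#' @export
evaluate <- function(manifest, model, split = "test", ssim_type = "global") {
  if (is.character(manifest) && length(manifest) == 1 && dir.exists(manifest))
    manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir")
  rows <- which(manifest$split == split)
  if (length(rows) == 0) stop("manifest has no '", split, "' rows")
  sp <- ssim_params(type = ssim_type)
  out <- vector("list", length(rows))
  failed <- character(0)
  for (k in seq_along(rows)) {
    i <- rows[k]
    paths <- file.path(dir, c(manifest$path_clean[i], manifest$path_artifact[i],
                              manifest$path_mask[i]))
    if (!all(file.exists(paths))) {
      failed <- c(failed, paths[!file.exists(paths)])
      next
    }
    clean <- load_image(paths[1])
    art <- load_image(paths[2])
    mask <- load_mask(paths[3])
    rec <- if (identical(model, "oracle")) clean else
      apply_inpainter(model, art, mask)
    reg <- region_spec("masked", mask)
    bbox <- region_spec("bbox", mask)
    out[[k]] <- data.frame(id = manifest$id[i],
                           psnr = psnr(rec, clean, reg),
                           psnr_before = psnr(art, clean, reg),
                           ssim = ssim_metric(rec, clean, bbox, sp),
                           ssim_before = ssim_metric(art, clean, bbox, sp))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no evaluable rows; missing files: ",
                         paste(failed, collapse = ", "))
  if (length(failed) > 0)
    warning("skipped missing files: ", paste(failed, collapse = ", "))
  structure(out, means = colMeans(out[, -1, drop = FALSE]),
            failed = failed, class = c("metrics_report", "data.frame"))
}

apply_inpainter <- function(model, image, mask) {
  if (is.character(model)) {
    if (model == "identity") return(image)
    model <- load_checkpoint(model)
  }
  inpaint(image, mask, model)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Inpainting metrics over", nrow(x), "images\n")
  m <- attr(x, "means")
  for (nm in names(m)) cat(sprintf("  mean %-12s %8.4f\n", nm, m[[nm]]))
  invisible(x)
}
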