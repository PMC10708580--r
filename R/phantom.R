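# Synthetic corneal phantom: a bright multilayer corneal arc over a dark
# background with multiplicative speckle, plus the stripe-mask corruption
# protocol that emulates saturation artifacts.  The phantom stands in for
# clinical AS-OCT B-scans, which are not publicly available; it reproduces
# the statistical structure the inpainting task needs (tilted bright arc,
# three layer boundaries, speckle, dark background), not acquisition physics.

#' Phantom scene parameters
#'
#' The cornea is modelled as a circular arc: pixels whose distance to the
#' arc's center falls within three consecutive radial bands are assigned the
#' epithelium, Bowman's-layer and stroma-to-endothelium intensities.  Tilt
#' rotates the whole arc about the image center.  Speckle is multiplicative:
#' `image = clean * (1 + strength * g)` with `g` standard normal, clipped to
#' `[0, 1]`.
#'
#' @param height,width Image size in pixels.
#' @param tilt_deg Signed arc rotation about the image center, degrees.
#' @param arc_radius Radius of the anterior corneal surface, pixels;
#'   defaults to `1.1 * width`.
#' @param layer_thicknesses Radial thickness in pixels of the epithelium,
#'   Bowman's-layer and stroma-to-endothelium bands (anterior to posterior).
#' @param layer_intensities Band intensities in `[0, 1]`, same order.
#' @param background_level Background intensity in `[0, 1]`.
#' @param speckle_strength Multiplicative speckle standard deviation
#'   (dimensionless, >= 0).
#' @param apex_frac Row of the arc apex as a fraction of the image height.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical scenes.
#' @return An object of class `"phantom_params"`.
#' @export
phantom_params <- function(height = 256L, width = 256L, tilt_deg = 0,
                           arc_radius = NULL,
                           layer_thicknesses = NULL,
                           layer_intensities = c(0.65, 0.85, 0.45),
                           background_level = 0.05,
                           speckle_strength = 0.25,
                           apex_frac = 0.18, seed = 0L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height <= 0 || width <= 0) stop("height and width must be positive")
  if (is.null(arc_radius)) arc_radius <- round(1.1 * width)
  if (is.null(layer_thicknesses))
    layer_thicknesses <- pmax(1L, round(height * c(0.031, 0.02, 0.105)))
  if (length(layer_thicknesses) != 3L || any(layer_thicknesses < 1))
    stop("layer_thicknesses must be three positive pixel counts")
  if (sum(layer_thicknesses) >= height)
    stop("layer thicknesses must sum to less than the image height")
  if (length(layer_intensities) != 3L ||
      any(layer_intensities < 0 | layer_intensities > 1))
    stop("layer_intensities must be three values in [0,1]")
  if (background_level < 0 || background_level > 1)
    stop("background_level must be in [0,1]")
  if (speckle_strength < 0) stop("speckle_strength must be >= 0")
  structure(list(height = height, width = width, tilt_deg = tilt_deg,
                 arc_radius = arc_radius,
                 layer_thicknesses = as.numeric(layer_thicknesses),
                 layer_intensities = layer_intensities,
                 background_level = background_level,
                 speckle_strength = speckle_strength,
                 apex_frac = apex_frac, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a corneal phantom scene
#'
#' Renders the artifact-free image together with three 1-pixel-wide boundary
#' label masks: EP (anterior epithelium surface), BL (posterior surface of
#' Bowman's layer) and EN (posterior endothelium surface).  Each boundary
#' mask has exactly one marked pixel per column where that boundary crosses
#' the frame; in every such column the rows are ordered EP < BL < EN.
#'
#' @param params A [phantom_params()].
#' @return An object of class `"phantom_scene"`: list with `image` (matrix
#'   in `[0, 1]`), `boundaries` (list of binary matrices `EP`, `BL`, `EN`)
#'   and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  h <- params$height; w <- params$width
  R <- params$arc_radius
  t <- params$layer_thicknesses
  # circle center before tilt: apex on the vertical midline
  apex_row <- params$apex_frac * (h - 1)
  cx0 <- (w - 1) / 2
  cy0 <- apex_row + R
  # tilt = rotation of the center about the image center
  ox <- (w - 1) / 2; oy <- (h - 1) / 2
  th <- params$tilt_deg * pi / 180
  vx <- cx0 - ox; vy <- cy0 - oy
  cx <- ox + cos(th) * vx - sin(th) * vy
  cy <- oy + sin(th) * vx + cos(th) * vy

  cols <- matrix(rep(0:(w - 1), each = h), h, w)
  rows <- matrix(rep(0:(h - 1), times = w), h, w)
  dist <- sqrt((cols - cx)^2 + (rows - cy)^2)

  img <- matrix(params$background_level, h, w)
  r_ep <- R
  r_bl <- R - t[1] - t[2]
  r_en <- R - sum(t)
  img[dist <= r_ep & dist > R - t[1]] <- params$layer_intensities[1]
  img[dist <= R - t[1] & dist > r_bl] <- params$layer_intensities[2]
  img[dist <= r_bl & dist > r_en] <- params$layer_intensities[3]

  boundary_mask <- function(r) {
    m <- matrix(0, h, w)
    for (c in 0:(w - 1)) {
      disc <- r^2 - (c - cx)^2
      if (disc < 0) next
      y <- cy - sqrt(disc)   # upper intersection (anterior side)
      yr <- round(y)
      if (yr >= 0 && yr < h) m[yr + 1, c + 1] <- 1
    }
    m
  }
  ep <- boundary_mask(r_ep)
  if (sum(ep) == 0)
    stop("phantom geometry error: the corneal arc does not intersect the frame")
  boundaries <- list(EP = ep, BL = boundary_mask(r_bl), EN = boundary_mask(r_en))

  if (params$speckle_strength > 0) {
    g <- with_seed(params$seed, matrix(stats::rnorm(h * w), h, w))
    img <- img * (1 + params$speckle_strength * g)
  }
  img <- clamp01(img)
  structure(list(image = img, boundaries = boundaries, params = params),
            class = "phantom_scene")
}

#' Stripe-mask parameters
#'
#' A saturation-artifact mask is a single vertical stripe; its width is
#' drawn uniformly from `width_range` and its center column uniformly from
#' `center_range` (0-based, half-open column convention).  Test-set masks
#' are conventionally drawn wider than training masks.
#'
#' @param width_range Integer interval `c(min, max)` of stripe widths, pixels.
#' @param center_range Integer interval of admissible center columns
#'   (0-based); `NULL` means the whole width at mask-sampling time.
#' @param seed Integer seed.
#' @return An object of class `"mask_params"`.
#' @export
mask_params <- function(width_range = c(8L, 24L), center_range = NULL,
                        seed = 0L) {
  width_range <- as.integer(width_range)
  if (length(width_range) != 2L || width_range[1] < 1 ||
      width_range[1] > width_range[2])
    stop("width_range must be c(min, max) with 1 <= min <= max")
  structure(list(width_range = width_range, center_range = center_range,
                 seed = as.integer(seed)),
            class = "mask_params")
}

#' Sample a stripe artifact mask
#'
#' @param params A [mask_params()].
#' @param shape Image shape `c(height, width)`.
#' @return A binary matrix (1 = repair region) whose marked region is a
#'   single contiguous vertical stripe.
#' @export
sample_mask <- function(params, shape) {
  stopifnot(inherits(params, "mask_params"))
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  wr <- params$width_range
  if (wr[2] >= w) stop("mask width_range exceeds the image width")
  cr <- params$center_range
  if (is.null(cr)) cr <- c(0L, w - 1L)
  cr <- as.integer(cr)
  if (cr[1] < 0 || cr[2] >= w || cr[1] > cr[2])
    stop("center_range must lie within [0, width)")
  draw <- with_seed(params$seed, {
    width <- if (wr[1] == wr[2]) wr[1] else
      sample(seq(wr[1], wr[2]), 1L)
    center <- if (cr[1] == cr[2]) cr[1] else
      sample(seq(cr[1], cr[2]), 1L)
    c(width, center)
  })
  width <- draw[1]; center <- draw[2]
  start <- max(0L, center - width %/% 2L)
  end <- min(w, start + width)           # half-open [start, end)
  m <- matrix(0, h, w)
  m[, (start + 1):end] <- 1
  m
}

#' Corrupt a clean image with a stripe artifact
#'
#' `artifact = clean * (1 - mask) + fill * mask`: every pixel outside the
#' stripe equals the clean image; inside the stripe the configured fill
#' intensity is written (1.0 emulates a saturated white stripe).
#'
#' @param clean Clean image (matrix in `[0, 1]`).
#' @param mask Binary artifact mask of the same shape.
#' @param fill Fill intensity in `[0, 1]`.
#' @return An object of class `"paired_sample"`: list with `artifact_image`,
#'   `clean_image`, `mask`, `fill`.
#' @export
corrupt <- function(clean, mask, fill = 1.0) {
  check_same_shape(clean, mask, "corrupt")
  if (fill < 0 || fill > 1) stop("fill must be in [0,1]")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  art <- clean * (1 - mask) + fill * mask
  structure(list(artifact_image = art, clean_image = clean, mask = mask,
                 fill = fill),
            class = "paired_sample")
}

#' Build a paired phantom dataset on disk
#'
#' Writes clean/artifact/mask 8-bit grayscale PNG triplets plus a tab-
#' separated manifest and a YAML sidecar recording the generating
#' parameters.  Per-sample tilt is drawn uniformly from `tilt_range` and
#' per-sample seeds are derived from `seed`, so a rerun with the same
#' arguments reproduces the files byte for byte.  Test-set masks are drawn
#' from `test_mask_params`, conventionally wider than the training masks.
#'
#' @param n_train,n_test Number of training and test pairs.
#' @param out_dir Output directory (created if missing).
#' @param params A [phantom_params()] template (its `seed`/`tilt_deg` are
#'   overridden per sample).
#' @param train_mask_params,test_mask_params [mask_params()] for the two
#'   splits.
#' @param tilt_range Uniform range of per-sample tilt, degrees.
#' @param fill Artifact fill intensity.
#' @param seed Base seed for the whole dataset.
#' @return The manifest as a data frame (invisibly also written to
#'   `manifest.tsv`), with attribute `"dir"`.
#' @export
build_dataset <- function(n_train, n_test, out_dir,
                          params = phantom_params(),
                          train_mask_params = mask_params(c(8L, 24L)),
                          test_mask_params = mask_params(c(24L, 40L)),
                          tilt_range = c(-10, 10), fill = 1.0,
                          seed = 0L) {
  for (d in file.path(out_dir, c("clean", "artifact", "mask")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  tilts <- with_seed(seed, stats::runif(n, tilt_range[1], tilt_range[2]))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    split <- if (i <= n_train) "train" else "test"
    p <- params
    p$seed <- as.integer((seed + i) %% .Machine$integer.max)
    p$tilt_deg <- tilts[i]
    scene <- generate_phantom(p)
    mp <- if (split == "train") train_mask_params else test_mask_params
    mp$seed <- as.integer((seed + 10000L + i) %% .Machine$integer.max)
    m <- sample_mask(mp, dim(scene$image))
    pair <- corrupt(scene$image, m, fill)
    fc <- file.path("clean", sprintf("%s_%04d.png", split, i))
    fa <- file.path("artifact", sprintf("%s_%04d.png", split, i))
    fm <- file.path("mask", sprintf("%s_%04d.png", split, i))
    save_image(pair$clean_image, file.path(out_dir, fc))
    save_image(pair$artifact_image, file.path(out_dir, fa))
    save_mask(pair$mask, file.path(out_dir, fm))
    rows[[i]] <- data.frame(id = i, split = split, path_clean = fc,
                            path_artifact = fa, path_mask = fm,
                            seed = p$seed, tilt = tilts[i],
                            mask_seed = mp$seed,
                            mask_width = sum(m[1, ]),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- params
  class(meta) <- NULL
  yaml::write_yaml(list(phantom = meta, fill = fill, seed = seed,
                        tilt_range = tilt_range,
                        train_width_range = train_mask_params$width_range,
                        test_width_range = test_mask_params$width_range),
                   file.path(out_dir, "dataset.yaml"))
  attr(manifest, "dir") <- normalizePath(out_dir)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param dir Dataset directory written by [build_dataset()].
#' @return Manifest data frame with attributes `"dir"` and `"meta"` (the
#'   YAML sidecar, when present).
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.tsv")
  if (!file.exists(path)) stop("no manifest.tsv under ", dir)
  manifest <- utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  attr(manifest, "dir") <- normalizePath(dir)
  yml <- file.path(dir, "dataset.yaml")
  if (file.exists(yml)) attr(manifest, "meta") <- yaml::read_yaml(yml)
  manifest
}

# Regenerate the ground-truth scene for a manifest row (boundary labels are
# not stored on disk; the phantom is deterministic in its seed).
scene_for_row <- function(manifest, i) {
  meta <- attr(manifest, "meta")
  if (is.null(meta)) stop("manifest lacks dataset.yaml metadata")
  p <- do.call(phantom_params, meta$phantom[setdiff(names(meta$phantom),
                                                    c("seed", "tilt_deg"))])
  p$seed <- manifest$seed[i]
  p$tilt_deg <- manifest$tilt[i]
  generate_phantom(p)
}
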