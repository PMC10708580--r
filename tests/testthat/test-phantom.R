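test_that("phantom generation is deterministic and geometrically sound", {
  p <- phantom_params(64, 64, seed = 0)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$image, b$image)
  expect_true(all(a$image >= 0 & a$image <= 1))
  # the corneal arc is brighter than background
  inside <- a$image[a$boundaries$EP == 1]
  expect_gt(mean(a$image[a$image > p$background_level]), p$background_level)

  # apex near top-center for zero tilt: EP row at the center column is the
  # minimum EP row
  ep_rows <- apply(a$boundaries$EP, 2, function(col) which(col == 1)[1])
  expect_equal(unname(which.min(ep_rows)), 32, tolerance = 2)
})

test_that("opposite tilts give mirror-symmetric noiseless phantoms", {
  i1 <- tiny_phantom(64, tilt = 10)$image
  i2 <- tiny_phantom(64, tilt = -10)$image
  expect_equal(i1, i2[, ncol(i2):1])
})

test_that("zero speckle gives piecewise-constant band intensities", {
  p <- phantom_params(64, 64, speckle_strength = 0)
  img <- generate_phantom(p)$image
  vals <- sort(unique(as.numeric(img)))
  expect_true(all(vals %in% c(p$background_level, p$layer_intensities)))
})

test_that("boundary labels are one-per-column and anterior-to-posterior ordered", {
  for (tilt in c(-8, 0, 12)) {
    sc <- tiny_phantom(64, tilt = tilt, speckle = 0.2)
    for (b in sc$boundaries) expect_true(all(colSums(b) <= 1))
    ep <- sc$boundaries$EP; bl <- sc$boundaries$BL; en <- sc$boundaries$EN
    cols <- which(colSums(ep) * colSums(bl) * colSums(en) > 0)
    expect_gt(length(cols), 10)
    for (j in cols) {
      expect_lt(which(ep[, j] == 1), which(bl[, j] == 1))
      expect_lt(which(bl[, j] == 1), which(en[, j] == 1))
    }
  }
})

test_that("invalid phantom geometry and parameters are rejected", {
  expect_error(phantom_params(64, 64, layer_thicknesses = c(30, 30, 30)),
               "thickness")
  expect_error(phantom_params(64, 64, layer_intensities = c(2, 0.5, 0.5)),
               "intensities")
  # arc entirely below the frame
  p <- phantom_params(64, 64, apex_frac = 3)
  expect_error(generate_phantom(p), "geometry")
})

test_that("sampled masks are single stripes with the requested geometry", {
  # width 8 centered at column 32 (0-based) -> columns 28..35
  m <- sample_mask(mask_params(c(8L, 8L), c(32L, 32L)), c(64, 64))
  on_cols <- which(colSums(m) > 0) - 1
  expect_equal(on_cols, 28:35)
  expect_equal(sum(m), 8 * 64)

  m1 <- sample_mask(mask_params(c(1L, 1L), c(10L, 10L)), c(64, 64))
  expect_equal(sum(m1), 64)

  a <- sample_mask(mask_params(c(4L, 16L), seed = 1), c(64, 64))
  b <- sample_mask(mask_params(c(4L, 16L), seed = 2), c(64, 64))
  expect_false(identical(a, b))

  # stripes are contiguous column ranges
  for (mm in list(m, a, b)) {
    cc <- which(colSums(mm) > 0)
    expect_equal(cc, seq(min(cc), max(cc)))
    expect_true(all(mm %in% c(0, 1)))
  }
  expect_error(sample_mask(mask_params(c(8L, 80L)), c(64, 64)), "width")
  expect_error(sample_mask(mask_params(c(4L, 8L), c(70L, 80L)), c(64, 64)),
               "center_range")
})

test_that("corrupt overwrites exactly the stripe with the fill value", {
  clean <- matrix(0, 64, 64)
  m <- sample_mask(mask_params(c(8L, 8L), c(32L, 32L)), c(64, 64))
  pair <- corrupt(clean, m, fill = 1.0)
  expect_equal(pair$artifact_image[m == 1], rep(1, sum(m)))
  expect_equal(pair$artifact_image[m == 0], rep(0, sum(m == 0)))

  # identity with an all-zero mask
  sc <- tiny_phantom(64, seed = 3, speckle = 0.2)
  pair0 <- corrupt(sc$image, matrix(0, 64, 64))
  expect_identical(pair0$artifact_image, sc$image)

  # exactly width * height pixels differ when the fill is off-range
  pair1 <- corrupt(sc$image, m, fill = 1.0)
  expect_equal(sum(pair1$artifact_image != sc$image),
               sum(sc$image[m == 1] != 1))
  expect_equal(sum(m), 8 * 64)

  expect_error(corrupt(sc$image, matrix(0, 32, 32)), "shape")
})

test_that("corrupt is idempotent outside the stripe", {
  sc <- tiny_phantom(64, seed = 4, speckle = 0.2)
  m <- sample_mask(mask_params(c(6L, 6L), c(20L, 20L)), c(64, 64))
  once <- corrupt(sc$image, m)$artifact_image
  twice <- corrupt(once, m)$artifact_image
  expect_identical(once[m == 0], twice[m == 0])
  expect_identical(once, twice)
})

test_that("build_dataset writes reproducible triplets with wider test masks", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(n_train = 4, n_test = 2,
               params = phantom_params(64, 64),
               train_mask_params = mask_params(c(4L, 8L)),
               test_mask_params = mask_params(c(10L, 14L)),
               seed = 5)
  man <- do.call(build_dataset, c(args, list(out_dir = d1)))
  expect_equal(nrow(man), 6)
  expect_equal(sum(man$split == "train"), 4)
  files <- file.path(d1, unlist(man[, c("path_clean", "path_artifact", "path_mask")]))
  expect_true(all(file.exists(files)))

  do.call(build_dataset, c(args, list(out_dir = d2)))
  for (f in unlist(man[, c("path_clean", "path_artifact", "path_mask")])) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  expect_gt(min(man$mask_width[man$split == "test"]),
            max(man$mask_width[man$split == "train"]))

  # manifest round trip and ground-truth regeneration
  man2 <- read_manifest(d1)
  expect_equal(man2$seed, man$seed)
  sc <- stripefill:::scene_for_row(man2, 1)
  expect_equal(round(load_image(file.path(d1, man$path_clean[1])) * 255),
               round(sc$image * 255))
})
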