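test_that("overlay stripping fills boxes with local background and touches nothing else", {
  # no boxes: identity
  img <- matrix(runif(64 * 64), 64)
  out <- strip_annotations(raw_us_image(img))
  expect_identical(out$pixels, img)
  expect_equal(nrow(out$annotation_boxes), 0)

  # constant surround forces the fill value
  cimg <- matrix(100, 64, 64)
  cimg[11:18, 21:28] <- 255
  boxes <- data.frame(x0 = 20L, y0 = 10L, x1 = 28L, y1 = 18L)
  out <- strip_annotations(cimg, boxes)
  expect_true(all(out$pixels == 100))

  # pixels outside the box are bit-identical
  img2 <- matrix(runif(64 * 64), 64)
  out2 <- strip_annotations(img2, boxes)
  keep <- matrix(TRUE, 64, 64); keep[11:18, 21:28] <- FALSE
  expect_identical(out2$pixels[keep], img2[keep])
})

test_that("overlay stripping removes the generator's bright corner blocks", {
  ph <- generate_phantom(phantom_spec(1, seed = 404))
  expect_gt(nrow(ph$annotation_boxes), 0)
  img <- ph$record$image
  out <- strip_annotations(img, ph$annotation_boxes)$pixels
  for (i in seq_len(nrow(ph$annotation_boxes))) {
    b <- ph$annotation_boxes[i, ]
    rows <- (b$y0 + 1):b$y1; cols <- (b$x0 + 1):b$x1
    patch <- out[rows, cols]
    bg <- img[-unlist(lapply(seq_len(nrow(ph$annotation_boxes)), function(j)
      (ph$annotation_boxes$y0[j] + 1):ph$annotation_boxes$y1[j])), ]
    expect_lt(max(patch), mean(bg) + 3 * stats::sd(bg))
  }
})

test_that("out-of-bounds annotation boxes raise an error naming the box", {
  img <- matrix(0, 64, 64)
  expect_error(strip_annotations(img, data.frame(x0 = 60, y0 = 0,
                                                 x1 = 70, y1 = 8)),
               "box 1")
  expect_error(raw_us_image(img, data.frame(x0 = -1, y0 = 0,
                                            x1 = 8, y1 = 8)),
               "outside")
})

test_that("canonicalisation resamples to 256x256 on the unit intensity scale", {
  x <- matrix(runif(512 * 512), 512)
  y <- to_canonical(x)
  expect_equal(dim(y), c(256, 256))
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  # constant image maps to zeros
  expect_true(all(to_canonical(matrix(7, 100, 100)) == 0))
  expect_error(to_canonical(matrix(numeric(0), 0, 0)), "empty")
})

test_that("canonicalisation is idempotent and matches a naive resampler", {
  x <- matrix(runif(256 * 256), 256)
  x <- (x - min(x)) / (max(x) - min(x))
  expect_lt(max(abs(to_canonical(x) - x)), 1e-6)
  # corner checkerboard: compare against the independent double-loop oracle
  cb <- matrix(c(0, 255, 255, 0), 2, 2)
  got <- to_canonical(cb, 16)
  ref <- oracle_bilinear(cb, 16, 16)
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_equal(got, ref, tolerance = 1e-12)
  expect_lt(got[1, 1], 0.05)
  expect_gt(got[1, 16], 0.95)
})

test_that("mask resampling stays binary and preserves area fractions", {
  expect_true(all(resize_mask(matrix(0, 100, 100)) == 0))
  expect_true(all(resize_mask(matrix(1, 300, 300)) == 1))
  m <- matrix(0, 512, 512)
  m[129:384, 129:384] <- 1  # central square, 25% of the area
  r <- resize_mask(m, 256)
  expect_true(all(r %in% c(0, 1)))
  expect_lt(abs(sum(r) / 256^2 - 0.25), 2 * 256 / 256^2)
  expect_error(resize_mask(matrix(0.5, 10, 10)), "binary")
})

test_that("augmentation is seed-deterministic and label/shape preserving", {
  rec <- tiny_records(2, seed = 5, image_size = 64)[[1]]
  a1 <- augment_record(rec, seed = 99)
  a2 <- augment_record(rec, seed = 99)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  # degenerate parameter ranges give the identity
  id <- augment_record(rec, seed = 1, scale_range = c(1, 1),
                       gamma_range = c(1, 1))
  expect_equal(id$image, rec$image, tolerance = 1e-12)
  expect_identical(id$mask, rec$mask)
})

test_that("augmentation keeps masks binary with bounded area change", {
  rec <- tiny_records(2, seed = 6, image_size = 64)[[2]]
  a0 <- sum(rec$mask)
  for (s in 1:100) {
    a <- augment_record(rec, seed = s)
    expect_identical(a$label, rec$label)
    expect_true(all(a$mask %in% c(0, 1)))
    # scale in [0.9, 1.1] bounds the area ratio by ~[0.81, 1.21]
    expect_gt(sum(a$mask) / a0, 0.75)
    expect_lt(sum(a$mask) / a0, 1.27)
  }
})

test_that("manifest round trip through PNG files reproduces records", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(4, 0.5, seed = 21, image_size = 64,
                         short_semi_range_benign = c(3, 4),
                         short_semi_range_malignant = c(5, 8),
                         n_boxes_range = c(0L, 0L))
  write_dataset(ds, dir)
  recs <- read_manifest(file.path(dir, "manifest.csv"), dir, size = 64)
  expect_length(recs, 4)
  for (i in 1:4) {
    expect_identical(recs[[i]]$mask, ds$records[[i]]$mask)
    expect_identical(recs[[i]]$label, ds$records[[i]]$label)
    expect_identical(recs[[i]]$patient_id, ds$records[[i]]$patient_id)
    # read_manifest min-max rescales; compare to the rescaled original,
    # within 8-bit PNG quantisation
    ref <- ds$records[[i]]$image
    ref <- (ref - min(ref)) / (max(ref) - min(ref))
    expect_lt(max(abs(recs[[i]]$image - ref)), 0.01)
  }
})
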