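# Moment-based long/short axis ratio of a binary mask.
mask_aspect <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx), symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}

test_that("phantom generation is a deterministic function of the spec", {
  p1 <- generate_phantom(phantom_spec(1, seed = 33))
  p2 <- generate_phantom(phantom_spec(1, seed = 33))
  expect_identical(p1$record$image, p2$record$image)
  expect_identical(p1$record$mask, p2$record$mask)
  expect_identical(p1$annotation_boxes, p2$annotation_boxes)
  p3 <- generate_phantom(phantom_spec(1, seed = 34))
  expect_false(identical(p1$record$image, p3$record$image))
})

test_that("lesion morphology separates the classes by design", {
  asp_b <- sapply(1:15, function(s)
    mask_aspect(generate_phantom(phantom_spec(0, seed = s))$record$mask))
  asp_m <- sapply(1:15, function(s)
    mask_aspect(generate_phantom(phantom_spec(1, seed = 100 + s))$record$mask))
  expect_true(all(asp_b >= 2.0))
  expect_true(all(asp_m <= 1.5))
  # empirical aspect-ratio distributions do not overlap
  expect_gt(min(asp_b), max(asp_m))
})

test_that("lesions are hypoechoic, in-bounds and clear of the overlays", {
  for (s in c(1, 2, 3, 50, 51)) {
    lab <- as.integer(s %% 2 == 0)
    ph <- generate_phantom(phantom_spec(lab, seed = s))
    r <- ph$record
    expect_equal(r$label, lab)
    expect_true(min(r$image) >= 0 && max(r$image) <= 1)
    # area within the bounds implied by the admissible semi-axes
    expect_gt(sum(r$mask), pi * 10 * 5)
    expect_lt(sum(r$mask), pi * 60 * 60)
    # 4-pixel border margin
    expect_equal(sum(r$mask[c(1:4, 253:256), ]), 0)
    expect_equal(sum(r$mask[, c(1:4, 253:256)]), 0)
    # the mask never touches an annotation box
    for (i in seq_len(nrow(ph$annotation_boxes))) {
      b <- ph$annotation_boxes[i, ]
      expect_equal(sum(r$mask[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1]), 0)
    }
    # lesion interior darker than surrounding tissue
    expect_lt(mean(r$image[r$mask == 1 & !is.na(r$mask)]),
              0.7 * mean(r$image[r$mask == 0]))
  }
})

test_that("phantom masks are single connected components", {
  for (s in c(5, 6, 7)) {
    m <- generate_phantom(phantom_spec(s %% 2, seed = s))$record$mask
    # flood fill from one foreground pixel must reach the whole mask
    idx <- which(m == 1, arr.ind = TRUE)
    visited <- matrix(FALSE, nrow(m), ncol(m))
    queue <- list(idx[1, ])
    visited[idx[1, 1], idx[1, 2]] <- TRUE
    n_vis <- 1L
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] == 1 && !visited[q[1], q[2]]) {
          visited[q[1], q[2]] <- TRUE
          n_vis <- n_vis + 1L
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    expect_equal(n_vis, sum(m))
  }
})

test_that("dataset generation stratifies labels and shares patients", {
  ds <- generate_dataset(60, 0.5, seed = 7, image_size = 64,
                         short_semi_range_benign = c(2.5, 3.2),
                         short_semi_range_malignant = c(4, 6),
                         n_boxes_range = c(0L, 0L))
  expect_equal(sum(ds$labels), 30)
  expect_length(ds$records, 60)
  # roughly 20% of patients contribute two nodes
  tab <- table(ds$patient_ids)
  expect_gt(sum(tab == 2), 2)
  expect_true(all(tab <= 2))
  # reports CSV is aligned with the records
  expect_equal(ds$reports$label, ds$labels)
  expect_error(generate_dataset(10, 0, seed = 1), "both classes")
  expect_error(generate_dataset(1, 0.5, seed = 1), "at least 2")
})

test_that("error-free reports classify perfectly; planted errors show up", {
  ds <- generate_dataset(40, 0.5, seed = 9, image_size = 64,
                         short_semi_range_benign = c(2.5, 3.2),
                         short_semi_range_malignant = c(4, 6),
                         n_boxes_range = c(0L, 0L))
  r <- evaluate_reports(ds$reports)
  expect_equal(r$metrics$sen, 1)
  expect_equal(r$metrics$spe, 1)
  expect_equal(r$unresolved, 0)
  # with a 20% error rate the report accuracy lands near 0.8
  ds2 <- generate_dataset(1000, 0.5, seed = 10, image_size = 64,
                          report_error_rate = 0.2,
                          short_semi_range_benign = c(2.5, 3.2),
                          short_semi_range_malignant = c(4, 6),
                          n_boxes_range = c(0L, 0L))
  r2 <- evaluate_reports(ds2$reports)
  expect_lt(abs(r2$metrics$acc - 0.8), 0.03)
})

test_that("the neck-level count fixture is internally consistent", {
  counts <- node_level_counts()
  expect_equal(ncol(counts), 3)
  expect_equal(nrow(counts), 13)
  expect_true(all(counts$malignant >= 0 & counts$benign >= 0))
})
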