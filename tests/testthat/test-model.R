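test_that("configuration invariants are enforced", {
  expect_error(ynet_config(input_size = 250), "divisible")
  expect_error(ynet_config(ppm_bins = c(3, 3, 5)), "increasing")
  expect_error(ynet_config(input_size = 64, ppm_bins = c(3, 5)),
               "bottleneck")
  expect_error(ynet_config(num_classes = 1), "num_classes")
})

test_that("forward pass honours the output shape contract", {
  cfg <- tiny_config()
  m <- build_ynet(cfg, seed = 1)
  x <- matrix(runif(32 * 32), 32)
  out <- ynet_forward(m, x)
  expect_equal(dim(out$seg_logits), c(32, 32, 1))
  expect_equal(dim(out$class_logits), c(2, 1))
  expect_true(all(is.finite(out$seg_logits)))
  # all-zero input stays finite
  out0 <- ynet_forward(m, matrix(0, 32, 32))
  expect_true(all(is.finite(out0$seg_logits)))
  expect_true(all(is.finite(out0$class_logits)))
  expect_error(ynet_forward(m, matrix(0, 16, 16)), "shape")
})

test_that("classification-only mode drops the decoder and its parameters", {
  m <- build_ynet(tiny_config(), seed = 1)
  mc <- build_ynet(tiny_config(classification_only = TRUE), seed = 1)
  expect_lt(ynet_nparams(mc), ynet_nparams(m))
  out <- ynet_forward(mc, matrix(runif(32 * 32), 32))
  expect_null(out$seg_logits)
  expect_length(out$class_logits, 2)
})

test_that("builds and forwards are deterministic given a seed", {
  m1 <- build_ynet(tiny_config(), seed = 7)
  m2 <- build_ynet(tiny_config(), seed = 7)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(32 * 32), 32)
  o1 <- ynet_forward(m1, x)
  o2 <- ynet_forward(m2, x)
  expect_identical(o1$seg_logits, o2$seg_logits)
  expect_identical(o1$class_logits, o2$class_logits)
  m3 <- build_ynet(tiny_config(), seed = 8)
  expect_false(identical(m1$params, m3$params))
})

test_that("a randomly initialised model is not input-degenerate", {
  m <- build_ynet(tiny_config(), seed = 3)
  x <- matrix(runif(32 * 32), 32)
  a <- ynet_forward(m, x)$class_logits
  b <- ynet_forward(m, 1 - x)$class_logits
  expect_gt(max(abs(a - b)), 1e-9)
})

test_that("batched inference equals per-image inference", {
  m <- build_ynet(tiny_config(), seed = 4)
  xs <- array(runif(32 * 32 * 5), c(32, 32, 5))
  batch <- ynet_forward(m, xs)
  for (i in 1:5) {
    single <- ynet_forward(m, xs[, , i])
    expect_equal(batch$seg_logits[, , i], single$seg_logits[, , 1],
                 tolerance = 1e-12)
    expect_equal(batch$class_logits[, i], single$class_logits[, 1],
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("ynetus")
  cfg <- ynet_config(input_size = 16, encoder_levels = 2, base_channels = 4,
                     ppm_bins = c(1, 2), esp_dilations = c(1, 2))
  m <- build_ynet(cfg, seed = 3)
  set.seed(9)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  msk <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  lab <- c(0L, 1L)
  loss_fn <- function(params) {
    out <- ns$ynet_forward_core(cfg, params, m$bn, x, train = TRUE)
    ns$ag_bce_logits(out$seg, msk) + ns$ag_softmax_ce(out$cls, lab)
  }
  tape <- ns$ag_tape()
  P <- lapply(m$params, function(p) ns$ag_leaf(tape, p))
  out <- ns$ynet_forward_core(cfg, P, m$bn, x, train = TRUE)
  loss <- ns$ag_axpy(ns$ag_bce_logits(out$seg, msk),
                     ns$ag_softmax_ce(out$cls, lab), 1)
  ns$ag_backward(loss)
  set.seed(11)
  for (nm in sample(names(m$params), 20)) {
    g <- P[[nm]]$grad
    expect_false(is.null(g), label = paste("gradient of", nm))
    i <- sample(length(m$params[[nm]]), 1)
    eps <- 1e-5
    pp <- m$params
    pp[[nm]][i] <- pp[[nm]][i] + eps
    lp <- loss_fn(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    lm <- loss_fn(pp)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-4, abs(num) + abs(g[i])), 1e-4,
              label = sprintf("gradient of %s[%d]", nm, i))
  }
})

test_that("prediction thresholds the two heads as documented", {
  m <- build_ynet(tiny_config(), seed = 5)
  x <- matrix(runif(32 * 32), 32)
  p <- ynet_predict(m, x, seg_threshold = 0.5, class_cutoff = 0.5)
  expect_true(all(p$mask %in% c(0, 1)))
  expect_equal(p$mask, (p$seg_prob >= 0.5) * 1L)
  expect_equal(sum(p$class_prob), 1, tolerance = 1e-12)
  expect_equal(p$label, as.integer(p$malignant_prob >= 0.5))
  # a threshold above every probability empties the mask
  p2 <- ynet_predict(m, x, seg_threshold = max(p$seg_prob) + 1e-9)
  expect_equal(sum(p2$mask), 0)
  # sweeping the cutoff can only shrink the predicted-positive set
  scores <- runif(50)
  pos <- sapply(seq(0, 1, by = 0.05), function(ct) sum(scores >= ct))
  expect_true(all(diff(pos) <= 0))
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  m <- build_ynet(tiny_config(), seed = 6)
  x <- matrix(runif(32 * 32), 32)
  ref <- ynet_forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ynet(m, path)
  m2 <- load_ynet(path, config = tiny_config())
  got <- ynet_forward(m2, x)
  expect_identical(got$seg_logits, ref$seg_logits)
  expect_identical(got$class_logits, ref$class_logits)
  expect_error(load_ynet(path, config = tiny_config(base_channels = 16)),
               "match")
})
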