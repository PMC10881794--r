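# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (double loops, exhaustive scans) and share
# no code with the implementations they test.

# Naive bilinear resampling with half-pixel centres and edge clamping.
oracle_bilinear <- function(x, ho, wo) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, ho, wo)
  for (oy in seq_len(ho)) {
    sy <- min(max((oy - 0.5) * h / ho - 0.5, 0), h - 1)
    y0 <- floor(sy); fy <- sy - y0
    y1 <- min(y0 + 1, h - 1)
    for (ox in seq_len(wo)) {
      sx <- min(max((ox - 0.5) * w / wo - 0.5, 0), w - 1)
      x0 <- floor(sx); fx <- sx - x0
      x1 <- min(x0 + 1, w - 1)
      out[oy, ox] <-
        x[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        x[y1 + 1, x0 + 1] * fy * (1 - fx) +
        x[y0 + 1, x1 + 1] * (1 - fy) * fx +
        x[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# AUC as the Mann-Whitney concordance probability by exhaustive pair
# counting (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Best Youden J over an exhaustive scan of candidate thresholds.
oracle_best_j <- function(scores, labels) {
  cand <- c(sort(unique(scores)), Inf)
  best <- -Inf
  for (t in cand) {
    sen <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spe <- sum(scores < t & labels == 0) / sum(labels == 0)
    best <- max(best, sen + spe - 1)
  }
  best
}

# Hand-rolled joint cross-entropy: mean per-pixel binary CE from logits
# plus lambda times the image-level CE from class logits.
oracle_joint_loss <- function(seg_logits, mask, class_logits, label, lambda) {
  p <- 1 / (1 + exp(-seg_logits))
  lseg <- -mean(mask * log(p) + (1 - mask) * log(1 - p))
  q <- exp(class_logits - max(class_logits))
  q <- q / sum(q)
  lseg + lambda * (-log(q[label + 1]))
}

# A small Y-Net configuration that keeps unit tests fast.
tiny_config <- function(...) {
  ynet_config(input_size = 32L, encoder_levels = 3L, base_channels = 8L,
              ppm_bins = c(2L, 4L), esp_dilations = c(1L, 2L), ...)
}

# Deterministic miniature phantom set shared by training tests.
tiny_records <- function(n, seed = 1L, image_size = 32L) {
  ds <- generate_dataset(n, 0.5, seed = seed, image_size = image_size,
                         short_semi_range_benign = c(2.5, 3.2),
                         short_semi_range_malignant = c(4, 6),
                         n_boxes_range = c(0L, 0L))
  ds$records
}
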