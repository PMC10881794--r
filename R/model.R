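# Y-Net: a U-Net-style encoder/decoder for lesion segmentation with a
# parallel classification branch sharing the encoder.  The encoder is
# residual with efficient-spatial-pyramid (ESP) blocks — the inner 3x3
# convolution of each residual unit is replaced by parallel dilated 3x3
# convolutions with hierarchical additive fusion — and the bottleneck
# carries a pyramid pooling module (PPM).  The decoder mirrors the encoder
# and receives, at every resolution, both the usual concatenation skip from
# the last encoding block and a superposition (element-wise addition) skip
# from the first encoding block at that resolution.

#' Y-Net architecture and inference configuration
#'
#' Collects every architectural hyperparameter of the network.  Defaults
#' give a compact model (four stride-2 encoder stages, 16 base channels)
#' sized so that training on CPU is practical; all knobs are exposed.
#'
#' @param input_size Side of the square input image in pixels. Must be
#'   divisible by `2^encoder_levels`.
#' @param in_channels Number of input channels (1 for grayscale B-mode).
#' @param num_classes Number of diagnostic classes (2: benign/malignant).
#' @param encoder_levels Number of stride-2 downsampling stages.
#' @param base_channels Channels after the first stage; doubled per stage.
#' @param ppm_bins Strictly increasing pyramid-pooling bin sizes; each must
#'   not exceed the bottleneck spatial size
#'   `input_size / 2^encoder_levels`.
#' @param esp_dilations Dilation rates of the parallel 3x3 branches in each
#'   ESP block.
#' @param classification_only If `TRUE` the decoder and segmentation head
#'   are omitted and the model only classifies.
#' @param seg_threshold Default probability threshold used to binarize the
#'   segmentation map.
#' @return An object of class `ynet_config` (a validated list).
#' @export
ynet_config <- function(input_size = 256L, in_channels = 1L,
                        num_classes = 2L, encoder_levels = 4L,
                        base_channels = 16L, ppm_bins = c(3L, 5L, 7L, 9L),
                        esp_dilations = c(1L, 2L, 4L, 8L),
                        classification_only = FALSE, seg_threshold = 0.5) {
  cfg <- list(input_size = as.integer(input_size),
              in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              encoder_levels = as.integer(encoder_levels),
              base_channels = as.integer(base_channels),
              ppm_bins = as.integer(ppm_bins),
              esp_dilations = as.integer(esp_dilations),
              classification_only = isTRUE(classification_only),
              seg_threshold = as.numeric(seg_threshold))
  class(cfg) <- "ynet_config"
  validate_ynet_config(cfg)
  cfg
}

validate_ynet_config <- function(cfg) {
  if (cfg$input_size %% 2L^cfg$encoder_levels != 0L)
    stop("input_size must be divisible by 2^encoder_levels")
  bottleneck <- cfg$input_size %/% 2L^cfg$encoder_levels
  if (any(diff(cfg$ppm_bins) <= 0L))
    stop("ppm_bins must be strictly increasing")
  if (any(cfg$ppm_bins > bottleneck))
    stop("ppm_bins must not exceed the bottleneck spatial size (",
         bottleneck, ")")
  if (cfg$num_classes < 2L) stop("num_classes must be at least 2")
  if (cfg$base_channels < length(cfg$esp_dilations))
    stop("base_channels must be at least the number of ESP dilations")
  invisible(cfg)
}

# ---- parameter construction -------------------------------------------------

ynet_ch <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$encoder_levels) - 1L)

new_param_store <- function() {
  st <- new.env(parent = emptyenv())
  st$params <- list()
  st$bn <- list()
  st
}

# Convolutions feeding batch-norm are bias-free (a bias would be cancelled
# by the mean subtraction); only BN-less convolutions carry one.
add_conv <- function(st, name, kh, kw, cin, cout, bias = FALSE) {
  fan_in <- kh * kw * cin
  st$params[[paste0(name, ".w")]] <-
    array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
          c(kh, kw, cin, cout))
  if (bias) st$params[[paste0(name, ".b")]] <- numeric(cout)
  invisible(st)
}

add_bn <- function(st, name, c) {
  st$params[[paste0(name, ".g")]] <- rep(1, c)
  st$params[[paste0(name, ".be")]] <- rep(0, c)
  stats_env <- new.env(parent = emptyenv())
  stats_env$running_mean <- rep(0, c)
  stats_env$running_var <- rep(1, c)
  st$bn[[name]] <- stats_env
  invisible(st)
}

add_esp <- function(st, name, c, dils) {
  k <- length(dils)
  cr <- max(c %/% k, 1L)
  add_conv(st, paste0(name, ".red"), 1L, 1L, c, cr)
  add_bn(st, paste0(name, ".redbn"), cr)
  for (i in seq_len(k))
    add_conv(st, paste0(name, ".d", i), 3L, 3L, cr, cr)
  add_bn(st, paste0(name, ".catbn"), k * cr)
  add_conv(st, paste0(name, ".proj"), 1L, 1L, k * cr, c)
  add_bn(st, paste0(name, ".projbn"), c)
  invisible(st)
}

#' Build a Y-Net model
#'
#' Instantiates all network parameters (He-initialised convolutions, unit
#' batch-norm scales) deterministically from `seed`.
#'
#' @param config A [ynet_config()].
#' @param seed Integer seed controlling parameter initialisation; equal
#'   seeds and configs give bit-identical models.
#' @return An object of class `ynet`: a list with elements `config`,
#'   `params` (named list of arrays) and `bn` (running batch-norm
#'   statistics).
#' @export
build_ynet <- function(config = ynet_config(), seed = 1L) {
  validate_ynet_config(config)
  cfg <- config
  ch <- ynet_ch(cfg)
  L <- cfg$encoder_levels
  dils <- cfg$esp_dilations
  st <- new_param_store()
  with_seed(seed, {
    cin <- cfg$in_channels
    for (l in seq_len(L)) {
      add_conv(st, sprintf("enc%d.down", l), 3L, 3L, cin, ch[l])
      add_bn(st, sprintf("enc%d.downbn", l), ch[l])
      add_esp(st, sprintf("enc%d.esp", l), ch[l], dils)
      cin <- ch[l]
    }
    # pyramid pooling module on the bottleneck
    nb <- length(cfg$ppm_bins)
    cp <- max(ch[L] %/% nb, 1L)
    for (i in seq_len(nb)) {
      add_conv(st, sprintf("ppm.b%d", i), 1L, 1L, ch[L], cp)
      add_bn(st, sprintf("ppm.b%dbn", i), cp)
    }
    add_conv(st, "ppm.fuse", 1L, 1L, ch[L] + nb * cp, ch[L])
    add_bn(st, "ppm.fusebn", ch[L])
    # classification branch: GAP of post-PPM features -> hidden dense ->
    # C logits (a single linear readout underfits shape-level features)
    hid <- max(ch[L] %/% 2L, 4L)
    st$params[["cls.fc1.w"]] <-
      matrix(stats::rnorm(hid * ch[L], sd = sqrt(2 / ch[L])), hid, ch[L])
    st$params[["cls.fc1.b"]] <- numeric(hid)
    st$params[["cls.fc2.w"]] <-
      matrix(stats::rnorm(cfg$num_classes * hid, sd = sqrt(2 / hid)),
             cfg$num_classes, hid)
    st$params[["cls.fc2.b"]] <- numeric(cfg$num_classes)
    if (!cfg$classification_only) {
      for (l in seq(L - 1L, 1L)) {
        add_conv(st, sprintf("dec%d.proj", l), 1L, 1L, ch[l + 1L], ch[l])
        add_bn(st, sprintf("dec%d.projbn", l), ch[l])
        add_conv(st, sprintf("dec%d.red", l), 1L, 1L, 2L * ch[l], ch[l])
        add_bn(st, sprintf("dec%d.redbn", l), ch[l])
        add_esp(st, sprintf("dec%d.esp", l), ch[l], dils)
      }
      hc <- max(cfg$base_channels %/% 2L, 4L)
      add_conv(st, "seg.red", 1L, 1L, ch[1L], hc)
      add_bn(st, "seg.redbn", hc)
      add_conv(st, "seg.conv", 3L, 3L, hc, hc)
      add_bn(st, "seg.convbn", hc)
      add_conv(st, "seg.out", 1L, 1L, hc, 1L, bias = TRUE)
      # start the lesion logit at the background prior (a few percent of
      # pixels are foreground) so early gradients cannot kill the narrow
      # head before it localises
      st$params[["seg.out.b"]][] <- -3
    }
  })
  model <- list(config = cfg, params = st$params, bn = st$bn)
  class(model) <- "ynet"
  model
}

#' @export
print.ynet <- function(x, ...) {
  cfg <- x$config
  cat("Y-Net model\n")
  cat(sprintf("  input %dx%dx%d, %d encoder levels, base %d channels\n",
              cfg$input_size, cfg$input_size, cfg$in_channels,
              cfg$encoder_levels, cfg$base_channels))
  cat(sprintf("  PPM bins: %s; ESP dilations: %s\n",
              paste(cfg$ppm_bins, collapse = "/"),
              paste(cfg$esp_dilations, collapse = "/")))
  cat(sprintf("  mode: %s; parameters: %d\n",
              if (cfg$classification_only) "classification only"
              else "joint segmentation + classification",
              ynet_nparams(x)))
  invisible(x)
}

#' Number of trainable parameters of a Y-Net model
#' @param model A `ynet` model.
#' @return Integer parameter count.
#' @export
ynet_nparams <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- forward pass -----------------------------------------------------------

# Shared forward over plain arrays (inference) or tape nodes (training).
# `P` maps parameter names to arrays or leaf nodes; `bnst` holds the
# batch-norm running-statistic environments.
ynet_forward_core <- function(cfg, P, bnst, x, train) {
  conv_bn_relu <- function(t, name, bname, stride = 1L, pad = 0L, dil = 1L) {
    t <- ag_conv(t, P[[paste0(name, ".w")]], NULL, stride, pad, dil)
    ag_bn_relu(t, P[[paste0(bname, ".g")]], P[[paste0(bname, ".be")]],
               bnst[[bname]], train)
  }
  esp <- function(t, name) {
    # reduce -> parallel dilated 3x3 -> hierarchical additive fusion ->
    # concat -> project; residual add of the block input, then ReLU
    r <- conv_bn_relu(t, paste0(name, ".red"), paste0(name, ".redbn"))
    branches <- list()
    acc <- NULL
    for (i in seq_along(cfg$esp_dilations)) {
      d <- cfg$esp_dilations[i]
      b <- ag_conv(r, P[[sprintf("%s.d%d.w", name, i)]], NULL, 1L, d, d)
      acc <- if (is.null(acc)) b else ag_add(acc, b)
      branches[[i]] <- acc
    }
    cat_ <- ag_bn_relu(ag_concat_c(branches),
                       P[[paste0(name, ".catbn.g")]],
                       P[[paste0(name, ".catbn.be")]],
                       bnst[[paste0(name, ".catbn")]], train)
    pr <- ag_conv(cat_, P[[paste0(name, ".proj.w")]], NULL, 1L, 0L, 1L)
    pr <- ag_bn(pr, P[[paste0(name, ".projbn.g")]],
                P[[paste0(name, ".projbn.be")]],
                bnst[[paste0(name, ".projbn")]], train)
    ag_relu(ag_add(pr, t))
  }

  L <- cfg$encoder_levels
  sizes <- cfg$input_size %/% 2L^seq_len(L)
  first <- vector("list", L)   # first encoding block at each resolution
  last <- vector("list", L)    # last encoding block at each resolution
  t <- x
  for (l in seq_len(L)) {
    t <- conv_bn_relu(t, sprintf("enc%d.down", l), sprintf("enc%d.downbn", l),
                      stride = 2L, pad = 1L)
    first[[l]] <- t
    t <- esp(t, sprintf("enc%d.esp", l))
    last[[l]] <- t
  }

  # pyramid pooling on the bottleneck
  bsz <- sizes[L]
  pooled <- list(t)
  for (i in seq_along(cfg$ppm_bins)) {
    b <- cfg$ppm_bins[i]
    p <- ag_adapool(t, b)
    p <- conv_bn_relu(p, sprintf("ppm.b%d", i), sprintf("ppm.b%dbn", i))
    pooled[[i + 1L]] <- ag_bilinear(p, bsz, bsz)
  }
  btl <- ag_concat_c(pooled)
  btl <- conv_bn_relu(btl, "ppm.fuse", "ppm.fusebn")

  cls <- ag_relu(ag_dense(ag_gap(btl), P[["cls.fc1.w"]], P[["cls.fc1.b"]]))
  cls <- ag_dense(cls, P[["cls.fc2.w"]], P[["cls.fc2.b"]])

  seg <- NULL
  if (!cfg$classification_only) {
    t <- btl
    for (l in seq(L - 1L, 1L)) {
      t <- conv_bn_relu(t, sprintf("dec%d.proj", l), sprintf("dec%d.projbn", l))
      t <- ag_bilinear(t, sizes[l], sizes[l])
      t <- ag_concat_c(list(t, last[[l]]))
      t <- conv_bn_relu(t, sprintf("dec%d.red", l), sprintf("dec%d.redbn", l))
      t <- ag_add(t, first[[l]])       # Y-Net superposition skip
      t <- esp(t, sprintf("dec%d.esp", l))
    }
    # segmentation head at the first-stage resolution; the single-channel
    # logit map is then upsampled to the input size
    t <- conv_bn_relu(t, "seg.red", "seg.redbn")
    t <- conv_bn_relu(t, "seg.conv", "seg.convbn", pad = 1L)
    seg <- ag_conv(t, P[["seg.out.w"]], P[["seg.out.b"]], 1L, 0L, 1L)
    seg <- ag_bilinear(seg, cfg$input_size, cfg$input_size)
  }
  list(seg = seg, cls = cls)
}

# Coerce a matrix / (H,W,N) / (H,W,1,N) input into a (H,W,1,N) batch.
as_input_batch <- function(x, cfg) {
  if (is.list(x) && !is.null(x[[1L]]$image))
    x <- vapply(x, function(r) r$image,
                matrix(0, cfg$input_size, cfg$input_size))
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) stop("input must be an image array")
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d[1L], d[2L], 1L, d[3L]))
  d <- dim(x)
  if (d[1L] != cfg$input_size || d[2L] != cfg$input_size ||
      d[3L] != cfg$in_channels)
    stop(sprintf("input shape %dx%dx%d does not match the model's %dx%dx%d",
                 d[1L], d[2L], d[3L],
                 cfg$input_size, cfg$input_size, cfg$in_channels))
  x
}

#' Run the Y-Net forward pass
#'
#' Evaluates the network in inference mode (batch-norm uses running
#' statistics, so per-item outputs do not depend on batch composition).
#'
#' @param model A `ynet` model.
#' @param x A single image matrix, an `(H, W, N)` or `(H, W, 1, N)` array,
#'   or a list of records with an `image` field.
#' @return A list with `seg_logits` (`H x W x N` array, `NULL` in
#'   classification-only mode) and `class_logits` (`C x N` matrix).
#' @export
ynet_forward <- function(model, x) {
  cfg <- model$config
  xb <- as_input_batch(x, cfg)
  out <- ynet_forward_core(cfg, model$params, model$bn, xb, train = FALSE)
  seg <- NULL
  if (!is.null(out$seg)) {
    d <- dim(out$seg)
    seg <- array(out$seg, c(d[1L], d[2L], d[4L]))
  }
  list(seg_logits = seg, class_logits = out$cls)
}

#' Predict segmentation mask and class for one image
#'
#' Applies the logistic function to the segmentation logits and binarizes at
#' `seg_threshold`; applies softmax to the class logits and calls the image
#' malignant when the malignant probability reaches `class_cutoff` (the
#' operating point normally chosen on an ROC curve, see [choose_cutoff()]).
#'
#' @param model A trained `ynet` model.
#' @param image A canonical image matrix (values in `[0, 1]`).
#' @param seg_threshold Probability threshold for the binary mask.
#' @param class_cutoff Malignant-probability cutoff for the predicted label.
#' @return A list of class `ynet_prediction`: `seg_prob`, `mask` (binary
#'   matrix; `NULL` in classification-only mode), `class_prob` (named
#'   vector), `label` (0 benign / 1 malignant), `malignant_prob`.
#' @export
ynet_predict <- function(model, image,
                         seg_threshold = model$config$seg_threshold,
                         class_cutoff = 0.5) {
  out <- ynet_forward(model, image)
  z <- out$class_logits[, 1L]
  p <- exp(z - max(z))
  p <- p / sum(p)
  names(p) <- c("benign", "malignant")[seq_along(p)]
  pm <- unname(p[2L])
  res <- list(seg_prob = NULL, mask = NULL, class_prob = p,
              malignant_prob = pm,
              label = as.integer(pm >= class_cutoff))
  if (!is.null(out$seg_logits)) {
    sp <- 1 / (1 + exp(-out$seg_logits[, , 1L]))
    res$seg_prob <- sp
    res$mask <- (sp >= seg_threshold) * 1L
  }
  class(res) <- "ynet_prediction"
  res
}

# ---- checkpointing ----------------------------------------------------------

#' Save a Y-Net model to a checkpoint file
#'
#' The checkpoint is a single archive holding the configuration, all
#' parameters and the batch-norm running statistics.
#'
#' @param model A `ynet` model.
#' @param path Output file path.
#' @export
save_ynet <- function(model, path) {
  bn <- lapply(model$bn, function(e)
    list(running_mean = e$running_mean, running_var = e$running_var))
  saveRDS(list(config = unclass(model$config), params = model$params,
               bn = bn), path)
  invisible(path)
}

#' Load a Y-Net model from a checkpoint file
#'
#' @param path Checkpoint written by [save_ynet()].
#' @param config Optional [ynet_config()]; if supplied, loading fails unless
#'   it matches the checkpointed configuration exactly.
#' @return A `ynet` model.
#' @export
load_ynet <- function(path, config = NULL) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "ynet_config"
  if (!is.null(config) && !identical(unclass(config), unclass(cfg)))
    stop("checkpoint configuration does not match the requested config")
  bn <- lapply(obj$bn, function(s) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- s$running_mean
    e$running_var <- s$running_var
    e
  })
  model <- list(config = cfg, params = obj$params, bn = bn)
  class(model) <- "ynet"
  model
}
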