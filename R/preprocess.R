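# Preprocessing: overlay stripping, canonical 256x256 rescaling,
# mask resampling, training-time augmentation, and dataset I/O.
#
# Conventions: images are numeric matrices indexed [row, column] with the
# origin at the top-left; pixel coordinates in annotation boxes are 0-based
# and half-open (x0 <= x < x1 on columns, y0 <= y < y1 on rows).

#' Construct a raw ultrasound image
#'
#' A raw image is the exported scanner frame before preprocessing: a
#' grayscale pixel matrix plus the rectangular regions occupied by machine
#' parameters and body markers burned into the corners by the workstation.
#'
#' @param pixels Numeric matrix of grayscale intensities (0–255 integer or
#'   0–1 real scale; at least 32x32).
#' @param annotation_boxes Data frame with columns `x0`, `y0`, `x1`, `y1`
#'   (0-based, half-open pixel rectangles), or `NULL` for none.
#' @return An object of class `raw_us_image`.
#' @export
raw_us_image <- function(pixels, annotation_boxes = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 32L || ncol(pixels) < 32L)
    stop("image must be at least 32x32 pixels")
  boxes <- annotation_boxes %||%
    data.frame(x0 = integer(), y0 = integer(),
               x1 = integer(), y1 = integer())
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(boxes)))
  for (i in seq_len(nrow(boxes))) check_box(boxes[i, ], dim(pixels), i)
  structure(list(pixels = pixels, annotation_boxes = boxes),
            class = "raw_us_image")
}

check_box <- function(b, d, i) {
  if (b$x0 < 0 || b$y0 < 0 || b$x1 > d[2L] || b$y1 > d[1L] ||
      b$x0 >= b$x1 || b$y0 >= b$y1)
    stop(sprintf(
      "annotation box %d [x0=%d,y0=%d,x1=%d,y1=%d] lies outside the %dx%d image",
      i, b$x0, b$y0, b$x1, b$y1, d[1L], d[2L]))
  invisible(b)
}

#' Remove corner annotation overlays from a raw image
#'
#' Replaces the pixels inside every annotation box by the median intensity
#' of a 2-pixel border ring around that box (clipped to the image), which
#' approximates the local background.  Pixels outside the boxes are left
#' untouched and the box list is cleared.
#'
#' @param image A [raw_us_image()], or a plain matrix together with `boxes`.
#' @param boxes Annotation-box data frame when `image` is a matrix.
#' @return A `raw_us_image` with overlays filled and no remaining boxes.
#' @export
strip_annotations <- function(image, boxes = NULL) {
  if (!inherits(image, "raw_us_image"))
    image <- raw_us_image(image, boxes)
  px <- image$pixels
  d <- dim(px)
  bx <- image$annotation_boxes
  for (i in seq_len(nrow(bx))) {
    b <- bx[i, ]
    check_box(b, d, i)
    # 1-based inclusive interior rows/cols of the half-open 0-based box
    rows <- (b$y0 + 1L):b$y1
    cols <- (b$x0 + 1L):b$x1
    ring_rows <- max(1L, b$y0 - 1L):min(d[1L], b$y1 + 2L)
    ring_cols <- max(1L, b$x0 - 1L):min(d[2L], b$x1 + 2L)
    patch <- px[ring_rows, ring_cols, drop = FALSE]
    inside <- outer(ring_rows %in% rows, ring_cols %in% cols, "&")
    ring <- patch[!inside]
    if (length(ring) == 0L)
      stop(sprintf("annotation box %d covers the whole image", i))
    px[rows, cols] <- stats::median(ring)
  }
  raw_us_image(px, NULL)
}

#' Rescale an image to the canonical network input
#'
#' Bilinearly resamples to `size` x `size` and linearly rescales intensities
#' to `[0, 1]` by `(x - min) / (max - min)`; a constant image maps to all
#' zeros.  Annotation overlays should be stripped first.
#'
#' @param image A [raw_us_image()] (with no remaining boxes) or a numeric
#'   matrix.
#' @param size Output side length (default 256).
#' @return A `size` x `size` matrix with values in `[0, 1]`.
#' @export
to_canonical <- function(image, size = 256L) {
  px <- if (inherits(image, "raw_us_image")) image$pixels else image
  if (is.null(px) || length(px) == 0L)
    stop("empty image")
  if (!is.matrix(px)) stop("image must be a matrix")
  y <- .bilinear_fwd(array(px, c(dim(px), 1L, 1L)), size, size)[, , 1L, 1L]
  rng <- range(y)
  if (rng[2L] > rng[1L]) (y - rng[1L]) / (rng[2L] - rng[1L])
  else matrix(0, size, size)
}

#' Resample a binary mask without interpolating labels
#'
#' Nearest-neighbour resampling, so the output stays strictly binary.
#'
#' @param mask Binary (`{0,1}`) numeric matrix.
#' @param size Output side length (default 256).
#' @return Binary `size` x `size` matrix.
#' @export
resize_mask <- function(mask, size = 256L) {
  if (!is.matrix(mask) || !is_binary(mask))
    stop("mask must be a binary {0,1} matrix")
  .nearest_resize(mask, size, size)
}

#' Construct a lymph-node record
#'
#' One case: canonical image, ground-truth target-node mask, reference
#' label, and grouping metadata.
#'
#' @param image Canonical image matrix (values in `[0, 1]`).
#' @param mask Binary mask matrix of the same shape (1 = target node).
#' @param label 0 (benign) or 1 (malignant).
#' @param patient_id Opaque patient identifier (grouping key for splits).
#' @param neck_level Anatomical neck level (e.g. `"III-left"`) or
#'   `"unknown"`.
#' @return An object of class `ln_record`.
#' @export
ln_record <- function(image, mask, label, patient_id,
                      neck_level = "unknown") {
  stopifnot(is.matrix(image), is.matrix(mask))
  if (!identical(dim(image), dim(mask)))
    stop("mask shape must equal image shape")
  if (!is_binary(mask)) stop("mask must be binary {0,1}")
  if (!label %in% c(0, 1)) stop("label must be 0 (benign) or 1 (malignant)")
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]")
  structure(list(image = image, mask = mask, label = as.integer(label),
                 patient_id = as.character(patient_id),
                 neck_level = as.character(neck_level)),
            class = "ln_record")
}

#' Training-time augmentation of a record
#'
#' Applies, deterministically for a given seed, a random isotropic scale
#' jitter (image and mask identically, about the image centre, recropped or
#' zero-padded back to the original size) and a random gamma adjustment of
#' the image intensities.  The label is never changed and the mask stays
#' binary.
#'
#' @param record An [ln_record()].
#' @param seed Integer seed; equal seeds give bit-identical outputs.
#' @param scale_range Range of the isotropic scale factor.
#' @param gamma_range Range of the gamma exponent.
#' @return The augmented `ln_record`.
#' @export
augment_record <- function(record, seed, scale_range = c(0.9, 1.1),
                           gamma_range = c(0.8, 1.25)) {
  stopifnot(inherits(record, "ln_record"))
  with_seed(seed, {
    s <- stats::runif(1, scale_range[1L], scale_range[2L])
    g <- stats::runif(1, gamma_range[1L], gamma_range[2L])
  })
  img <- record$image
  msk <- record$mask
  n <- nrow(img)
  if (s != 1) {
    # destination pixel centres map to source centres contracted by 1/s
    ctr <- (n - 1) / 2
    src <- (seq_len(n) - 1 - ctr) / s + ctr          # 0-based source coords
    # image: bilinear with edge clamping
    sc <- pmin(pmax(src, 0), n - 1)
    i0 <- floor(sc); w1 <- sc - i0
    i0 <- as.integer(i0) + 1L
    i1 <- pmin(i0 + 1L, n)
    a <- record$image
    top <- a[i0, i0] * ((1 - w1) %o% (1 - w1)) + a[i0, i1] * ((1 - w1) %o% w1)
    bot <- a[i1, i0] * (w1 %o% (1 - w1)) + a[i1, i1] * (w1 %o% w1)
    img <- top + bot
    # mask: nearest neighbour, zero outside the source frame
    ni <- as.integer(round(src)) + 1L
    valid <- ni >= 1L & ni <= n
    msk <- matrix(0, n, n)
    msk[valid, valid] <- record$mask[ni[valid], ni[valid], drop = FALSE]
  }
  img <- pmin(pmax(img, 0), 1)^g
  ln_record(img, msk, record$label, record$patient_id, record$neck_level)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a grayscale ultrasound image file
#'
#' Supports 8-bit grayscale PNG and TIFF; RGB inputs are converted to
#' luminance by channel averaging.  Values are returned on the `[0, 1]`
#' scale used throughout the package.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of intensities in `[0, 1]`.
#' @export
read_us_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext))
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3L]), drop = FALSE],
                                       c(1L, 2L), mean)
  x
}

#' Read a binary mask image
#'
#' PNG masks use `{0, 255}` pixel values, mapped here to `{0, 1}` (any
#' value of 0.5 and above counts as foreground).
#'
#' @param path Path to a mask PNG.
#' @return Binary matrix.
#' @export
read_mask <- function(path) {
  (read_us_image(path) >= 0.5) * 1
}

#' Load a dataset manifest into records
#'
#' The manifest is a CSV with columns `image_path`, `mask_path`, `label`,
#' `patient_id`, `neck_level`, with paths relative to `base_dir`.  Optional
#' columns `x0`, `y0`, `x1`, `y1` (or a separate boxes CSV keyed the same
#' way) give one annotation box per row; rows may repeat an image to supply
#' several boxes.  Each image is overlay-stripped, rescaled to the canonical
#' size and paired with its nearest-neighbour-resampled mask.
#'
#' @param manifest Path to the manifest CSV (or a data frame).
#' @param base_dir Directory that image/mask paths are relative to.
#' @param size Canonical image size.
#' @return List of [ln_record()] objects.
#' @export
read_manifest <- function(manifest, base_dir = ".", size = 256L) {
  df <- if (is.data.frame(manifest)) manifest
        else utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "label", "patient_id")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  has_boxes <- all(c("x0", "y0", "x1", "y1") %in% names(df))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    px <- read_us_image(file.path(base_dir, r$image_path))
    boxes <- NULL
    if (has_boxes && !is.na(r$x0))
      boxes <- data.frame(x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1)
    raw <- strip_annotations(raw_us_image(px, boxes))
    img <- to_canonical(raw, size)
    msk <- resize_mask(read_mask(file.path(base_dir, r$mask_path)), size)
    ln_record(img, msk, r$label, r$patient_id,
              if ("neck_level" %in% names(df)) r$neck_level else "unknown")
  })
}
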