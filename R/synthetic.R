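# Seeded generator of B-mode-like speckle phantoms: one hypoechoic
# lymph-node lesion with class-dependent morphology (benign nodes are
# elongated and usually keep an echogenic hilum; malignant nodes are
# rounded, lose the hilum and carry punctate bright foci emulating
# microcalcifications), plus optional dark vessel distractors, corner
# machine-annotation overlays, and paired synthetic report texts.

#' Specification of one synthetic lymph-node phantom
#'
#' Defaults encode the study conditions the generator emulates: benign
#' nodes elongated (long/short axis ratio at least about 2, echogenic hilum
#' present with probability 0.9), malignant nodes rounded (ratio at most
#' 1.5, 2–6 bright punctate foci, no hilum), lesion intensity about 40% of
#' the surrounding tissue, multiplicative speckle, a dark vessel distractor
#' in half the frames, and 1–2 bright corner annotation boxes with recorded
#' coordinates.
#'
#' @param class_label 0 (benign) or 1 (malignant).
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec.
#' @param image_size Side length in pixels.
#' @param benign_aspect,malignant_aspect Ranges of the long/short axis
#'   ratio per class.
#' @param short_semi_range_benign,short_semi_range_malignant Ranges of the
#'   short semi-axis in pixels.
#' @param lesion_intensity Lesion echo level relative to background.
#' @param hilum_prob Probability a benign node shows an echogenic hilum.
#' @param n_foci_range Range of the number of punctate foci (malignant).
#' @param vessel_prob Probability of a dark vessel distractor.
#' @param speckle_shape Gamma shape of the multiplicative speckle (larger =
#'   smoother).
#' @param n_boxes_range Range of the number of corner annotation boxes.
#' @param margin Minimum distance from the lesion to the image border.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label, seed, image_size = 256L,
                         benign_aspect = c(2.15, 3.5),
                         malignant_aspect = c(1.05, 1.45),
                         short_semi_range_benign = c(5.5, 16),
                         short_semi_range_malignant = c(10, 30),
                         lesion_intensity = 0.4, hilum_prob = 0.9,
                         n_foci_range = c(2L, 6L), vessel_prob = 0.5,
                         speckle_shape = 4, n_boxes_range = c(1L, 2L),
                         margin = 4L) {
  if (!class_label %in% c(0, 1)) stop("class_label must be 0 or 1")
  structure(list(class_label = as.integer(class_label),
                 seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 benign_aspect = benign_aspect,
                 malignant_aspect = malignant_aspect,
                 short_semi_range_benign = short_semi_range_benign,
                 short_semi_range_malignant = short_semi_range_malignant,
                 lesion_intensity = lesion_intensity,
                 hilum_prob = hilum_prob,
                 n_foci_range = as.integer(n_foci_range),
                 vessel_prob = vessel_prob,
                 speckle_shape = speckle_shape,
                 n_boxes_range = as.integer(n_boxes_range),
                 margin = as.integer(margin)),
            class = "phantom_spec")
}

# Raster of a filled rotated ellipse: centre (cy, cx), semi-axes (a, b)
# along/across the orientation angle theta, on an n x n grid (1-based
# pixel centres).
ellipse_mask <- function(n, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

#' Generate one lymph-node phantom
#'
#' Renders a smooth tissue background multiplied by gamma speckle, a
#' hypoechoic rotated-ellipse lesion with class-dependent internal
#' features, optional vessel distractor, and bright corner annotation
#' overlays.  The ground-truth mask is the exact ellipse raster; it never
#' touches the annotation boxes, and the lesion keeps the requested border
#' margin.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `record` (an [ln_record()]), `annotation_boxes`
#'   (data frame of 0-based half-open rectangles), and `geometry` (centre,
#'   semi-axes, orientation).
#' @export
generate_phantom <- function(spec) {
  n <- spec$image_size
  m <- spec$margin
  with_seed(spec$seed, {
    malignant <- spec$class_label == 1L
    aspect <- if (malignant)
      stats::runif(1, spec$malignant_aspect[1], spec$malignant_aspect[2])
    else stats::runif(1, spec$benign_aspect[1], spec$benign_aspect[2])
    br <- if (malignant) spec$short_semi_range_malignant
          else spec$short_semi_range_benign
    b <- stats::runif(1, br[1], br[2])
    a <- b * aspect
    if (2 * (a + m) >= n)
      stop(sprintf("lesion (semi-axis %.1f px) cannot fit a %dx%d image with margin %d",
                   a, n, n, m))
    theta <- stats::runif(1, 0, pi)

    # corner annotation boxes (0-based, half-open), inset 2 px
    nb <- sample_one(seq(spec$n_boxes_range[1], spec$n_boxes_range[2]))
    corners <- if (nb > 0L) sample(4L, nb) else integer()
    boxes <- data.frame(x0 = integer(), y0 = integer(),
                        x1 = integer(), y1 = integer())
    for (k in corners) {
      w <- sample_one(30:60); h <- sample_one(12:24)
      x0 <- if (k %in% c(1L, 3L)) 2L else n - 2L - w
      y0 <- if (k %in% c(1L, 2L)) 2L else n - 2L - h
      boxes <- rbind(boxes, data.frame(x0 = x0, y0 = y0,
                                       x1 = x0 + w, y1 = y0 + h))
    }

    # place the lesion: inside the border margin and clear of the boxes
    for (try in 1:200) {
      cy <- stats::runif(1, a + m + 1, n - a - m)
      cx <- stats::runif(1, a + m + 1, n - a - m)
      clear <- all(cx + a < boxes$x0 | cx - a > boxes$x1 |
                     cy + a < boxes$y0 | cy - a > boxes$y1)
      if (clear) break
      if (try == 200)
        stop("could not place the lesion clear of the annotation boxes")
    }
    mask <- ellipse_mask(n, cy, cx, a, b, theta)

    # smooth tissue background: low-resolution uniform field, bilinearly
    # upsampled, as echo level in [0.45, 0.75]
    coarse <- array(stats::runif(64, 0.45, 0.75), c(8L, 8L, 1L, 1L))
    bg <- .bilinear_fwd(coarse, n, n)[, , 1L, 1L]

    echo <- bg * (1 - (1 - spec$lesion_intensity) * mask)
    if (malignant) {
      nf <- sample_one(seq(spec$n_foci_range[1], spec$n_foci_range[2]))
      for (i in seq_len(nf)) {
        # punctate echogenic focus inside the node
        rho <- sqrt(stats::runif(1)) * 0.6
        ang <- stats::runif(1, 0, 2 * pi)
        fy <- cy + rho * (a * cos(ang) * sin(theta) + b * sin(ang) * cos(theta))
        fx <- cx + rho * (a * cos(ang) * cos(theta) - b * sin(ang) * sin(theta))
        f <- ellipse_mask(n, fy, fx, stats::runif(1, 1.5, 3),
                          stats::runif(1, 1.5, 3), 0)
        echo <- echo * (1 - f) + f * bg * 1.9
      }
    } else if (stats::runif(1) < spec$hilum_prob) {
      # echogenic hilum: bright central stripe along the long axis
      hil <- ellipse_mask(n, cy, cx, 0.55 * a, 0.35 * b, theta) * mask
      echo <- echo * (1 - hil) + hil * bg * 1.1
    }

    if (stats::runif(1) < spec$vessel_prob) {
      # dark vessel distractor: disc (transverse) or tube (longitudinal),
      # rejection-placed clear of the lesion and the boxes
      va <- stats::runif(1, 6, 16)
      vaspect <- if (stats::runif(1) < 0.5) 1 else stats::runif(1, 4, 8)
      vlong <- va * vaspect
      if (2 * (vlong + 2) >= n) vlong <- -1  # does not fit; skip the vessel
      for (try in seq_len(if (vlong > 0) 100L else 0L)) {
        vy <- stats::runif(1, vlong + 2, n - vlong - 2)
        vx <- stats::runif(1, vlong + 2, n - vlong - 2)
        sep <- sqrt((vy - cy)^2 + (vx - cx)^2) > vlong + a + 4
        clear <- all(vx + vlong < boxes$x0 | vx - vlong > boxes$x1 |
                       vy + vlong < boxes$y0 | vy - vlong > boxes$y1)
        if (sep && clear) {
          vth <- stats::runif(1, 0, pi)
          ves <- ellipse_mask(n, vy, vx, vlong, va, vth)
          echo <- echo * (1 - 0.65 * ves)
          break
        }
      }
    }

    # multiplicative speckle (gamma with mean 1), then the burned-in
    # bright overlay text blocks, then clamp to [0, 1]
    speckle <- matrix(stats::rgamma(n * n, shape = spec$speckle_shape,
                                    rate = spec$speckle_shape), n, n)
    img <- echo * speckle
    for (i in seq_len(nrow(boxes))) {
      rows <- (boxes$y0[i] + 1L):boxes$y1[i]
      cols <- (boxes$x0[i] + 1L):boxes$x1[i]
      img[rows, cols] <- stats::runif(length(rows) * length(cols), 0.6, 1)
    }
    img <- pmin(pmax(img, 0), 1)

    list(record = ln_record(img, mask, spec$class_label,
                            patient_id = paste0("P", spec$seed)),
         annotation_boxes = boxes,
         geometry = list(cy = cy, cx = cx, a = a, b = b, theta = theta))
  })
}

#' Generate a synthetic lymph-node dataset
#'
#' Draws `n` phantoms with independent specs, stratified so that exactly
#' `round(n * malignant_fraction)` are malignant.  Patient identifiers are
#' assigned so that roughly 20% of patients contribute two nodes, giving
#' the patient-grouped splitter something to respect.  Each record gets a
#' paired free-text report drawn from the diagnosis-dictionary keywords of
#' its class; with probability `report_error_rate` the report is drawn from
#' the wrong class instead.
#'
#' @param n Number of phantoms (at least 2; both classes must appear).
#' @param malignant_fraction Fraction of malignant records in `(0, 1)`.
#' @param seed Master seed for the whole dataset.
#' @param report_error_rate Probability a report contradicts its label.
#' @param image_size Phantom side length.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A list of class `ln_dataset`: `records` (list of
#'   [ln_record()]), `annotation_boxes` (list of data frames), `reports`
#'   (data frame `record_id`, `report_text`, `label`), `labels`,
#'   `patient_ids`.
#' @export
generate_dataset <- function(n, malignant_fraction = 0.5, seed = 1L,
                             report_error_rate = 0, image_size = 256L,
                             ...) {
  if (n < 2L) stop("need at least 2 records")
  nmal <- round(n * malignant_fraction)
  if (nmal < 1L || nmal > n - 1L)
    stop("malignant_fraction must leave both classes represented")
  dict <- diagnosis_dictionary()
  with_seed(seed, {
    labels <- sample(c(rep(1L, nmal), rep(0L, n - nmal)))
    # ~20% of patients contribute two nodes: with p patients and n - p of
    # them contributing twice, n - p ~ 0.2 p  =>  p ~ n / 1.2
    p <- max(ceiling(n / 1.2), 2L)
    pool <- c(seq_len(p), sample.int(p, n - p))
    patient_ids <- paste0("P", sample(pool))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    rep_flip <- stats::runif(n) < report_error_rate
    rep_draw <- stats::runif(n)
    levels_pool <- c(outer(c("I", "II", "III", "IV", "V", "VI"),
                           c("left", "right"), paste, sep = "-"), "VII")
    neck <- sample(levels_pool, n, replace = TRUE)
  })
  recs <- vector("list", n)
  boxes <- vector("list", n)
  texts <- character(n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(labels[i], seeds[i],
                                        image_size = image_size, ...))
    r <- ph$record
    r$patient_id <- patient_ids[i]
    r$neck_level <- neck[i]
    recs[[i]] <- r
    boxes[[i]] <- ph$annotation_boxes
    rep_class <- if (rep_flip[i]) 1L - labels[i] else labels[i]
    kws <- if (rep_class == 1L) dict$malignant else dict$benign
    kw <- kws[1L + floor(rep_draw[i] * length(kws))]
    texts[i] <- sprintf("Conclusion: %s, level %s of the neck.",
                        kw, neck[i])
  }
  structure(list(records = recs, annotation_boxes = boxes,
                 reports = data.frame(record_id = sprintf("R%04d", seq_len(n)),
                                      report_text = texts, label = labels,
                                      stringsAsFactors = FALSE),
                 labels = labels, patient_ids = patient_ids),
            class = "ln_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes per-record image and mask PNGs plus `manifest.csv`,
#' `reports.csv` and `boxes.csv` into `dir`, in the layout
#' [read_manifest()] consumes.
#'
#' @param ds An `ln_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$records)
  rows <- lapply(seq_len(n), function(i) {
    r <- ds$records[[i]]
    id <- ds$reports$record_id[i]
    ipath <- file.path("images", paste0(id, ".png"))
    mpath <- file.path("masks", paste0(id, ".png"))
    png::writePNG(r$image, file.path(dir, ipath))
    png::writePNG(r$mask, file.path(dir, mpath))
    data.frame(record_id = id, image_path = ipath, mask_path = mpath,
               label = r$label, patient_id = r$patient_id,
               neck_level = r$neck_level, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$reports, file.path(dir, "reports.csv"),
                   row.names = FALSE)
  bx <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- ds$annotation_boxes[[i]]
    if (nrow(b) == 0L) NULL
    else cbind(record_id = ds$reports$record_id[i], b)
  }))
  if (is.null(bx))
    bx <- data.frame(record_id = character(), x0 = integer(),
                     y0 = integer(), x1 = integer(), y1 = integer())
  utils::write.csv(bx, file.path(dir, "boxes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Bundled per-neck-level lymph-node location counts
#'
#' A small bookkeeping fixture: the number of included benign and malignant
#' nodes at each cervical neck level (I–VII, left/right).
#'
#' @return Data frame with columns `location`, `malignant`, `benign`.
#' @export
node_level_counts <- function() {
  utils::read.csv(system.file("extdata", "node_level_counts.csv",
                              package = "ynetus", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
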