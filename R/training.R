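# Training: joint cross-entropy loss, patient-grouped train/test
# splitting with k-fold cross-validation, and the Adam optimisation loop.

#' Training configuration
#'
#' @param batch_size Images per optimisation step.
#' @param initial_lr Initial learning rate of the Adam optimiser.
#' @param epochs Number of passes over the training records.
#' @param lambda Non-negative weight of the classification term in the
#'   joint loss (`L = L_seg + lambda * L_cls`).
#' @param k_folds Number of cross-validation folds over training patients.
#' @param test_fraction Fraction of patients held out as the test set.
#' @param seed Master seed; fans out to the split, parameter
#'   initialisation, augmentation and batch order.
#' @param augment Apply scale/gamma augmentation to training batches.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, initial_lr = 0.001, epochs = 20L,
                         lambda = 1, k_folds = 5L,
                         test_fraction = 1 / 5.6, seed = 42L,
                         augment = TRUE) {
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (k_folds < 2L) stop("k_folds must be at least 2")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, epochs = as.integer(epochs),
                 lambda = lambda, k_folds = as.integer(k_folds),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Joint segmentation + classification cross-entropy loss
#'
#' `L_seg` is the mean per-pixel binary cross-entropy of the segmentation
#' logits against the binary mask; `L_cls` is the cross-entropy of the
#' class logits against the image-level label.  The joint loss is
#' `L_seg + lambda * L_cls`; with `seg_logits = NULL` (classification-only
#' mode) the classification term alone is returned.
#'
#' @param seg_logits Per-pixel logits (matrix or array matching `mask`),
#'   or `NULL`.
#' @param mask Binary `{0,1}` target mask of the same shape.
#' @param class_logits Length-`C` vector, or `C x N` matrix, of class
#'   logits.
#' @param label Image-level label(s) in `{0, 1}`.
#' @param lambda Classification-loss weight (default 1).
#' @return Non-negative scalar loss.
#' @export
joint_loss <- function(seg_logits, mask, class_logits, label, lambda = 1) {
  if (is.vector(class_logits)) class_logits <- matrix(class_logits)
  if (!is_binary(label)) stop("label must be 0 or 1")
  lcls <- ag_softmax_ce(class_logits, as.integer(label))
  if (is.null(seg_logits)) return(lcls)
  if (!identical(dim(seg_logits), dim(mask)) &&
      !identical(length(seg_logits), length(mask)))
    stop("seg_logits and mask must have the same shape")
  if (!is_binary(mask)) stop("mask must be binary {0,1}")
  ag_bce_logits(seg_logits, mask) + lambda * lcls
}

#' Patient-grouped train/test split with cross-validation folds
#'
#' Splits records into train and test so that no patient contributes to
#' both, then partitions the training patients into `k` folds of sizes
#' differing by at most one patient.  Deterministic given `seed`.
#'
#' @param records List of [ln_record()]s (or any list whose elements have a
#'   `patient_id`), or a data frame with a `patient_id` column.
#' @param test_fraction Fraction of patients held out for testing.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: `train_ids` / `test_ids` (record
#'   indices), `fold_assignment` (named integer vector, fold of each train
#'   record index), `test_patients`, `fold_of_patient`.
#' @export
split_dataset <- function(records, test_fraction = 1 / 5.6, k = 5L,
                          seed = 42L) {
  pid <- if (is.data.frame(records)) as.character(records$patient_id)
         else vapply(records, function(r) r$patient_id, character(1))
  patients <- unique(pid)
  np <- length(patients)
  ntest <- max(1L, round(np * test_fraction))
  if (np - ntest < k)
    stop(sprintf("only %d training patients for %d folds", np - ntest, k))
  with_seed(seed, {
    test_pat <- sample(patients, ntest)
    train_pat <- sample(setdiff(patients, test_pat))  # shuffled
  })
  fold_of_patient <- stats::setNames(rep_len(seq_len(k), length(train_pat)),
                                     train_pat)
  test_ids <- which(pid %in% test_pat)
  train_ids <- which(!pid %in% test_pat)
  fold_assignment <- stats::setNames(unname(fold_of_patient[pid[train_ids]]),
                                     train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 fold_assignment = fold_assignment,
                 test_patients = test_pat,
                 fold_of_patient = fold_of_patient),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split: %d train / %d test records; folds: %s\n",
              length(x$train_ids), length(x$test_ids),
              paste(table(x$fold_assignment), collapse = "/")))
  invisible(x)
}

# ---- optimiser --------------------------------------------------------------

adam_state <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- st$m[[nm]]
    if (is.null(m)) { m <- g * 0; st$v[[nm]] <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  params
}

# ---- fitting ----------------------------------------------------------------

records_to_batch <- function(records, idx, cfg, augment_seeds = NULL) {
  nb <- length(idx)
  s <- cfg$input_size
  x <- array(0, c(s, s, 1L, nb))
  msk <- array(0, c(s, s, 1L, nb))
  lab <- integer(nb)
  for (j in seq_along(idx)) {
    r <- records[[idx[j]]]
    if (!is.null(augment_seeds)) r <- augment_record(r, augment_seeds[j])
    x[, , 1L, j] <- r$image
    msk[, , 1L, j] <- r$mask
    lab[j] <- r$label
  }
  list(x = x, mask = msk, label = lab)
}

#' Fit a Y-Net model on a set of records
#'
#' Plain mini-batch optimisation of the joint loss with Adam, without
#' cross-validation (see [ynet_train()] for the full protocol).
#' Deterministic given `cfg$seed`.
#'
#' @param model A `ynet` model (its parameters are the starting point).
#' @param records List of [ln_record()]s.
#' @param cfg A [train_config()].
#' @return A list: `model` (trained), `history` (data frame with per-epoch
#'   `loss`, `seg_loss`, `cls_loss`; the segmentation columns are `NA` in
#'   classification-only mode).
#' @export
ynet_fit <- function(model, records, cfg = train_config()) {
  n <- length(records)
  if (n == 0L) stop("no training records")
  cls_only <- model$config$classification_only
  opt <- adam_state()
  seeds <- derive_seeds(cfg$seed, 2L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     seg_loss = numeric(), cls_loss = numeric())
  epoch_seeds <- derive_seeds(seeds[1L], max(cfg$epochs, 1L))
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    aug_seeds <- if (cfg$augment)
      with_seed(epoch_seeds[ep] %/% 2L + ep,
                sample.int(.Machine$integer.max - 1L, n))
    ep_loss <- ep_seg <- ep_cls <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      b <- records_to_batch(records, idx, model$config,
                            if (cfg$augment) aug_seeds[idx])
      tape <- ag_tape()
      P <- lapply(model$params, function(p) ag_leaf(tape, p))
      out <- ynet_forward_core(model$config, P, model$bn, b$x, train = TRUE)
      lcls <- ag_softmax_ce(out$cls, b$label)
      lcls_v <- ag_value(lcls)
      if (cls_only) {
        loss <- lcls
        lseg_v <- NA_real_
      } else {
        lseg <- ag_bce_logits(out$seg, b$mask)
        loss <- ag_axpy(lseg, lcls, cfg$lambda)
        lseg_v <- ag_value(lseg)
      }
      loss_v <- ag_value(loss)
      ag_backward(loss)   # releases tape values; read losses before this
      grads <- lapply(P, function(nd) nd$grad)
      model$params <- adam_update(model$params, grads, opt, cfg$initial_lr)
      ep_loss <- ep_loss + loss_v
      ep_seg <- ep_seg + lseg_v
      ep_cls <- ep_cls + lcls_v
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   seg_loss = ep_seg / nb,
                                   cls_loss = ep_cls / nb))
  }
  list(model = model, history = hist)
}

#' Evaluate a Y-Net model on a set of records
#'
#' Runs inference on every record (in mini-batches; batch-norm uses running
#' statistics so results are batch-independent), computes the per-record
#' Dice coefficient against the ground-truth masks, classification metrics
#' at `class_cutoff`, and the ROC/AUC of the malignant probability.
#'
#' @param model A trained `ynet` model.
#' @param records List of [ln_record()]s.
#' @param seg_threshold Probability threshold for the binary mask.
#' @param class_cutoff Malignant-probability cutoff.
#' @param batch_size Inference batch size.
#' @return A list: `dice` (per-record vector, `NULL` in
#'   classification-only mode), `dice_summary`, `scores` (malignant
#'   probabilities), `labels`, `predicted`, `metrics`
#'   ([diagnostic_metrics()]), `roc` ([roc_auc()] result or `NULL` if one
#'   class is absent).
#' @export
ynet_evaluate <- function(model, records,
                          seg_threshold = model$config$seg_threshold,
                          class_cutoff = 0.5, batch_size = 8L) {
  n <- length(records)
  cfg <- model$config
  scores <- numeric(n)
  dvals <- if (cfg$classification_only) NULL else numeric(n)
  labels <- vapply(records, function(r) r$label, integer(1))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    b <- records_to_batch(records, idx, cfg)
    out <- ynet_forward_core(cfg, model$params, model$bn, b$x, train = FALSE)
    z <- out$cls
    z <- sweep(z, 2L, apply(z, 2L, max))
    p <- exp(z)
    scores[idx] <- p[2L, ] / colSums(p)
    if (!cfg$classification_only) {
      for (j in seq_along(idx)) {
        pm <- 1 / (1 + exp(-out$seg[, , 1L, j]))
        dvals[idx[j]] <- dice((pm >= seg_threshold) * 1,
                              records[[idx[j]]]$mask)
      }
    }
  }
  predicted <- as.integer(scores >= class_cutoff)
  roc <- if (length(unique(labels)) == 2L) roc_auc(scores, labels) else NULL
  list(dice = dvals,
       dice_summary = if (!is.null(dvals)) summarize_dice(dvals),
       scores = scores, labels = labels, predicted = predicted,
       metrics = diagnostic_metrics(confusion_counts(predicted, labels)),
       roc = roc)
}

#' Train a Y-Net with cross-validation and final refit
#'
#' The full protocol: k-fold cross-validation over the training partition
#' of `split` (per-fold validation Dice and classification accuracy are
#' recorded), followed by a retrain on the whole training partition that
#' yields the final model.  Each fold and the final run rebuild the model
#' from `model$config` with seeds fanned out from `cfg$seed`, so the whole
#' procedure is deterministic.
#'
#' @param model A `ynet` model defining the architecture (as built by
#'   [build_ynet()]).
#' @param records List of [ln_record()]s covering all split indices.
#' @param split A [split_dataset()] plan.
#' @param cfg A [train_config()].
#' @return A list: `model` (final, trained on all training records),
#'   `history` (per-epoch losses of the final fit), `cv` (data frame with
#'   per-fold `fold`, `n_val`, `dice_median`, `accuracy`).
#' @export
ynet_train <- function(model, records, split, cfg = train_config()) {
  k <- cfg$k_folds
  folds <- sort(unique(split$fold_assignment))
  if (length(folds) < 2L) stop("split plan has fewer than 2 folds")
  if (any(table(split$fold_assignment) == 0L)) stop("empty fold")
  seeds <- derive_seeds(cfg$seed, length(folds) + 1L)
  cv <- data.frame()
  for (f in seq_along(folds)) {
    val_ids <- as.integer(names(split$fold_assignment)[
      split$fold_assignment == folds[f]])
    tr_ids <- setdiff(split$train_ids, val_ids)
    if (length(val_ids) == 0L || length(tr_ids) == 0L) stop("empty fold")
    m <- build_ynet(model$config, seed = seeds[f])
    fcfg <- cfg
    fcfg$seed <- seeds[f]
    fit <- ynet_fit(m, records[tr_ids], fcfg)
    ev <- ynet_evaluate(fit$model, records[val_ids])
    cv <- rbind(cv, data.frame(
      fold = folds[f], n_val = length(val_ids),
      dice_median = if (is.null(ev$dice)) NA_real_ else ev$dice_summary$median,
      accuracy = ev$metrics$acc))
  }
  final <- build_ynet(model$config, seed = seeds[length(seeds)])
  fcfg <- cfg
  fcfg$seed <- seeds[length(seeds)]
  fit <- ynet_fit(final, records[split$train_ids], fcfg)
  list(model = fit$model, history = fit$history, cv = cv)
}
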