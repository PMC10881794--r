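# Desk-scale end-to-end experiment on synthetic phantoms: the stand-in for
# a clinical evaluation, used by the test suite and the acceptance script.

#' Train and evaluate a Y-Net on a seeded phantom dataset
#'
#' Runs the full pipeline at desk scale: generate `n` phantoms, split them
#' by patient (about `1 - test_fraction` of patients for training), train
#' the joint model for `epochs` epochs, pick the classification cutoff by
#' Youden's J on the training-set ROC, and score the held-out records
#' (per-case Dice, diagnostic metrics at the chosen cutoff, AUC).  The
#' classification-only variant is then trained and evaluated under the
#' same harness.  Everything is a deterministic function of `seed`.
#'
#' @param seed Master seed for data generation, splitting, initialisation
#'   and training.
#' @param n Number of phantoms (default 250, giving about 200 training
#'   records at the default `test_fraction`).
#' @param malignant_fraction Fraction of malignant phantoms.
#' @param test_fraction Fraction of patients held out.
#' @param epochs Training epochs for the joint model.
#' @param cls_epochs Training epochs for the classification-only variant.
#' @param config A [ynet_config()] for the joint model.
#' @param quiet Suppress progress messages.
#' @return A list with elements `joint` and `cls_only`, each holding
#'   `eval` (see [ynet_evaluate()]), `cutoff`, `history` and `model`, plus
#'   `n_train` / `n_test`.
#' @export
ynet_synthetic_benchmark <- function(seed = 42L, n = 250L,
                                     malignant_fraction = 0.5,
                                     test_fraction = 0.2, epochs = 20L,
                                     cls_epochs = 8L,
                                     config = ynet_config(),
                                     quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating %d phantoms (seed %d)", n, seed)
  ds <- generate_dataset(n, malignant_fraction, seed = seed)
  split <- split_dataset(ds$records, test_fraction, k = 5L, seed = seed)
  tr <- ds$records[split$train_ids]
  te <- ds$records[split$test_ids]
  say("training joint model on %d records for %d epochs", length(tr), epochs)
  fit <- ynet_fit(build_ynet(config, seed = seed), tr,
                  train_config(epochs = epochs, seed = seed))
  cut <- choose_cutoff(ynet_evaluate(fit$model, tr)$roc)
  ev <- ynet_evaluate(fit$model, te, class_cutoff = cut$threshold)
  say("joint: Dice median %.3f, accuracy %.3f, AUC %.3f",
      ev$dice_summary$median, ev$metrics$acc, ev$roc$auc)

  ccfg <- config
  ccfg$classification_only <- TRUE
  say("training classification-only variant for %d epochs", cls_epochs)
  fitc <- ynet_fit(build_ynet(ccfg, seed = seed), tr,
                   train_config(epochs = cls_epochs, seed = seed))
  cutc <- choose_cutoff(ynet_evaluate(fitc$model, tr)$roc)
  evc <- ynet_evaluate(fitc$model, te, class_cutoff = cutc$threshold)
  say("cls-only: accuracy %.3f, AUC %.3f", evc$metrics$acc, evc$roc$auc)

  list(joint = list(eval = ev, cutoff = cut$threshold,
                    history = fit$history, model = fit$model),
       cls_only = list(eval = evc, cutoff = cutc$threshold,
                       history = fitc$history, model = fitc$model),
       n_train = length(tr), n_test = length(te))
}
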