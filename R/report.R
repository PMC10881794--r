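# Keyword-dictionary classification of free-text ultrasound report
# conclusions into benign / malignant, and scoring of a report set against
# reference labels.

#' Ultrasound diagnosis dictionary
#'
#' The default keyword sets map report phrases to a final diagnosis:
#' lymphadenopathy, abnormal lymph node, metastasis, CA/Ca, suspicious
#' calcification and suspicious necrosis read as malignant; normal lymph
#' node, reactive hyperplasia and normal structure read as benign.  Users
#' may extend or replace the sets (e.g. from YAML via
#' [read_dictionary()]).
#'
#' @param malignant,benign Character vectors of keywords.  The two sets
#'   must be disjoint case-insensitively.
#' @return Object of class `diagnosis_dictionary`.
#' @export
diagnosis_dictionary <- function(
    malignant = c("lymphadenopathy", "abnormal lymph node", "metastasis",
                  "CA", "Ca", "suspicious calcification",
                  "suspicious necrosis"),
    benign = c("normal lymph node", "reactive hyperplasia",
               "normal structure")) {
  malignant <- as.character(malignant)
  benign <- as.character(benign)
  if (length(intersect(tolower(malignant), tolower(benign))) > 0L)
    stop("malignant and benign keyword sets must be disjoint")
  structure(list(malignant = malignant, benign = benign),
            class = "diagnosis_dictionary")
}

#' Read a diagnosis dictionary from YAML
#'
#' The file must have top-level keys `malignant` and `benign`, each a list
#' of keyword strings.
#'
#' @param path Path to a YAML file.
#' @return A [diagnosis_dictionary()].
#' @export
read_dictionary <- function(path) {
  y <- yaml::read_yaml(path)
  diagnosis_dictionary(y$malignant, y$benign)
}

#' Write a diagnosis dictionary to YAML
#' @param dict A [diagnosis_dictionary()].
#' @param path Output path.
#' @export
write_dictionary <- function(dict, path) {
  yaml::write_yaml(list(malignant = as.list(dict$malignant),
                        benign = as.list(dict$benign)), path)
  invisible(path)
}

# Case-insensitive keyword match.  Keywords of up to two letters (the
# carcinoma abbreviations "CA"/"Ca") are matched as whole words only, so
# they do not fire inside e.g. "calcification"; longer keywords match as
# substrings of the normalised text.
keyword_hits <- function(text, keywords) {
  lt <- tolower(trimws(text))
  hit <- vapply(keywords, function(k) {
    lk <- tolower(k)
    if (nchar(lk) <= 2L)
      grepl(paste0("\\b", lk, "\\b"), lt, perl = TRUE)
    else grepl(lk, lt, fixed = TRUE)
  }, logical(1))
  keywords[hit]
}

#' Classify one free-text report conclusion
#'
#' Case-insensitive keyword matching against the dictionary.  Any malignant
#' keyword present makes the verdict malignant even if benign keywords also
#' match (suspicion of malignancy is what triggers fine-needle aspiration);
#' only benign keywords give a benign verdict; no keyword at all leaves the
#' report unresolved.
#'
#' @param text Non-empty report string.
#' @param dict A [diagnosis_dictionary()].
#' @return Object of class `report_verdict`: `label` (0, 1 or
#'   `NA` = unresolved) and `matched_keywords`.
#' @export
classify_report <- function(text, dict = diagnosis_dictionary()) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("report text must be a non-empty string")
  mal <- keyword_hits(text, dict$malignant)
  ben <- keyword_hits(text, dict$benign)
  label <- if (length(mal) > 0L) 1L else if (length(ben) > 0L) 0L
           else NA_integer_
  structure(list(label = label,
                 matched_keywords = unname(c(mal, ben))),
            class = "report_verdict")
}

#' Score a report set against reference labels
#'
#' Classifies every report with [classify_report()]; unresolved reports are
#' excluded from the confusion counts but tallied.  The resolved verdicts
#' are scored with [diagnostic_metrics()].
#'
#' @param reports Data frame with columns `report_text` (or `text`) and
#'   `label` (0/1 reference).
#' @param dict A [diagnosis_dictionary()].
#' @return A list: `metrics` ([diagnostic_metrics()]), `unresolved`
#'   (count), `verdicts` (integer vector with `NA` for unresolved).
#' @export
evaluate_reports <- function(reports, dict = diagnosis_dictionary()) {
  txt_col <- intersect(c("report_text", "text"), names(reports))[1L]
  if (is.na(txt_col) || !"label" %in% names(reports))
    stop("reports must have columns report_text (or text) and label")
  if (!is_binary(reports$label)) stop("reference labels must be 0 or 1")
  verdicts <- vapply(reports[[txt_col]],
                     function(t) classify_report(t, dict)$label,
                     integer(1), USE.NAMES = FALSE)
  resolved <- !is.na(verdicts)
  if (!any(resolved))
    stop("all reports are unresolved; metrics are undefined")
  list(metrics = diagnostic_metrics(
         confusion_counts(verdicts[resolved], reports$label[resolved])),
       unresolved = sum(!resolved),
       verdicts = verdicts)
}
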