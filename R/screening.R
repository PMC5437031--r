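# Consensus batch screening of compound libraries with the three
# ensembles.

#' Screen a compound library with three ensembles
#'
#' Predicts every library compound with the SVM, RF and XGBoost ensembles,
#' flags consensus carcinogens (all three classes positive),
#' high-confidence hits, and duplicates of the training set (canonical
#' SMILES keys). High-confidence rule "strict": all three probabilities
#' strictly greater than `cutoff` (0.8); "permissive": consensus plus any
#' probability at or above the cutoff.
#'
#' @param x curated [CompoundSet-class] library (labels not required).
#' @param models named list with elements `svm`, `rf`, `xgb`, each an
#'   [EnsembleModel-class].
#' @param training optional [CompoundSet-class]; used to flag library
#'   compounds duplicating the training data (defaults to the keys stored
#'   in the models).
#' @param high_confidence "strict" or "permissive".
#' @param cutoff high-confidence probability cutoff (default 0.8).
#' @return list(report, summary). `report` is sorted by decreasing mean
#'   probability with columns id, name, prob_svm, prob_rf, prob_xgb,
#'   class_svm, class_rf, class_xgb, mean_probability, consensus,
#'   high_confidence, duplicate_of_training. `summary` counts per-model
#'   positives, consensus, high-confidence and novel consensus compounds.
#' @export
screenLibrary <- function(x, models, training = NULL,
                          high_confidence = c("strict", "permissive"),
                          cutoff = 0.8) {
  high_confidence <- match.arg(high_confidence)
  stopifnot(is(x, "CompoundSet"))
  need <- c("svm", "rf", "xgb")
  if (!is.list(models) || !all(need %in% names(models)) ||
      !all(vapply(need, function(n) is(models[[n]], "EnsembleModel"),
                  logical(1))))
    stop("`models` must be a named list with EnsembleModel elements ",
         "'svm', 'rf' and 'xgb'", call. = FALSE)
  if (length(x) == 0L)
    return(list(report = data.frame(), summary = list(
      n_library = 0L, positives = c(svm = 0L, rf = 0L, xgb = 0L),
      consensus = 0L, high_confidence = 0L, novel_consensus = 0L)))
  fams <- unique(unlist(lapply(models, function(m) names(m@members))))
  matrices <- computeMatrices(x, fams)
  preds <- lapply(models, function(m) ensemblePredict(m, matrices))
  ids <- compoundIds(x)
  rec <- compoundData(x)
  keys <- cleanSmiles(x)
  train_keys <- if (!is.null(training)) cleanSmiles(training) else
    unique(unlist(lapply(models, function(m) m@training_keys)))
  probs <- cbind(svm = preds$svm$probability,
                 rf = preds$rf$probability,
                 xgb = preds$xgb$probability)
  classes <- cbind(svm = preds$svm$class, rf = preds$rf$class,
                   xgb = preds$xgb$class)
  consensus <- rowSums(classes) == 3L
  hc <- switch(high_confidence,
    strict = rowSums(probs > cutoff) == 3L & consensus,
    permissive = consensus & rowSums(probs >= cutoff) >= 1L)
  report <- data.frame(
    id = ids, name = rec$name,
    prob_svm = probs[, "svm"], prob_rf = probs[, "rf"],
    prob_xgb = probs[, "xgb"],
    class_svm = classes[, "svm"], class_rf = classes[, "rf"],
    class_xgb = classes[, "xgb"],
    mean_probability = rowMeans(probs),
    consensus = consensus, high_confidence = hc,
    duplicate_of_training = unname(keys %in% train_keys),
    stringsAsFactors = FALSE)
  report <- report[order(-report$mean_probability, report$id), ]
  rownames(report) <- NULL
  summary <- list(
    n_library = length(ids),
    positives = c(svm = sum(classes[, "svm"]), rf = sum(classes[, "rf"]),
                  xgb = sum(classes[, "xgb"])),
    consensus = sum(consensus),
    high_confidence = sum(hc),
    novel_consensus = sum(report$consensus & !report$duplicate_of_training))
  list(report = report, summary = summary)
}

#' Write a screening report
#'
#' CSV of the per-compound table plus a JSON summary. An empty result is
#' valid output.
#'
#' @param screen result of [screenLibrary()].
#' @param csv path for the per-compound CSV (NULL to skip).
#' @param json path for the summary JSON (NULL to skip).
#' @export
writeScreeningReport <- function(screen, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(screen$report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(screen$summary, json, auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(screen)
}
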