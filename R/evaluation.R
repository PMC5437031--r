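# Repeated k-fold cross-validation, external validation and learning
# curves for the fingerprint ensembles.

#' Cross-validation configuration
#'
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 100; k x repeats metric
#'   records are produced).
#' @param stratified stratify folds by class (default TRUE; FALSE gives
#'   the literal "randomly divided into k equal parts" protocol).
#' @param seed integer; fold assignments derive from it.
#' @return a list of class "cvConfig".
#' @export
cvConfig <- function(k = 5L, repeats = 100L, stratified = TRUE, seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cvConfig")
}

# fold assignment; sizes within +/- 1; resamples (with a message) when a
# training fold would miss a class
.makeFolds <- function(y, k, stratified, seed) {
  n <- length(y)
  for (attempt in seq_len(100L)) {
    folds <- withSeed(seed + attempt - 1L, {
      if (stratified) {
        f <- integer(n)
        for (cl in unique(y)) {
          idx <- sample(which(y == cl))
          f[idx] <- rep_len(sample(seq_len(k)), length(idx))
        }
        f
      } else {
        sample(rep_len(seq_len(k), n))
      }
    })
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds != f])) == 2L && sum(folds == f) > 0L,
      logical(1)))
    if (ok) {
      if (attempt > 1L)
        message("fold assignment resampled ", attempt - 1L,
                " time(s) to keep both classes in every training fold")
      return(folds)
    }
  }
  stop("could not build folds with both classes in every training fold",
       call. = FALSE)
}

#' Repeated k-fold cross-validation of a fingerprint ensemble
#'
#' For every repeat the data are split into k folds (stratified by
#' default); for every fold an ensemble is trained on the remaining folds
#' and scored on the held-out fold. With `fs$scope = "fold"` (default)
#' feature selection is recomputed on the training rows of each fold;
#' `"global"` selects once on the full dataset before the loop. Records are
#' returned in (repeat, fold) order; all randomness derives from
#' `cv$seed`.
#'
#' @param x labeled, curated [CompoundSet-class].
#' @param fingerprints families to fuse (default [topFingerprints()]).
#' @param algorithm learning algorithm.
#' @param cv a [cvConfig()].
#' @param fs a [featSelConfig()].
#' @param base a [baseConfig()]; NULL uses the algorithm's defaults.
#' @param matrices optional precomputed family matrices.
#' @param verbose print one line per repeat.
#' @return a [CVResultSet-class] with k x repeats metric records and a
#'   mean/SD summary (AUC scaled to percent in the summary).
#' @export
repeatedCV <- function(x, fingerprints = topFingerprints(),
                       algorithm = c("random_forest", "svm_rbf", "xgboost"),
                       cv = cvConfig(), fs = featSelConfig(), base = NULL,
                       matrices = NULL, verbose = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(base)) base <- baseConfig(algorithm, seed = cv$seed)
  base$algorithm <- algorithm
  stopifnot(is(x, "CompoundSet"))
  y <- compoundLabels(x)
  if (anyNA(y)) stop("all compounds must be labeled", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  if (is.null(matrices)) matrices <- computeMatrices(x, fingerprints)
  vals <- lapply(matrices[fingerprints], .asValues)
  kept_global <- NULL
  if (fs$scope == "global")
    kept_global <- lapply(vals, function(v) featureSelect(v, fs)$report@kept)
  rows <- vector("list", cv$repeats * cv$k)
  ri <- 0L
  for (r in seq_len(cv$repeats)) {
    folds <- .makeFolds(y, cv$k, cv$stratified,
                        deriveSeed(cv$seed, paste0("cv-repeat-", r)))
    for (f in seq_len(cv$k)) {
      tr <- folds != f
      probs <- matrix(NA_real_, sum(!tr), length(fingerprints))
      for (m in seq_along(fingerprints)) {
        fam <- fingerprints[m]
        v <- vals[[fam]]
        kept <- if (!is.null(kept_global)) kept_global[[fam]] else
          featureSelect(v[tr, , drop = FALSE], fs)$report@kept
        if (length(kept) == 0L) { probs[, m] <- 0.5; next }
        bc <- base
        bc$seed <- deriveSeed(base$seed,
                              paste("fit", algorithm, fam, r, f, sep = "-"))
        mdl <- trainBase(v[tr, kept, drop = FALSE], y[tr], bc,
                         fingerprint = fam)
        probs[, m] <- predictBase(mdl, v[!tr, , drop = FALSE])
      }
      met <- computeMetrics(y[!tr], rowMeans(probs))
      ri <- ri + 1L
      rows[[ri]] <- cbind(data.frame(repeat_ = r, fold = f), met)
    }
    if (verbose) message("repeat ", r, "/", cv$repeats, " done")
  }
  records <- do.call(rbind, rows)
  names(records)[1] <- "repeat"
  new("CVResultSet", records = records,
      summary = .cvSummarize(records),
      config = list(k = cv$k, repeats = cv$repeats,
                    stratified = cv$stratified, seed = cv$seed,
                    scope = fs$scope, algorithm = algorithm,
                    fingerprints = fingerprints))
}

# mean/SD of Q, SE, SP and AUC (as percent) over the metric records
.cvSummarize <- function(records) {
  vals <- data.frame(Q = records$Q, SE = records$SE, SP = records$SP,
                     AUC = 100 * records$AUC)
  data.frame(metric = names(vals),
             mean = vapply(vals, function(v) mean(v, na.rm = TRUE),
                           numeric(1)),
             sd = vapply(vals, function(v) stats::sd(v, na.rm = TRUE),
                         numeric(1)),
             row.names = NULL)
}

#' Validate a trained ensemble on an external dataset
#'
#' The external set is checked for structural overlap with the model's
#' training compounds (canonical-SMILES keys); overlaps trigger a warning
#' naming the duplicates but predictions are still produced.
#'
#' @param model an [EnsembleModel-class].
#' @param x labeled, curated [CompoundSet-class].
#' @return list(metrics = one-row metric data.frame,
#'   predictions = per-compound probability table).
#' @export
externalValidate <- function(model, x) {
  stopifnot(is(model, "EnsembleModel"), is(x, "CompoundSet"))
  if (length(x) == 0L) stop("empty external dataset", call. = FALSE)
  y <- compoundLabels(x)
  if (anyNA(y)) stop("external compounds must be labeled", call. = FALSE)
  dup <- compoundIds(x)[cleanSmiles(x) %in% model@training_keys]
  if (length(dup))
    warning("external compounds duplicated in training set: ",
            paste(utils::head(dup, 10), collapse = ", "))
  pred <- ensemblePredict(model, x)
  pred$label <- unname(y)
  list(metrics = computeMetrics(y, pred$probability, model@threshold),
       predictions = pred)
}

#' Learning curve: performance as a function of training-set size
#'
#' For every size, compounds are repeatedly subsampled without replacement;
#' each subsample is evaluated by k-fold cross-validation and (optionally)
#' an ensemble trained on the whole subsample is scored on the external
#' set. Summaries are mean and standard error across repeats.
#'
#' @param x labeled, curated [CompoundSet-class].
#' @param sizes training-set sizes (default 100 to min(1000, n) by 100).
#' @param repeats subsample draws per size (default 100).
#' @param algorithm learning algorithm (default random forest, which needs
#'   no tuning).
#' @param external optional labeled [CompoundSet-class] for external
#'   validation at each size.
#' @param fingerprints families to fuse.
#' @param cv_k folds of the inner cross-validation.
#' @param fs a [featSelConfig()].
#' @param seed integer seed.
#' @return list(records, summary): `records` has one row per
#'   (size, repeat, phase) with the metric values; `summary` has mean and
#'   standard error per (size, phase, metric).
#' @export
learningCurve <- function(x, sizes = NULL, repeats = 100L,
                          algorithm = "random_forest", external = NULL,
                          fingerprints = topFingerprints(), cv_k = 5L,
                          fs = featSelConfig(), seed = 1L) {
  stopifnot(is(x, "CompoundSet"))
  n <- length(x)
  if (is.null(sizes)) sizes <- seq(100L, min(1000L, n), by = 100L)
  if (max(sizes) > n)
    stop("requested size ", max(sizes), " exceeds dataset size ", n,
         call. = FALSE)
  y_all <- compoundLabels(x)
  matrices <- computeMatrices(x, fingerprints)
  ext_matrices <- if (!is.null(external))
    computeMatrices(external, fingerprints) else NULL
  rows <- list()
  for (size in sizes) {
    for (rep_i in seq_len(repeats)) {
      sub <- NULL
      for (attempt in seq_len(100L)) {
        cand <- withSeed(
          deriveSeed(seed, paste("lc", size, rep_i, attempt, sep = "-")),
          sample(n, size))
        if (length(unique(y_all[cand])) == 2L) { sub <- sort(cand); break }
      }
      if (is.null(sub)) stop("could not draw a two-class subsample")
      xs <- x[sub]
      sub_matrices <- lapply(matrices, function(fm)
        .rewrap(fm, .asValues(fm)[sub, , drop = FALSE]))
      cvres <- repeatedCV(xs, fingerprints, algorithm,
                          cv = cvConfig(k = cv_k, repeats = 1L,
                                        seed = deriveSeed(seed,
                                          paste("lc-cv", size, rep_i,
                                                sep = "-"))),
                          fs = fs, matrices = sub_matrices)
      rec <- cvRecords(cvres)
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, rep = rep_i, phase = "cv",
        Q = mean(rec$Q), SE = mean(rec$SE), SP = mean(rec$SP),
        AUC = 100 * mean(rec$AUC))
      if (!is.null(external)) {
        mdl <- trainEnsemble(xs, fingerprints, algorithm, fs = fs,
                             base = baseConfig(algorithm,
                               seed = deriveSeed(seed,
                                 paste("lc-train", size, rep_i,
                                       sep = "-"))),
                             matrices = sub_matrices)
        ev <- suppressWarnings(externalValidate(mdl, external))
        m <- ev$metrics
        rows[[length(rows) + 1L]] <- data.frame(
          size = size, rep = rep_i, phase = "external",
          Q = m$Q, SE = m$SE, SP = m$SP, AUC = 100 * m$AUC)
      }
    }
  }
  records <- do.call(rbind, rows)
  long <- do.call(rbind, lapply(c("Q", "SE", "SP", "AUC"), function(met) {
    agg <- stats::aggregate(records[[met]],
                            by = list(size = records$size,
                                      phase = records$phase),
                            FUN = function(v) c(mean = mean(v),
                              se = stats::sd(v) / sqrt(length(v))))
    data.frame(size = agg$size, phase = agg$phase, metric = met,
               mean = agg$x[, "mean"], se = agg$x[, "se"])
  }))
  list(records = records, summary = long[order(long$metric, long$phase,
                                               long$size), ])
}

#' Write cross-validation results to disk
#'
#' Tidy per-fold CSV (repeat, fold, confusion counts, metrics) plus a JSON
#' summary of the configuration and the mean/SD table.
#'
#' @param x a [CVResultSet-class].
#' @param csv path for the records CSV (NULL to skip).
#' @param json path for the summary JSON (NULL to skip).
#' @export
writeCVResult <- function(x, csv = NULL, json = NULL) {
  stopifnot(is(x, "CVResultSet"))
  if (!is.null(csv)) utils::write.csv(cvRecords(x), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(config = x@config,
                              summary = cvSummary(x)),
                         json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(x)
}
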