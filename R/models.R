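# Base classifiers (radial SVM, random forest, gradient-boosted trees) and
# their fusion into probability-averaging ensembles.

#' Default fingerprint set for ensembles
#'
#' The seven families whose base classifiers are fused by default: the
#' three hashed families, MACCS, Pubchem, and the Klekota-Roth bit and
#' count families. The five remaining families (Estate, FP4, FP4C, AP2D,
#' AP2DC) give clearly weaker base classifiers and are left out.
#'
#' @return character vector of 7 family names.
#' @export
topFingerprints <- function() {
  c("CDK", "CDKExt", "CDKGraph", "MACCS", "Pubchem", "KR", "KRC")
}

#' Base-classifier configuration
#'
#' Random forest: ntree = 500 and mtry = floor(sqrt(p)) unless overridden.
#' SVM-RBF: fixed C/gamma by default (gamma = 1/p when NULL); with
#' `tune = TRUE`, C and gamma are drawn log-uniformly from
#' [2^-5, 2^15] x [2^-15, 2^3] (`n_draws` draws) and picked by inner
#' `inner_k`-fold accuracy on the training rows only. XGBoost: fixed
#' eta/max_depth/min_child_weight/nrounds by default; with `tune = TRUE`
#' the grid eta {0.05, 0.1, 0.3} x max_depth {3, 6, 9} x
#' min_child_weight {1, 5} x nrounds {100, 300} is searched by inner CV.
#'
#' @param algorithm "svm_rbf", "random_forest" or "xgboost".
#' @param seed integer; makes fits and tuning draws reproducible.
#' @param ... overrides for the per-algorithm defaults listed above.
#' @return a list of class "baseConfig".
#' @export
baseConfig <- function(algorithm = c("random_forest", "svm_rbf", "xgboost"),
                       seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    random_forest = list(ntree = 500L, mtry = NULL),
    svm_rbf = list(C = 1, gamma = NULL, tune = FALSE, n_draws = 30L,
                   inner_k = 5L, C_range = c(2^-5, 2^15),
                   gamma_range = c(2^-15, 2^3)),
    xgboost = list(eta = 0.1, max_depth = 6L, min_child_weight = 1,
                   nrounds = 100L, tune = FALSE, inner_k = 5L,
                   grid = expand.grid(eta = c(0.05, 0.1, 0.3),
                                      max_depth = c(3L, 6L, 9L),
                                      min_child_weight = c(1, 5),
                                      nrounds = c(100L, 300L))))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown ", algorithm, " option(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(c(list(algorithm = algorithm, seed = as.integer(seed)),
              defaults), class = "baseConfig")
}

.checkTrainInput <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  if (ncol(X) == 0L) stop("no feature columns to train on", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  list(X = X, y = y)
}

.innerFolds <- function(y, k, seed) {
  withSeed(seed, {
    folds <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

.innerCvAccuracy <- function(X, y, k, seed, fit_fun, pred_fun) {
  folds <- .innerFolds(y, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    fit <- fit_fun(X[tr, , drop = FALSE], y[tr])
    p <- pred_fun(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum((p >= 0.5) == (y[!tr] == 1L))
  }
  correct / length(y)
}

.fitSvm <- function(X, y, C, gamma, seed) {
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  withSeed(seed,
    e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = C, gamma = gamma, probability = TRUE, scale = FALSE))
}

.predSvm <- function(fit, X) {
  pr <- attr(stats::predict(fit, X, probability = TRUE), "probabilities")
  unname(pr[, "1"])
}

.fitRf <- function(X, y, ntree, mtry, seed, importance = FALSE) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 num.trees = ntree, mtry = min(mtry, ncol(X)),
                 probability = TRUE, seed = seed, num.threads = 1L,
                 importance = if (importance) "impurity" else "none")
}

.predRf <- function(fit, X) {
  unname(stats::predict(fit, data = X, num.threads = 1L)$predictions[, "1"])
}

.fitXgb <- function(X, y, eta, max_depth, min_child_weight, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  withSeed(seed,
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = eta,
                    max_depth = max_depth,
                    min_child_weight = min_child_weight,
                    nthread = 1L),
      data = dtrain, nrounds = nrounds, verbose = 0))
}

.predXgb <- function(fit, X) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X)))
}

#' Train one fingerprint-specific base classifier
#'
#' Any hyperparameter search runs only on the supplied training rows,
#' through seeded inner cross-validation.
#'
#' @param X numeric matrix of selected fingerprint features.
#' @param y 0/1 labels (both classes required).
#' @param config a [baseConfig()].
#' @param fingerprint family name recorded on the model (metadata).
#' @return a [TrainedBaseClassifier-class].
#' @export
trainBase <- function(X, y, config = baseConfig(), fingerprint = "custom") {
  ck <- .checkTrainInput(X, y)
  X <- ck$X; y <- ck$y
  alg <- config$algorithm
  seed <- config$seed
  fit <- switch(alg,
    svm_rbf = {
      C <- config$C; gamma <- config$gamma
      if (isTRUE(config$tune)) {
        draws <- withSeed(deriveSeed(seed, "svm-search"), data.frame(
          C = exp(stats::runif(config$n_draws, log(config$C_range[1]),
                               log(config$C_range[2]))),
          gamma = exp(stats::runif(config$n_draws, log(config$gamma_range[1]),
                                   log(config$gamma_range[2])))))
        acc <- vapply(seq_len(nrow(draws)), function(d)
          .innerCvAccuracy(X, y, config$inner_k,
                           deriveSeed(seed, "svm-inner"),
                           function(Xt, yt) .fitSvm(Xt, yt, draws$C[d],
                                                    draws$gamma[d], seed),
                           .predSvm), numeric(1))
        best <- which.max(acc)
        C <- draws$C[best]; gamma <- draws$gamma[best]
      }
      .fitSvm(X, y, C, gamma, seed)
    },
    random_forest = .fitRf(X, y, config$ntree, config$mtry, seed),
    xgboost = {
      par <- config[c("eta", "max_depth", "min_child_weight", "nrounds")]
      if (isTRUE(config$tune)) {
        grid <- config$grid
        acc <- vapply(seq_len(nrow(grid)), function(g)
          .innerCvAccuracy(X, y, config$inner_k,
                           deriveSeed(seed, "xgb-inner"),
                           function(Xt, yt) .fitXgb(Xt, yt, grid$eta[g],
                             grid$max_depth[g], grid$min_child_weight[g],
                             grid$nrounds[g], seed),
                           .predXgb), numeric(1))
        best <- which.max(acc)
        par <- as.list(grid[best, ])
      }
      .fitXgb(X, y, par$eta, par$max_depth, par$min_child_weight,
              par$nrounds, seed)
    })
  new("TrainedBaseClassifier", fingerprint = fingerprint, algorithm = alg,
      kept_columns = colnames(X), fit = fit, config = unclass(config))
}

#' Predict class probabilities with a base classifier
#'
#' @param model a [TrainedBaseClassifier-class].
#' @param X full fingerprint matrix (or values) for the model's family; the
#'   model's kept columns are extracted, and an error names the member if
#'   any are missing.
#' @return numeric vector of carcinogen probabilities in [0, 1].
#' @export
predictBase <- function(model, X) {
  stopifnot(is(model, "TrainedBaseClassifier"))
  v <- .asValues(X)
  miss <- setdiff(model@kept_columns, colnames(v))
  if (length(miss))
    stop("member ", model@fingerprint, ": missing feature columns: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  v <- v[, model@kept_columns, drop = FALSE]
  p <- switch(model@algorithm,
    svm_rbf = .predSvm(model@fit, v),
    random_forest = .predRf(model@fit, v),
    xgboost = .predXgb(model@fit, v))
  pmin(pmax(p, 0), 1)
}

#' Train an ensemble over a fingerprint set
#'
#' Computes (or reuses) the family matrices, applies zero-variance and
#' correlation filtering per family on the supplied training data, trains
#' one base classifier per family, and fuses them with mean-probability
#' averaging.
#'
#' @param x labeled, curated [CompoundSet-class].
#' @param fingerprints families to fuse (default [topFingerprints()]).
#' @param algorithm learning algorithm for all members.
#' @param fs a [featSelConfig()] (selection here is always on the data
#'   given, i.e. "global" with respect to `x`).
#' @param base a [baseConfig()]; its algorithm field is overridden.
#' @param matrices optional named list of precomputed
#'   [FingerprintMatrix-class] objects.
#' @param threshold decision cutoff on the mean probability.
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(x, fingerprints = topFingerprints(),
                          algorithm = c("random_forest", "svm_rbf",
                                        "xgboost"),
                          fs = featSelConfig(), base = NULL,
                          matrices = NULL, threshold = 0.5) {
  algorithm <- match.arg(algorithm)
  if (is.null(base)) base <- baseConfig(algorithm)
  base$algorithm <- algorithm
  stopifnot(is(x, "CompoundSet"))
  y <- compoundLabels(x)
  if (anyNA(y)) stop("all training compounds must be labeled", call. = FALSE)
  if (is.null(matrices)) matrices <- computeMatrices(x, fingerprints)
  members <- list()
  for (fam in fingerprints) {
    sel <- featureSelect(matrices[[fam]], fs)
    bc <- base
    bc$seed <- deriveSeed(base$seed, paste0("base-", algorithm, "-", fam))
    members[[fam]] <- trainBase(fpValues(sel$matrix), y, bc,
                                fingerprint = fam)
  }
  new("EnsembleModel", algorithm = algorithm, members = members,
      threshold = threshold, training_keys = unname(cleanSmiles(x)),
      version = "1")
}

#' Ensemble prediction by probability averaging
#'
#' The ensemble probability of each compound is the arithmetic mean of the
#' member probabilities; the class is carcinogen when the mean reaches the
#' model threshold.
#'
#' @param model an [EnsembleModel-class].
#' @param x a curated [CompoundSet-class], or a named list of
#'   [FingerprintMatrix-class] covering every member family.
#' @return data.frame: id, one `prob_<family>` column per member,
#'   probability (the mean), class (0/1).
#' @export
ensemblePredict <- function(model, x) {
  stopifnot(is(model, "EnsembleModel"))
  fams <- names(model@members)
  if (is(x, "CompoundSet")) {
    matrices <- computeMatrices(x, fams)
    ids <- compoundIds(x)
  } else {
    matrices <- x
    miss <- setdiff(fams, names(matrices))
    if (length(miss))
      stop("missing fingerprint matrices for member(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ids <- rownames(.asValues(matrices[[fams[1]]]))
  }
  probs <- vapply(fams, function(fam)
    predictBase(model@members[[fam]], matrices[[fam]]),
    numeric(length(ids)))
  if (length(ids) == 1L) probs <- matrix(probs, nrow = 1,
                                         dimnames = list(NULL, fams))
  pbar <- rowMeans(probs)
  out <- data.frame(id = ids, probs, check.names = FALSE)
  names(out)[-1] <- paste0("prob_", fams)
  out$probability <- pbar
  out$class <- as.integer(pbar >= model@threshold)
  rownames(out) <- NULL
  out
}

#' Rank fingerprint families by mean cross-validated accuracy
#'
#' Averages each family's accuracy across algorithms and orders families
#' from best to worst with a stable sort (ties keep input order).
#'
#' @param cv_table data.frame with columns `algorithm`, `fingerprint`, `Q`.
#' @param k optionally return only the top k families.
#' @return character vector of family names, best first.
#' @export
rankFingerprints <- function(cv_table, k = NULL) {
  stopifnot(all(c("fingerprint", "Q") %in% names(cv_table)))
  fams <- unique(cv_table$fingerprint)
  means <- vapply(fams, function(f)
    mean(cv_table$Q[cv_table$fingerprint == f]), numeric(1))
  ord <- order(-means)   # radix sort: stable for ties
  out <- fams[ord]
  if (!is.null(k)) out <- utils::head(out, k)
  out
}

#' Save an ensemble model bundle
#'
#' Writes a versioned archive (RDS) of the members, their kept columns and
#' configurations; boosted-tree members are stored in their raw
#' serialization format. [loadEnsemble()] refuses archives with an
#' incompatible format version.
#'
#' @param model an [EnsembleModel-class].
#' @param path output file.
#' @export
saveEnsemble <- function(model, path) {
  stopifnot(is(model, "EnsembleModel"))
  members <- lapply(model@members, function(mb) {
    fit <- mb@fit
    raw <- NULL
    if (mb@algorithm == "xgboost") {
      raw <- xgboost::xgb.save.raw(fit)
      fit <- NULL
    }
    list(fingerprint = mb@fingerprint, algorithm = mb@algorithm,
         kept_columns = mb@kept_columns, fit = fit, raw = raw,
         config = mb@config)
  })
  saveRDS(list(format_version = "1",
               package_version = as.character(utils::packageVersion(
                 "CarcinoEnsemble")),
               algorithm = model@algorithm, threshold = model@threshold,
               training_keys = model@training_keys, members = members),
          path)
  invisible(path)
}

#' Load an ensemble model bundle
#'
#' @param path archive written by [saveEnsemble()].
#' @return an [EnsembleModel-class].
#' @export
loadEnsemble <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, "1"))
    stop("incompatible model archive version: ",
         bundle$format_version %||% "<missing>", call. = FALSE)
  members <- lapply(bundle$members, function(mb) {
    fit <- mb$fit
    if (mb$algorithm == "xgboost") fit <- xgboost::xgb.load.raw(mb$raw)
    new("TrainedBaseClassifier", fingerprint = mb$fingerprint,
        algorithm = mb$algorithm, kept_columns = mb$kept_columns,
        fit = fit, config = mb$config)
  })
  names(members) <- vapply(members, function(m) m@fingerprint, character(1))
  new("EnsembleModel", algorithm = bundle$algorithm, members = members,
      threshold = bundle$threshold, training_keys = bundle$training_keys,
      version = bundle$format_version)
}
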