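# Substructure importance: random-forest Gini importance of structural
# fingerprint keys, with per-class occurrence counts.

#' Gini importance of structural fingerprint keys
#'
#' Trains `repeats` independently seeded random forests (ntree trees each)
#' on the feature-selected fingerprint matrix of the full labeled dataset
#' and averages the per-key mean decrease in Gini impurity. Only
#' structural-key and count families are interpretable; hashed-path
#' families are refused.
#'
#' @param x labeled, curated [CompoundSet-class].
#' @param family structural fingerprint family name (e.g. "MACCS").
#' @param repeats number of forest reseeds used for the mean and SD.
#' @param seed integer seed.
#' @param fs a [featSelConfig()] applied before fitting.
#' @param ntree trees per forest.
#' @param matrix optional precomputed [FingerprintMatrix-class].
#' @return data.frame sorted by decreasing mean importance (ties by key
#'   index): key, description, smarts, mean_decrease_gini,
#'   sd_decrease_gini, n_present_positives, n_present_negatives. The
#'   [SelectionReport-class] of the feature selection is attached as
#'   attribute "selection".
#' @export
giniImportance <- function(x, family, repeats = 10L, seed = 1L,
                           fs = featSelConfig(), ntree = 500L,
                           matrix = NULL) {
  spec <- fingerprintSpec(family)
  if (spec@kind == "hashed-path")
    stop("hashed-path family ", family,
         " has no interpretable bits; use a structural-key family",
         call. = FALSE)
  stopifnot(is(x, "CompoundSet"))
  y <- compoundLabels(x)
  if (anyNA(y)) stop("all compounds must be labeled", call. = FALSE)
  if (is.null(matrix)) matrix <- computeMatrix(x, spec)
  sel <- featureSelect(matrix, fs)
  v <- .asValues(sel$matrix)
  if (ncol(v) == 0L) stop("no features survive selection", call. = FALSE)
  imp <- vapply(seq_len(repeats), function(r) {
    fit <- .fitRf(v, y, ntree = ntree, mtry = NULL,
                  seed = deriveSeed(seed, paste0("imp-", family, "-", r)),
                  importance = TRUE)
    ranger::importance(fit)[colnames(v)]
  }, numeric(ncol(v)))
  if (ncol(v) == 1L) imp <- matrix(imp, nrow = 1,
                                   dimnames = list(colnames(v), NULL))
  dict <- keyDictionary(family)
  di <- match(colnames(v), dict$name)
  present_pos <- colSums(v[y == 1L, , drop = FALSE] > 0L)
  present_neg <- colSums(v[y == 0L, , drop = FALSE] > 0L)
  tab <- data.frame(
    key = colnames(v),
    description = dict$description[di],
    smarts = dict$smarts[di],
    mean_decrease_gini = rowMeans(imp),
    sd_decrease_gini = apply(imp, 1, stats::sd),
    n_present_positives = as.integer(present_pos),
    n_present_negatives = as.integer(present_neg),
    stringsAsFactors = FALSE)
  ord <- order(-tab$mean_decrease_gini, dict$index[di])
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "selection") <- sel$report
  tab
}

#' First k rows of an importance table
#'
#' @param tab importance table from [giniImportance()] (already sorted).
#' @param k number of rows (default 5).
#' @return the first k rows; if k exceeds the table, all rows with a
#'   warning.
#' @export
topFeatures <- function(tab, k = 5L) {
  stopifnot(is.data.frame(tab))
  if (k > nrow(tab)) {
    warning("k = ", k, " exceeds table size ", nrow(tab),
            "; returning all rows")
    k <- nrow(tab)
  }
  tab[seq_len(max(0L, k)), , drop = FALSE]
}

#' Per-class occurrence counts of a SMARTS pattern
#'
#' Counts the molecules (not matches) of each class containing at least
#' one match of the pattern, using OpenBabel's SMARTS matcher.
#'
#' @param x labeled, curated [CompoundSet-class].
#' @param smarts a single SMARTS string.
#' @return named integer vector: n_positives_with_match,
#'   n_negatives_with_match.
#' @export
occurrenceCounts <- function(x, smarts) {
  stopifnot(is(x, "CompoundSet"))
  .assertScalarChr(smarts, "smarts")
  y <- compoundLabels(x)
  if (anyNA(y)) stop("all compounds must be labeled", call. = FALSE)
  smi <- cleanSmiles(x)
  names(smi) <- paste0("s", seq_along(smi))
  sdfs <- ChemmineR::smiles2sdf(smi)
  hits <- tryCatch(ChemmineR::smartsSearchOB(sdfs, smarts),
                   error = function(e)
                     stop("invalid SMARTS pattern: ", smarts, call. = FALSE))
  matched <- names(smi) %in% names(hits)[hits > 0]
  c(n_positives_with_match = sum(matched & y == 1L),
    n_negatives_with_match = sum(matched & y == 0L))
}
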