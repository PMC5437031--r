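# Feature selection: zero-variance removal followed by a greedy pairwise
# correlation filter (caret::findCorrelation-style, made deterministic).

#' Feature-selection configuration
#'
#' @param correlation_cutoff columns are removed until no pair has
#'   |Pearson r| above this value (default 0.7).
#' @param scope "fold" recomputes the selection on the training rows of
#'   every cross-validation fold (leakage-safe default); "global" selects
#'   once on the whole dataset, reproducing the protocol in which features
#'   were selected on the full training set before cross-validation.
#' @return a list of class "featSelConfig".
#' @export
featSelConfig <- function(correlation_cutoff = 0.7,
                          scope = c("fold", "global")) {
  stopifnot(correlation_cutoff > 0, correlation_cutoff < 1)
  structure(list(correlation_cutoff = correlation_cutoff,
                 scope = match.arg(scope)),
            class = "featSelConfig")
}

.asValues <- function(x) {
  if (is(x, "FingerprintMatrix")) fpValues(x) else as.matrix(x)
}

.rewrap <- function(x, values) {
  if (is(x, "FingerprintMatrix"))
    new("FingerprintMatrix", values = values, spec = fpSpec(x))
  else values
}

#' Remove zero-variation columns
#'
#' Drops every column with a single unique value; survivor order is
#' preserved.
#'
#' @param x a [FingerprintMatrix-class] or plain matrix.
#' @return list(matrix = filtered input, report = [SelectionReport-class]).
#' @export
zeroVarianceFilter <- function(x) {
  v <- .asValues(x)
  if (ncol(v) == 0L) stop("empty matrix", call. = FALSE)
  uniq1 <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    all(col == col[1L])
  }, logical(1))
  kept <- colnames(v)[!uniq1]
  list(matrix = .rewrap(x, v[, !uniq1, drop = FALSE]),
       report = new("SelectionReport", kept = kept,
                    dropped_zero_var = colnames(v)[uniq1],
                    dropped_correlated = character(0),
                    cutoff = NA_real_))
}

#' Remove highly correlated columns
#'
#' Greedy rule: repeatedly locate the pair with the largest |Pearson r|
#' above the cutoff (ties resolved in column-major order) and drop the
#' member with the larger mean absolute correlation against all remaining
#' columns (ties drop the later column in input order). The survivors are
#' guaranteed to have no pair with |r| above the cutoff, and the result is
#' deterministic given the input column order.
#'
#' @param x a [FingerprintMatrix-class] or matrix with zero-variance
#'   columns already removed.
#' @param config a [featSelConfig()].
#' @return list(matrix, report); the report maps each dropped column to the
#'   partner that triggered its removal.
#' @export
correlationFilter <- function(x, config = featSelConfig()) {
  v <- .asValues(x)
  cutoff <- config$correlation_cutoff
  if (ncol(v) < 2L) {
    return(list(matrix = x,
                report = new("SelectionReport", kept = colnames(v),
                             dropped_zero_var = character(0),
                             dropped_correlated = character(0),
                             cutoff = cutoff)))
  }
  A <- abs(stats::cor(v))
  if (any(!is.finite(A)))
    stop("non-finite correlations; remove zero-variance columns first",
         call. = FALSE)
  diag(A) <- 0
  alive <- rep(TRUE, ncol(v))
  names(alive) <- colnames(v)
  partner <- character(0)
  repeat {
    Aa <- A[alive, alive, drop = FALSE]
    if (nrow(Aa) < 2L) break
    mx <- max(Aa)
    if (mx <= cutoff) break
    hits <- which(Aa == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    mi <- mean(Aa[i, ]); mj <- mean(Aa[j, ])
    drop_j <- if (mi > mj) i else j   # equal means -> drop later column j
    keep_j <- if (drop_j == i) j else i
    dn <- rownames(Aa)[drop_j]
    partner[dn] <- rownames(Aa)[keep_j]
    alive[dn] <- FALSE
  }
  kept <- names(alive)[alive]
  list(matrix = .rewrap(x, v[, kept, drop = FALSE]),
       report = new("SelectionReport", kept = kept,
                    dropped_zero_var = character(0),
                    dropped_correlated = partner,
                    cutoff = cutoff))
}

#' Zero-variance then correlation filtering in one step
#'
#' @param x a [FingerprintMatrix-class] or matrix.
#' @param config a [featSelConfig()].
#' @return list(matrix, report) with a merged [SelectionReport-class].
#' @export
featureSelect <- function(x, config = featSelConfig()) {
  zv <- zeroVarianceFilter(x)
  if (length(zv$report@kept) == 0L)
    return(list(matrix = zv$matrix,
                report = new("SelectionReport", kept = character(0),
                             dropped_zero_var = zv$report@dropped_zero_var,
                             dropped_correlated = character(0),
                             cutoff = config$correlation_cutoff)))
  cf <- correlationFilter(zv$matrix, config)
  list(matrix = cf$matrix,
       report = new("SelectionReport", kept = cf$report@kept,
                    dropped_zero_var = zv$report@dropped_zero_var,
                    dropped_correlated = cf$report@dropped_correlated,
                    cutoff = config$correlation_cutoff))
}

#' Trace dropped keys to their kept representatives
#'
#' Follows the removal-partner chain of a [SelectionReport-class] until a
#' kept column is reached. Keys that were dropped as zero-variance have no
#' representative and are omitted.
#'
#' @param report a SelectionReport.
#' @param keys character vector of column names.
#' @return named character vector: kept representative per input key.
#' @export
selectionRepresentatives <- function(report, keys) {
  stopifnot(is(report, "SelectionReport"))
  out <- character(0)
  for (k in keys) {
    cur <- k
    steps <- 0L
    while (!(cur %in% report@kept) && steps < 1000L) {
      nxt <- report@dropped_correlated[cur]
      if (is.na(nxt) || is.null(nxt)) { cur <- NA_character_; break }
      cur <- unname(nxt)
      steps <- steps + 1L
    }
    if (!is.na(cur) && cur %in% report@kept) out[k] <- cur
  }
  out
}

#' Serialize a SelectionReport as JSON
#'
#' @param report a SelectionReport.
#' @param path output file.
#' @export
writeSelectionReport <- function(report, path) {
  stopifnot(is(report, "SelectionReport"))
  jsonlite::write_json(
    list(kept = report@kept,
         dropped_zero_var = report@dropped_zero_var,
         dropped_correlated = as.list(report@dropped_correlated),
         cutoff = report@cutoff),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
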