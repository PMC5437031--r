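#' @import methods
NULL

EXCLUSION_LEVELS <- c("none", "too_few_carbons", "heavy_metal", "polymer",
                      "mixture", "unparseable")

#' CompoundSet: a curated table of compounds
#'
#' Holds one record per compound: identifiers, the SMILES as read, the
#' canonical SMILES after salt stripping, an optional binary carcinogenicity
#' label (1 = carcinogen, 0 = non-carcinogen) and the exclusion reason
#' assigned by curation (one of `none`, `too_few_carbons`, `heavy_metal`,
#' `polymer`, `mixture`, `unparseable`). Record order is stable and ids are
#' unique.
#'
#' @slot records data.frame with columns id, name, smiles_raw, smiles_clean,
#'   label, exclusion_reason, polymer, n_big_fragments.
#' @slot provenance free-text source tag.
#' @export
setClass("CompoundSet",
         representation(records = "data.frame", provenance = "character"))

setValidity("CompoundSet", function(object) {
  rec <- object@records
  need <- c("id", "name", "smiles_raw", "smiles_clean", "label",
            "exclusion_reason", "polymer", "n_big_fragments")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) return("compound ids must be unique")
  if (!all(rec$exclusion_reason %in% EXCLUSION_LEVELS))
    return("invalid exclusion_reason value")
  lab <- rec$label[!is.na(rec$label)]
  if (length(lab) && !all(lab %in% c(0L, 1L)))
    return("labels must be 0/1 (or NA)")
  TRUE
})

#' Construct a CompoundSet from a records data.frame
#' @param records data.frame; missing optional columns are filled.
#' @param provenance free-text source tag.
#' @return a [CompoundSet-class] object.
#' @export
CompoundSet <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  nr <- nrow(records)
  fill <- function(x) rep(x, length.out = nr)
  if (is.null(records$id)) records$id <- as.character(seq_len(nr))
  records$id <- as.character(records$id)
  if (is.null(records$name)) records$name <- records$id
  if (is.null(records$smiles_raw)) records$smiles_raw <- fill(NA_character_)
  if (is.null(records$smiles_clean)) records$smiles_clean <- fill(NA_character_)
  if (is.null(records$label)) records$label <- fill(NA_integer_)
  records$label <- as.integer(records$label)
  if (is.null(records$exclusion_reason)) records$exclusion_reason <- fill("none")
  if (is.null(records$polymer)) records$polymer <- fill(FALSE)
  if (is.null(records$n_big_fragments))
    records$n_big_fragments <- fill(NA_integer_)
  rownames(records) <- NULL
  new("CompoundSet", records = records, provenance = provenance)
}

#' FingerprintSpec: one fingerprint family
#'
#' @slot name family abbreviation (one of the 12 supported families).
#' @slot kind "hashed-path", "structural-key" or "key-count".
#' @slot length number of bits / count slots.
#' @export
setClass("FingerprintSpec",
         representation(name = "character", kind = "character",
                        length = "integer"))

#' FingerprintMatrix: compounds x fingerprint features
#'
#' @slot values integer matrix, rows = compounds (rownames = ids), columns
#'   named "<family>-<index>". Bit families contain 0/1; count families
#'   contain non-negative integers.
#' @slot spec the [FingerprintSpec-class] that produced it.
#' @export
setClass("FingerprintMatrix",
         representation(values = "matrix", spec = "FingerprintSpec"))

setValidity("FingerprintMatrix", function(object) {
  v <- object@values
  if (any(v < 0)) return("fingerprint entries must be non-negative")
  if (object@spec@kind %in% c("hashed-path", "structural-key") &&
      length(v) && any(v > 1L))
    return("bit-kind fingerprint entries must be 0/1")
  TRUE
})

#' SelectionReport: result of a feature-selection step
#'
#' @slot kept ordered surviving column names.
#' @slot dropped_zero_var columns removed for having a single unique value.
#' @slot dropped_correlated named character vector: names are removed
#'   columns, values are the kept/partner column whose correlation triggered
#'   the removal.
#' @slot cutoff correlation cutoff used (NA for pure zero-variance reports).
#' @export
setClass("SelectionReport",
         representation(kept = "character", dropped_zero_var = "character",
                        dropped_correlated = "character", cutoff = "numeric"))

#' TrainedBaseClassifier: one fingerprint-specific fitted model
#'
#' @slot fingerprint family name.
#' @slot algorithm "svm_rbf", "random_forest" or "xgboost".
#' @slot kept_columns feature columns the model was fit on.
#' @slot fit opaque fitted model object.
#' @slot config the configuration list used.
#' @export
setClass("TrainedBaseClassifier",
         representation(fingerprint = "character", algorithm = "character",
                        kept_columns = "character", fit = "ANY",
                        config = "list"))

#' EnsembleModel: fused fingerprint-specific base classifiers
#'
#' The ensemble probability is the arithmetic mean of the member
#' probabilities; a compound is called a carcinogen when that mean reaches
#' the decision threshold (default 0.5).
#'
#' @slot algorithm learning algorithm shared by the members.
#' @slot members named list of [TrainedBaseClassifier-class] (one per family).
#' @slot threshold decision cutoff on the mean probability.
#' @slot training_keys canonical SMILES of the training compounds (used to
#'   flag duplicates when screening).
#' @slot version serialization format version.
#' @export
setClass("EnsembleModel",
         representation(algorithm = "character", members = "list",
                        threshold = "numeric", training_keys = "character",
                        version = "character"))

setValidity("EnsembleModel", function(object) {
  fams <- vapply(object@members, function(m) m@fingerprint, character(1))
  if (anyDuplicated(fams)) return("members must cover distinct families")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must be in [0,1]")
  TRUE
})

#' CVResultSet: repeated cross-validation results
#'
#' @slot records data.frame with one row per (repeat, fold): confusion
#'   counts and Q/SE/SP/AUC.
#' @slot summary data.frame of mean and SD for Q, SE, SP, AUC.
#' @slot config list recording k, repeats, stratification, seed, scope.
#' @export
setClass("CVResultSet",
         representation(records = "data.frame", summary = "data.frame",
                        config = "list"))

setMethod("show", "CompoundSet", function(object) {
  rec <- object@records
  cur <- sum(rec$exclusion_reason == "none")
  lab <- table(factor(rec$label[rec$exclusion_reason == "none"],
                      levels = c(0, 1)))
  cat("CompoundSet:", nrow(rec), "records (", cur, "curated )\n")
  cat("  labels: ", lab[["1"]], "carcinogen /", lab[["0"]],
      "non-carcinogen,", sum(is.na(rec$label)), "unlabeled\n")
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "FingerprintSpec", function(object) {
  cat(sprintf("FingerprintSpec %s (%s, %d features)\n",
              object@name, object@kind, object@length))
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix %s: %d compounds x %d features\n",
              object@spec@name, nrow(object@values), ncol(object@values)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel (%s): %d members [%s], threshold %.2f\n",
              object@algorithm, length(object@members),
              paste(names(object@members), collapse = ", "),
              object@threshold))
})

setMethod("show", "CVResultSet", function(object) {
  cfg <- object@config
  cat(sprintf("CVResultSet: %d folds x %d repeats (%d records)\n",
              cfg$k, cfg$repeats, nrow(object@records)))
  print(object@summary, digits = 4)
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf(
    "SelectionReport: %d kept, %d zero-variance, %d correlated (cutoff %s)\n",
    length(object@kept), length(object@dropped_zero_var),
    length(object@dropped_correlated), format(object@cutoff)))
})

#' Number of compounds in a CompoundSet
#' @param x a CompoundSet.
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@records))

#' Subset a CompoundSet by position or id
#' @param x a CompoundSet.
#' @param i integer, logical or character (id) index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$id)
  rec <- x@records[i, , drop = FALSE]
  rownames(rec) <- NULL
  new("CompoundSet", records = rec, provenance = x@provenance)
})

# ---- accessors -------------------------------------------------------------

#' Records of a CompoundSet as a data.frame
#' @param x a CompoundSet.
#' @return data.frame of compound records.
#' @export
compoundData <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  x@records
}

#' Curated view of a CompoundSet (records with exclusion_reason "none")
#' @param x a CompoundSet.
#' @return a CompoundSet containing only retained records.
#' @export
curated <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  x[x@records$exclusion_reason == "none"]
}

#' Compound ids
#' @param x a CompoundSet.
#' @export
compoundIds <- function(x) compoundData(x)$id

#' Binary labels (1 = carcinogen), NA when unlabeled
#' @param x a CompoundSet.
#' @export
compoundLabels <- function(x) {
  lab <- compoundData(x)$label
  names(lab) <- compoundIds(x)
  lab
}

#' Clean (salt-stripped, canonical) SMILES
#' @param x a CompoundSet.
#' @export
cleanSmiles <- function(x) {
  s <- compoundData(x)$smiles_clean
  names(s) <- compoundIds(x)
  s
}

#' Values matrix of a FingerprintMatrix
#' @param x a FingerprintMatrix.
#' @export
fpValues <- function(x) {
  stopifnot(is(x, "FingerprintMatrix"))
  x@values
}

#' Spec of a FingerprintMatrix
#' @param x a FingerprintMatrix.
#' @export
fpSpec <- function(x) {
  stopifnot(is(x, "FingerprintMatrix"))
  x@spec
}

#' Per-fold records of a CVResultSet
#' @param x a CVResultSet.
#' @export
cvRecords <- function(x) {
  stopifnot(is(x, "CVResultSet"))
  x@records
}

#' Mean/SD summary of a CVResultSet
#' @param x a CVResultSet.
#' @export
cvSummary <- function(x) {
  stopifnot(is(x, "CVResultSet"))
  x@summary
}
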