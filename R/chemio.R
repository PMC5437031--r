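# Reading, canonicalizing and curating compound tables.
#
# Curation follows four inclusion rules applied in order (the first rule
# that fires provides the exclusion reason): (1) fewer than three carbon
# atoms; (2) elements outside the organic set (the "heavy metal" rule);
# (3) polymers (only detectable through an explicit per-row flag column);
# (4) mixtures (two or more fragments that each carry >= 3 carbons).

#' Read a delimited table of SMILES compounds
#'
#' Reads a CSV/TSV with a header, maps the configured columns, and
#' canonicalizes every SMILES. Rows whose SMILES does not parse are kept
#' with `exclusion_reason = "unparseable"` so that every input row appears
#' exactly once in the result.
#'
#' @param path file path.
#' @param columns named list mapping record fields to column names:
#'   `id`, `smiles` (required if present in the file), `name`, `label`,
#'   `polymer` (optional).
#' @param sep field separator; guessed from the file extension by default.
#' @param provenance free-text source tag.
#' @return a [CompoundSet-class].
#' @export
readSmilesTable <- function(path,
                            columns = list(id = "id", name = "name",
                                           smiles = "SMILES",
                                           label = "label"),
                            sep = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty compound table: ", path)
    return(CompoundSet(data.frame(id = character(0), smiles_raw = character(0)),
                       provenance = provenance))
  }
  for (field in c("id", "smiles")) {
    colname <- columns[[field]]
    if (is.null(colname) || !colname %in% names(tab))
      stop("mapped column for '", field, "' (", colname %||% "<missing>",
           ") not present in ", path, call. = FALSE)
  }
  rec <- data.frame(id = as.character(tab[[columns$id]]),
                    smiles_raw = as.character(tab[[columns$smiles]]),
                    stringsAsFactors = FALSE)
  rec$name <- if (!is.null(columns$name) && columns$name %in% names(tab))
    as.character(tab[[columns$name]]) else rec$id
  rec$label <- if (!is.null(columns$label) && columns$label %in% names(tab))
    as.integer(tab[[columns$label]]) else NA_integer_
  rec$polymer <- if (!is.null(columns$polymer) &&
                     columns$polymer %in% names(tab))
    as.logical(tab[[columns$polymer]]) else FALSE
  if (anyDuplicated(rec$id)) {
    warning("duplicated ids made unique with suffixes")
    rec$id <- make.unique(rec$id, sep = "_dup")
  }
  rec$smiles_clean <- canonicalSmiles(rec$smiles_raw)
  rec$exclusion_reason <- ifelse(is.na(rec$smiles_clean), "unparseable", "none")
  rec$n_big_fragments <- NA_integer_
  CompoundSet(rec, provenance = provenance)
}

#' Read compounds from an SDF file
#'
#' Structures are converted to canonical SMILES; an optional data field
#' carries the binary label.
#'
#' @param path SDF file path.
#' @param label_field name of the SDF data field holding the 0/1 label
#'   (NA if absent).
#' @param provenance free-text source tag.
#' @return a [CompoundSet-class].
#' @export
readSdfCompounds <- function(path, label_field = "label",
                             provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sdfs <- ChemmineR::read.SDFset(path)
  n <- length(sdfs)
  ids <- ChemmineR::sdfid(sdfs)
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ids <- make.unique(ifelse(nzchar(ids), ids,
                              paste0("sdf", seq_len(n))), sep = "_dup")
  smi <- rep(NA_character_, n)
  lab <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    smi[k] <- tryCatch(
      as.character(ChemmineR::sdf2smiles(sdfs[k])),
      error = function(e) NA_character_)
    db <- ChemmineR::datablock(sdfs[[k]])
    if (!is.na(label_field) && label_field %in% names(db))
      lab[k] <- suppressWarnings(as.integer(db[[label_field]]))
  }
  rec <- data.frame(id = ids, name = ids, smiles_raw = smi,
                    label = lab, polymer = FALSE, stringsAsFactors = FALSE)
  rec$smiles_clean <- canonicalSmiles(rec$smiles_raw)
  rec$exclusion_reason <- ifelse(is.na(rec$smiles_clean), "unparseable", "none")
  rec$n_big_fragments <- NA_integer_
  CompoundSet(rec, provenance = provenance)
}

# fragment-selection rule: most heavy atoms, tie -> larger MW, tie ->
# lexicographically smallest canonical SMILES. Returns list(kept=, nbig=).
.selectFragment <- function(can) {
  frags <- .splitFragments(can)
  if (length(frags) <= 1L)
    return(list(kept = can, nbig = NA_integer_))
  mols <- buildMolGraphList(frags)
  ok <- !vapply(mols, is.null, logical(1))
  if (!any(ok)) return(list(kept = NA_character_, nbig = NA_integer_))
  frags <- frags[ok]; mols <- mols[ok]
  heavy <- vapply(mols, .molHeavyAtoms, numeric(1))
  mw <- vapply(mols, .molWeight, numeric(1))
  ord <- order(-heavy, -mw, frags)
  kept <- frags[ord[1]]
  carb <- vapply(mols, .molCarbons, numeric(1))
  list(kept = kept, nbig = as.integer(sum(carb >= 3L)))
}

#' Strip salts and counter-ions
#'
#' For every multi-fragment structure, retains the fragment with the most
#' heavy atoms (ties broken by molecular weight, then by lexicographically
#' smallest canonical SMILES) and re-canonicalizes. Single-fragment inputs
#' pass through unchanged. The number of fragments carrying >= 3 carbons is
#' recorded for the downstream mixture rule.
#'
#' @param x a [CompoundSet-class] whose `smiles_clean` is canonical.
#' @return the CompoundSet with salts removed.
#' @export
stripSalts <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  rec <- x@records
  multi <- which(!is.na(rec$smiles_clean) &
                 grepl(".", rec$smiles_clean, fixed = TRUE))
  for (i in multi) {
    sel <- .selectFragment(rec$smiles_clean[i])
    if (is.na(sel$kept)) {
      rec$exclusion_reason[i] <- "unparseable"
      next
    }
    rec$smiles_clean[i] <- canonicalSmiles(sel$kept)
    rec$n_big_fragments[i] <- sel$nbig
  }
  single <- setdiff(which(!is.na(rec$smiles_clean)), multi)
  rec$n_big_fragments[single] <- 1L
  x@records <- rec
  validObject(x)
  x
}

#' Apply the curation rules
#'
#' Assigns each record its first triggered exclusion reason, in rule order:
#' fewer than three carbons; elements outside H, B, C, N, O, F, Si, P, S,
#' Cl, Br, I; polymer flag; mixture (>= 2 fragments with >= 3 carbons each
#' before salt stripping). Filtering never raises; records already flagged
#' `unparseable` are left as they are. Idempotent.
#'
#' @param x a salt-stripped [CompoundSet-class].
#' @param verbose print a per-reason summary.
#' @return the CompoundSet with exclusion reasons populated.
#' @export
curateCompounds <- function(x, verbose = FALSE) {
  stopifnot(is(x, "CompoundSet"))
  rec <- x@records
  idx <- which(rec$exclusion_reason != "unparseable")
  if (length(idx)) {
    mols <- buildMolGraphList(rec$smiles_clean[idx])
    for (k in seq_along(idx)) {
      i <- idx[k]
      m <- mols[[k]]
      if (is.null(m)) { rec$exclusion_reason[i] <- "unparseable"; next }
      reason <- "none"
      if (.molCarbons(m) < 3L) {
        reason <- "too_few_carbons"
      } else if (!all(m$elem %in% ORGANIC_ELEMENTS)) {
        reason <- "heavy_metal"
      } else if (isTRUE(rec$polymer[i])) {
        reason <- "polymer"
      } else if (!is.na(rec$n_big_fragments[i]) &&
                 rec$n_big_fragments[i] >= 2L) {
        reason <- "mixture"
      }
      rec$exclusion_reason[i] <- reason
    }
  }
  x@records <- rec
  if (verbose) print(curationSummary(x))
  validObject(x)
  x
}

#' Counts of records per exclusion reason
#' @param x a CompoundSet.
#' @return named integer vector over all exclusion reasons.
#' @export
curationSummary <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  table(factor(x@records$exclusion_reason, levels = EXCLUSION_LEVELS))
}

#' Remove compounds of `a` whose structure occurs in `b`
#'
#' Comparison uses the canonical SMILES of the salt-stripped structure as
#' the structure key, so different spellings of the same molecule are
#' recognized as duplicates.
#'
#' @param a,b curated [CompoundSet-class] objects.
#' @return the records of `a` absent from `b`, as a CompoundSet.
#' @export
deduplicate <- function(a, b) {
  stopifnot(is(a, "CompoundSet"), is(b, "CompoundSet"))
  keys_b <- b@records$smiles_clean
  keep <- is.na(a@records$smiles_clean) |
    !(a@records$smiles_clean %in% keys_b)
  a[which(keep)]
}

#' Write a CompoundSet as CSV
#'
#' Writes id, name, SMILES (as read), smiles_clean, label and
#' exclusion_reason. Round-trips through [readSmilesTable()] with stable
#' record order.
#'
#' @param x a CompoundSet.
#' @param path output file.
#' @export
writeCompounds <- function(x, path) {
  stopifnot(is(x, "CompoundSet"))
  out <- data.frame(id = x@records$id, name = x@records$name,
                    SMILES = x@records$smiles_raw,
                    smiles_clean = x@records$smiles_clean,
                    label = x@records$label,
                    exclusion_reason = x@records$exclusion_reason,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
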