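# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

# CompoundSet straight from SMILES (canonicalized, salt-stripped, curated)
tinySet <- function(smiles, labels = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  rec <- data.frame(id = ids, smiles_raw = smiles,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) rec$label <- as.integer(labels)
  rec$smiles_clean <- canonicalSmiles(rec$smiles_raw)
  rec$exclusion_reason <- ifelse(is.na(rec$smiles_clean), "unparseable",
                                 "none")
  curateCompounds(stripSalts(CompoundSet(rec, provenance = "test")))
}

# a CompoundSet whose records are taken as-is (no curation pass); for
# descriptor oracles on molecules the curation rules would reject
rawSet <- function(smiles, ids = paste0("r", seq_along(smiles))) {
  rec <- data.frame(id = ids, smiles_raw = smiles,
                    stringsAsFactors = FALSE)
  rec$smiles_clean <- canonicalSmiles(rec$smiles_raw)
  CompoundSet(rec, provenance = "test-raw")
}

# the frozen 300-compound planted-motif fixture (seed 1, study defaults)
frozenFixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- generateFixture(fixtureConfig(seed = 1L))
  .fixture_cache$fx
}

# fingerprint matrices of the frozen fixture, computed once per family
frozenMatrices <- function(families) {
  if (is.null(.fixture_cache$mats)) .fixture_cache$mats <- list()
  miss <- setdiff(families, names(.fixture_cache$mats))
  if (length(miss))
    .fixture_cache$mats[miss] <- computeMatrices(frozenFixture()$compounds,
                                                 miss)
  .fixture_cache$mats[families]
}

# small planted-motif fixture for unit tests
smallFixture <- function(n = 60L, seed = 7L) {
  key <- paste0("small", n, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generateFixture(
      fixtureConfig(n_total = n, seed = seed))
  .fixture_cache[[key]]
}

# relabel a CompoundSet (e.g. for label-shuffled null runs)
withLabels <- function(cs, labels) {
  rec <- compoundData(cs)
  rec$label <- as.integer(labels)
  CompoundSet(rec, provenance = "relabeled")
}

# exhaustive O(n^2) AUC oracle: pair counting with ties at 1/2
aucPairCount <- function(y, p) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}
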