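# Seeded generator of labeled synthetic molecule sets with planted
# substructure-label associations. Scaffolds are random alkyl/aryl
# assemblies (carbon chains of 3-8 atoms, optional benzene ring) so every
# generated structure is organic, connected, and carries at least three
# carbons -- fixtures exercise the curation rules without fighting them.
# Motif branches (by default an N-nitrosamine fragment enriched among
# positives and a carboxylic acid enriched among negatives) are attached
# to the scaffold core with configurable enrichment and leak
# probabilities; the manifest records the planted ground truth.

#' Default planted motifs
#'
#' A nitrosamine branch (contains N-N and N=O) enriched in the positive
#' class and a carboxylic-acid branch enriched in the negative class, each
#' present with probability `enrich` in its enriched class and `leak` in
#' the other class. Each motif lists the SMARTS signatures of its
#' fingerprint keys (see [matchKeys()]).
#'
#' @param enrich probability of the motif in its enriched class.
#' @param leak probability in the other class.
#' @return list of motif definitions.
#' @export
defaultMotifs <- function(enrich = 0.8, leak = 0.2) {
  list(
    list(name = "nitrosamine", branch = "CN(C)N=O", class = 1L,
         enrich = enrich, leak = leak,
         smarts = c("[#7]~[#7]", "[#7]=[#8]", "[#7]~[#7]=[#8]")),
    list(name = "carboxylic_acid", branch = "CC(=O)O", class = 0L,
         enrich = enrich, leak = leak,
         smarts = c("[CX3](=[OX1])[OX2H1]")))
}

#' Fixture-generator configuration
#'
#' @param n_total number of compounds (>= 10).
#' @param positive_fraction fraction labeled carcinogen (class sizes exact
#'   to within one compound).
#' @param motifs list of motif definitions (see [defaultMotifs()]).
#' @param chain_range min/max carbon-chain length of the scaffold.
#' @param ring_prob probability of attaching a benzene ring.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a list of class "fixtureConfig".
#' @export
fixtureConfig <- function(n_total = 300L, positive_fraction = 0.5,
                          motifs = defaultMotifs(),
                          chain_range = c(3L, 8L), ring_prob = 0.3,
                          seed = 1L) {
  stopifnot(n_total >= 10L, positive_fraction >= 0, positive_fraction <= 1,
            length(chain_range) == 2L, chain_range[1] >= 1L,
            chain_range[2] >= chain_range[1],
            ring_prob >= 0, ring_prob <= 1)
  for (mt in motifs)
    stopifnot(mt$enrich >= 0, mt$enrich <= 1, mt$leak >= 0, mt$leak <= 1,
              is.character(mt$branch), mt$class %in% c(0L, 1L))
  structure(list(n_total = as.integer(n_total),
                 positive_fraction = positive_fraction, motifs = motifs,
                 chain_range = as.integer(chain_range),
                 ring_prob = ring_prob, seed = as.integer(seed)),
            class = "fixtureConfig")
}

#' Generate a synthetic labeled compound set
#'
#' @param config a [fixtureConfig()].
#' @return list(compounds = curated [CompoundSet-class] with zero
#'   exclusions, manifest = data.frame(id, smiles, label, motifs) recording
#'   the planted ground truth).
#' @export
generateFixture <- function(config = fixtureConfig()) {
  stopifnot(inherits(config, "fixtureConfig"))
  n <- config$n_total
  n_pos <- round(n * config$positive_fraction)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  gen <- withSeed(deriveSeed(config$seed, "fixture"), {
    labels <- sample(labels)
    smiles <- character(n)
    planted <- character(n)
    for (i in seq_len(n)) {
      branches <- character(0)
      present <- character(0)
      for (mt in config$motifs) {
        p <- if (labels[i] == mt$class) mt$enrich else mt$leak
        if (stats::runif(1) < p) {
          branches <- c(branches, mt$branch)
          present <- c(present, mt$name)
        }
      }
      if (stats::runif(1) < config$ring_prob)
        branches <- c(branches, "c1ccccc1")
      L <- sample(seq(config$chain_range[1], config$chain_range[2]), 1L)
      smiles[i] <- paste0(
        "C", paste0("(", branches, ")", collapse = ""),
        strrep("C", L - 1L))
      planted[i] <- paste(present, collapse = ";")
    }
    list(labels = labels, smiles = smiles, planted = planted)
  })
  ids <- sprintf("FIX%04d", seq_len(n))
  manifest <- data.frame(id = ids, smiles = gen$smiles, label = gen$labels,
                         motifs = gen$planted, stringsAsFactors = FALSE)
  rec <- data.frame(id = ids, name = ids, smiles_raw = gen$smiles,
                    label = gen$labels, polymer = FALSE,
                    stringsAsFactors = FALSE)
  rec$smiles_clean <- canonicalSmiles(rec$smiles_raw)
  if (anyNA(rec$smiles_clean))
    stop("fixture grammar produced unparseable SMILES", call. = FALSE)
  rec$exclusion_reason <- "none"
  rec$n_big_fragments <- 1L
  cs <- curateCompounds(stripSalts(CompoundSet(
    rec, provenance = sprintf("synthetic fixture (seed %d)", config$seed))))
  if (any(compoundData(cs)$exclusion_reason != "none"))
    stop("fixture compounds failed curation", call. = FALSE)
  list(compounds = cs, manifest = manifest)
}

#' Fingerprint keys of the planted motifs
#'
#' Maps every motif of a fixture configuration to the key names of a
#' structural family whose SMARTS equal the motif's signature patterns.
#'
#' @param config a [fixtureConfig()].
#' @param family structural fingerprint family name.
#' @return named list: character vector of key names per motif.
#' @export
fixtureMotifKeys <- function(config, family) {
  stopifnot(inherits(config, "fixtureConfig"))
  out <- lapply(config$motifs, function(mt) matchKeys(family, mt$smarts))
  names(out) <- vapply(config$motifs, `[[`, character(1), "name")
  out
}

#' Write a fixture to disk
#'
#' SMILES CSV (readable by [readSmilesTable()]) plus a manifest JSON.
#'
#' @param fixture result of [generateFixture()].
#' @param csv path for the compound CSV.
#' @param json optional path for the manifest JSON.
#' @export
writeFixture <- function(fixture, csv, json = NULL) {
  utils::write.csv(
    data.frame(id = fixture$manifest$id, name = fixture$manifest$id,
               SMILES = fixture$manifest$smiles,
               label = fixture$manifest$label),
    csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(fixture$manifest, json, pretty = TRUE)
  invisible(csv)
}
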