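# Fingerprint key dictionaries.
#
# The 12 families have the standard sizes (CDK/CDKExt/CDKGraph 1024, Estate
# 79, MACCS 166, Pubchem 881, FP4/FP4C 307, KR/KRC 4860, AP2D/AP2DC 780).
# Bit positions of the historical implementations are not reproduced: each
# structural-key family is assembled here from a documented grammar of key
# types --
#   fg    curated functional-group patterns (with their SMARTS),
#   bond  element-pair bond patterns (single/double/triple/aromatic),
#   elem  element-count keys (presence or >= m thresholds),
#   ring  ring-count keys (size / aromaticity / heteroatom),
#   pair  atom-class pairs at a fixed topological (shortest-path) distance,
#   estate  Kier-Hall style atom-type signatures --
# padded deterministically to the exact family length. Count-variant
# families (FP4C, KRC, AP2DC) share their parent's dictionary and report
# match counts; their bit parents are the indicator count > 0, which holds
# by construction because those families use match-count key types only
# (threshold keys are confined to the bit-only families).

FP_FAMILIES <- data.frame(
  name = c("CDK", "CDKExt", "CDKGraph", "Estate", "MACCS", "Pubchem",
           "FP4", "FP4C", "KR", "KRC", "AP2D", "AP2DC"),
  kind = c("hashed-path", "hashed-path", "hashed-path", "structural-key",
           "structural-key", "structural-key", "structural-key", "key-count",
           "structural-key", "key-count", "structural-key", "key-count"),
  length = c(1024L, 1024L, 1024L, 79L, 166L, 881L, 307L, 307L, 4860L,
             4860L, 780L, 780L),
  stringsAsFactors = FALSE
)

# 12 disjoint atom classes for pair-at-distance keys. Order matters: it
# fixes the key enumeration (N-N and N-O at distance 1 land on AP2D-13 and
# AP2D-14).
.CLS12_NAMES <- c("C", "N", "O", "Car", "Nar", "S", "P", "F", "Cl", "Br",
                  "I", "X")

# 30 disjoint atom classes for the large (KR-sized) pair key set.
.CLS30_NAMES <- c("cat", "ani", "Car", "Cring", "Ctriple", "CH3", "CnextO",
                  "CnextN", "CnextHal", "Cacyc", "Nar", "Nring", "NH2",
                  "NH1", "NH0", "Oring", "OH", "Odbl", "Osingle", "Sring",
                  "Sdbl", "Sother", "P", "F", "Cl", "Br", "I", "B", "Si",
                  "X")

.HALOGENS <- c("F", "Cl", "Br", "I")

# ---- curated functional-group keys ----------------------------------------

.FG_DEFS <- local({
  d <- function(id, smarts, desc) list(id = id, smarts = smarts, desc = desc)
  list(
    d("nn_any",       "[#7]~[#7]",                   "N-N bond (any order)"),
    d("n_dbl_o",      "[#7]=[#8]",                   "N=O"),
    d("nnitroso",     "[#7]~[#7]=[#8]",              "N-nitroso (N-N=O)"),
    d("nitro",        "[#7](~[#8])~[#8]",            "nitro-like N bonded to two O"),
    d("azo",          "[#7]=[#7]",                   "azo N=N"),
    d("hydrazine",    "[NX3][NX3]",                  "hydrazine N-N single"),
    d("carbox_acid",  "[CX3](=[OX1])[OX2H1]",        "carboxylic acid"),
    d("ester",        "[CX3](=[OX1])[OX2H0][#6]",    "ester"),
    d("amide",        "[CX3](=[OX1])[NX3]",          "amide"),
    d("urea",         "[NX3][CX3](=[OX1])[NX3]",     "urea"),
    d("aldehyde",     "[CX3H1]=[OX1]",               "aldehyde"),
    d("ketone",       "[#6][CX3](=[OX1])[#6]",       "ketone"),
    d("carbonyl",     "[CX3]=[OX1]",                 "carbonyl C=O"),
    d("hydroxyl",     "[OX2H]",                      "hydroxyl"),
    d("alcohol",      "[CX4][OX2H]",                 "aliphatic alcohol"),
    d("phenol",       "[OX2H][c]",                   "phenol-type OH on aromatic C"),
    d("ether",        "[#6][OX2H0][#6]",             "ether oxygen"),
    d("prim_amine",   "[NX3;H2][#6]",                "primary amine"),
    d("sec_amine",    "[NX3;H1]([#6])[#6]",          "secondary amine"),
    d("tert_amine",   "[NX3;H0]([#6])([#6])[#6]",    "tertiary amine"),
    d("arom_n",       "[#7;a]",                      "aromatic nitrogen"),
    d("aniline",      "[NX3][c]",                    "aniline-type N on aromatic C"),
    d("nitrile",      "[NX1]#[CX2]",                 "nitrile"),
    d("isocyanate",   "[NX2]=[CX2]=[OX1]",           "isocyanate N=C=O"),
    d("thiol",        "[SX2H]",                      "thiol"),
    d("thioether",    "[#6][SX2H0][#6]",             "thioether sulfur"),
    d("s_dbl_o",      "[#16]=[#8]",                  "S=O"),
    d("sulfone",      "[#16](=[#8])=[#8]",           "sulfone / sulfonyl"),
    d("halide_sp3",   "[CX4][F,Cl,Br,I]",            "halogen on sp3 carbon"),
    d("halide_arom",  "[c][F,Cl,Br,I]",              "halogen on aromatic carbon"),
    d("epoxide",      "[#8;r3]",                     "oxygen in three-membered ring"),
    d("aziridine",    "[#7;r3]",                     "nitrogen in three-membered ring"),
    d("benzene",      "c1ccccc1",                    "carbocyclic aromatic six-ring"),
    d("het_arom_ring", NA_character_,                "aromatic ring with heteroatom"),
    d("p_dbl_o",      "[#15]=[#8]",                  "P=O"),
    d("dbl_cc",       "[#6]=[#6]",                   "non-aromatic C=C"),
    d("trp_cc",       "[#6]#[#6]",                   "C#C"),
    d("methyl",       "[CX4H3]",                     "methyl group"),
    d("quart_c",      "[CX4]([#6])([#6])([#6])[#6]", "carbon with four carbon neighbours"),
    d("cation",       "[*+]",                        "positively charged atom"),
    d("anion",        "[*-]",                        "negatively charged atom"),
    d("o_any",        "[#8]",                        "oxygen atom"),
    d("n_any",        "[#7]",                        "nitrogen atom"),
    d("s_any",        "[#16]",                       "sulfur atom"),
    d("hal_any",      "[F,Cl,Br,I]",                 "halogen atom")
  )
})

# ---- E-state atom types ----------------------------------------------------
# Signature = (element, implicit H, # single, # double, # triple, # aromatic
# bonds to heavy atoms). 79 types in a fixed order; exotic-element types are
# legitimately all-zero on organics and fall to zero-variance filtering.

.estateTypeTable <- function() {
  rows <- c(
    "sCH3 C 3 1 0 0 0",   "dCH2 C 2 0 1 0 0",   "ssCH2 C 2 2 0 0 0",
    "tCH C 1 0 0 1 0",    "dsCH C 1 1 1 0 0",   "aaCH C 1 0 0 0 2",
    "sssCH C 1 3 0 0 0",  "ddC C 0 0 2 0 0",    "tsC C 0 1 0 1 0",
    "dssC C 0 2 1 0 0",   "aasC C 0 1 0 0 2",   "aaaC C 0 0 0 0 3",
    "ssssC C 0 4 0 0 0",
    "sNH3 N 3 1 0 0 0",   "sNH2 N 2 1 0 0 0",   "ssNH2 N 2 2 0 0 0",
    "dNH N 1 0 1 0 0",    "ssNH N 1 2 0 0 0",   "aaNH N 1 0 0 0 2",
    "tN N 0 0 0 1 0",     "sssNH N 1 3 0 0 0",  "dsN N 0 1 1 0 0",
    "aaN N 0 0 0 0 2",    "sssN N 0 3 0 0 0",   "ddsN N 0 1 2 0 0",
    "aasN N 0 1 0 0 2",   "ssssN N 0 4 0 0 0",
    "sOH O 1 1 0 0 0",    "dO O 0 0 1 0 0",     "ssO O 0 2 0 0 0",
    "aaO O 0 0 0 0 2",
    "sF F 0 1 0 0 0",
    "sSH S 1 1 0 0 0",    "dS S 0 0 1 0 0",     "ssS S 0 2 0 0 0",
    "aaS S 0 0 0 0 2",    "dssS S 0 2 1 0 0",   "ddssS S 0 2 2 0 0",
    "sPH2 P 2 1 0 0 0",   "ssPH P 1 2 0 0 0",   "sssP P 0 3 0 0 0",
    "dsssP P 0 3 1 0 0",  "sssssP P 0 5 0 0 0",
    "sCl Cl 0 1 0 0 0",   "sBr Br 0 1 0 0 0",   "sI I 0 1 0 0 0",
    "sSiH3 Si 3 1 0 0 0", "ssSiH2 Si 2 2 0 0 0", "sssSiH Si 1 3 0 0 0",
    "ssssSi Si 0 4 0 0 0",
    "sBH2 B 2 1 0 0 0",   "ssBH B 1 2 0 0 0",   "sssB B 0 3 0 0 0",
    "sGeH3 Ge 3 1 0 0 0", "ssGeH2 Ge 2 2 0 0 0", "sssGeH Ge 1 3 0 0 0",
    "ssssGe Ge 0 4 0 0 0",
    "sAsH2 As 2 1 0 0 0", "ssAsH As 1 2 0 0 0", "sssAs As 0 3 0 0 0",
    "dsssAs As 0 3 1 0 0", "sssssAs As 0 5 0 0 0",
    "sSeH Se 1 1 0 0 0",  "dSe Se 0 0 1 0 0",   "ssSe Se 0 2 0 0 0",
    "aaSe Se 0 0 0 0 2",  "dssSe Se 0 2 1 0 0", "ddssSe Se 0 2 2 0 0",
    "sSnH3 Sn 3 1 0 0 0", "ssSnH2 Sn 2 2 0 0 0", "sssSnH Sn 1 3 0 0 0",
    "ssssSn Sn 0 4 0 0 0",
    "sPbH3 Pb 3 1 0 0 0", "ssPbH2 Pb 2 2 0 0 0", "sssPbH Pb 1 3 0 0 0",
    "ssssPb Pb 0 4 0 0 0",
    "sLi Li 0 1 0 0 0",   "ssBe Be 0 2 0 0 0",  "ssHg Hg 0 2 0 0 0"
  )
  parts <- strsplit(rows, " +")
  tab <- data.frame(
    code = vapply(parts, `[`, character(1), 1),
    elem = vapply(parts, `[`, character(1), 2),
    nH = as.integer(vapply(parts, `[`, character(1), 3)),
    s = as.integer(vapply(parts, `[`, character(1), 4)),
    d = as.integer(vapply(parts, `[`, character(1), 5)),
    t = as.integer(vapply(parts, `[`, character(1), 6)),
    a = as.integer(vapply(parts, `[`, character(1), 7)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 79L, !anyDuplicated(tab$code))
  tab$sig <- paste(tab$elem, tab$nH, tab$s, tab$d, tab$t, tab$a)
  stopifnot(!anyDuplicated(tab$sig))
  tab
}

# ---- generator blocks ------------------------------------------------------

.keyRow <- function(type, p1 = "", p2 = "", p3 = "", smarts = NA_character_,
                    desc = "") {
  data.frame(type = type, p1 = as.character(p1), p2 = as.character(p2),
             p3 = as.character(p3), smarts = smarts, description = desc,
             stringsAsFactors = FALSE)
}

.fgBlock <- function(ids = NULL) {
  defs <- .FG_DEFS
  if (!is.null(ids)) {
    all_ids <- vapply(defs, `[[`, character(1), "id")
    defs <- defs[match(ids, all_ids)]
  }
  do.call(rbind, lapply(defs, function(f)
    .keyRow("fg", f$id, smarts = f$smarts, desc = f$desc)))
}

.elemBlock <- function(elems, mins) {
  do.call(rbind, mapply(function(e, m) {
    sm <- if (m == 1L) switch(e,
      HAL = "[F,Cl,Br,I]", CAT = "[*+]", ANI = "[*-]",
      paste0("[#", .elementNumber(e), "]")) else NA_character_
    .keyRow("elem", e, m, smarts = sm,
            desc = sprintf(">= %d %s atom(s)", m, e))
  }, elems, mins, SIMPLIFY = FALSE))
}

.elementNumber <- function(e) {
  c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
    Cl = 17, Br = 35, I = 53)[[e]]
}

.ringBlock <- function(kinds, sizes, mins) {
  do.call(rbind, mapply(function(kk, ss, mm) {
    .keyRow("ring", kk, ss, mm,
            desc = sprintf(">= %s %s ring(s)%s", mm, kk,
                           if (ss == "0") "" else paste0(" of size ", ss)))
  }, kinds, sizes, mins, SIMPLIFY = FALSE))
}

# full deterministic bond-pattern enumeration: 66 single + 28 double +
# 6 triple + 10 aromatic = 110 keys
.bondEnumeration <- function() {
  E <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Si", "B")
  sym <- function(o) c(`-` = "-", `=` = "=", `#` = "#", `:` = ":")[[o]]
  rows <- list()
  pairsOf <- function(els) {
    out <- list()
    for (i in seq_along(els)) for (j in i:length(els))
      out[[length(out) + 1L]] <- c(els[i], els[j])
    out
  }
  add <- function(a, b, o) {
    sm <- if (o == ":") {
      paste0("[#", .elementNumber(a), "]:[#", .elementNumber(b), "]")
    } else {
      paste0("[#", .elementNumber(a), "]", sym(o),
             "[#", .elementNumber(b), "]")
    }
    rows[[length(rows) + 1L]] <<- .keyRow(
      "bond", a, b, o, smarts = sm,
      desc = sprintf("%s%s%s bond", a, sym(o), b))
  }
  for (p in pairsOf(E)) add(p[1], p[2], "-")
  for (p in pairsOf(c("C", "N", "O", "S", "P", "Si", "B"))) add(p[1], p[2], "=")
  for (p in pairsOf(c("C", "N", "O"))) add(p[1], p[2], "#")
  for (p in pairsOf(c("C", "N", "O", "S"))) add(p[1], p[2], ":")
  do.call(rbind, rows)
}

# pair-at-distance enumeration for a class scheme: for each distance in
# `dists` (outer loop) all unordered class pairs in scheme order (inner),
# optionally truncated
.pairEnumeration <- function(scheme, dists, limit = NULL) {
  cls <- if (scheme == "cls12") .CLS12_NAMES else .CLS30_NAMES
  rows <- list()
  for (dd in dists) {
    for (i in seq_along(cls)) for (j in i:length(cls)) {
      rows[[length(rows) + 1L]] <- .keyRow(
        "pair", paste0(scheme, ":", i), paste0(scheme, ":", j), dd,
        desc = sprintf("%s-%s at topological distance %d", cls[i], cls[j],
                       dd))
      if (!is.null(limit) && length(rows) >= limit) return(do.call(rbind, rows))
    }
  }
  do.call(rbind, rows)
}

.estateBlock <- function() {
  tab <- .estateTypeTable()
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    .keyRow("estate", i, desc = paste0("E-state atom type ", tab$code[i]))))
}

# ---- family assembly -------------------------------------------------------

.keysetCache <- new.env(parent = emptyenv())

.assembleFamily <- function(family) {
  base <- switch(family,
    Estate = .estateBlock(),
    MACCS = {
      blocks <- rbind(
        .fgBlock(),
        .elemBlock(c("B", "Si", "P", "S", "F", "Cl", "Br", "I", "N", "O"),
                   rep(1L, 10)),
        .elemBlock(c("N", "N", "O", "O", "S", "HAL", "HAL", "C", "C", "C"),
                   c(2L, 4L, 2L, 4L, 2L, 2L, 4L, 8L, 16L, 24L)),
        .ringBlock(c(rep("any", 6), "arom", "arom", "aliph", "het", "any",
                     "any"),
                   c(3:8, 0, 0, 0, 0, 0, 0),
                   c(rep(1L, 6), 1L, 2L, 1L, 1L, 2L, 3L)),
        .bondEnumeration()[c(1:12, 16:25, 67:74, 95:98, 101:106), ][1:30, ],
        .pairEnumeration("cls12", 2:3, limit = 59))
      # field-conventional anchors: key 52 = N~N, key 63 = N=O
      stopifnot(nrow(blocks) == 166L)
      ord <- seq_len(166L)
      ord[c(1L, 52L)] <- ord[c(52L, 1L)]
      ord[c(2L, 63L)] <- ord[c(63L, 2L)]
      blocks[ord, ]
    },
    Pubchem = rbind(
      .elemBlock(c("C", "C", "C", "C", "C", "N", "N", "N", "N",
                   "O", "O", "O", "O", "O", "S", "S", "S", "P", "P",
                   "F", "F", "F", "Cl", "Cl", "Cl", "Br", "Br", "I",
                   "Si", "B", "HAL", "HAL", "HAL", "HAL", "CAT", "ANI",
                   "C", "N", "O", "S"),
                 c(2L, 4L, 8L, 16L, 32L, 1L, 2L, 4L, 8L,
                   1L, 2L, 4L, 8L, 16L, 1L, 2L, 4L, 1L, 2L,
                   1L, 2L, 4L, 1L, 2L, 4L, 1L, 2L, 1L,
                   1L, 1L, 1L, 2L, 4L, 8L, 1L, 1L,
                   64L, 16L, 32L, 8L)),
      .ringBlock(rep(c("any", "any", "arom", "aliph"), 8),
                 rep(3:10, each = 4),
                 rep(c(1L, 2L, 1L, 1L), 8)),
      .ringBlock(c("any", "any", "any", "any", "het", "het",
                   "arom", "arom", "arom", "arom"),
                 rep(0, 10),
                 c(1L, 2L, 3L, 4L, 1L, 2L, 1L, 2L, 3L, 4L)),
      .fgBlock(),
      .bondEnumeration(),
      .pairEnumeration("cls12", 1:8),
      .pairEnumeration("cls12", 9, limit = 20)),
    FP4 = rbind(
      .fgBlock(),
      .elemBlock(c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Si", "B"),
                 rep(1L, 11)),
      .ringBlock(c("any", "arom", "aliph", "het"), rep(0, 4), rep(1L, 4)),
      .bondEnumeration(),
      .pairEnumeration("cls12", 2:3, limit = 137)),
    KR = rbind(
      .pairEnumeration("cls30", 1:10),
      .fgBlock(),
      .bondEnumeration(),
      .elemBlock(c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Si", "B"),
                 rep(1L, 11)),
      .ringBlock(c("any", "arom", "aliph", "het"), rep(0, 4), rep(1L, 4)),
      .pairEnumeration("cls12", 1, limit = 40)),
    AP2D = .pairEnumeration("cls12", 1:10),
    stop("no structural dictionary for family ", family))
  base
}

#' Key dictionary of a fingerprint family
#'
#' Returns the full key table of a structural-key or count family: key name
#' (`<family>-<index>`), key type, parameters, the SMARTS pattern where the
#' key has an exact SMARTS equivalent (`NA` for distance/threshold/signature
#' keys), and a plain-text description. Count families (FP4C, KRC, AP2DC)
#' share the dictionary of their bit parent.
#'
#' @param family family abbreviation (see [fingerprintFamilies()]).
#' @return data.frame with columns family, index, name, type, p1, p2, p3,
#'   smarts, description.
#' @export
keyDictionary <- function(family) {
  .assertScalarChr(family, "family")
  info <- fingerprintSpec(family)
  if (info@kind == "hashed-path")
    stop("hashed-path family ", family, " has no key dictionary",
         call. = FALSE)
  parent <- if (family %in% c("FP4C", "KRC", "AP2DC"))
    sub("C$", "", family) else family
  if (!is.null(.keysetCache[[parent]])) {
    dict <- .keysetCache[[parent]]
  } else {
    dict <- .assembleFamily(parent)
    expected <- FP_FAMILIES$length[FP_FAMILIES$name == parent]
    if (nrow(dict) != expected)
      stop(sprintf("internal: %s dictionary has %d keys, expected %d",
                   parent, nrow(dict), expected))
    dict$family <- parent
    dict$index <- seq_len(nrow(dict))
    dict$name <- paste0(parent, "-", dict$index)
    rownames(dict) <- NULL
    .keysetCache[[parent]] <- dict
  }
  if (family != parent) {
    dict$family <- family
    dict$name <- paste0(family, "-", dict$index)
  }
  dict[, c("family", "index", "name", "type", "p1", "p2", "p3", "smarts",
           "description")]
}

#' Find fingerprint keys by SMARTS pattern
#'
#' Maps SMARTS strings to the key names of a family whose keys carry exactly
#' those patterns. Useful for locating the fingerprint bits of a known
#' substructure (e.g. the planted motifs of the synthetic fixtures).
#'
#' @param family family abbreviation.
#' @param smarts character vector of SMARTS strings.
#' @return character vector of key names (possibly empty).
#' @export
matchKeys <- function(family, smarts) {
  dict <- keyDictionary(family)
  dict$name[!is.na(dict$smarts) & dict$smarts %in% smarts]
}

#' Write a key dictionary as plain text
#'
#' One key per line: index, SMARTS (or NA), description; tab-separated.
#'
#' @param family family abbreviation.
#' @param path output file.
#' @export
writeKeyDictionary <- function(family, path) {
  dict <- keyDictionary(family)
  utils::write.table(dict[, c("index", "smarts", "description")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
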