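# Molecular graph layer: SMILES -> canonical SMILES -> annotated graph.
# Parsing and canonicalization are delegated to OpenBabel through
# ChemmineR/ChemmineOB; everything downstream (implicit hydrogens, aromatic
# flags, topological distances) is assembled here into a plain-list "molgraph"
# that the fingerprint engine consumes.

ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Br", "I")

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971,
  Br = 79.904, Sn = 118.71, I = 126.904, Ba = 137.33, Pt = 195.08,
  Hg = 200.59, Pb = 207.2, Li = 6.94, Be = 9.012, Ti = 47.867, Cd = 112.41
)

# Miller atomic polarizabilities (A^3), used for the Apol descriptor.
.ATOMIC_POLARIZABILITY <- c(
  H = 0.667, B = 3.03, C = 1.76, N = 1.10, O = 0.802, F = 0.557,
  Si = 5.38, P = 3.63, S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35,
  Na = 24.11, K = 43.4, Li = 24.33, Ca = 22.8, Mg = 10.6
)

.STANDARD_VALENCE <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

# old-style SDF charge codes (atom block field 5)
.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

#' Canonicalize SMILES strings
#'
#' Canonical SMILES via OpenBabel. Unparseable inputs yield `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalSmiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  keep <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(keep)) return(out)
  tags <- paste0("q", seq_along(smiles))
  src <- paste0(trimws(smiles[keep]), "\t", tags[keep], "\n", collapse = "")
  res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = src),
                  error = function(e) "")
  if (!nzchar(res)) return(out)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                character(1))
  can <- vapply(parts, `[`, character(1), 1)
  idx <- match(got, tags)
  ok <- !is.na(idx) & nzchar(can)
  out[idx[ok]] <- trimws(can[ok])
  out
}

# Build molgraph list objects for a character vector of *valid* canonical
# SMILES. Returns a list (same length, names kept); individual failures NULL.
buildMolGraphList <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(list())
  nm <- names(smiles) %||% paste0("mol", seq_len(n))
  names(smiles) <- paste0("g", seq_len(n))
  sdfs <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                   error = function(e) NULL)
  out <- vector("list", n)
  names(out) <- nm
  if (is.null(sdfs) || length(sdfs) == 0L) return(out)
  ringinfo <- tryCatch(
    ChemmineR::rings(sdfs, type = "all", arom = TRUE),
    error = function(e) NULL)
  have <- match(ChemmineR::cid(sdfs), names(smiles))
  for (k in seq_along(sdfs)) {
    i <- have[k]
    if (is.na(i)) next
    ri <- if (!is.null(ringinfo)) ringinfo[[k]] else NULL
    res <- tryCatch(
      .molgraphFromSdf(sdfs[[k]], smiles[[i]], ri),
      error = function(e) NULL)
    if (!is.null(res)) out[[i]] <- res
  }
  out
}

.molgraphFromSdf <- function(sdf, can, ringinfo = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  elem <- gsub("_\\d+$", "", rownames(ab))
  charge <- integer(n)
  if (ncol(ab) >= 5L) {
    # 5th numeric atom-block field = old-style SDF charge code
    code <- as.character(as.integer(ab[, 5L]))
    charge <- unname(.CHARGE_CODE[code])
    charge[is.na(charge)] <- 0L
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bi <- integer(0); bj <- integer(0); border <- integer(0)
  } else {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    border <- as.integer(bb[, 3])
  }
  # ring perception (ChemmineR): atom names like "C_3" -> index 3
  arom_atom <- rep(FALSE, n)
  ring_atom <- rep(FALSE, n)
  ring_sizes <- integer(0)
  ring_arom  <- logical(0)
  ring_het   <- logical(0)
  ring_bond_key <- character(0)
  arom_bond_key <- character(0)
  ringlists <- list()
  if (is.null(ringinfo)) {
    ringinfo <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE),
      error = function(e) NULL)
  }
  if (!is.null(ringinfo) && length(ringinfo$RINGS %||% list()) > 0L) {
    rr <- ringinfo$RINGS
    ar <- ringinfo$AROMATIC
    for (ri in seq_along(rr)) {
      idx <- as.integer(sub("^.*_", "", rr[[ri]]))
      ringlists[[ri]] <- idx
      ring_atom[idx] <- TRUE
      isar <- isTRUE(ar[[ri]])
      if (isar) arom_atom[idx] <- TRUE
      ring_sizes <- c(ring_sizes, length(idx))
      ring_arom  <- c(ring_arom, isar)
      ring_het   <- c(ring_het, any(elem[idx] != "C"))
      pk <- paste(pmin(idx, c(idx[-1], idx[1])),
                  pmax(idx, c(idx[-1], idx[1])), sep = "-")
      ring_bond_key <- c(ring_bond_key, pk)
      if (isar) arom_bond_key <- c(arom_bond_key, pk)
    }
  }
  bkey <- paste(pmin(bi, bj), pmax(bi, bj), sep = "-")
  bond_ring <- bkey %in% ring_bond_key
  bond_arom <- bkey %in% arom_bond_key
  # implicit hydrogens from standard valences (charge-adjusted for N/O/S/P)
  bondsum <- numeric(n)
  deg <- integer(n)
  if (length(bi)) {
    for (b in seq_along(bi)) {
      bondsum[bi[b]] <- bondsum[bi[b]] + border[b]
      bondsum[bj[b]] <- bondsum[bj[b]] + border[b]
      deg[bi[b]] <- deg[bi[b]] + 1L
      deg[bj[b]] <- deg[bj[b]] + 1L
    }
  }
  nH <- integer(n)
  for (a in seq_len(n)) {
    vals <- .STANDARD_VALENCE[[elem[a]]]
    if (is.null(vals)) { nH[a] <- 0L; next }
    vals <- vals + ifelse(elem[a] %in% c("N", "O", "S", "P"), charge[a], 0L)
    cand <- vals[vals >= bondsum[a]]
    nH[a] <- if (length(cand)) as.integer(min(cand) - bondsum[a]) else 0L
  }
  # topological distance matrix
  if (n == 1L) {
    D <- matrix(0L, 1, 1)
  } else if (length(bi) == 0L) {
    D <- matrix(Inf, n, n); diag(D) <- 0
  } else {
    g <- igraph::make_graph(rbind(bi, bj), n = n, directed = FALSE)
    D <- igraph::distances(g)
  }
  list(natoms = n, elem = elem, charge = charge, nH = nH, degree = deg,
       arom = arom_atom, inring = ring_atom,
       bonds = data.frame(i = bi, j = bj, order = border,
                          arom = bond_arom, inring = bond_ring),
       rings = list(sizes = ring_sizes, arom = ring_arom, het = ring_het,
                    atoms = ringlists),
       dist = D, smiles = can)
}

# heavy-atom count, carbon count and MW of a molgraph (implicit H included
# in MW); used by salt stripping and curation
.molHeavyAtoms <- function(m) m$natoms
.molCarbons <- function(m) sum(m$elem == "C")
.molWeight <- function(m) {
  mass <- .ATOMIC_MASS[m$elem]
  mass[is.na(mass)] <- 0
  sum(mass) + sum(m$nH) * .ATOMIC_MASS[["H"]]
}
.molApol <- function(m) {
  pol <- .ATOMIC_POLARIZABILITY[m$elem]
  pol[is.na(pol)] <- mean(.ATOMIC_POLARIZABILITY)
  sum(pol) + sum(m$nH) * .ATOMIC_POLARIZABILITY[["H"]]
}
.molWiener <- function(m) {
  if (m$natoms < 2L) return(0)
  D <- m$dist
  s <- sum(D[upper.tri(D)])
  if (!is.finite(s)) stop("Wiener index undefined for disconnected structure")
  s
}

# split a (canonical) SMILES into fragments at top-level dots
.splitFragments <- function(can) {
  strsplit(can, ".", fixed = TRUE)[[1]]
}
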