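# Fingerprint computation engine.
#
# Structural-key families evaluate their key dictionary against the
# molecular graph (counts first, thresholded to bits for bit families).
# Hashed families enumerate simple linear atom paths of up to 8 atoms,
# canonicalize each path string (lexicographic minimum of the two reading
# directions) and hash it into 1024 bits with a fixed polynomial hash
# (h = (h*31 + byte) mod 1048573, bit = h mod 1024). Everything is a pure
# function of the canonical SMILES, so equal structures give equal vectors.

#' Supported fingerprint families
#'
#' @return data.frame with columns name, kind, length for the 12 supported
#'   fingerprint families.
#' @export
fingerprintFamilies <- function() FP_FAMILIES

#' Construct a FingerprintSpec
#'
#' @param name family abbreviation: CDK, CDKExt, CDKGraph, Estate, MACCS,
#'   Pubchem, FP4, FP4C, KR, KRC, AP2D or AP2DC.
#' @return a [FingerprintSpec-class].
#' @export
fingerprintSpec <- function(name) {
  .assertScalarChr(name, "fingerprint family")
  i <- match(name, FP_FAMILIES$name)
  if (is.na(i))
    stop("unknown fingerprint family '", name, "'; valid names: ",
         paste(FP_FAMILIES$name, collapse = ", "), call. = FALSE)
  new("FingerprintSpec", name = FP_FAMILIES$name[i],
      kind = FP_FAMILIES$kind[i], length = FP_FAMILIES$length[i])
}

#' Build molecular graphs for the curated compounds of a CompoundSet
#'
#' Parsing is the slow step of fingerprint computation; build the graphs
#' once and pass them to [computeMatrix()] when computing several families.
#'
#' @param x a curated [CompoundSet-class] (all exclusion reasons "none").
#' @return named list of molecular graph objects, one per compound.
#' @export
molGraphs <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  rec <- compoundData(x)
  bad <- rec$id[rec$exclusion_reason != "none"]
  if (length(bad))
    stop("uncurated records present: ", paste(utils::head(bad, 5),
         collapse = ", "), call. = FALSE)
  smi <- rec$smiles_clean
  names(smi) <- rec$id
  mols <- buildMolGraphList(smi)
  fail <- names(mols)[vapply(mols, is.null, logical(1))]
  if (length(fail))
    stop("failed to build molecular graph for: ",
         paste(utils::head(fail, 5), collapse = ", "), call. = FALSE)
  mols
}

# ---- per-molecule auxiliary annotations ------------------------------------

.molAux <- function(m) {
  n <- m$natoms
  nbr <- replicate(n, list(j = integer(0), o = integer(0), a = logical(0)),
                   simplify = FALSE)
  b <- m$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      nbr[[i]]$j <- c(nbr[[i]]$j, j)
      nbr[[i]]$o <- c(nbr[[i]]$o, b$order[k])
      nbr[[i]]$a <- c(nbr[[i]]$a, b$arom[k])
      nbr[[j]]$j <- c(nbr[[j]]$j, i)
      nbr[[j]]$o <- c(nbr[[j]]$o, b$order[k])
      nbr[[j]]$a <- c(nbr[[j]]$a, b$arom[k])
    }
  }
  in3 <- rep(FALSE, n)
  for (ri in seq_along(m$rings$atoms))
    if (length(m$rings$atoms[[ri]]) == 3L) in3[m$rings$atoms[[ri]]] <- TRUE
  # E-state style bond signature per atom (heavy bonds only)
  nS <- nD <- nT <- nA <- integer(n)
  for (a in seq_len(n)) {
    o <- nbr[[a]]$o; ar <- nbr[[a]]$a
    nA[a] <- sum(ar)
    nS[a] <- sum(o == 1L & !ar)
    nD[a] <- sum(o == 2L & !ar)
    nT[a] <- sum(o == 3L)
  }
  sig <- paste(m$elem, m$nH, nS, nD, nT, nA)
  list(nbr = nbr, in3ring = in3, sig = sig,
       cls12 = .classify12(m, nbr), cls30 = .classify30(m, nbr, in3),
       X = m$degree + m$nH)
}

.classify12 <- function(m, nbr) {
  cls <- integer(m$natoms)
  for (a in seq_len(m$natoms)) {
    e <- m$elem[a]
    cls[a] <- if (e == "C") { if (m$arom[a]) 4L else 1L
    } else if (e == "N") { if (m$arom[a]) 5L else 2L
    } else if (e == "O") 3L else
      switch(e, S = 6L, P = 7L, F = 8L, Cl = 9L, Br = 10L, I = 11L, 12L)
  }
  cls
}

.classify30 <- function(m, nbr, in3) {
  n <- m$natoms
  cls <- integer(n)
  for (a in seq_len(n)) {
    e <- m$elem[a]
    ne <- m$elem[nbr[[a]]$j]
    ord <- nbr[[a]]$o
    cls[a] <-
      if (m$charge[a] > 0L) 1L else if (m$charge[a] < 0L) 2L else
      if (e == "C") {
        if (m$arom[a]) 3L else if (m$inring[a]) 4L else
        if (any(ord == 3L)) 5L else if (m$nH[a] == 3L) 6L else
        if (any(ne == "O")) 7L else if (any(ne == "N")) 8L else
        if (any(ne %in% .HALOGENS)) 9L else 10L
      } else if (e == "N") {
        if (m$arom[a]) 11L else if (m$inring[a]) 12L else
        if (m$nH[a] >= 2L) 13L else if (m$nH[a] == 1L) 14L else 15L
      } else if (e == "O") {
        if (m$inring[a]) 16L else if (m$nH[a] >= 1L) 17L else
        if (any(ord == 2L & !nbr[[a]]$a)) 18L else 19L
      } else if (e == "S") {
        if (m$inring[a]) 20L else
        if (any(ord == 2L & !nbr[[a]]$a)) 21L else 22L
      } else switch(e, P = 23L, F = 24L, Cl = 25L, Br = 26L, I = 27L,
                    B = 28L, Si = 29L, 30L)
  }
  cls
}

# unordered class-pair-at-distance codes "i|j|d" for all atom pairs
.pairCodes <- function(m, cls, maxd = 10L) {
  n <- m$natoms
  if (n < 2L) return(character(0))
  D <- m$dist
  ut <- which(upper.tri(D) & is.finite(D) & D >= 1 & D <= maxd,
              arr.ind = TRUE)
  if (nrow(ut) == 0L) return(character(0))
  ci <- cls[ut[, 1]]; cj <- cls[ut[, 2]]
  paste(pmin(ci, cj), pmax(ci, cj), D[ut], sep = "|")
}

# ---- functional-group counts ----------------------------------------------

.fgCount <- function(id, m, aux) {
  n <- m$natoms
  nbr <- aux$nbr
  elem <- m$elem
  bonds <- m$bonds
  # per-atom tests used repeatedly
  hasDblTo <- function(a, e) {
    nb <- nbr[[a]]
    any(nb$o == 2L & !nb$a & elem[nb$j] == e)
  }
  dblPartners <- function(a, e) {
    nb <- nbr[[a]]
    nb$j[nb$o == 2L & !nb$a & elem[nb$j] == e]
  }
  isOX1 <- function(a) elem[a] == "O" & m$degree[a] == 1L & m$nH[a] == 0L
  hasTerminalDblO <- function(a) {
    p <- dblPartners(a, "O"); any(vapply(p, isOX1, logical(1)))
  }
  isNX3 <- function(a) elem[a] == "N" & !m$arom[a] & aux$X[a] == 3L
  cnt <- switch(id,
    nn_any = sum(elem[bonds$i] == "N" & elem[bonds$j] == "N"),
    n_dbl_o = sum(bonds$order == 2L & !bonds$arom &
                  ((elem[bonds$i] == "N" & elem[bonds$j] == "O") |
                   (elem[bonds$i] == "O" & elem[bonds$j] == "N"))),
    nnitroso = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && any(elem[nbr[[a]]$j] == "N" &
        vapply(nbr[[a]]$j, function(b) elem[b] == "N" && hasDblTo(b, "O"),
               logical(1))), logical(1))),
    nitro = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && sum(elem[nbr[[a]]$j] == "O") >= 2L, logical(1))),
    azo = sum(bonds$order == 2L & !bonds$arom &
              elem[bonds$i] == "N" & elem[bonds$j] == "N"),
    hydrazine = sum(bonds$order == 1L & !bonds$arom &
                    elem[bonds$i] == "N" & elem[bonds$j] == "N" &
                    vapply(seq_len(nrow(bonds)), function(k)
                      isNX3(bonds$i[k]) && isNX3(bonds$j[k]), logical(1))),
    carbox_acid = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && aux$X[a] == 3L &&
        hasTerminalDblO(a) &&
        any(vapply(nbr[[a]]$j[nbr[[a]]$o == 1L], function(b)
          elem[b] == "O" && m$nH[b] == 1L && m$degree[b] == 1L,
          logical(1))), logical(1))),
    ester = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && aux$X[a] == 3L &&
        hasTerminalDblO(a) &&
        any(vapply(nbr[[a]]$j[nbr[[a]]$o == 1L], function(b)
          elem[b] == "O" && m$nH[b] == 0L && m$degree[b] == 2L &&
            any(elem[nbr[[b]]$j] == "C" & nbr[[b]]$j != a),
          logical(1))), logical(1))),
    amide = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && aux$X[a] == 3L &&
        hasTerminalDblO(a) &&
        any(vapply(nbr[[a]]$j, isNX3, logical(1))), logical(1))),
    urea = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && hasTerminalDblO(a) &&
        sum(vapply(nbr[[a]]$j, isNX3, logical(1))) >= 2L, logical(1))),
    aldehyde = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && m$nH[a] == 1L && m$degree[a] == 2L &&
        hasTerminalDblO(a), logical(1))),
    ketone = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && hasTerminalDblO(a) &&
        sum(elem[nbr[[a]]$j[nbr[[a]]$o == 1L]] == "C") >= 2L, logical(1))),
    carbonyl = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && aux$X[a] == 3L && hasTerminalDblO(a),
      logical(1))),
    hydroxyl = sum(elem == "O" & m$nH == 1L & m$degree == 1L),
    alcohol = sum(vapply(seq_len(n), function(a)
      elem[a] == "O" && m$nH[a] == 1L && m$degree[a] == 1L &&
        length(nbr[[a]]$j) == 1L && {
          b <- nbr[[a]]$j[1]
          elem[b] == "C" && !m$arom[b] && aux$X[b] == 4L
        }, logical(1))),
    phenol = sum(vapply(seq_len(n), function(a)
      elem[a] == "O" && m$nH[a] == 1L && m$degree[a] == 1L &&
        any(elem[nbr[[a]]$j] == "C" & m$arom[nbr[[a]]$j]), logical(1))),
    ether = sum(vapply(seq_len(n), function(a)
      elem[a] == "O" && !m$arom[a] && m$nH[a] == 0L && m$degree[a] == 2L &&
        all(elem[nbr[[a]]$j] == "C"), logical(1))),
    prim_amine = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && !m$arom[a] && m$nH[a] == 2L && m$degree[a] == 1L &&
        elem[nbr[[a]]$j[1]] == "C", logical(1))),
    sec_amine = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && !m$arom[a] && m$nH[a] == 1L && m$degree[a] == 2L &&
        all(elem[nbr[[a]]$j] == "C"), logical(1))),
    tert_amine = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && !m$arom[a] && m$nH[a] == 0L && m$degree[a] == 3L &&
        all(elem[nbr[[a]]$j] == "C"), logical(1))),
    arom_n = sum(elem == "N" & m$arom),
    aniline = sum(vapply(seq_len(n), function(a)
      isNX3(a) && any(elem[nbr[[a]]$j] == "C" & m$arom[nbr[[a]]$j]),
      logical(1))),
    nitrile = sum(vapply(seq_len(n), function(a)
      elem[a] == "N" && m$degree[a] == 1L && m$nH[a] == 0L &&
        any(nbr[[a]]$o == 3L & elem[nbr[[a]]$j] == "C"), logical(1))),
    isocyanate = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && m$degree[a] == 2L && m$nH[a] == 0L &&
        hasDblTo(a, "N") && hasDblTo(a, "O"), logical(1))),
    thiol = sum(elem == "S" & m$nH == 1L & m$degree == 1L),
    thioether = sum(vapply(seq_len(n), function(a)
      elem[a] == "S" && !m$arom[a] && m$nH[a] == 0L && m$degree[a] == 2L &&
        all(elem[nbr[[a]]$j] == "C"), logical(1))),
    s_dbl_o = sum(bonds$order == 2L & !bonds$arom &
                  ((elem[bonds$i] == "S" & elem[bonds$j] == "O") |
                   (elem[bonds$i] == "O" & elem[bonds$j] == "S"))),
    sulfone = sum(vapply(seq_len(n), function(a)
      elem[a] == "S" && length(dblPartners(a, "O")) >= 2L, logical(1))),
    halide_sp3 = sum(vapply(seq_len(nrow(bonds)), function(k) {
      i <- bonds$i[k]; j <- bonds$j[k]
      isC <- function(a) elem[a] == "C" && !m$arom[a] && aux$X[a] == 4L
      (isC(i) && elem[j] %in% .HALOGENS) ||
        (isC(j) && elem[i] %in% .HALOGENS)
    }, logical(1))),
    halide_arom = sum(vapply(seq_len(nrow(bonds)), function(k) {
      i <- bonds$i[k]; j <- bonds$j[k]
      (elem[i] == "C" && m$arom[i] && elem[j] %in% .HALOGENS) ||
        (elem[j] == "C" && m$arom[j] && elem[i] %in% .HALOGENS)
    }, logical(1))),
    epoxide = sum(elem == "O" & aux$in3ring),
    aziridine = sum(elem == "N" & aux$in3ring),
    benzene = {
      r <- m$rings
      sum(vapply(seq_along(r$sizes), function(ri)
        r$sizes[ri] == 6L && r$arom[ri] && !r$het[ri], logical(1)))
    },
    het_arom_ring = sum(m$rings$arom & m$rings$het),
    p_dbl_o = sum(bonds$order == 2L & !bonds$arom &
                  ((elem[bonds$i] == "P" & elem[bonds$j] == "O") |
                   (elem[bonds$i] == "O" & elem[bonds$j] == "P"))),
    dbl_cc = sum(bonds$order == 2L & !bonds$arom &
                 elem[bonds$i] == "C" & elem[bonds$j] == "C"),
    trp_cc = sum(bonds$order == 3L &
                 elem[bonds$i] == "C" & elem[bonds$j] == "C"),
    methyl = sum(elem == "C" & m$nH == 3L & m$degree == 1L),
    quart_c = sum(vapply(seq_len(n), function(a)
      elem[a] == "C" && !m$arom[a] && m$degree[a] == 4L &&
        all(elem[nbr[[a]]$j] == "C"), logical(1))),
    cation = sum(m$charge > 0L),
    anion = sum(m$charge < 0L),
    o_any = sum(elem == "O"),
    n_any = sum(elem == "N"),
    s_any = sum(elem == "S"),
    hal_any = sum(elem %in% .HALOGENS),
    stop("unknown functional-group key: ", id))
  as.integer(cnt)
}

# ---- dictionary evaluation -------------------------------------------------

.elemCountOf <- function(m, sym) {
  switch(sym,
    HAL = sum(m$elem %in% .HALOGENS),
    CAT = sum(m$charge > 0L),
    ANI = sum(m$charge < 0L),
    sum(m$elem == sym))
}

.ringCountOf <- function(m, kind, size) {
  r <- m$rings
  if (!length(r$sizes)) return(0L)
  sel <- rep(TRUE, length(r$sizes))
  if (size > 0L) sel <- sel & r$sizes == size
  sel <- sel & switch(kind,
    any = TRUE, arom = r$arom, aliph = !r$arom, het = r$het)
  sum(sel)
}

.bondCountOf <- function(m, a, b, o) {
  bonds <- m$bonds
  if (!nrow(bonds)) return(0L)
  ei <- m$elem[bonds$i]; ej <- m$elem[bonds$j]
  epair <- (ei == a & ej == b) | (ei == b & ej == a)
  sel <- switch(o,
    `-` = bonds$order == 1L & !bonds$arom,
    `=` = bonds$order == 2L & !bonds$arom,
    `#` = bonds$order == 3L,
    `:` = bonds$arom)
  sum(epair & sel)
}

# counts for every key of a family dictionary, one molecule
.familyCounts <- function(dict, m, aux, estate_tab) {
  out <- integer(nrow(dict))
  types <- dict$type
  # pair keys en bloc per scheme
  for (scheme in c("cls12", "cls30")) {
    ki <- which(types == "pair" & startsWith(dict$p1, scheme))
    if (!length(ki)) next
    codes <- .pairCodes(m, aux[[scheme]])
    if (length(codes)) {
      tab <- table(codes)
      want <- paste(sub(paste0(scheme, ":"), "", dict$p1[ki]),
                    sub(paste0(scheme, ":"), "", dict$p2[ki]),
                    dict$p3[ki], sep = "|")
      hit <- match(want, names(tab))
      out[ki] <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
    }
  }
  ki <- which(types == "elem")
  for (k in ki) {
    cnt <- .elemCountOf(m, dict$p1[k])
    out[k] <- max(0L, cnt - as.integer(dict$p2[k]) + 1L)
  }
  ki <- which(types == "ring")
  for (k in ki) {
    cnt <- .ringCountOf(m, dict$p1[k], as.integer(dict$p2[k]))
    out[k] <- max(0L, cnt - as.integer(dict$p3[k]) + 1L)
  }
  ki <- which(types == "bond")
  for (k in ki)
    out[k] <- .bondCountOf(m, dict$p1[k], dict$p2[k], dict$p3[k])
  ki <- which(types == "fg")
  for (k in ki) out[k] <- .fgCount(dict$p1[k], m, aux)
  ki <- which(types == "estate")
  if (length(ki)) {
    tab <- table(aux$sig)
    hit <- match(estate_tab$sig[as.integer(dict$p1[ki])], names(tab))
    out[ki] <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  out
}

# ---- hashed path families --------------------------------------------------

.hashString <- function(s, nbits = 1024L) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1048573
  as.integer(h %% nbits)
}

# all simple paths with 1..maxatoms atoms, each undirected path once
.enumPaths <- function(m, aux, maxatoms = 8L) {
  n <- m$natoms
  acc <- vector("list", 256L)
  cnt <- 0L
  push <- function(p) {
    cnt <<- cnt + 1L
    if (cnt > length(acc)) length(acc) <<- 2L * length(acc)
    acc[[cnt]] <<- p
  }
  nbrIdx <- lapply(aux$nbr, `[[`, "j")
  visited <- logical(n)
  walk <- function(path) {
    last <- path[length(path)]
    for (nx in nbrIdx[[last]]) {
      if (visited[nx]) next
      p2 <- c(path, nx)
      if (nx > path[1]) push(p2)   # record once per direction
      if (length(p2) < maxatoms) {
        visited[nx] <<- TRUE
        walk(p2)
        visited[nx] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    push(s)
    visited[s] <- TRUE
    walk(s)
    visited[s] <- FALSE
  }
  acc[seq_len(cnt)]
}

.hashedBits <- function(m, aux, variant, nbits = 1024L) {
  atok <- switch(variant,
    CDK = m$elem,
    CDKGraph = m$elem,
    CDKExt = paste0(m$elem,
                    ifelse(m$arom, "*", ifelse(m$inring, "@", "")),
                    ifelse(m$charge > 0L, "+",
                           ifelse(m$charge < 0L, "-", ""))))
  n <- m$natoms
  bsym <- matrix("", n, n)
  b <- m$bonds
  if (nrow(b)) {
    sym <- ifelse(b$arom, ":",
                  c("-", "=", "#")[pmin(b$order, 3L)])
    if (variant == "CDKGraph") sym <- rep("~", nrow(b))
    bsym[cbind(b$i, b$j)] <- sym
    bsym[cbind(b$j, b$i)] <- sym
  }
  paths <- .enumPaths(m, aux)
  strs <- vapply(paths, function(p) {
    k <- length(p)
    if (k == 1L) return(atok[p])
    fwd <- atok[p[1]]
    for (t in 2:k) fwd <- paste0(fwd, bsym[p[t - 1], p[t]], atok[p[t]])
    rp <- rev(p)
    rev_ <- atok[rp[1]]
    for (t in 2:k) rev_ <- paste0(rev_, bsym[rp[t - 1], rp[t]], atok[rp[t]])
    if (fwd <= rev_) fwd else rev_
  }, character(1))
  strs <- unique(strs)
  bits <- integer(nbits)
  bits[vapply(strs, .hashString, integer(1), nbits = nbits) + 1L] <- 1L
  bits
}

# ---- public API ------------------------------------------------------------

.fingerprintVector <- function(m, spec, dict = NULL, estate_tab = NULL) {
  if (spec@kind == "hashed-path") {
    aux <- .molAux(m)
    return(.hashedBits(m, aux, spec@name))
  }
  aux <- .molAux(m)
  cnts <- .familyCounts(dict, m, aux, estate_tab)
  if (spec@kind == "structural-key") as.integer(cnts > 0L) else cnts
}

#' Compute one fingerprint vector
#'
#' @param x a curated [CompoundSet-class] with a single record (or a record
#'   id selected from a larger set via `[`).
#' @param spec a [FingerprintSpec-class] or family name.
#' @return integer vector of length `spec@length`, named by key.
#' @export
computeFingerprint <- function(x, spec) {
  if (is.character(spec)) spec <- fingerprintSpec(spec)
  fm <- computeMatrix(x, spec)
  v <- fpValues(fm)
  if (nrow(v) != 1L)
    stop("computeFingerprint expects a single compound; got ", nrow(v))
  v[1, ]
}

#' Compute a fingerprint matrix for a compound set
#'
#' Rows follow dataset order; columns are named `<family>-<index>`. The
#' result is deterministic for a given set of canonical SMILES.
#'
#' @param x a curated [CompoundSet-class].
#' @param spec a [FingerprintSpec-class] or family name.
#' @param mols optional pre-built [molGraphs()] list.
#' @return a [FingerprintMatrix-class].
#' @export
computeMatrix <- function(x, spec, mols = NULL) {
  if (is.character(spec)) spec <- fingerprintSpec(spec)
  stopifnot(is(x, "CompoundSet"))
  dict <- estate_tab <- NULL
  if (spec@kind != "hashed-path") {
    dict <- keyDictionary(spec@name)
    colnames_ <- dict$name
    if (any(dict$type == "estate")) estate_tab <- .estateTypeTable()
  } else {
    colnames_ <- paste0(spec@name, "-", seq_len(spec@length))
  }
  if (length(x) == 0L) {
    v <- matrix(0L, 0L, spec@length,
                dimnames = list(NULL, colnames_))
    return(new("FingerprintMatrix", values = v, spec = spec))
  }
  if (is.null(mols)) mols <- molGraphs(x)
  ids <- compoundIds(x)
  mols <- mols[ids]
  if (any(vapply(mols, is.null, logical(1))))
    stop("molecular graphs missing for some compounds", call. = FALSE)
  v <- matrix(0L, length(ids), spec@length,
              dimnames = list(ids, colnames_))
  for (r in seq_along(ids))
    v[r, ] <- .fingerprintVector(mols[[r]], spec, dict, estate_tab)
  new("FingerprintMatrix", values = v, spec = spec)
}

#' Compute fingerprint matrices for several families at once
#'
#' Builds the molecular graphs a single time and reuses them.
#'
#' @param x a curated [CompoundSet-class].
#' @param families character vector of family names.
#' @return named list of [FingerprintMatrix-class] objects.
#' @export
computeMatrices <- function(x, families) {
  mols <- molGraphs(x)
  out <- lapply(families, function(f) computeMatrix(x, f, mols = mols))
  names(out) <- families
  out
}

#' Molecular descriptors for chemical-space inspection
#'
#' MW, ALogP, hydrogen-bond acceptor and donor counts (computed by
#' OpenBabel), the Wiener path number (sum of topological distances over
#' all heavy-atom pairs) and Apol (sum of atomic polarizabilities,
#' including implicit hydrogens; Miller values).
#'
#' @param x a curated [CompoundSet-class].
#' @return data.frame with columns MW, ALogP, nHBAcc, nHBDon, Wiener, Apol;
#'   one row per compound (rownames = ids).
#' @export
computeDescriptors <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  mols <- molGraphs(x)
  ids <- compoundIds(x)
  smi <- cleanSmiles(x)
  names(smi) <- paste0("d", seq_along(smi))
  sdfs <- ChemmineR::smiles2sdf(smi)
  pr <- ChemmineR::propOB(sdfs)
  hit <- match(paste0("d", seq_along(ids)), rownames(pr))
  if (anyNA(hit)) hit <- match(paste0("d", seq_along(ids)), pr$title)
  out <- data.frame(
    MW = pr$MW[hit],
    ALogP = pr$logP[hit],
    nHBAcc = pr$HBA1[hit],
    nHBDon = pr$HBD[hit],
    Wiener = vapply(mols, .molWiener, numeric(1)),
    Apol = vapply(mols, .molApol, numeric(1)),
    row.names = ids)
  if (any(out$MW <= 0, na.rm = TRUE)) warning("non-positive MW computed")
  out
}
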