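# Fingerprint families: declared sizes, determinism, key semantics.

test_that("family lengths match the declared contract", {
  fams <- fingerprintFamilies()
  expected <- c(CDK = 1024L, CDKExt = 1024L, CDKGraph = 1024L, Estate = 79L,
                MACCS = 166L, Pubchem = 881L, FP4 = 307L, FP4C = 307L,
                KR = 4860L, KRC = 4860L, AP2D = 780L, AP2DC = 780L)
  expect_equal(stats::setNames(fams$length, fams$name), expected)
  for (f in fams$name)
    expect_equal(fingerprintSpec(f)@length, expected[[f]])
  # dictionaries enumerate exactly the declared lengths
  for (f in fams$name[fams$kind != "hashed-path"])
    expect_equal(nrow(keyDictionary(f)), expected[[f]])
  # count families share their parent's key dictionary
  for (p in c("FP4", "KR", "AP2D")) {
    a <- keyDictionary(p); b <- keyDictionary(paste0(p, "C"))
    expect_equal(a$smarts, b$smarts)
    expect_equal(a$description, b$description)
  }
})

test_that("computed vectors have the declared length and naming", {
  cs <- tinySet("CCCN(C)N=O")
  for (f in fingerprintFamilies()$name) {
    v <- computeFingerprint(cs, f)
    expect_length(v, fingerprintSpec(f)@length)
    expect_equal(names(v)[1], paste0(f, "-1"))
  }
})

test_that("structural keys match substructures: N-N bit set only with N-N", {
  cs <- tinySet(c("c1ccccc1CC", "CCCN(C)N=O"), ids = c("benz", "ndma"))
  v <- fpValues(computeMatrix(cs, "MACCS"))
  nn <- matchKeys("MACCS", "[#7]~[#7]")
  expect_length(nn, 1L)
  expect_equal(unname(v["benz", nn]), 0L)
  expect_equal(unname(v["ndma", nn]), 1L)
})

test_that("matrices follow dataset order, and empty input gives a full-width header", {
  fx <- smallFixture(20)
  fm <- computeMatrix(fx$compounds, "MACCS")
  expect_equal(rownames(fpValues(fm)), compoundIds(fx$compounds))
  fm0 <- computeMatrix(fx$compounds[integer(0)], "KR")
  expect_equal(dim(fpValues(fm0)), c(0L, 4860L))
  expect_equal(colnames(fpValues(fm0))[4860], "KR-4860")
})

test_that("equal canonical structures give equal vectors (determinism)", {
  spellings <- c("CCCN(C)N=O", "O=NN(C)CCC", "N(CCC)(C)N=O")
  sets <- lapply(spellings, tinySet)
  for (f in c("MACCS", "KR", "AP2DC", "CDK", "CDKExt", "CDKGraph")) {
    vecs <- lapply(sets, computeFingerprint, spec = f)
    expect_equal(unname(vecs[[1]]), unname(vecs[[2]]), info = f)
    expect_equal(unname(vecs[[1]]), unname(vecs[[3]]), info = f)
  }
  # and across repeated computation
  expect_identical(fpValues(computeMatrix(sets[[1]], "Pubchem")),
                   fpValues(computeMatrix(sets[[1]], "Pubchem")))
})

test_that("bit families are the indicator of their count variants", {
  fx <- smallFixture(30)
  mols <- molGraphs(fx$compounds)
  for (p in c("FP4", "KR", "AP2D")) {
    bit <- fpValues(computeMatrix(fx$compounds, p, mols = mols))
    cnt <- fpValues(computeMatrix(fx$compounds, paste0(p, "C"),
                                  mols = mols))
    expect_true(all(cnt >= 0L))
    expect_identical(bit, matrix(as.integer(cnt > 0L), nrow(cnt),
                                 dimnames = dimnames(bit)), info = p)
  }
})

test_that("structural-key bits agree with an independent SMARTS matcher", {
  panel <- c("CCCN(CCC)N=O", "CCC(=O)O", "c1ccccc1O", "CCCN", "CCNCC",
             "CCN(C)C", "Nc1ccccc1", "CC(=O)OC", "CC(=O)NC", "CNC(=O)NC",
             "CCC=O", "CC(=O)C", "CCCS", "CSCC", "CS(=O)(=O)C", "CCCCl",
             "Clc1ccccc1", "CC1CO1", "CC1CN1", "c1ccncc1", "CC(C)(C)C",
             "N#CCC", "O=C=NCC", "CCOCC", "OCC(O)CO", "c1ccc2ccccc2c1",
             "C1CCCCC1", "CC(Br)CC", "CCCCI", "FC(F)(F)CC", "CCP(=O)(O)O",
             "CN=NC", "CNNCC", "[O-]C(=O)CC[N+](C)(C)C",
             "O=[N+]([O-])c1ccccc1", "CCCCCC(=O)OCC", "c1ccsc1",
             "c1cc[nH]c1", "CC(N)C(=O)O", "CCC(C)N=O", "CCCON=O",
             "c1ccc(cc1)S(=O)(=O)N", "CC(C)CO", "CCC=CC", "CNC(=O)C",
             "c1ccoc1", "CC(C)Cc1ccccc1", "CCCCN(C)N=O", "CCCCO",
             "CC(C)C(C)N")
  cs <- curated(tinySet(panel))
  expect_gte(length(cs), 45L)
  smi <- cleanSmiles(cs)
  names(smi) <- compoundIds(cs)
  sdfs <- ChemmineR::smiles2sdf(smi)
  for (fam in c("FP4", "MACCS")) {
    v <- fpValues(computeMatrix(cs, fam))
    dict <- keyDictionary(fam)
    for (k in which(!is.na(dict$smarts))) {
      hits <- suppressWarnings(ChemmineR::smartsSearchOB(sdfs,
                                                         dict$smarts[k]))
      ob <- as.integer(hits[compoundIds(cs)] > 0)
      mine <- as.integer(v[, dict$name[k]] > 0)
      expect_equal(mine, ob,
                   info = paste(fam, dict$name[k], dict$smarts[k]))
    }
  }
})

test_that("uncurated records are refused with the record id", {
  cs <- tinySet(c("CO", "CCCC"), ids = c("tiny", "ok"))
  expect_error(computeMatrix(cs, "MACCS"), "tiny")
})

test_that("descriptor oracles: Wiener path counts and H-bond counts", {
  # ethane: single pair at distance 1; n-butane: path graph P4 sums to 10
  d <- computeDescriptors(rawSet(c("CC", "CCCC", "CO")))
  expect_equal(d$Wiener, c(1, 10, 1))
  # methanol: one donor, one acceptor
  expect_equal(d$nHBDon[3], 1)
  expect_equal(d$nHBAcc[3], 1)
  expect_true(all(d$MW > 0))
  expect_true(all(d$Apol > 0))
  # brute-force Wiener on a branched molecule via igraph distances
  m <- CarcinoEnsemble:::buildMolGraphList("CC(C)CC")[[1]]
  D <- m$dist
  expect_equal(computeDescriptors(rawSet("CC(C)CC"))$Wiener,
               sum(D[upper.tri(D)]))
})

test_that("key dictionaries can be exported as plain text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeKeyDictionary("Estate", path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 79L)
  expect_error(keyDictionary("CDK"), "hashed-path")
})
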