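test_that("peptide construction validates residues and termini", {
  p <- peptide(WT, id = "wt")
  expect_s4_class(p, "PeptideSequence")
  expect_equal(length(p), 13L)
  expect_equal(as.character(p), WT)
  expect_error(peptide(""), "at least one residue")
  expect_error(peptide("MAZ"), "non-canonical")
  expect_error(peptide("MA", nTerminus = "weird"), "nTerminus")
  amide <- peptide(MTP2, cTerminus = "amide")
  expect_equal(amide@cTerminus, "amide")
})

test_that("bundled scales load complete and self-consistent", {
  for (nm in availableScales()) {
    sc <- loadScale(nm)
    expect_s4_class(sc, "ResidueScale")
    expect_length(scaleValues(sc), 20L)
    expect_setequal(names(scaleValues(sc)),
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  err <- tryCatch(loadScale("nonexistent"), error = identity)
  expect_s3_class(err, "pepscan_error")
  expect_match(conditionMessage(err), "kyte_doolittle")
  ## calibration examples: mean/sum over the parent reproduce the panel
  kd <- scaleValues(loadScale("kyte_doolittle"))
  expect_matches_printed(mean(kd[strsplit(WT, "")[[1]]]), "0.346")
  ww <- scaleValues(loadScale("ww_interface"))
  expect_matches_printed(sum(ww[strsplit(WT, "")[[1]]]), "1.75")
})

test_that("descriptors reproduce the published wild-type and mutant values", {
  expect_matches_printed(bomanIndex(WT), "0.42")
  expect_matches_printed(bomanIndex(MTP2), "2.06")
  expect_matches_printed(gravy(WT), "0.346")
  expect_matches_printed(gravy(MTP1), "1.41")
  expect_matches_printed(wwInterface(WT), "1.75")
  expect_matches_printed(wwInterface("MAGAHQAVAFQFT"), "-0.26")
  expect_identical(netCharge(MTP1), 1L)
  expect_identical(netCharge("MAGAHQAVAFQFT"), 0L)
  expect_identical(netCharge("GGGG"), 0L)
  expect_identical(hydrophobicRatio(WT), 61L)
  expect_identical(hydrophobicRatio(MTP2), 46L)
  expect_identical(hydrophobicRatio(MTP1), 60L)  # Gly not hydrophobic
  expect_identical(hydrophobicRatio("GGGG"), 0L)
})

test_that("mean descriptors are composition averages", {
  expect_equal(bomanIndex("AA"), bomanIndex("A"))
  expect_equal(gravy("W"), scaleValues(loadScale("kyte_doolittle"))[["W"]])
  ## sum decomposition for the interface descriptor
  expect_equal(wwInterface("MAEAH") + wwInterface("QAVAFQFT"),
               wwInterface(WT), tolerance = 1e-12)
})

test_that("molecular weight uses average masses, free termini by default", {
  expect_lt(abs(molecularWeight(MTP2) - 1447.60), 0.1)
  expect_lt(abs(molecularWeight(MTP1) - 1546.90), 0.1)
  ## glycine + water from standard atomic weights (C2H3NO + H2O)
  g_expected <- (2 * 12.011 + 3 * 1.008 + 14.007 + 15.999) +
    (2 * 1.008 + 15.999)
  expect_lt(abs(molecularWeight("G") - g_expected), 0.01)
  expect_lt(abs(molecularWeight("G") - 75.07), 0.01)
  ## amide option removes 0.98 Da
  expect_equal(molecularWeight(MTP2, cTerminus = "amide"),
               molecularWeight(MTP2) - 0.9847, tolerance = 1e-9)
})

test_that("mass additivity: concatenation loses one water", {
  set.seed(11)
  for (i in 1:20) {
    a <- as.character(randomPeptide(sample(1:12, 1)))
    b <- as.character(randomPeptide(sample(1:12, 1)))
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 18.0153,
                 tolerance = 1e-6)
  }
})

test_that("profile equals the tuple of single-descriptor calls", {
  p <- descriptorProfile(MTP2)
  expect_equal(bomanIndex(p), bomanIndex(MTP2))
  expect_equal(gravy(p), gravy(MTP2))
  expect_equal(wwInterface(p), wwInterface(MTP2))
  expect_equal(netCharge(p), netCharge(MTP2))
  expect_equal(hydrophobicRatio(p), hydrophobicRatio(MTP2))
  expect_equal(molecularWeight(p), molecularWeight(MTP2))
  df <- as.data.frame(p)
  expect_named(df, c("mol_weight", "boman_index", "hydrophobic_ratio",
                     "net_charge", "gravy", "ww_interface"))
})

test_that("every descriptor is permutation invariant", {
  set.seed(42)
  for (i in 1:25) {
    s <- as.character(randomPeptide(sample(5:25, 1)))
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(bomanIndex(s), bomanIndex(sh))
    expect_equal(gravy(s), gravy(sh))
    expect_equal(wwInterface(s), wwInterface(sh), tolerance = 1e-12)
    expect_identical(netCharge(s), netCharge(sh))
    expect_identical(hydrophobicRatio(s), hydrophobicRatio(sh))
    expect_equal(molecularWeight(s), molecularWeight(sh),
                 tolerance = 1e-9)
  }
})

test_that("mean descriptors stay within their scale's range", {
  bo <- scaleValues(loadScale("boman"))
  kd <- scaleValues(loadScale("kyte_doolittle"))
  set.seed(3)
  for (i in 1:50) {
    s <- randomPeptide(sample(1:30, 1))
    expect_gte(bomanIndex(s), min(bo)); expect_lte(bomanIndex(s), max(bo))
    expect_gte(gravy(s), min(kd)); expect_lte(gravy(s), max(kd))
  }
})

test_that("mutations apply, validate and leave the parent untouched", {
  wt <- peptide(WT, id = "wt")
  m2 <- applyMutations(wt, list(mutation(8, "V", "K"),
                                mutation(12, "F", "D")))
  expect_equal(as.character(m2), MTP2)
  expect_equal(as.character(wt), WT)           # parent unmodified
  expect_equal(as.character(applyMutations(wt, list())), WT)
  expect_equal(as.character(applyMutations(wt, c("V8K", "F12D"))), MTP2)
  expect_error(applyMutations(wt, mutation(3, "A", "G")),
               "original mismatch")
  expect_error(applyMutations(wt, c("V8K", "V8D")), "more than once")
  expect_error(applyMutations(wt, mutation(99, "A", "G")), "beyond")
  expect_error(mutation("8K"), "cannot parse")
  expect_error(mutation(8, "V", "Z"), "canonical")
})

test_that("display truncation goes toward zero at printed precision", {
  expect_equal(truncateToZero(17.23 / 13, 2), 1.32)
  expect_equal(truncateToZero(-25.30 / 15, 2), -1.68)
  expect_equal(truncateToZero(1.3 / 13, 3), 0.1)   # guard vs binary error
  expect_equal(truncateToZero(-0.13846, 3), -0.138)
})

test_that("FASTA writer and reader round-trip peptides", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  ps <- list(peptide(WT, id = "wt"), peptide(MTP1, id = "MTP1"))
  writePeptideFasta(ps, tf)
  back <- readPeptideFasta(tf)
  expect_equal(vapply(back, as.character, ""),
               c(wt = WT, MTP1 = MTP1))
  expect_error(readPeptideFasta(withr::local_tempfile()), "not found")
})
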