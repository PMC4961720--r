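test_that("shift-table fixtures parse and cross-validate", {
  t2 <- readShiftTable(shift_fixture("mtp1_tfe"))
  expect_s4_class(t2, "ShiftTable")
  expect_equal(as.character(t2@peptide), MTP1)
  expect_equal(t2@solvent, "TFE_H2O_1_1")
  a <- t2@records[t2@records$atom == "aCH", ]
  expect_equal(nrow(a), 15L)
  expect_equal(a$shift_ppm[a$residue_index == 13], 3.72)

  t3 <- readShiftTable(shift_fixture("mtp2_dmso"))
  expect_equal(t3@records$shift_ppm[t3@records$residue_index == 1 &
                                      t3@records$atom == "aCH"], 3.84)
  ## explicit sequence must agree with the records
  expect_error(readShiftTable(shift_fixture("mtp2_dmso"), sequence = MTP1),
               "does not match")
})

test_that("malformed shift tables are rejected with line numbers", {
  write_tab <- function(lines) {
    tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    writeLines(c("#! sequence=MA",
                 "residue_index\tresidue\tatom\tshift_ppm\tnote", lines), tf)
    tf
  }
  expect_error(readShiftTable(write_tab("1\tZ\taCH\t4.2\t")),
               "line 3.*unknown residue")
  expect_error(readShiftTable(write_tab("1\tMet\taCH\tx\t")),
               "line 3.*not numeric")
  expect_error(readShiftTable(write_tab("1\tMet\tqCH\t4.2\t")),
               "line 3.*atom label")
  expect_error(readShiftTable(write_tab("1\tAla\taCH\t4.2\t")),
               "does not match")
  expect_error(readShiftTable(write_tab(c("1\tMet\taCH\t4.2\t",
                                          "1\tMet\taCH\t4.3\t"))),
               "duplicate aCH")
  expect_error(readShiftTable(write_tab("1\tMet\taCH\t14.2\t")),
               "outside 0-12")
})

test_that("alpha-CH deviations subtract the random-coil reference", {
  ref <- loadRandomCoil()
  ## table built exactly at the reference: all deviations zero
  tab0 <- syntheticShiftTable(WT, noiseSd = 0)
  expect_equal(csdData(csdAlpha(tab0, ref))$delta_ppm, rep(0, 13))
  ## uniform helical offset is recovered exactly
  tabh <- syntheticShiftTable(WT, helixSegments = list(c(1, 13)),
                              noiseSd = 0, helixShift = -0.30)
  expect_equal(csdData(csdAlpha(tabh, ref))$delta_ppm, rep(-0.30, 13))
  ## the designed peptide's C-terminal valine is strongly helical in TFE
  tfe <- csdAlpha(readShiftTable(shift_fixture("mtp1_tfe")), ref)
  expect_lt(csdData(tfe)$delta_ppm[13], -0.1)
})

test_that("deviations are linear in a uniform shift offset", {
  tab <- readShiftTable(shift_fixture("mtp2_tfe"))
  base <- csdData(csdAlpha(tab))$delta_ppm
  for (cshift in c(-0.2, 0.07)) {
    shifted <- tab
    a <- shifted@records$atom == "aCH"
    shifted@records$shift_ppm[a] <- shifted@records$shift_ppm[a] + cshift
    expect_equal(csdData(csdAlpha(shifted))$delta_ppm, base + cshift,
                 tolerance = 1e-12)
  }
})

test_that("helix classification follows the threshold-and-run rule", {
  mk <- function(deltas) {
    n <- length(deltas)
    ref <- loadRandomCoil()
    tab <- syntheticShiftTable(paste(rep("A", n), collapse = ""),
                               noiseSd = 0)
    a <- tab@records$atom == "aCH"
    tab@records$shift_ppm[a] <- scaleValues(ref)[["A"]] + deltas
    csdAlpha(tab)
  }
  all_h <- classifyStructure(mk(rep(-0.3, 10)))
  expect_true(all(csdData(all_h)$label == "helical"))
  expect_equal(all_h@overall, "helical")

  all_c <- classifyStructure(mk(rep(0, 10)))
  expect_true(all(csdData(all_c)$label == "coil"))
  expect_equal(all_c@overall, "coil")

  ## three isolated sub-threshold residues do not make a helix
  d <- rep(0, 10); d[c(2, 5, 8)] <- -0.3
  iso <- classifyStructure(mk(d), minRun = 4)
  expect_equal(iso@overall, "coil")
  expect_true(all(csdData(iso)$label == "coil"))

  expect_error(classifyStructure(mk(rep(0, 5)), minRun = 0), "minRun")
})

test_that("run extraction matches a brute-force scan of labels", {
  brute_runs <- function(cand, minRun) {
    lab <- rep(FALSE, length(cand))
    i <- 1L
    while (i <= length(cand)) {
      j <- i
      while (j <= length(cand) && cand[j]) j <- j + 1L
      if (cand[i] && (j - i) >= minRun) lab[i:(j - 1L)] <- TRUE
      i <- max(j, i + 1L)
    }
    lab
  }
  ref <- loadRandomCoil()
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(5:25, 1)
    deltas <- ifelse(stats::runif(n) < 0.4, -0.3, 0)
    minRun <- sample(1:5, 1)
    tab <- syntheticShiftTable(paste(rep("A", n), collapse = ""),
                               noiseSd = 0)
    a <- tab@records$atom == "aCH"
    tab@records$shift_ppm[a] <- scaleValues(ref)[["A"]] + deltas
    got <- csdData(classifyStructure(csdAlpha(tab), minRun = minRun))$label
    want <- ifelse(brute_runs(deltas < -0.1, minRun), "helical", "coil")
    expect_equal(got, want)
  }
})

test_that("restraint categories bin by sequence separation and conserve", {
  r <- syntheticRestraints(15, c(intra = 60, seq = 37, medium = 14,
                                 long = 0), seed = 1)
  s <- restraintStats(r, torsions = 4)
  expect_equal(unname(restraintCounts(s)), c(111, 60, 37, 14, 0, 4))

  empty <- restraintStats(syntheticRestraints(10, c(intra = 0, seq = 0,
                                                    medium = 0, long = 0)))
  expect_equal(unname(restraintCounts(empty)), rep(0, 6))

  one <- data.frame(residue_i = 1L, resname_i = "ALA", atom_i = "HA",
                    residue_j = 8L, resname_j = "ALA", atom_j = "HN",
                    upper_bound = 5)
  expect_equal(restraintCounts(restraintStats(one))[["long_range"]], 1)

  ## conservation fuzz over random restraint lists
  set.seed(8)
  for (i in 1:100) {
    n <- sample(0:80, 1)
    rr <- data.frame(residue_i = sample(1:20, n, TRUE),
                     resname_i = rep("ALA", n), atom_i = rep("HA", n),
                     residue_j = sample(1:20, n, TRUE),
                     resname_j = rep("ALA", n), atom_j = rep("HN", n),
                     upper_bound = runif(n, 2, 6))
    cc <- restraintCounts(restraintStats(rr))
    expect_equal(cc[["total"]],
                 cc[["intraresidue"]] + cc[["sequential"]] +
                   cc[["medium_range"]] + cc[["long_range"]])
    expect_equal(cc[["total"]], n)
  }
})

test_that("UPL lists parse, validate and round-trip", {
  tf <- withr::local_tempfile(fileext = ".upl")
  writeLines(c("# comment line", "1 LYS HA 2 VAL HN 3.5"), tf)
  r <- readUpl(tf)
  expect_equal(nrow(r), 1L)
  expect_equal(abs(r$residue_i - r$residue_j), 1L)
  expect_equal(r$upper_bound, 3.5)

  writeLines("# only a comment", tf)
  expect_equal(nrow(readUpl(tf)), 0L)

  writeLines("1 LYS HA 2 VAL HN -3.5", tf)
  expect_error(readUpl(tf), "line 1.*positive")
  writeLines("1 LYS HA 2 VAL HN", tf)
  expect_error(readUpl(tf), "7 whitespace-separated")

  r2 <- syntheticRestraints(12, c(intra = 5, seq = 4, medium = 3,
                                  long = 2), seed = 5)
  writeUpl(r2, tf)
  expect_equal(readUpl(tf), r2)
})

test_that("contact summary aggregates pairs by gap class", {
  seqs <- data.frame(residue_i = 1:5, resname_i = "ALA", atom_i = "HN",
                     residue_j = 2:6, resname_j = "ALA", atom_j = "HN",
                     upper_bound = 4)
  cs <- noeContactSummary(seqs)
  expect_true(all(cs$gap == 1L))
  expect_true(all(cs$category == "sequential"))

  expect_equal(nrow(noeContactSummary(seqs[0, ])), 0L)

  med <- data.frame(residue_i = c(1, 2, 1), resname_i = "ALA",
                    atom_i = "HA", residue_j = c(4, 5, 4),
                    resname_j = "ALA", atom_j = "HN", upper_bound = 5)
  cs2 <- noeContactSummary(med)
  expect_equal(cs2$n[cs2$i == 1 & cs2$j == 4], 2L)
  expect_true(all(cs2$category == "medium_range"))
})

test_that("planted helical segments are recovered from noisy tables", {
  ## 200 seeded replicates, sigma = 0.03 ppm: per-residue accuracy >= 95%
  acc <- numeric(200)
  for (k in seq_len(200)) {
    pep <- randomPeptide(20, seed = 1000 + k)
    start <- 3 + (k %% 8)
    seg <- c(start, start + 7)
    tab <- syntheticShiftTable(pep, helixSegments = list(seg),
                               noiseSd = 0.03, seed = 2000 + k)
    got <- csdData(classifyStructure(csdAlpha(tab)))$label
    truth <- ifelse(seq_len(20) %in% seg[1]:seg[2], "helical", "coil")
    acc[k] <- mean(got == truth)
  }
  expect_gte(mean(acc), 0.95)
})
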