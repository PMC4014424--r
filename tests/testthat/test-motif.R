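test_that("the grammar recognizes constructed DR/IR/ER elements", {
  ## direct repeat, spacer A
  dr1 <- findElements("AGGTCAAAGGTCA")
  expect_equal(dr1[, c("family", "spacer", "mismatches", "spacer_seq")],
               data.frame(family = "DR", spacer = 1L, mismatches = 0L,
                          spacer_seq = "A"))
  ## inverted repeat: h1 . N . rc(h2)
  ir1 <- findElements(paste0("AGGTCA", "T", "TGACCT"))
  expect_equal(ir1$family, "IR")
  expect_equal(ir1$spacer, 1L)
  expect_equal(ir1$mismatches, 0L)
  ## everted repeat: rc(h1) . N^6 . h2
  er6 <- findElements(paste0("TGACCT", "ACGTAC", "AGGTCA"))
  expect_equal(er6$family, "ER")
  expect_equal(er6$spacer, 6L)
  ## minus-strand DR appears as rc(h2) . N^n . rc(h1)
  drm <- findElements(paste0("TGTTCT", "GG", "TGACCT"))
  expect_true(any(drm$family == "DR" & drm$strand == "-" & drm$spacer == 2 &
                    drm$mismatches == 0))
  ## AGAACA is on equal footing by default but can be restricted
  m2 <- halfSiteModel(halves = c("AGGTCA", "AGTTCA"))
  expect_false(any(findElements(paste0("AGAACA", "AGAACA"), m2)$mismatches == 0))
})

test_that("N in a half-site never matches; sequences shorter than 12 error", {
  calls <- findElements(paste0("AGGTCN", "A", "AGGTCA"))
  expect_false(any(calls$start == 1 & calls$spacer == 1))
  expect_error(findElements("AGGTCA"), "shorter")
})

test_that("best element follows mismatch then DR < IR < ER then spacer order", {
  mk <- function(family, spacer, mm, start = 1, strand = "+")
    data.frame(family = family, spacer = spacer, strand = strand,
               start = start, mismatches = mm, spacer_seq = "",
               stringsAsFactors = FALSE)
  expect_equal(bestElement(rbind(mk("DR", 1, 0), mk("IR", 1, 1)))$label, "DR1")
  expect_equal(bestElement(rbind(mk("DR", 4, 1), mk("IR", 1, 1)))$label, "DR4")
  expect_equal(bestElement(rbind(mk("DR", 4, 1), mk("DR", 2, 1)))$label, "DR2")
  expect_equal(bestElement(mk("DR", 1, 0)[0, ])$label, "none")
  expect_equal(bestElement(NULL)$family, "none")
})

test_that("scanner matches the exhaustive brute-force oracle on random windows", {
  set.seed(101)
  for (i in 1:30) {
    s <- randomDna(250, gc = runif(1, 0.3, 0.6))
    got <- normalizeCalls(findElements(s))
    want <- normalizeCalls(oracleFindElements(s))
    expect_identical(got, want)
  }
  ## also under a nonstandard mismatch budget
  m <- halfSiteModel(maxMismatchPerHalf = 2L, maxTotalMismatch = 2L)
  for (i in 1:5) {
    s <- randomDna(150)
    expect_identical(normalizeCalls(findElements(s, m)),
                     normalizeCalls(oracleFindElements(s, perHalf = 2,
                                                       total = 2)))
  }
})

test_that("call multiset is reverse-complement invariant", {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  set.seed(33)
  for (i in 1:15) {
    s <- randomDna(200)
    a <- findElements(s)
    b <- findElements(rc(s))
    key <- function(df) sort(paste(df$family, df$spacer, df$mismatches))
    expect_identical(key(a), key(b))
  }
})

test_that("raising the mismatch budget never removes a call", {
  set.seed(55)
  for (i in 1:10) {
    s <- randomDna(200)
    tight <- findElements(s, halfSiteModel(maxTotalMismatch = 1L))
    loose <- findElements(s, halfSiteModel(maxTotalMismatch = 2L))
    k <- function(df) paste(df$family, df$spacer, df$strand, df$start)
    expect_true(all(k(tight) %in% k(loose)))
  }
})

test_that("windows are extracted at [center-125, center+125) with truncation", {
  genome <- DNAStringSet(c(chr1 = randomDna(3000), tiny = randomDna(300)))
  pk <- peaksAt("chr1", 1000)
  w <- extractWindow(pk, genome)
  expect_equal(width(w), 250)
  ## 1-based center 1000 (0-based 999): 0-based window [874, 1124) is
  ## 1-based [875, 1124]
  expect_equal(as.character(w[[1]]),
               as.character(subseq(genome[["chr1"]], 875, 1124)))
  ## 1-based center 51 on a 300-bp contig: truncated to 175 nt
  pkt <- peaksAt("tiny", 51, width = 40)
  expect_warning(wt <- extractWindow(pkt, genome), "truncated")
  expect_equal(width(wt), 175)
  expect_error(extractWindow(peaksAt("chrZ", 100), genome), "absent")
})

test_that("planted window motifs are recovered at the planted offset", {
  set.seed(77)
  sim <- simMotifWindows(30, c(DR1 = 0.4, IR1 = 0.3), width = 250)
  for (i in which(sim$truth$label != "none")) {
    calls <- findElements(sim$seqs[[i]])
    b <- bestElement(calls)
    expect_equal(b$label, sim$truth$label[i])
    expect_equal(b$mismatches, 0L)
    expect_equal(b$start, sim$truth$start[i])
  }
  ## scrubbed background windows contain nothing under the model budget
  for (i in which(sim$truth$label == "none"))
    expect_equal(nrow(findElements(sim$seqs[[i]])), 0L)
})

test_that("frequency tables are best-hit-exclusive and complete to 100", {
  best <- data.frame(label = c(rep("DR1", 29), rep("none", 71)))
  tab <- motifFrequencyTable(best)
  expect_equal(tab$percent[tab$motif == "DR1"], 29)
  expect_equal(sum(tab$percent), 100)
  allNone <- motifFrequencyTable(data.frame(label = rep("none", 5)))
  expect_equal(allNone$percent[allNone$motif == "none"], 100)
  expect_error(motifFrequencyTable(best[0, , drop = FALSE]), "empty")
})

test_that("stratum comparison gives z-tests with continuity handling", {
  tabA <- motifFrequencyTable(data.frame(label = c(rep("DR1", 72),
                                                   rep("none", 185))))
  ## identical tables: delta 0, p 1
  same <- compareStrata(tabA, tabA)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
  ## DR1 28% (72/257) vs 8% (39/490): strong depletion
  tabB <- motifFrequencyTable(data.frame(label = c(rep("DR1", 39),
                                                   rep("none", 451))))
  cmp <- compareStrata(tabA, tabB)
  expect_lt(cmp$delta[cmp$motif == "DR1"], 0)
  expect_lt(cmp$p_value[cmp$motif == "DR1"], 0.01)
  ## z agrees with the standard two-proportion test without correction
  pt <- stats::prop.test(c(72, 39), c(257, 490), correct = FALSE)
  expect_equal(cmp$z[cmp$motif == "DR1"]^2, unname(pt$statistic),
               tolerance = 1e-10)
  ## degenerate single-peak strata: finite outputs, no crash
  t1 <- motifFrequencyTable(data.frame(label = "DR1"))
  t2 <- motifFrequencyTable(data.frame(label = "none"))
  d <- compareStrata(t1, t2)
  expect_true(all(is.finite(d$z)))
})
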