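test_that("seeded bundles are bit-exact across runs, on disk too", {
  cfg <- simConfig(nChrom = 1L, chromLen = 7e5, nGenes = 8L, nPeaks = 24L)
  b1 <- simulateBundle(cfg, seed = 7)
  b2 <- simulateBundle(cfg, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(b1, d1); writeBundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 2e7),
                     readBin(file.path(d2, f), "raw", 2e7), label = f)
  ## a different seed changes the bundle
  b3 <- simulateBundle(cfg, seed = 8)
  expect_false(identical(as.character(genomeSeq(b1)[[1]]),
                         as.character(genomeSeq(b3)[[1]])))
})

test_that("bundle written to disk reads back equivalent", {
  b <- defaultBundle()
  d <- withr::local_tempdir()
  writeBundle(b, d)
  b2 <- readBundle(d)
  expect_identical(as.character(genomeSeq(b2)), as.character(genomeSeq(b)))
  expect_equal(start(peakSet(b2)), start(peakSet(b)))
  expect_equal(mcols(peakSet(b2))$enrichment, mcols(peakSet(b))$enrichment)
  expect_identical(as.list(mcols(geneModels(b2))$exons),
                   as.list(mcols(geneModels(b))$exons))
  expect_equal(exprTable(b2), exprTable(b))
  ## track equality on the covered positions (trailing zeros are implicit)
  for (ch in names(consTrack(b))) {
    n <- length(consTrack(b2)[[ch]])
    expect_equal(as.numeric(consTrack(b2)[[ch]]),
                 as.numeric(consTrack(b)[[ch]][seq_len(n)]))
  }
  expect_equal(truthManifest(b2)$peaks$class, truthManifest(b)$peaks$class)
})

test_that("planted region classes are recovered for every placed peak", {
  b <- defaultBundle()
  ann <- annotatePeaks(peakSet(b), geneModels(b))
  truth <- truthManifest(b)$peaks
  expect_identical(ann$region_class, truth$class)
  ## non-desert peaks are assigned to the planted gene at the planted distance
  sel <- truth$class != "gene_desert"
  expect_identical(ann$gene_id[sel], truth$gene_id[sel])
  expect_equal(ann$tss_distance[sel], as.numeric(truth$tss_distance[sel]))
  expect_lte(abs(sum(summarizeDistribution(ann)$percent) - 100), 1)
})

test_that("an all-promoter mixture closes the loop at 100% promoter", {
  mix <- c(promoter = 1, five_prime_distal_I = 0, five_prime_distal_II = 0,
           within_gene = 0, three_prime_proximal = 0,
           three_prime_distal_I = 0, three_prime_distal_II = 0,
           gene_desert = 0)
  b <- simulateBundle(simConfig(nChrom = 1L, chromLen = 7e5, nGenes = 8L,
                                nPeaks = 15L, classMix = mix), seed = 2)
  s <- summarizeDistribution(annotatePeaks(peakSet(b), geneModels(b)))
  expect_equal(s$percent[s$region_class == "promoter"], 100)
})

test_that("motif-free background yields no exact-consensus call", {
  b <- defaultBundle()
  truth <- truthManifest(b)$peaks
  none <- truth$motif == "none"
  wins <- extractWindow(peakSet(b)[none], genomeSeq(b))
  exact <- halfSiteModel(maxMismatchPerHalf = 0L, maxTotalMismatch = 0L)
  for (i in seq_along(wins))
    expect_equal(nrow(findElements(wins[[i]], exact)), 0L)
  ## under the default budget, any residual background call has >= 1 mismatch
  some <- sample(which(none), 20)
  for (i in some) {
    calls <- findElements(extractWindow(peakSet(b)[i], genomeSeq(b))[[1]])
    if (nrow(calls)) expect_true(all(calls$mismatches >= 1))
  }
})

test_that("planted motifs are recovered as each peak's best element", {
  b <- defaultBundle()
  truth <- truthManifest(b)$peaks
  planted <- which(truth$motif != "none")
  best <- scanPeaks(peakSet(b)[planted], genomeSeq(b))
  expect_identical(best$label, truth$motif[planted])
  expect_true(all(best$mismatches == 0))
})

test_that("truth verification passes untouched and localizes injected faults", {
  b <- defaultBundle()
  v <- verifyTruth(b)
  expect_equal(attr(v, "n_fail"), 0)
  ## corrupt a single base inside one planted motif -> exactly one failure
  truth <- truthManifest(b)$peaks
  i <- which(truth$motif != "none")[1]
  bBad <- b
  ch <- truth$chrom[i]
  at <- truth$motif_start[i]
  g <- genomeSeq(bBad)
  old <- as.character(subseq(g[[ch]], at, at))
  subseq(g[[ch]], at, at) <- DNAString(setdiff(c("A", "C", "G", "T"), old)[1])
  bBad@genome <- g
  vBad <- verifyTruth(bBad)
  expect_equal(attr(vBad, "n_fail"), 1)
  expect_equal(vBad$check[!vBad$pass], "motif_sequence")
  expect_equal(vBad$item[!vBad$pass], truth$peak_id[i])
  ## shuffled expression column -> only expression-truth failures
  bShuf <- b
  set.seed(1)
  e <- exprTable(bShuf)
  e$fpkm_sh1 <- sample(e$fpkm_sh1)
  bShuf@expr <- e
  vShuf <- verifyTruth(bShuf)
  fails <- vShuf[!vShuf$pass, ]
  expect_gt(nrow(fails), 0)
  expect_true(all(fails$check == "expression_de"))
})

test_that("infeasible placement errors name the class", {
  mix <- c(promoter = 0, five_prime_distal_I = 0, five_prime_distal_II = 0,
           within_gene = 0, three_prime_proximal = 0,
           three_prime_distal_I = 0, three_prime_distal_II = 0,
           gene_desert = 1)
  ## genes everywhere on a short chromosome: no desert point exists
  expect_error(
    simulateBundle(simConfig(nChrom = 1L, chromLen = 3e5, nGenes = 6L,
                             geneZone = c(0.02, 0.98), nPeaks = 4L,
                             geneGap = c(30000L, 40000L), classMix = mix),
                   seed = 3),
    "gene_desert")
})
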