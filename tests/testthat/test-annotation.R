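## A small two-gene landscape used in several blocks:
## gA: chr1 plus strand, [100001, 110000], 3 exons
## gB: chr1 minus strand, [400001, 408000], single exon
.annGenes <- function() {
  combineGR(
    geneGR("chr1", 100001, 110000, "+", "gA",
           exons = IRanges(c(100001, 103001, 108001),
                           c(100500, 103400, 110000))),
    geneGR("chr1", 400001, 408000, "-", "gB"))
}

test_that("signed TSS distance is strand-aware with upstream negative", {
  genes <- .annGenes()
  ## 500 bp genomically left of gA's TSS (plus strand) -> -500
  ## 500 bp genomically right of gB's TSS (minus strand) -> also -500
  pk <- peaksAt("chr1", c(100001 - 500, 408000 + 500))
  asg <- assignNearestGene(pk, genes)
  expect_equal(asg$gene_id, c("gA", "gB"))
  expect_equal(asg$tss_distance, c(-500, -500))
})

test_that("region classification follows the band taxonomy", {
  genes <- .annGenes()
  centers <- c(100001 - 500,    # promoter
               100001 - 5000,   # 5' distal I
               100001 - 50000,  # 5' distal II
               100001,          # d = 0 -> within_gene (promoter is strictly upstream)
               102000,          # intron 1 of gA
               110000 + 1500,   # 3' proximal
               110000 + 5000,   # 3' distal I (relative to gA TES)
               408000 + 150000) # would be 150 kb upstream of gB -> desert?
  pk <- peaksAt("chr1", centers)
  ann <- annotatePeaks(pk, genes)
  expect_equal(ann$region_class[1:7],
               c("promoter", "five_prime_distal_I", "five_prime_distal_II",
                 "within_gene", "within_gene", "three_prime_proximal",
                 "three_prime_distal_I"))
  expect_equal(ann$subfeature[4:5], c("exon 1", "intron 1"))
  ## >100 kb from both ends of the nearest gene -> gene desert
  expect_equal(ann$region_class[8], "gene_desert")
  ## chromosome without genes -> gene_desert, no gene id
  lone <- annotatePeaks(peaksAt("chr9", 5000), genes)
  expect_equal(lone$region_class, "gene_desert")
  expect_true(is.na(lone$gene_id))
})

test_that("proximal-promoter flag is a 1-kb window over promoter/within", {
  genes <- .annGenes()
  pk <- peaksAt("chr1", c(100001 - 800, 100001 - 1500, 100001 + 900,
                          100001 + 3000))
  ann <- annotatePeaks(pk, genes)
  expect_equal(ann$proximal_promoter, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("nearest-TSS ties resolve deterministically regardless of order", {
  gL <- geneGR("chr1", 1000, 3000, "+", "left")     # TSS 1000
  gR <- geneGR("chr1", 1600, 4000, "+", "right")    # TSS 1600
  pk <- peaksAt("chr1", 1300, width = 100)          # |d| = 300 to both
  a1 <- assignNearestGene(pk, combineGR(gL, gR))
  a2 <- assignNearestGene(pk, combineGR(gR, gL))
  expect_identical(a1$gene_id, a2$gene_id)
  ## tie-break: smaller |TES distance| (gL TES 3000 at 1700, gR TES 4000 at 2700)
  expect_equal(a1$gene_id, "left")
})

test_that("assignment matches the exhaustive quadratic oracle", {
  set.seed(7)
  for (rep in 1:5) {
    ng <- sample(5:20, 1)
    genes <- do.call(combineGR, lapply(seq_len(ng), function(i) {
      s <- sample.int(5e5, 1)
      geneGR(sample(c("chr1", "chr2"), 1), s, s + sample(500:20000, 1),
             sample(c("+", "-"), 1), sprintf("g%02d", i))
    }))
    pk <- peaksAt(sample(c("chr1", "chr2"), 200, replace = TRUE),
                  sample.int(6e5, 200) + 1000)
    got <- assignNearestGene(pk, genes)$gene_id
    expect_identical(got, oracleNearestGene(pk, genes))
  }
})

test_that("subfeature mapping counts 5'->3' in the gene's orientation", {
  ## 3-exon minus-strand gene: the genomically last exon is exon 1
  g <- geneGR("chr1", 1001, 9000, "-", "gm",
              exons = IRanges(c(1001, 4001, 8001), c(1400, 4400, 9000)))
  sub <- mapSubfeature(c(8500, 4200, 1200, 6000, 2000), g)
  expect_equal(sub$label,
               c("exon 1", "exon 2", "exon 3", "intron 1", "intron 2"))
  ## brute-force walk over a 3-exon plus-strand gene
  gp <- geneGR("chr1", 1001, 9000, "+", "gp",
               exons = IRanges(c(1001, 4001, 8001), c(1400, 4400, 9000)))
  walk <- function(p) {
    ex <- mcols(gp)$exons[[1]]
    for (k in seq_along(ex)) {
      if (p >= start(ex)[k] && p <= end(ex)[k]) return(paste("exon", k))
      if (k < length(ex) && p > end(ex)[k] && p < start(ex)[k + 1])
        return(paste("intron", k))
    }
    stop("off gene")
  }
  pos <- c(1001, 1400, 1401, 4000, 4001, 5000, 8001, 9000)
  expect_equal(mapSubfeature(pos, gp)$label, vapply(pos, walk, ""))
  ## single-exon gene: any internal position is exon 1
  g1 <- geneGR("chr1", 100, 900, "+", "g1")
  expect_equal(unique(mapSubfeature(c(100, 500, 900), g1)$label), "exon 1")
  expect_error(mapSubfeature(99, g1), "outside")
})

test_that("distribution summary rounds half away and sums to ~100", {
  genes <- .annGenes()
  pk <- peaksAt("chr1", rep(100001 - 500, 7))      # all promoter
  ann <- annotatePeaks(pk, genes)
  s <- summarizeDistribution(ann)
  expect_equal(s$percent[s$region_class == "promoter"], 100)
  expect_error(summarizeDistribution(ann[0, ]), "empty")
  ## mixed classes: percents sum to 100 +/- 1
  ann2 <- annotatePeaks(peaksAt("chr1", c(rep(99501, 3), 102000,
                                          100001 - 5000, 100001 - 50000,
                                          110000 + 1500)), genes)
  expect_lte(abs(sum(summarizeDistribution(ann2)$percent) - 100), 1)
})

test_that("TSS histogram bins 15-bp left-closed and is flat under uniform truth", {
  genes <- geneGR("chr1", 1e6, 1e6 + 1e4, "+", "g")
  ## peak at d = 0 increments the bin containing 0
  ann0 <- annotatePeaks(peaksAt("chr1", 1e6), genes)
  h0 <- tssHistogram(ann0)
  expect_equal(sum(h0$count), 1)
  hit <- h0[h0$count == 1, ]
  expect_true(hit$bin_start <= 0 && 0 < hit$bin_end)
  ## no proximal peaks -> all zero
  hN <- tssHistogram(annotatePeaks(peaksAt("chr1", 1e6 - 5000), genes))
  expect_true(all(hN$count == 0))
  ## uniform planted distances -> chi-square not rejected at alpha = 0.01
  set.seed(11)
  d <- sample(-1000:1000, 1500, replace = TRUE)
  ann <- annotatePeaks(peaksAt("chr1", 1e6 + d), genes)
  ann <- ann[ann$proximal_promoter, ]
  h <- tssHistogram(ann)
  full <- h$bin_end <= 1000            # last bin covers [995, 1010): shorter support
  expect_equal(sum(h$count), nrow(ann))
  p <- suppressWarnings(stats::chisq.test(h$count[full])$p.value)
  expect_gt(p, 0.01)
})

test_that("distal histograms bin by 10 kb / 100 kb with planted decay recovered", {
  genes <- geneGR("chr1", 2e6, 2e6 + 1e4, "+", "g")
  ## d = -15 kb falls in the [10, 20) kb 5' distal II bin
  ann <- annotatePeaks(peaksAt("chr1", 2e6 - 15000), genes)
  h <- distalHistogram(ann)
  h5 <- h[h$category == "five_prime_distal_II", ]
  expect_equal(h5$count[h5$bin_start == 10000], 1)
  expect_equal(sum(h$count), 1)
  ## empty distal set -> all zeros
  h0 <- distalHistogram(annotatePeaks(peaksAt("chr1", 2e6 - 100), genes))
  expect_true(all(h0$count == 0))
  ## monotone-decaying planted distances -> monotone bin counts
  dists <- rep(seq(15000, 95000, by = 10000), times = 9:1)
  annD <- annotatePeaks(peaksAt("chr1", 2e6 - dists), genes)
  hD <- distalHistogram(annD)
  cnt <- hD$count[hD$category == "five_prime_distal_II"]
  expect_equal(cnt, 9:1)
})

test_that("distance-band summaries give five-number stats and flag missing genes", {
  genes <- .annGenes()
  pk <- peaksAt("chr1", rep(100001 - 500, 4), enrichment = 3.5)
  ann <- annotatePeaks(pk, genes)
  expr <- data.frame(gene_id = "gA", fpkm_control = 8,
                     fpkm_sh1 = 8, fpkm_sh2 = 8)
  s <- summarizeByDistance(ann, pk, expr)
  expect_equal(s$enr_median[s$n > 0], 3.5)
  expect_equal(s$fpkm_median[s$n > 0], 8)
  expect_true(all(is.na(s$enr_median[s$n == 0])))
  ## assigned gene missing from the expression table is excluded + counted
  expr2 <- data.frame(gene_id = "other", fpkm_control = 1,
                      fpkm_sh1 = 1, fpkm_sh2 = 1)
  expect_message(s2 <- summarizeByDistance(ann, pk, expr2), "without expression")
  expect_equal(attr(s2, "n_missing_expression"), 4)
})

test_that("classification is invariant under genome mirroring", {
  ## mirror: pos -> L - pos + 1, strands flipped; every region class must
  ## be preserved (strand antisymmetry of the taxonomy)
  L <- 1e6
  genes <- combineGR(
    geneGR("chr1", 200001, 210000, "+", "g1",
           exons = IRanges(c(200001, 206001), c(201000, 210000))),
    geneGR("chr1", 500001, 502000, "-", "g2"))
  mirrorGenes <- combineGR(
    geneGR("chr1", L - 210000 + 1, L - 200001 + 1, "-", "g1",
           exons = IRanges(L - c(210000, 201000) + 1,
                           L - c(206001, 200001) + 1)),
    geneGR("chr1", L - 502000 + 1, L - 500001 + 1, "+", "g2"))
  set.seed(3)
  centers <- sample.int(L - 2000, 300) + 1000
  pk <- peaksAt("chr1", centers, width = 251)        # odd width: exact mirror
  pkM <- peaksAt("chr1", L - centers + 1, width = 251)
  a <- annotatePeaks(pk, genes)
  m <- annotatePeaks(pkM, mirrorGenes)
  expect_identical(m$region_class, a$region_class)
  expect_identical(m$tss_distance, a$tss_distance)
  expect_identical(m$subfeature, a$subfeature)
})
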