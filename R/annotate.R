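## Nearest-TSS assignment and the promoter/distal/gene-desert taxonomy.
##
## A peak is assigned to the gene whose TSS is closest to the peak center
## (unsigned distance), then classified relative to that gene:
##   within_gene          center between TSS and TES (inclusive; d = 0 is
##                        within_gene: the promoter band starts 1 bp upstream)
##   promoter             d in [-2000, -1]
##   five_prime_distal_I  d in (-10000, -2000)      (open edges)
##   five_prime_distal_II d in [-100000, -10000]
##   three_prime_*        mirrored bands on the signed TES distance
##   gene_desert          min(|d_TSS|, |d_TES|) > 100000, or no gene on the
##                        chromosome
## where d is the signed center-to-TSS distance in the gene's orientation
## (negative = upstream). Band edges are chosen so the bands tile the
## integers exactly. Ties on |d| break by smaller |TES distance|, then
## lexicographic gene_id, so assignment is deterministic and
## data-order-independent.

#' Assign each peak to the gene with the nearest TSS
#'
#' @param peaks a `GRanges` of peaks (see [readPeaks()]).
#' @param genes a `GRanges` of gene models (see [readGeneModels()]).
#' @return a `data.frame` with one row per peak: `peak_id`, `gene_id`
#'   (`NA` when the peak's chromosome has no gene), `tss_distance` and
#'   `tes_distance` (signed, gene orientation, negative = upstream).
#' @export
assignNearestGene <- function(peaks, genes) {
  n <- length(peaks)
  centers <- peakCenter(peaks)
  pchrom <- as.character(seqnames(peaks))
  gchrom <- as.character(seqnames(genes))
  gid <- mcols(genes)$gene_id
  out <- data.frame(peak_id = mcols(peaks)$peak_id,
                    gene_id = rep(NA_character_, n),
                    tss_distance = rep(NA_real_, n),
                    tes_distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (ch in unique(pchrom)) {
    pi <- which(pchrom == ch)
    gi <- which(gchrom == ch)
    if (!length(gi)) next
    g <- genes[gi]
    tss <- .tssPos(g)
    ## sorted-TSS search: candidates are the flanking TSSs by findInterval,
    ## then every gene achieving the minimal unsigned distance enters the
    ## tie-break (smaller |TES distance|, then gene_id).
    o <- order(tss)
    tssS <- tss[o]
    for (p in pi) {
      ctr <- centers[p]
      k <- findInterval(ctr, tssS)
      dmin <- min(abs(ctr - tssS[pmax(pmin(c(k, k + 1L), length(tssS)), 1L)]))
      cand <- which(abs(tss - ctr) == dmin)
      if (length(cand) > 1L) {
        dte <- abs(.signedTesDist(ctr, g[cand]))
        cand <- cand[order(dte, gid[gi][cand])]
      }
      w <- cand[1L]
      out$gene_id[p] <- gid[gi][w]
      out$tss_distance[p] <- .signedTssDist(ctr, g[w])
      out$tes_distance[p] <- .signedTesDist(ctr, g[w])
    }
  }
  out
}

#' Classify signed TSS/TES distances into the region taxonomy
#'
#' Total, vectorized classifier over signed distances (gene orientation,
#' negative = upstream of the site). `NA` distances (no gene on the
#' chromosome) classify as `gene_desert`.
#'
#' @param tss_distance signed center-to-TSS distances.
#' @param tes_distance signed center-to-TES distances.
#' @return character vector of region classes (see `REGION_CLASSES`).
#' @export
classifyRegion <- function(tss_distance, tes_distance) {
  d <- tss_distance; e <- tes_distance
  cls <- rep("gene_desert", length(d))
  within <- !is.na(d) & d >= 0 & e <= 0
  up <- !is.na(d) & d < 0
  down <- !is.na(d) & e > 0
  ad <- abs(d)
  cls[within] <- "within_gene"
  cls[up & ad <= 2000] <- "promoter"
  cls[up & ad > 2000 & ad < 10000] <- "five_prime_distal_I"
  cls[up & ad >= 10000 & ad <= 100000] <- "five_prime_distal_II"
  cls[down & e <= 2000] <- "three_prime_proximal"
  cls[down & e > 2000 & e < 10000] <- "three_prime_distal_I"
  cls[down & e >= 10000 & e <= 100000] <- "three_prime_distal_II"
  cls
}

#' Map a within-gene position onto exon/intron structure
#'
#' Exons and introns are numbered 1-based, 5' to 3' in the gene's
#' orientation (the genomically last exon of a minus-strand gene is exon 1).
#'
#' @param centers integer positions inside the gene body.
#' @param gene a single-element `GRanges` gene model.
#' @return a `data.frame` with columns `type` (`"exon"`/`"intron"`),
#'   `index`, and `label` (e.g. `"intron 2"`).
#' @export
mapSubfeature <- function(centers, gene) {
  stopifnot(length(gene) == 1L)
  ex <- mcols(gene)$exons[[1L]]
  nE <- length(ex)
  minus <- as.character(strand(gene)) == "-"
  if (any(centers < start(gene) | centers > end(gene)))
    .stopf("mapSubfeature: position outside the gene body")
  type <- character(length(centers)); idx <- integer(length(centers))
  for (i in seq_along(centers)) {
    p <- centers[i]
    j <- findInterval(p, start(ex))          # genomic exon index at or before p
    if (j >= 1L && p <= end(ex)[j]) {
      type[i] <- "exon"
      idx[i] <- if (minus) nE - j + 1L else j
    } else {
      ## p lies between genomic exon j and j+1 (transcript bounds guarantee
      ## j >= 1 for within-gene positions off an exon)
      type[i] <- "intron"
      idx[i] <- if (minus) nE - j else j
    }
  }
  data.frame(type = type, index = idx, label = paste(type, idx),
             stringsAsFactors = FALSE)
}

#' Annotate peaks: nearest gene, region class, subfeature, proximal flag
#'
#' The workhorse wrapper: assigns each peak to its nearest-TSS gene,
#' classifies the region, maps within-gene peaks onto exons/introns, and
#' flags proximal-promoter peaks (center within 1 kb of the TSS).
#'
#' @inheritParams assignNearestGene
#' @param proximalWindow half-width (bp) of the proximal-promoter flag
#'   (default 1000).
#' @return a `data.frame` with one row per peak: `peak_id`, `chrom`,
#'   `center`, `gene_id`, `tss_distance`, `tes_distance`, `region_class`,
#'   `subfeature` (`"exon k"`/`"intron k"` for within-gene peaks, else
#'   `NA`), `proximal_promoter` (logical).
#' @export
annotatePeaks <- function(peaks, genes, proximalWindow = 1000) {
  ann <- assignNearestGene(peaks, genes)
  ann$chrom <- as.character(seqnames(peaks))
  ann$center <- peakCenter(peaks)
  ann$region_class <- classifyRegion(ann$tss_distance, ann$tes_distance)
  ann$subfeature <- NA_character_
  wg <- which(ann$region_class == "within_gene")
  if (length(wg)) {
    gid <- mcols(genes)$gene_id
    for (g in unique(ann$gene_id[wg])) {
      rows <- wg[ann$gene_id[wg] == g]
      sub <- mapSubfeature(ann$center[rows], genes[match(g, gid)])
      ann$subfeature[rows] <- sub$label
    }
  }
  ann$proximal_promoter <- !is.na(ann$tss_distance) &
    abs(ann$tss_distance) <= proximalWindow &
    ann$region_class %in% c("promoter", "within_gene")
  ann[, c("peak_id", "chrom", "center", "gene_id", "tss_distance",
          "tes_distance", "region_class", "subfeature", "proximal_promoter")]
}

#' Per-class counts and percentages of a peak annotation
#'
#' Percentages are integer, rounded half away from zero, so they sum to
#' 100 +/- 1. The proximal-promoter fraction (a flag orthogonal to the
#' region classes: the promoter band is 2 kb, the proximal flag 1 kb) is
#' attached as attribute `"proximal_promoter"`.
#'
#' @param ann annotation `data.frame` from [annotatePeaks()].
#' @return a `data.frame` with columns `region_class`, `count`, `percent`.
#' @export
summarizeDistribution <- function(ann) {
  if (!nrow(ann)) .stopf("summarizeDistribution: empty annotation")
  total <- nrow(ann)
  cnt <- vapply(REGION_CLASSES, function(cl) sum(ann$region_class == cl), 0L)
  out <- data.frame(region_class = REGION_CLASSES, count = as.integer(cnt),
                    percent = .pct(cnt, total), stringsAsFactors = FALSE,
                    row.names = NULL)
  npp <- sum(ann$proximal_promoter)
  attr(out, "proximal_promoter") <-
    list(count = npp, percent = .pct(npp, total), total = total)
  out
}

#' Histogram of proximal-promoter peak positions around the TSS
#'
#' Bins the signed TSS distances of proximal-promoter peaks into
#' left-closed bins covering `[-window, +window]`.
#'
#' @param ann annotation `data.frame` from [annotatePeaks()].
#' @param window half-width in bp (default 1000).
#' @param bin bin width in bp (default 15).
#' @return a `data.frame` with `bin_start`, `bin_end` (left-closed,
#'   right-open, in signed distance units) and `count`; counts sum to the
#'   number of proximal-promoter peaks.
#' @export
tssHistogram <- function(ann, window = 1000, bin = 15) {
  nb <- ceiling((2 * window + 1) / bin)
  starts <- -window + bin * (seq_len(nb) - 1L)
  d <- ann$tss_distance[ann$proximal_promoter]
  idx <- floor((d + window) / bin) + 1L
  cnt <- tabulate(idx, nbins = nb)
  data.frame(bin_start = starts, bin_end = starts + bin, count = cnt)
}

#' Histograms of distal peak distances
#'
#' Bins the 5' distal II and 3' distal II peaks by distance to the
#' TSS/TES (10 kb bins over 10--100 kb) and gene-desert peaks by their
#' distance to the nearest gene end (100 kb bins).
#'
#' @param ann annotation `data.frame` from [annotatePeaks()].
#' @param binDistal bin width for the distal II bands (default 10000).
#' @param binDesert bin width for gene deserts (default 1e5).
#' @return a `data.frame` with `category`, `bin_start`, `bin_end`, `count`
#'   (distances unsigned, bins left-closed).
#' @export
distalHistogram <- function(ann, binDistal = 10000, binDesert = 1e5) {
  out <- list()
  five <- abs(ann$tss_distance[ann$region_class == "five_prime_distal_II"])
  three <- abs(ann$tes_distance[ann$region_class == "three_prime_distal_II"])
  dmin <- pmin(abs(ann$tss_distance), abs(ann$tes_distance))
  desert <- dmin[ann$region_class == "gene_desert" & !is.na(dmin)]
  mk <- function(x, lo, hi, bw, cat) {
    nb <- ceiling((hi - lo) / bw)
    starts <- lo + bw * (seq_len(nb) - 1L)
    cnt <- tabulate(pmin(floor((x - lo) / bw) + 1L, nb), nbins = nb)
    data.frame(category = cat, bin_start = starts, bin_end = starts + bw,
               count = cnt, stringsAsFactors = FALSE)
  }
  hi <- max(c(desert, 2e5))
  rbind(mk(five, 1e4, 1e5, binDistal, "five_prime_distal_II"),
        mk(three, 1e4, 1e5, binDistal, "three_prime_distal_II"),
        mk(desert, 1e5, hi, binDesert, "gene_desert"))
}

#' Five-number summaries of enrichment and expression by TSS distance
#'
#' Groups peaks into unsigned TSS-distance bands and summarizes peak
#' enrichment and the assigned gene's control FPKM per band.
#'
#' @param ann annotation `data.frame` from [annotatePeaks()].
#' @param peaks the `GRanges` the annotation was computed from.
#' @param expr expression `data.frame` (see [readExpression()]).
#' @param breaks band edges on `|tss_distance|` in bp.
#' @return a `data.frame`, one row per band, with `n`, enrichment
#'   five-number columns and FPKM five-number columns (`NA` for empty
#'   bands). Peaks whose assigned gene has no expression row are excluded
#'   from the FPKM summaries; the excluded count is attribute
#'   `"n_missing_expression"` (also reported via `message()`).
#' @export
summarizeByDistance <- function(ann, peaks, expr,
                                breaks = c(0, 1000, 2000, 10000, 1e5, Inf)) {
  stopifnot(nrow(ann) == length(peaks))
  ad <- abs(ann$tss_distance)
  band <- cut(ad, breaks = breaks, include.lowest = TRUE, right = TRUE)
  enr <- mcols(peaks)$enrichment
  fpkm <- expr$fpkm_control[match(ann$gene_id, expr$gene_id)]
  nmiss <- sum(!is.na(ann$gene_id) & is.na(fpkm))
  if (nmiss) message(nmiss, " peak(s) assigned to genes without expression rows")
  f5 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) rep(NA_real_, 5L) else fivenum(x)
  }
  rows <- lapply(levels(band), function(b) {
    i <- which(!is.na(band) & band == b)
    e <- f5(enr[i]); f <- f5(fpkm[i])
    data.frame(band = b, n = length(i),
               enr_min = e[1], enr_q1 = e[2], enr_median = e[3],
               enr_q3 = e[4], enr_max = e[5],
               fpkm_min = f[1], fpkm_q1 = f[2], fpkm_median = f[3],
               fpkm_q3 = f[4], fpkm_max = f[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_missing_expression") <- nmiss
  out
}
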