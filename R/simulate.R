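## Seeded synthetic-data generator.
##
## Generates a complete ground-truthed input bundle: genome FASTA, gene
## models, peaks placed so a planted region class holds under the band
## definitions, a conservation track with Gaussian bumps at peak centers,
## an expression table with planted knockdown responses, and enhancer-mark
## intervals overlapping a configured fraction of distal peaks. Background
## sequence is rejection-scrubbed so no repeat element at 0 mismatches
## occurs outside planted positions. Everything funnels through one seeded
## RNG, so a given (config, seed) pair reproduces the bundle bit-exactly.

#' Simulation configuration
#'
#' All knobs of [simulateBundle()], with defaults emulating the observed
#' early-differentiation study condition: a class mixture putting 45% of
#' peaks in the promoter + gene body and 48% more than 10 kb from genes,
#' motif plant rates of DR1 0.28 / DR4 0.03 / ER6 0.03 / IR1 0.08
#' proximally versus 0.08 / 0.16 / 0.11 / 0.16 distally, an 80:20
#' induced:repressed split of planted knockdown responses with ~76%
#' concordance between the two shRNAs, and per-mark distal overlap
#' fractions of 0.06 / 0.07 / 0.12 / 0.34.
#'
#' @param nChrom,chromLen number and length (bp) of chromosomes.
#' @param gcContent background GC fraction.
#' @param nGenes total gene models (split evenly across chromosomes).
#' @param exonCount,exonLen,intronLen ranges (min, max) for exon count and
#'   exon/intron lengths.
#' @param geneZone fraction interval of each chromosome where genes are
#'   placed; the remainder stays empty so gene deserts exist.
#' @param geneGap range of intergenic gaps (bp).
#' @param nPeaks number of peaks.
#' @param classMix named fractions over the eight region classes (sums
#'   to 1).
#' @param withinTssBias fraction of within-gene peaks placed within 1 kb
#'   of the TSS (drives the proximal-promoter fraction).
#' @param peakWidth peak width range (bp).
#' @param enrichBase,enrichAmp,enrichScale,enrichNoiseSd enrichment decays
#'   with TSS distance: `(base + amp * exp(-|d|/scale)) * lognormal(sd)`.
#' @param motifRates named list (`proximal`, `distal`, `other`) of named
#'   plant rates per motif label; the remainder of each stratum is planted
#'   motif-free.
#' @param consBumpHeight named bump heights per stratum; `consBumpSd`
#'   Gaussian sd (bp); `consBumpHalfWidth` track half-width around each
#'   center; `consNoise` uniform per-base noise amplitude.
#' @param exprMeanlog,exprSdlog log-normal FPKM distribution.
#' @param deFracCommon,deFracUnique fractions of genes planted responsive
#'   to both shRNAs / to a single shRNA.
#' @param plantedFc,fcNoiseSdlog,inducedFrac,nonDeFcRange planted fold
#'   change (multiplicative log-normal noise, sdlog), fraction induced
#'   after knockdown, and the fold-change range of non-responsive genes.
#' @param markOverlap named per-mark fractions of distal peaks whose
#'   +/- 2 kb flank a mark interval must overlap.
#' @param markWidth,nBackgroundMarks mark interval width and number of
#'   away-from-peak background intervals per mark.
#' @return a `SimulationConfig` (validated list).
#' @export
simConfig <- function(nChrom = 3L, chromLen = 2e6, gcContent = 0.41,
                      nGenes = 60L,
                      exonCount = c(2L, 8L), exonLen = c(100L, 400L),
                      intronLen = c(200L, 2000L),
                      geneZone = c(0.03, 0.55), geneGap = c(25000L, 45000L),
                      nPeaks = 180L,
                      classMix = c(promoter = 0.13,
                                   five_prime_distal_I = 0.04,
                                   five_prime_distal_II = 0.18,
                                   within_gene = 0.32,
                                   three_prime_proximal = 0.02,
                                   three_prime_distal_I = 0.01,
                                   three_prime_distal_II = 0.10,
                                   gene_desert = 0.20),
                      withinTssBias = 0.6,
                      peakWidth = c(300L, 600L),
                      enrichBase = 5, enrichAmp = 45, enrichScale = 20000,
                      enrichNoiseSd = 0.3,
                      motifRates = list(
                        proximal = c(DR1 = 0.28, DR4 = 0.03, ER6 = 0.03,
                                     IR1 = 0.08),
                        distal = c(DR1 = 0.08, DR4 = 0.16, ER6 = 0.11,
                                   IR1 = 0.16),
                        other = c(DR1 = 0.12, DR4 = 0.05, ER6 = 0.03,
                                  IR1 = 0.09)),
                      consBumpHeight = c(proximal = 0.5, distal = 0.35,
                                         other = 0.42),
                      consBumpSd = 60, consBumpHalfWidth = 300,
                      consNoise = 0.02,
                      exprMeanlog = 0, exprSdlog = 1.5,
                      deFracCommon = 0.15, deFracUnique = 0.045,
                      plantedFc = 4, fcNoiseSdlog = 0.1, inducedFrac = 0.8,
                      nonDeFcRange = c(1 / 1.2, 1.2),
                      markOverlap = c(P300 = 0.06, H3K27ac = 0.07,
                                      H3K4me1 = 0.12, H3K27me3 = 0.34),
                      markWidth = 500L, nBackgroundMarks = 8L) {
  cfg <- as.list(environment())
  if (abs(sum(classMix) - 1) > 1e-6) .stopf("classMix must sum to 1")
  if (!all(names(classMix) %in% REGION_CLASSES))
    .stopf("unknown region class in classMix")
  rateSums <- vapply(motifRates, sum, 0)
  if (any(unlist(motifRates) < 0) || any(rateSums > 1))
    .stopf("motif plant rates must be in [0,1] and sum to <= 1 per stratum")
  if (any(markOverlap < 0 | markOverlap > 1))
    .stopf("mark overlap fractions must be in [0,1]")
  if (chromLen <= 0 || nGenes <= 0 || nPeaks <= 0)
    .stopf("lengths and counts must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.randChars <- function(len, gc) {
  sample(.BASES, len, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else
  sample(rng[1]:rng[2], 1L)

## ---- genes -----------------------------------------------------------

.simGenes <- function(cfg) {
  perChrom <- rep(ceiling(cfg$nGenes / cfg$nChrom), cfg$nChrom)
  perChrom[cfg$nChrom] <- cfg$nGenes - sum(perChrom[-cfg$nChrom])
  rows <- list()
  for (c in seq_len(cfg$nChrom)) {
    ch <- paste0("chr", c)
    pos <- as.integer(cfg$geneZone[1] * cfg$chromLen)
    zoneEnd <- as.integer(cfg$geneZone[2] * cfg$chromLen)
    for (i in seq_len(perChrom[c])) {
      nEx <- .rint(cfg$exonCount)
      exL <- vapply(seq_len(nEx), function(k) .rint(cfg$exonLen), 0L)
      inL <- if (nEx > 1L)
        vapply(seq_len(nEx - 1L), function(k) .rint(cfg$intronLen), 0L)
      else integer(0)
      starts <- pos + c(0L, cumsum(exL[-nEx] + inL))
      ends <- starts + exL - 1L
      txEnd <- ends[nEx]
      if (txEnd > zoneEnd)
        .stopf("gene placement exceeds the gene zone on %s; enlarge chromLen or geneZone", ch)
      rows[[length(rows) + 1L]] <- list(
        chrom = ch, start = pos, end = txEnd,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("g%02d_%03d", c, i),
        exons = IRanges(starts, ends))
      pos <- txEnd + .rint(cfg$geneGap)
    }
  }
  gr <- GRanges(vapply(rows, `[[`, "", "chrom"),
                IRanges(vapply(rows, `[[`, 0L, "start"),
                        vapply(rows, `[[`, 0L, "end")),
                strand = vapply(rows, `[[`, "", "strand"))
  mcols(gr)$gene_id <- vapply(rows, `[[`, "", "gene_id")
  mcols(gr)$exons <- IRangesList(lapply(rows, `[[`, "exons"))
  gr
}

## ---- peak placement --------------------------------------------------

.classCounts <- function(mix, n) {
  raw <- mix * n
  cnt <- floor(raw)
  extra <- n - sum(cnt)
  if (extra > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(extra)]] <- cnt[o[seq_len(extra)]] + 1L
  }
  as.integer(cnt)
}

## Interior sampling ranges per class band (>= 1 bp inside every edge).
.sampleBandDistance <- function(class, geneLen, cfg) {
  switch(class,
    promoter = -.rint(c(2L, 1999L)),
    five_prime_distal_I = -.rint(c(2002L, 9998L)),
    five_prime_distal_II = -.rint(c(10001L, 99999L)),
    within_gene = {
      if (runif(1) < cfg$withinTssBias)
        .rint(c(0L, min(1000L, geneLen - 1L)))
      else .rint(c(0L, geneLen - 1L))
    },
    three_prime_proximal = .rint(c(2L, 1999L)),
    three_prime_distal_I = .rint(c(2002L, 9998L)),
    three_prime_distal_II = .rint(c(10001L, 99999L)))
}

.placePeaks <- function(cfg, genes) {
  classes <- rep(names(cfg$classMix), .classCounts(cfg$classMix, cfg$nPeaks))
  gchrom <- as.character(seqnames(genes))
  tss <- .tssPos(genes)
  tes <- .tesPos(genes)
  minus <- as.character(strand(genes)) == "-"
  glen <- width(genes)
  distalClasses <- c("five_prime_distal_II", "three_prime_distal_II",
                     "gene_desert")
  placedCtr <- lapply(seq_len(cfg$nChrom), function(i) integer(0))
  placedDist <- lapply(seq_len(cfg$nChrom), function(i) logical(0))
  names(placedCtr) <- names(placedDist) <- paste0("chr", seq_len(cfg$nChrom))
  margin <- 2501L   # keeps every window and +/-2 kb flank on-chromosome
  rows <- list()
  for (cl in classes) {
    isDistal <- cl %in% distalClasses
    done <- FALSE
    for (try in seq_len(5000L)) {
      if (cl == "gene_desert") {
        ch <- paste0("chr", sample.int(cfg$nChrom, 1L))
        pos <- sample.int(cfg$chromLen - 2L * margin, 1L) + margin
        gi <- which(gchrom == ch)
        dmin <- min(abs(pos - tss[gi]), abs(pos - tes[gi]))
        if (dmin <= 100001L) next
        gene <- NA_character_; d <- NA_integer_
      } else {
        w <- sample.int(length(genes), 1L)
        ch <- gchrom[w]
        geneBased3 <- cl %in% c("three_prime_proximal", "three_prime_distal_I",
                                "three_prime_distal_II")
        b <- .sampleBandDistance(cl, glen[w], cfg)
        pos <- if (geneBased3) {
          if (minus[w]) tes[w] - b else tes[w] + b
        } else {
          if (minus[w]) tss[w] - b else tss[w] + b
        }
        if (pos < margin || pos > cfg$chromLen - margin) next
        gi <- which(gchrom == ch)
        idx <- match(w, gi)
        dAll <- abs(pos - tss[gi])
        if (dAll[idx] > min(c(dAll[-idx], Inf)) - 1L) next
        gene <- mcols(genes)$gene_id[w]
        d <- if (minus[w]) tss[w] - pos else pos - tss[w]
      }
      ## distal-distal pairs stay >= 12 kb apart so a planted mark interval
      ## can never leak into a neighboring distal flank; any pair >= 700 bp
      ## so 250/500-bp windows never overlap.
      sep <- abs(placedCtr[[ch]] - pos)
      need <- ifelse(isDistal & placedDist[[ch]], 12000L, 700L)
      if (length(sep) && any(sep < need)) next
      placedCtr[[ch]] <- c(placedCtr[[ch]], pos)
      placedDist[[ch]] <- c(placedDist[[ch]], isDistal)
      rows[[length(rows) + 1L]] <- list(chrom = ch, center = pos, class = cl,
                                        gene_id = gene, d = d)
      done <- TRUE
      break
    }
    if (!done)
      .stopf("could not place a peak in class band '%s'; the band may be too small for the requested peaks", cl)
  }
  rows
}

## ---- background scrub ------------------------------------------------

## Exact hexamer hits against the half-site sets via a rolling base-4
## code; genome-scale, so the mismatch-tolerant scorer is not used here.
.exactHalfHits <- function(chars, halves, rcHalves) {
  ci <- match(chars, .BASES) - 1L
  n <- length(chars) - 5L
  if (n < 1L) return(list(fwd = logical(0), rc = logical(0)))
  hasN <- anyNA(ci)
  if (hasN) {
    bad <- is.na(ci)
    ci[bad] <- 0L
  }
  code <- numeric(n)
  nbad <- if (hasN) integer(n) else NULL
  for (k in 1:6) {
    code <- code * 4 + ci[k:(n + k - 1L)]
    if (hasN) nbad <- nbad + bad[k:(n + k - 1L)]
  }
  hcode <- function(h) {
    v <- match(strsplit(h, "")[[1]], .BASES) - 1L
    sum(v * 4^(5:0))
  }
  fwd <- code %in% vapply(halves, hcode, 0)
  rc <- code %in% vapply(rcHalves, hcode, 0)
  if (hasN) {
    fwd <- fwd & nbad == 0L
    rc <- rc & nbad == 0L
  }
  list(fwd = fwd, rc = rc)
}

## Remove every exact-consensus half-site hexamer (forward or reverse
## complement) from a chromosome's character vector by mutating one base.
## This is deliberately stronger than removing complete repeat elements:
## a surviving lone exact half-site could later pair with a planted exact
## half across a 0--8 nt gap and spoof a 0-mismatch element, so planted
## motifs must be the only source of exact half-sites. Mutations can
## create new exact hexamers, but only locally, so after one full scan
## only small neighborhoods of mutated bases are rescanned.
.scrubChrom <- function(chars, model) {
  L <- length(chars)
  hitStarts <- function(x) {
    h <- .exactHalfHits(x, model$halves, model$rcHalves)
    which(h$fwd | h$rc)
  }
  offend <- hitStarts(chars)
  while (length(offend)) {
    mutated <- integer(0)
    for (i in offend) {
      k <- i + sample.int(6L, 1L) - 1L
      chars[k] <- sample(setdiff(.BASES, chars[k]), 1L)
      mutated <- c(mutated, k)
    }
    offend <- integer(0)
    for (k in mutated) {
      lo <- max(1L, k - 6L)
      hi <- min(L, k + 6L)
      offend <- c(offend, hitStarts(chars[lo:hi]) + lo - 1L)
    }
    offend <- unique(offend)
  }
  chars
}

## Plant an element into a character-vector context and confirm that the
## only exact half-site hexamers in the surrounding region are the two
## intended halves (spacer or straddle bases can accidentally form one);
## redraw the element until the context is clean.
.plantElement <- function(chars, at, family, spacer, model, maxTries = 100L) {
  L <- length(chars)
  for (tr in seq_len(maxTries)) {
    el <- .buildElement(family, spacer, model$halves)
    len <- nchar(el$seq)
    lo <- max(1L, at - 5L)
    hi <- min(L, at + len - 1L + 5L)
    ctx <- chars[lo:hi]
    ctx[(at - lo + 1L):(at - lo + len)] <- strsplit(el$seq, "")[[1]]
    h <- .exactHalfHits(ctx, model$halves, model$rcHalves)
    hits <- which(h$fwd | h$rc)
    if (setequal(hits, c(at, at + 6L + spacer) - lo + 1L)) {
      chars[lo:hi] <- ctx
      return(list(chars = chars, el = el, len = len))
    }
  }
  .stopf("could not plant a clean %s%d element", family, spacer)
}

## ---- motif planting --------------------------------------------------

.rcString <- function(x)
  as.character(reverseComplement(DNAString(x)))

.motifLabelParts <- function(label) {
  list(family = substr(label, 1L, 2L),
       spacer = as.integer(sub("^..", "", label)))
}

.buildElement <- function(family, spacer, halves) {
  h1 <- sample(halves, 1L)
  h2 <- sample(halves, 1L)
  sp <- if (spacer > 0L) {
    ## DR1 spacers biased to A/G, the variant enriched in vivo
    if (family == "DR" && spacer == 1L)
      sample(c("A", "G"), 1L)
    else paste(sample(.BASES, spacer, replace = TRUE), collapse = "")
  } else ""
  core <- switch(family,
                 DR = paste0(h1, sp, h2),
                 IR = paste0(h1, sp, .rcString(h2)),
                 ER = paste0(.rcString(h1), sp, h2))
  strand <- if (family == "DR") sample(c("+", "-"), 1L) else "+"
  if (strand == "-") core <- .rcString(core)
  list(seq = core, strand = strand)
}

.drawMotifLabels <- function(rates, n) {
  cnt <- floor(rates * n + 0.5)
  while (sum(cnt) > n) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
  labels <- c(rep(names(cnt), cnt), rep("none", n - sum(cnt)))
  sample(labels)
}

## ---- expression ------------------------------------------------------

#' Simulate an expression table with planted knockdown responses
#'
#' Control FPKM is log-normal; genes planted as knockdown-responsive get a
#' fold change of `plantedFc` (or its reciprocal for the repressed class)
#' with multiplicative log-normal noise, and a control FPKM of at least 1
#' so the calls are unambiguous; non-responsive genes get fold changes
#' inside `nonDeFcRange`. Uses the current RNG state (seed beforehand).
#'
#' @param geneIds character vector of gene identifiers.
#' @inheritParams simConfig
#' @return a list with `expr` (a `data.frame` usable by [callDE()]) and
#'   `truth` (per-gene planted flags: `de_sh1`, `de_sh2`, `common`,
#'   `direction`).
#' @export
simExpressionTable <- function(geneIds, deFracCommon = 0.15,
                               deFracUnique = 0.045, plantedFc = 4,
                               fcNoiseSdlog = 0.1, inducedFrac = 0.8,
                               nonDeFcRange = c(1 / 1.2, 1.2),
                               exprMeanlog = 0, exprSdlog = 1.5) {
  n <- length(geneIds)
  nC <- round(deFracCommon * n)
  nU <- round(deFracUnique * n)
  perm <- sample.int(n)
  common <- perm[seq_len(nC)]
  only1 <- perm[nC + seq_len(nU)]
  only2 <- perm[nC + nU + seq_len(nU)]
  de1 <- logical(n); de1[c(common, only1)] <- TRUE
  de2 <- logical(n); de2[c(common, only2)] <- TRUE
  ctrl <- rlnorm(n, exprMeanlog, exprSdlog)
  anyDe <- de1 | de2
  while (any(ctrl[anyDe] < 1))
    ctrl[anyDe & ctrl < 1] <- rlnorm(sum(anyDe & ctrl < 1),
                                     exprMeanlog, exprSdlog)
  dir <- rep("none", n)
  dir[anyDe] <- ifelse(runif(sum(anyDe)) < inducedFrac, "induced", "repressed")
  fcFor <- function(de) {
    fc <- runif(n, nonDeFcRange[1], nonDeFcRange[2]) *
      rlnorm(n, 0, fcNoiseSdlog)
    planted <- ifelse(dir == "induced", plantedFc, 1 / plantedFc) *
      rlnorm(n, 0, fcNoiseSdlog)
    ifelse(de, planted, fc)
  }
  expr <- data.frame(gene_id = geneIds,
                     fpkm_control = signif(ctrl, 6),
                     fpkm_sh1 = signif(ctrl * fcFor(de1), 6),
                     fpkm_sh2 = signif(ctrl * fcFor(de2), 6),
                     stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = geneIds, de_sh1 = de1, de_sh2 = de2,
                      common = de1 & de2,
                      direction = ifelse(de1 & de2, dir, "none"),
                      stringsAsFactors = FALSE)
  list(expr = expr, truth = truth)
}

## ---- motif windows (standalone recovery generator) -------------------

#' Simulate peak-center windows with planted repeat elements
#'
#' Standalone window-level generator for motif-rate recovery: background
#' windows are rejection-sampled to contain no repeat element within the
#' given scrub budget, then exact-consensus elements are planted at the
#' window center at the configured per-label rates (deterministic counts,
#' `round(rate * n)`). Uses the current RNG state.
#'
#' @param n number of windows.
#' @param rates named plant rates (labels like `"DR1"`, `"ER6"`).
#' @param width window width (default 250).
#' @param gc background GC fraction.
#' @param model the [halfSiteModel()] that will be used for scanning.
#' @param scrub `"model"` (default): background contains no element within
#'   `model`'s full mismatch budget, so planted rates are the only signal;
#'   `"exact"`: background contains no 0-mismatch element only (residual
#'   higher-mismatch hits remain, as in genomic background).
#' @return a list with `seqs` (a `DNAStringSet`) and `truth` (per-window
#'   planted label/family/spacer/start/strand/sequence).
#' @export
simMotifWindows <- function(n, rates, width = 250, gc = 0.41,
                            model = halfSiteModel(),
                            scrub = c("model", "exact")) {
  scrub <- match.arg(scrub)
  scrubModel <- if (scrub == "model") model else
    halfSiteModel(halves = model$halves, maxMismatchPerHalf = 0L,
                  maxTotalMismatch = 0L, spacerRange = model$spacerRange)
  labels <- .drawMotifLabels(rates, n)
  seqs <- character(n)
  truth <- data.frame(window_id = sprintf("win_%04d", seq_len(n)),
                      label = labels, family = NA_character_,
                      spacer = NA_integer_, start = NA_integer_,
                      strand = NA_character_, element_seq = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(.randChars(width, gc), collapse = "")
      if (nrow(findElements(s, scrubModel))) next
      if (labels[i] == "none") {
        seqs[i] <- s
        break
      }
      ## plant, then require that the only exact half-sites in the whole
      ## window are the two planted halves (otherwise a background exact
      ## hexamer could pair with a planted half into a competing element)
      parts <- .motifLabelParts(labels[i])
      el <- .buildElement(parts$family, parts$spacer, model$halves)
      len <- nchar(el$seq)
      at <- floor((width - len) / 2) + 1L
      sv <- strsplit(s, "")[[1]]
      sv[at:(at + len - 1L)] <- strsplit(el$seq, "")[[1]]
      h <- .exactHalfHits(sv, model$halves, model$rcHalves)
      if (!setequal(which(h$fwd | h$rc), c(at, at + 6L + parts$spacer))) next
      seqs[i] <- paste(sv, collapse = "")
      truth$family[i] <- parts$family
      truth$spacer[i] <- parts$spacer
      truth$start[i] <- at
      truth$strand[i] <- el$strand
      truth$element_seq[i] <- el$seq
      break
    }
  }
  out <- DNAStringSet(seqs)
  names(out) <- truth$window_id
  list(seqs = out, truth = truth)
}

## ---- bundle ----------------------------------------------------------

#' Generate a complete synthetic input bundle
#'
#' @param config a [simConfig()].
#' @param seed integer seed; the bundle is a deterministic function of
#'   `(config, seed)`.
#' @return a [SimBundle-class] object.
#' @export
simulateBundle <- function(config = simConfig(), seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$nChrom))
  model <- halfSiteModel()

  genes <- .simGenes(cfg)
  placed <- .placePeaks(cfg, genes)

  ## genome, scrubbed of exact-consensus elements
  charsList <- lapply(chroms, function(ch)
    .scrubChrom(.randChars(cfg$chromLen, cfg$gcContent), model))
  names(charsList) <- chroms

  ## peak ranges + truth scaffold
  n <- length(placed)
  pchrom <- vapply(placed, `[[`, "", "chrom")
  pctr <- vapply(placed, function(x) as.integer(x$center), 0L)
  pclass <- vapply(placed, `[[`, "", "class")
  pgene <- vapply(placed, `[[`, "", "gene_id")
  pd <- vapply(placed, function(x) as.integer(x$d), 0L)
  o <- order(pchrom, pctr)
  pchrom <- pchrom[o]; pctr <- pctr[o]; pclass <- pclass[o]
  pgene <- pgene[o]; pd <- pd[o]
  widths <- vapply(seq_len(n), function(i) .rint(cfg$peakWidth), 0L)
  starts <- pctr - floor(widths / 2)
  peaks <- GRanges(pchrom, IRanges(starts, starts + widths - 1L))
  mcols(peaks)$peak_id <- sprintf("peak_%04d", seq_len(n))

  ## TSS distance for enrichment decay (deserts: distance to nearest TSS)
  tssAll <- .tssPos(genes)
  gch <- as.character(seqnames(genes))
  distTss <- vapply(seq_len(n), function(i) {
    if (!is.na(pd[i])) return(abs(pd[i]))
    min(abs(pctr[i] - tssAll[gch == pchrom[i]]))
  }, 0)
  mcols(peaks)$enrichment <- signif(
    (cfg$enrichBase + cfg$enrichAmp * exp(-distTss / cfg$enrichScale)) *
      rlnorm(n, 0, cfg$enrichNoiseSd), 6)

  stratum <- ifelse(pclass %in% c("five_prime_distal_II",
                                  "three_prime_distal_II", "gene_desert"),
                    "distal",
             ifelse(pclass %in% c("promoter", "within_gene") &
                      !is.na(pd) & abs(pd) <= 1000, "proximal", "other"))

  ## plant motifs
  truthPeaks <- data.frame(peak_id = mcols(peaks)$peak_id, chrom = pchrom,
                           center = pctr, class = pclass, gene_id = pgene,
                           tss_distance = pd, stratum = stratum,
                           motif = "none", motif_family = NA_character_,
                           motif_spacer = NA_integer_,
                           motif_start = NA_integer_,
                           motif_strand = NA_character_,
                           motif_seq = NA_character_,
                           stringsAsFactors = FALSE)
  for (st in c("proximal", "distal", "other")) {
    idx <- which(stratum == st)
    if (!length(idx)) next
    labels <- .drawMotifLabels(cfg$motifRates[[st]], length(idx))
    for (k in seq_along(idx)) {
      if (labels[k] == "none") next
      i <- idx[k]
      parts <- .motifLabelParts(labels[k])
      len <- 12L + parts$spacer
      at <- pctr[i] - floor(len / 2)
      planted <- .plantElement(charsList[[pchrom[i]]], at, parts$family,
                               parts$spacer, model)
      charsList[[pchrom[i]]] <- planted$chars
      el <- planted$el
      truthPeaks$motif[i] <- labels[k]
      truthPeaks$motif_family[i] <- parts$family
      truthPeaks$motif_spacer[i] <- parts$spacer
      truthPeaks$motif_start[i] <- at
      truthPeaks$motif_strand[i] <- el$strand
      truthPeaks$motif_seq[i] <- el$seq
    }
  }

  genome <- DNAStringSet(vapply(charsList, paste, "", collapse = ""))
  names(genome) <- chroms

  ## conservation track: Gaussian bump at every peak center
  hw <- cfg$consBumpHalfWidth
  buf <- lapply(chroms, function(ch) numeric(cfg$chromLen))
  names(buf) <- chroms
  offs <- seq(-hw, hw)
  shape <- exp(-offs^2 / (2 * cfg$consBumpSd^2))
  for (i in seq_len(n)) {
    h <- cfg$consBumpHeight[[stratum[i]]]
    val <- round(pmin(pmax(h * shape +
                             runif(length(offs), -cfg$consNoise,
                                   cfg$consNoise), 0), 1), 3)
    pos <- pctr[i] + offs
    ok <- pos >= 1L & pos <= cfg$chromLen
    buf[[pchrom[i]]][pos[ok]] <- val[ok]
  }
  track <- RleList(lapply(buf, Rle), compress = FALSE)
  names(track) <- chroms

  ## expression with planted knockdown responses
  ex <- simExpressionTable(mcols(genes)$gene_id,
                           deFracCommon = cfg$deFracCommon,
                           deFracUnique = cfg$deFracUnique,
                           plantedFc = cfg$plantedFc,
                           fcNoiseSdlog = cfg$fcNoiseSdlog,
                           inducedFrac = cfg$inducedFrac,
                           nonDeFcRange = cfg$nonDeFcRange,
                           exprMeanlog = cfg$exprMeanlog,
                           exprSdlog = cfg$exprSdlog)

  ## enhancer marks over a configured fraction of distal peaks
  distalIdx <- which(stratum == "distal")
  flank <- 2000L
  distalFlanks <- GRanges(pchrom[distalIdx],
                          IRanges(starts[distalIdx] - flank,
                                  starts[distalIdx] + widths[distalIdx] - 1L +
                                    flank))
  marks <- list()
  markTruth <- matrix(FALSE, nrow = length(distalIdx),
                      ncol = length(cfg$markOverlap),
                      dimnames = list(mcols(peaks)$peak_id[distalIdx],
                                      names(cfg$markOverlap)))
  fS <- start(distalFlanks); fE <- end(distalFlanks)
  fC <- as.character(seqnames(distalFlanks))
  for (m in names(cfg$markOverlap)) {
    kk <- round(cfg$markOverlap[[m]] * length(distalIdx))
    chosen <- if (kk > 0) sample(seq_along(distalIdx), kk) else integer(0)
    mch <- character(0); ms <- integer(0)
    for (j in chosen) {
      c0 <- fS[j] + sample.int(fE[j] - fS[j] + 1L, 1L) - 1L
      mch <- c(mch, fC[j])
      ms <- c(ms, max(c0 - floor(cfg$markWidth / 2), 1L))
      markTruth[j, m] <- TRUE
    }
    ## background intervals, kept clear of every distal flank
    for (b in seq_len(cfg$nBackgroundMarks)) {
      repeat {
        ch <- chroms[sample.int(cfg$nChrom, 1L)]
        s <- sample.int(cfg$chromLen - cfg$markWidth, 1L)
        onCh <- fC == ch
        if (!any(onCh & fS <= s + cfg$markWidth - 1L & fE >= s)) break
      }
      mch <- c(mch, ch); ms <- c(ms, s)
    }
    gr <- GRanges(mch, IRanges(ms, ms + cfg$markWidth - 1L))
    gr <- gr[order(as.character(seqnames(gr)), start(gr))]
    mcols(gr)$peak_id <- sprintf("%s_%03d", m, seq_along(gr))
    mcols(gr)$enrichment <- NA_real_
    marks[[m]] <- gr
  }

  markDf <- cbind(data.frame(peak_id = rownames(markTruth),
                             stringsAsFactors = FALSE),
                  as.data.frame(markTruth))
  rownames(markDf) <- NULL
  truth <- list(config = c(unclass(cfg), list(seed = seed)),
                peaks = truthPeaks,
                genes = ex$truth,
                marks = markDf)
  new("SimBundle", genome = genome, genes = genes, peaks = peaks,
      track = track, expr = ex$expr, marks = marks, truth = truth)
}

## ---- bundle persistence ----------------------------------------------

#' Write a bundle to standard on-disk formats
#'
#' Emits `genome.fa`, `genes.refflat`, `peaks.bed`,
#' `conservation.bedgraph`, `expression.tsv`, one `marks_<name>.bed` per
#' mark, and `truth.json`. A given bundle always writes byte-identical
#' files.
#'
#' @param bundle a `SimBundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(genomeSeq(bundle), file.path(dir, "genome.fa"), width = 80L)
  writeGeneModels(geneModels(bundle), file.path(dir, "genes.refflat"))
  writePeaks(peakSet(bundle), file.path(dir, "peaks.bed"))
  writeTrack(consTrack(bundle), file.path(dir, "conservation.bedgraph"))
  writeExpression(exprTable(bundle), file.path(dir, "expression.tsv"))
  for (m in names(markSets(bundle)))
    writePeaks(markSets(bundle)[[m]], file.path(dir, paste0("marks_", m, ".bed")))
  write_json(truthManifest(bundle), file.path(dir, "truth.json"),
             auto_unbox = TRUE, digits = NA, null = "null", na = "null",
             pretty = TRUE)
  invisible(dir)
}

#' Read a bundle back from disk
#'
#' @param dir a directory written by [writeBundle()].
#' @return a `SimBundle`.
#' @export
readBundle <- function(dir) {
  genome <- readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  markFiles <- list.files(dir, pattern = "^marks_.*\\.bed$", full.names = TRUE)
  marks <- lapply(markFiles, readPeaks)
  names(marks) <- sub("^marks_(.*)\\.bed$", "\\1", basename(markFiles))
  truth <- read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  new("SimBundle",
      genome = genome,
      genes = readGeneModels(file.path(dir, "genes.refflat")),
      peaks = readPeaks(file.path(dir, "peaks.bed")),
      track = readTrack(file.path(dir, "conservation.bedgraph")),
      expr = readExpression(file.path(dir, "expression.tsv")),
      marks = marks,
      truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- truth verification ----------------------------------------------

#' Verify that every planted fact of a bundle is recoverable
#'
#' Re-derives each planted fact from the bundle's data: planted motif
#' sequences are present at their genomic offsets; peak centers lie in
#' their planted class band relative to the planted gene; motif-free
#' peaks contain no exact-consensus element in their window; planted
#' knockdown responses pass (and planted non-responses fail) the double
#' cutoff; planted mark overlaps match interval intersection.
#'
#' @param bundle a `SimBundle` (or one re-read via [readBundle()]).
#' @param manifest a truth manifest (default: the bundle's own).
#' @return a `data.frame` with columns `check`, `item`, `pass`; attribute
#'   `"n_fail"` gives the number of failing facts.
#' @export
verifyTruth <- function(bundle, manifest = truthManifest(bundle)) {
  tp <- manifest$peaks
  genes <- geneModels(bundle)
  genome <- genomeSeq(bundle)
  expr <- exprTable(bundle)
  rows <- list()
  add <- function(check, item, pass)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, item = item,
                                             pass = pass,
                                             stringsAsFactors = FALSE)
  gid <- mcols(genes)$gene_id
  exact <- halfSiteModel(maxMismatchPerHalf = 0L, maxTotalMismatch = 0L)
  peaks <- peakSet(bundle)
  pid <- mcols(peaks)$peak_id
  for (i in seq_len(nrow(tp))) {
    ## geometry: center in planted band relative to planted gene
    if (tp$class[i] == "gene_desert") {
      gi <- which(as.character(seqnames(genes)) == tp$chrom[i])
      dmin <- min(abs(tp$center[i] - .tssPos(genes[gi])),
                  abs(tp$center[i] - .tesPos(genes[gi])))
      add("geometry", tp$peak_id[i], dmin > 100000)
    } else {
      g <- genes[match(tp$gene_id[i], gid)]
      d <- .signedTssDist(tp$center[i], g)
      e <- .signedTesDist(tp$center[i], g)
      okBand <- switch(tp$class[i],
        promoter = d >= -2000 & d <= -1,
        five_prime_distal_I = d > -10000 & d < -2000,
        five_prime_distal_II = d >= -100000 & d <= -10000,
        within_gene = d >= 0 & e <= 0,
        three_prime_proximal = e >= 1 & e <= 2000,
        three_prime_distal_I = e > 2000 & e < 10000,
        three_prime_distal_II = e >= 10000 & e <= 100000)
      add("geometry", tp$peak_id[i], isTRUE(okBand) && d == tp$tss_distance[i])
    }
    ## motif: planted sequence present / background exact-element-free
    if (!is.na(tp$motif_seq[i]) && tp$motif[i] != "none") {
      len <- nchar(tp$motif_seq[i])
      obs <- as.character(subseq(genome[[tp$chrom[i]]], tp$motif_start[i],
                                 tp$motif_start[i] + len - 1L))
      add("motif_sequence", tp$peak_id[i], identical(obs, tp$motif_seq[i]))
    } else {
      win <- extractWindow(peaks[match(tp$peak_id[i], pid)], genome)
      add("background_motif_free", tp$peak_id[i],
          nrow(findElements(win[[1L]], exact)) == 0L)
    }
  }
  ## expression truth recoverable through the double cutoff
  de <- callDE(expr)
  tg <- manifest$genes
  m <- match(tg$gene_id, de$gene_id)
  for (i in seq_len(nrow(tg))) {
    add("expression_de", tg$gene_id[i],
        de$common[m[i]] == tg$common[i] &&
          (!tg$common[i] || de$direction[m[i]] == tg$direction[i]))
  }
  ## mark overlaps
  tm <- manifest$marks
  if (!is.null(tm) && nrow(tm)) {
    dp <- peaks[match(tm$peak_id, pid)]
    for (m2 in setdiff(names(tm), "peak_id")) {
      hits <- colocalize(dp, markSets(bundle)[[m2]], flank = 2000)$hits
      for (i in seq_len(nrow(tm)))
        add(paste0("mark_", m2), tm$peak_id[i], hits[i] == tm[[m2]][i])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_fail") <- sum(!out$pass)
  out
}
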