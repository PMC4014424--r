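## Shared fixtures: small constructors, a memoized default bundle, and
## independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

.fixcache <- new.env(parent = emptyenv())

## One default synthetic bundle per test run (the generator is seeded, so
## this is reproducible across runs).
defaultBundle <- function() {
  if (is.null(.fixcache$bundle))
    .fixcache$bundle <- simulateBundle(simConfig(), seed = 42)
  .fixcache$bundle
}

## single gene model
geneGR <- function(chrom, start, end, strand, id, exons = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$gene_id <- id
  mcols(gr)$exons <- IRangesList(
    if (is.null(exons)) IRanges(start, end) else exons)
  gr
}

combineGR <- function(...) suppressWarnings(do.call(c, list(...)))

## peaks with exact centers (1-based)
peaksAt <- function(chrom, centers, width = 250, enrichment = 1,
                    ids = NULL) {
  s <- as.integer(centers - floor(width / 2))
  gr <- GRanges(chrom, IRanges(s, s + width - 1L))
  mcols(gr)$peak_id <- if (is.null(ids))
    sprintf("pk_%04d", seq_along(gr)) else ids
  mcols(gr)$enrichment <- rep_len(enrichment, length(gr))
  gr
}

randomDna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Brute-force repeat-element oracle: enumerates every (position, family,
## spacer, strand) tuple with substring Hamming distances; independent of
## the vectorized scanner.
oracleFindElements <- function(seq, halves = c("AGGTCA", "AGTTCA", "AGAACA"),
                               perHalf = 1, total = 2, spacers = 0:8) {
  rc1 <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
                           collapse = "")
  sv <- strsplit(toupper(seq), "")[[1]]
  hv <- lapply(halves, function(h) strsplit(h, "")[[1]])
  rv <- lapply(vapply(halves, rc1, ""), function(h) strsplit(h, "")[[1]])
  ham <- function(i, set) {
    sub <- sv[i:(i + 5L)]
    if (any(!sub %in% c("A", "C", "G", "T"))) return(Inf)
    min(vapply(set, function(h) sum(sub != h), 0))
  }
  L <- length(sv)
  out <- list()
  for (n in spacers) {
    for (i in seq_len(max(0L, L - 11L - n))) {
      j <- i + 6L + n
      f1 <- ham(i, hv); r1 <- ham(i, rv)
      f2 <- ham(j, hv); r2 <- ham(j, rv)
      cand <- list(list("DR", "+", f1, f2), list("DR", "-", r1, r2),
                   list("IR", "+", f1, r2), list("ER", "+", r1, f2))
      for (cb in cand) {
        if (cb[[3]] <= perHalf && cb[[4]] <= perHalf &&
            cb[[3]] + cb[[4]] <= total)
          out[[length(out) + 1L]] <- data.frame(
            family = cb[[1]], spacer = n, strand = cb[[2]], start = i,
            mismatches = cb[[3]] + cb[[4]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), spacer = integer(0),
                      strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

normalizeCalls <- function(df) {
  df <- df[, c("family", "spacer", "strand", "start", "mismatches")]
  df <- df[order(df$family, df$spacer, df$strand, df$start, df$mismatches), ]
  rownames(df) <- NULL
  df$mismatches <- as.integer(df$mismatches)
  df
}

## Quadratic nearest-TSS oracle with the package's tie-break rule.
oracleNearestGene <- function(peaks, genes) {
  ctr <- peakCenter(peaks)
  pch <- as.character(seqnames(peaks))
  gch <- as.character(seqnames(genes))
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  tes <- ifelse(minus, start(genes), end(genes))
  gid <- mcols(genes)$gene_id
  vapply(seq_along(peaks), function(i) {
    k <- which(gch == pch[i])
    if (!length(k)) return(NA_character_)
    d <- abs(ctr[i] - tss[k])
    k <- k[d == min(d)]
    if (length(k) > 1L) k <- k[order(abs(ctr[i] - tes[k]), gid[k])]
    gid[k[1L]]
  }, "")
}
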