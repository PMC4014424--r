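## Nuclear-receptor repeat-element grammar scanner.
##
## Non-steroidal nuclear receptors recognize the hexameric half-sites
## AGGTCA / AGTTCA / AGAACA arranged as direct (DR), everted (ER) or
## inverted (IR) repeats separated by 0-8 spacer nucleotides. Instead of
## an HMM this scanner uses an explicit consensus-with-mismatches grammar
## (at most `maxMismatchPerHalf` per half-site and `maxTotalMismatch` in
## total, each half matched against the closest consensus in the set),
## which is deterministic and brute-force verifiable. In window
## coordinates the plus-strand appearance of each family is
##   DRn (+ strand): h1 . N^n . h2
##   DRn (- strand): rc(h2) . N^n . rc(h1)
##   IRn:            h1 . N^n . rc(h2)   (self-complementary family)
##   ERn:            rc(h1) . N^n . h2   (self-complementary family)
## with h1, h2 drawn from the half-site set. IR/ER hits coincide with
## their own reverse complements and are reported once, on "+".

#' Half-site consensus model for the repeat-element grammar
#'
#' @param halves forward consensus half-sites (length-6 strings). The
#'   default keeps AGAACA on equal footing with AG(G/T)TCA; restrict to
#'   `c("AGGTCA", "AGTTCA")` to scan AG(G/T)TCA only.
#' @param maxMismatchPerHalf maximum mismatches tolerated in each
#'   half-site (default 1).
#' @param maxTotalMismatch maximum total mismatches over both half-sites
#'   (default 2).
#' @param spacerRange spacer lengths to scan (default `0:8`).
#' @return an object of class `HalfSiteModel` (a validated list).
#' @export
halfSiteModel <- function(halves = c("AGGTCA", "AGTTCA", "AGAACA"),
                          maxMismatchPerHalf = 1L, maxTotalMismatch = 2L,
                          spacerRange = 0:8) {
  halves <- toupper(halves)
  if (any(nchar(halves) != 6L)) .stopf("half-site consensus must be 6 nt")
  if (maxMismatchPerHalf < 0 || maxTotalMismatch < 0)
    .stopf("mismatch limits must be nonnegative")
  if (any(spacerRange < 0)) .stopf("spacer lengths must be nonnegative")
  structure(list(halves = halves,
                 rcHalves = as.character(
                   reverseComplement(DNAStringSet(halves))),
                 maxMismatchPerHalf = as.integer(maxMismatchPerHalf),
                 maxTotalMismatch = as.integer(maxTotalMismatch),
                 spacerRange = as.integer(spacerRange)),
            class = "HalfSiteModel")
}

#' Extract fixed-width windows around peak centers
#'
#' The window is `[center - width/2, center + width/2)` (250 nt by
#' default). Windows extending past a chromosome end are truncated with a
#' warning.
#'
#' @param peaks a `GRanges` of peaks.
#' @param genome a `DNAStringSet` of chromosome sequences.
#' @param width window width in nt (default 250).
#' @return a `DNAStringSet` named by `peak_id` (uppercase; N allowed).
#' @export
extractWindow <- function(peaks, genome, width = 250) {
  ch <- as.character(seqnames(peaks))
  missing <- setdiff(unique(ch), names(genome))
  if (length(missing))
    .stopf("chromosome absent from genome: %s", missing[1])
  half <- floor(width / 2)
  ctr <- peakCenter(peaks)
  s <- ctr - half
  e <- ctr + width - half - 1L
  lens <- setNames(width(genome), names(genome))[ch]
  sc <- pmax(s, 1L); ec <- pmin(e, lens)
  if (any(s < 1L | e > lens))
    .warnf("%d window(s) truncated at chromosome bounds", sum(s < 1L | e > lens))
  out <- DNAStringSet(toupper(vapply(seq_along(peaks), function(i)
    as.character(subseq(genome[[ch[i]]], sc[i], ec[i])), "")))
  names(out) <- mcols(peaks)$peak_id
  out
}

## minimal Hamming distance of each hexamer start position to a consensus
## set; positions whose hexamer contains a non-ACGT letter get Inf (N never
## matches).
.halfMismatch <- function(chars, halves) {
  L <- length(chars)
  n <- L - 5L
  if (n < 1L) return(numeric(0))
  ci <- match(chars, c("A", "C", "G", "T"))    # NA = N or other
  segs <- lapply(1:6, function(k) ci[k:(n + k - 1L)])
  best <- rep(Inf, n)
  for (h in halves) {
    hv <- match(strsplit(h, "")[[1]], c("A", "C", "G", "T"))
    acc <- integer(n)
    for (k in 1:6) acc <- acc + (segs[[k]] != hv[k])   # NA propagates
    best <- pmin(best, acc)
  }
  nbad <- integer(n)
  for (k in 1:6) nbad <- nbad + is.na(segs[[k]])
  best[nbad > 0L] <- Inf                               # N never matches
  best[is.na(best)] <- Inf
  best
}

#' Find all DR/ER/IR repeat elements in a sequence
#'
#' Scans every start position, spacer length and family under the
#' grammar above. Minus-strand DR hits are reported in window (plus
#' strand) coordinates; IR and ER hits, being identical under reverse
#' complement, are reported once with strand `"+"`.
#'
#' @param seq a character string, `DNAString`, or single-sequence input
#'   of length >= 12.
#' @param model a [halfSiteModel()].
#' @return a `data.frame` with columns `family` (`DR`/`IR`/`ER`),
#'   `spacer`, `strand`, `start` (1-based offset in the window),
#'   `mismatches`, `spacer_seq`. Zero rows when nothing matches.
#' @export
findElements <- function(seq, model = halfSiteModel()) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 12L) .stopf("findElements: sequence shorter than 12 nt")
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  fwd <- .halfMismatch(chars, model$halves)
  rc <- .halfMismatch(chars, model$rcHalves)
  per <- model$maxMismatchPerHalf
  tot <- model$maxTotalMismatch
  res <- vector("list", 0L)
  for (n in model$spacerRange) {
    off <- 6L + n
    m <- L - 11L - n
    if (m < 1L) next
    a <- seq_len(m)
    b <- a + off
    combos <- list(list("DR", "+", fwd[a], fwd[b]),
                   list("DR", "-", rc[a], rc[b]),
                   list("IR", "+", fwd[a], rc[b]),
                   list("ER", "+", rc[a], fwd[b]))
    for (cb in combos) {
      mm <- cb[[3]] + cb[[4]]
      ok <- which(cb[[3]] <= per & cb[[4]] <= per & mm <= tot)
      if (!length(ok)) next
      res[[length(res) + 1L]] <- data.frame(
        family = cb[[1]], spacer = n, strand = cb[[2]], start = ok,
        mismatches = as.integer(mm[ok]),
        spacer_seq = if (n == 0L) "" else
          substr(rep(s, length(ok)), ok + 6L, ok + 5L + n),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(family = character(0), spacer = integer(0),
                      strand = character(0), start = integer(0),
                      mismatches = integer(0), spacer_seq = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$start, out$spacer, out$family, out$strand), , drop = FALSE]
}

#' Pick the single best repeat element among calls
#'
#' Minimal mismatches; ties break by family order DR < IR < ER, then
#' smaller spacer, then leftmost start, then `+` strand. An empty call set
#' yields family `"none"`.
#'
#' @param calls a `data.frame` from [findElements()].
#' @return a one-row `data.frame` with the same columns plus `label`
#'   (e.g. `"DR1"`, or `"none"`).
#' @export
bestElement <- function(calls) {
  if (is.null(calls) || !nrow(calls)) {
    return(data.frame(family = "none", spacer = NA_integer_,
                      strand = NA_character_, start = NA_integer_,
                      mismatches = NA_integer_, spacer_seq = NA_character_,
                      label = "none", stringsAsFactors = FALSE))
  }
  fam <- match(calls$family, c("DR", "IR", "ER"))
  o <- order(calls$mismatches, fam, calls$spacer, calls$start,
             calls$strand != "+")
  b <- calls[o[1L], , drop = FALSE]
  b$label <- paste0(b$family, b$spacer)
  rownames(b) <- NULL
  b
}

#' Scan peaks for their best repeat element
#'
#' Extracts the peak-center window for every peak and reports each peak's
#' single best DR/ER/IR element (or `"none"`).
#'
#' @inheritParams extractWindow
#' @param model a [halfSiteModel()].
#' @return a `data.frame`, one row per peak: `peak_id` plus the
#'   [bestElement()] columns.
#' @export
scanPeaks <- function(peaks, genome, model = halfSiteModel(), width = 250) {
  wins <- extractWindow(peaks, genome, width = width)
  best <- lapply(seq_along(wins), function(i)
    bestElement(findElements(wins[[i]], model)))
  out <- do.call(rbind, best)
  data.frame(peak_id = mcols(peaks)$peak_id, out, stringsAsFactors = FALSE)
}

#' Per-motif frequency table over peaks
#'
#' Each peak contributes its single best element once; `"none"` completes
#' the percentages to 100.
#'
#' @param best a `data.frame` from [scanPeaks()] (or any table with a
#'   `label` column, one row per peak).
#' @return a `data.frame` with `motif`, `count`, `n`, `percent`
#'   (un-rounded, `100 * count / n`), sorted with `"none"` last.
#' @export
motifFrequencyTable <- function(best) {
  if (!nrow(best)) .stopf("motifFrequencyTable: empty stratum")
  n <- nrow(best)
  tab <- table(best$label)
  motifs <- setdiff(names(tab), "none")
  motifs <- motifs[order(match(substr(motifs, 1, 2), c("DR", "IR", "ER")),
                         as.integer(sub("^..", "", motifs)))]
  cnt <- as.integer(tab[motifs])
  out <- data.frame(motif = c(motifs, "none"),
                    count = c(cnt, if ("none" %in% names(tab))
                      as.integer(tab[["none"]]) else 0L),
                    stringsAsFactors = FALSE)
  out$n <- n
  out$percent <- 100 * out$count / n
  out
}

#' Compare per-motif frequencies between two peak strata
#'
#' Two-proportion z-test per motif (pooled standard error, two-sided).
#' When a motif has a zero (or saturated) count in either stratum a +0.5
#' continuity correction is applied to both counts (and +1 to both
#' denominators).
#'
#' @param tabA,tabB frequency tables from [motifFrequencyTable()]
#'   (stratum A is conventionally proximal, B distal).
#' @return a `data.frame` with one row per motif present in either
#'   stratum: `motif`, `p_a`, `p_b`, `delta` (`p_b - p_a`), `z`, `p_value`.
#' @export
compareStrata <- function(tabA, tabB) {
  motifs <- union(setdiff(tabA$motif, "none"), setdiff(tabB$motif, "none"))
  nA <- tabA$n[1L]; nB <- tabB$n[1L]
  getc <- function(tab, m) {
    i <- match(m, tab$motif)
    if (is.na(i)) 0L else tab$count[i]
  }
  rows <- lapply(motifs, function(m) {
    xa <- getc(tabA, m); xb <- getc(tabB, m)
    na <- nA; nb <- nB
    if (xa == 0L || xb == 0L || xa == na || xb == nb) {
      xa <- xa + 0.5; xb <- xb + 0.5; na <- na + 1; nb <- nb + 1
    }
    pa <- xa / na; pb <- xb / nb
    pp <- (xa + xb) / (na + nb)
    se <- sqrt(pp * (1 - pp) * (1 / na + 1 / nb))
    z <- if (se == 0) 0 else (pb - pa) / se
    data.frame(motif = m, p_a = getc(tabA, m) / nA, p_b = getc(tabB, m) / nB,
               delta = getc(tabB, m) / nB - getc(tabA, m) / nA,
               z = z, p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
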