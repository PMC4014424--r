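## Conservation-score profiles and GC-matched random backgrounds.
##
## Positions absent from the track score 0 (the UCSC convention for
## unscored bases), so the per-peak average always divides by the fixed
## window length.

#' Positional mean conservation profile around peak centers
#'
#' For offset k relative to each peak center (center = offset 0), the
#' profile value is the mean score at `center + k` over all peaks whose
#' window position lies on the chromosome; windows truncated at a
#' chromosome start contribute only their covered offsets.
#'
#' @param peaks a `GRanges` of peaks.
#' @param track an `RleList` conservation track ([readTrack()]).
#' @param halfWidth half-width of the profile in bp (default 250, i.e. a
#'   500-bp window).
#' @return a `data.frame` with `offset` (`-halfWidth .. halfWidth-1`),
#'   `mean` and `n` (peaks contributing at that offset).
#' @export
positionalProfile <- function(peaks, track, halfWidth = 250) {
  if (!length(peaks)) .stopf("positionalProfile: empty peak set")
  offsets <- seq(-halfWidth, halfWidth - 1L)
  ctr <- peakCenter(peaks)
  ch <- as.character(seqnames(peaks))
  acc <- numeric(length(offsets))
  n <- integer(length(offsets))
  for (i in seq_along(peaks)) {
    pos <- ctr[i] + offsets
    ok <- pos >= 1L
    acc[ok] <- acc[ok] + trackScores(track, ch[i], pos[ok])
    n <- n + ok
  }
  data.frame(offset = offsets, mean = ifelse(n > 0, acc / n, NA_real_), n = n)
}

#' Mean conservation score of each peak's center window
#'
#' Sum of per-base scores over the `length`-bp window centered on the
#' peak, divided by the fixed window length; absent positions contribute 0.
#'
#' @param peaks a `GRanges` of peaks.
#' @param track an `RleList` conservation track.
#' @param length window length in bp (default 250).
#' @return numeric vector, one mean score per peak.
#' @export
peakMeanScore <- function(peaks, track, length = 250) {
  half <- floor(length / 2)
  ctr <- peakCenter(peaks)
  ch <- as.character(seqnames(peaks))
  vapply(seq_along(peaks), function(i) {
    pos <- (ctr[i] - half):(ctr[i] + length - half - 1L)
    sum(trackScores(track, ch[i], pos)) / length
  }, 0)
}

.gcFraction <- function(genome, chrom, start, end) {
  w <- subseq(genome[[chrom]], start, end)
  unname(letterFrequency(w, "GC") / (end - start + 1L))
}

#' Sample GC- and length-matched random control intervals
#'
#' For each peak, draws uniform random same-chromosome intervals of the
#' window length until one matches the peak window's GC content within
#' `gcTol` and does not overlap any peak window. If `maxAttempts` draws
#' fail, the tolerance is doubled (with a message) and sampling resumes;
#' the tolerance actually in force is reported per control.
#'
#' Uses the current RNG state: call `set.seed()` beforehand for
#' reproducible controls.
#'
#' @param peaks a `GRanges` of peaks to match.
#' @param genome a `DNAStringSet`.
#' @param gcTol GC-fraction tolerance (default 0.02).
#' @param maxAttempts draws per tolerance level (default 1000).
#' @param width window length (default 250).
#' @param exclude a `GRanges` whose windows controls must not overlap
#'   (default: `peaks`); set to `NULL` to disable the exclusion.
#' @return a `data.frame`: `peak_id`, `chrom`, `start`, `end` (1-based,
#'   closed), `gc_peak`, `gc_control`, `attempts`, `tolerance` (the value
#'   in force when the control was accepted).
#' @export
sampleMatchedControl <- function(peaks, genome, gcTol = 0.02,
                                 maxAttempts = 1000, width = 250,
                                 exclude = peaks) {
  half <- floor(width / 2)
  ctr <- peakCenter(peaks)
  ch <- as.character(seqnames(peaks))
  forbid <- if (is.null(exclude)) GRanges() else {
    ec <- peakCenter(exclude)
    GRanges(seqnames(exclude), IRanges(ec - half, ec + width - half - 1L))
  }
  rows <- lapply(seq_along(peaks), function(i) {
    clen <- width(genome)[match(ch[i], names(genome))]
    if (is.na(clen)) .stopf("chromosome absent from genome: %s", ch[i])
    if (clen < width)
      .stopf("chromosome %s shorter than the %d-bp window", ch[i], width)
    ws <- max(ctr[i] - half, 1L)
    we <- min(ctr[i] + width - half - 1L, clen)
    gcPeak <- .gcFraction(genome, ch[i], ws, we)
    tol <- gcTol
    attempts <- 0L
    repeat {
      for (k in seq_len(maxAttempts)) {
        attempts <- attempts + 1L
        s <- sample.int(clen - width + 1L, 1L)
        e <- s + width - 1L
        if (length(forbid) &&
            length(findOverlaps(GRanges(ch[i], IRanges(s, e)), forbid)) > 0)
          next
        gc <- .gcFraction(genome, ch[i], s, e)
        if (abs(gc - gcPeak) <= tol) {
          return(data.frame(peak_id = mcols(peaks)$peak_id[i], chrom = ch[i],
                            start = s, end = e, gc_peak = gcPeak,
                            gc_control = gc, attempts = attempts,
                            tolerance = tol, stringsAsFactors = FALSE))
        }
      }
      tol <- tol * 2
      message("sampleMatchedControl: relaxing GC tolerance to ", tol,
              " for ", mcols(peaks)$peak_id[i])
    }
  })
  do.call(rbind, rows)
}

#' Compare peak conservation with GC-matched random backgrounds
#'
#' Per stratum: mean per-peak window score versus mean matched-control
#' score, with a two-sided Welch t-test. Strata with fewer than 2 peaks
#' are skipped with a warning.
#'
#' @param peakSets a named list of `GRanges`, one per stratum (e.g.
#'   proximal promoter, >10 kb from genes, all peaks).
#' @param track an `RleList` conservation track.
#' @param genome a `DNAStringSet`.
#' @param nControls controls per peak (default 1).
#' @param width window length (default 250).
#' @param gcTol GC tolerance passed to [sampleMatchedControl()].
#' @param exclude `GRanges` controls must avoid (default: union of all
#'   strata).
#' @return a `data.frame`, one row per evaluated stratum: `stratum`, `n`,
#'   `mean_peak`, `mean_control`, `t`, `p_value`; the per-stratum control
#'   tables are attached as attribute `"controls"`.
#' @export
conservationComparison <- function(peakSets, track, genome, nControls = 1,
                                   width = 250, gcTol = 0.02,
                                   exclude = NULL) {
  stopifnot(is.list(peakSets), !is.null(names(peakSets)))
  if (is.null(exclude))
    exclude <- do.call(c, lapply(unname(peakSets), function(g) {
      mcols(g) <- NULL
      g
    }))
  ctrlTabs <- list()
  rows <- lapply(names(peakSets), function(nm) {
    pk <- peakSets[[nm]]
    if (length(pk) < 2L) {
      .warnf("stratum '%s' has fewer than 2 peaks; skipped", nm)
      return(NULL)
    }
    ps <- peakMeanScore(pk, track, length = width)
    ex <- exclude
    mcols(ex) <- NULL
    mcols(ex)$peak_id <- sprintf("x%d", seq_along(ex))
    ctl <- do.call(rbind, lapply(seq_len(nControls), function(k)
      sampleMatchedControl(pk, genome, gcTol = gcTol, width = width,
                           exclude = ex)))
    cg <- GRanges(ctl$chrom, IRanges(ctl$start, ctl$end))
    mcols(cg)$peak_id <- ctl$peak_id
    cs <- peakMeanScore(cg, track, length = width)
    ## degenerate case: a constant track makes both groups constant
    tt <- if (stats::var(ps) + stats::var(cs) == 0) {
      list(statistic = if (mean(ps) == mean(cs)) 0 else Inf,
           p.value = if (mean(ps) == mean(cs)) 1 else 0)
    } else t.test(ps, cs, alternative = "two.sided")
    ctrlTabs[[nm]] <<- ctl
    data.frame(stratum = nm, n = length(pk), mean_peak = mean(ps),
               mean_control = mean(cs), t = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "controls") <- ctrlTabs
  out
}
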