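## Enhancer-mark co-localization around distal peaks.

#' Count distal peaks whose flanked interval overlaps mark intervals
#'
#' A peak counts once if its interval, extended by `flank` bp on each
#' side (or, with `mode = "center"`, the `center +/- flank` window),
#' intersects at least one mark interval. Overlap is half-open-consistent:
#' a mark beginning exactly where the flank ends does not overlap.
#'
#' @param peaks a `GRanges` of (pre-filtered distal) peaks.
#' @param marks a `GRanges` of mark intervals (e.g. from [readPeaks()]).
#' @param flank flank size in bp (default 2000).
#' @param mode flank the peak interval (`"flank"`, default) or the peak
#'   center (`"center"`).
#' @return a list: `n_overlapping`, `n_total`, `percent` (integer, half
#'   away from zero), `hits` (logical per peak).
#' @export
colocalize <- function(peaks, marks, flank = 2000,
                       mode = c("flank", "center")) {
  mode <- match.arg(mode)
  if (!length(marks)) .warnf("colocalize: empty mark set")
  win <- if (mode == "flank") {
    GRanges(seqnames(peaks),
            IRanges(pmax(start(peaks) - flank, 1L), end(peaks) + flank))
  } else {
    ctr <- peakCenter(peaks)
    GRanges(seqnames(peaks), IRanges(pmax(ctr - flank, 1L), ctr + flank))
  }
  hits <- countOverlaps(win, marks) > 0
  list(n_overlapping = sum(hits), n_total = length(peaks),
       percent = .pct(sum(hits), length(peaks)), hits = hits)
}

#' Mark-by-mark co-localization table with an any-mark aggregate
#'
#' Evaluates each mark independently over the same peak stratum and adds
#' an `"any"` row: the fraction of peaks overlapping at least one of the
#' marks (always >= the maximum single-mark fraction).
#'
#' @param peaks a `GRanges` of distal peaks.
#' @param markList a named list of mark `GRanges`.
#' @inheritParams colocalize
#' @return a `data.frame` with `mark`, `n_overlapping`, `n_total`,
#'   `percent`.
#' @export
multiMarkSummary <- function(peaks, markList, flank = 2000,
                             mode = c("flank", "center")) {
  mode <- match.arg(mode)
  stopifnot(is.list(markList), !is.null(names(markList)))
  res <- lapply(markList, function(m) colocalize(peaks, m, flank, mode))
  any_hits <- Reduce(`|`, lapply(res, `[[`, "hits"))
  out <- data.frame(mark = c(names(markList), "any"),
                    n_overlapping = c(vapply(res, `[[`, 0L, "n_overlapping"),
                                      sum(any_hits)),
                    n_total = length(peaks),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$percent <- .pct(out$n_overlapping, out$n_total)
  out
}
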