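#' Round half away from zero
#'
#' Integer (or fixed-digit) rounding where exact halves move away from zero,
#' matching how the percentage tables in this package are printed
#' (e.g. 166/490 -> 34). Base R `round()` rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector, rounded.
#' @examples
#' roundHalfAway(c(0.5, 1.5, -0.5, 2.345), digits = 0)
#' @export
roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## integer percentage with round-half-away semantics
.pct <- function(num, den) roundHalfAway(100 * num / den)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## 1-based center position of ranges: start + floor(width/2).
## Equals the BED-convention center (start0 + floor(width/2)) shifted by +1.

#' Center position of genomic ranges
#'
#' Deterministic center of an interval, `start + floor(width/2)` (1-based).
#' Even-width intervals have no exact midpoint; the convention keeps the
#' arithmetic integral and matches BED-style `start0 + floor(width/2)`.
#'
#' @param x a `GRanges`.
#' @return integer vector of center positions, one per range.
#' @export
peakCenter <- function(x) {
  as.integer(start(x) + floor(width(x) / 2))
}

## strand-aware TSS / TES (1-based positions)
.tssPos <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}
.tesPos <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
}

## signed distance from position to TSS in the gene's orientation:
## negative upstream of the TSS, positive downstream.
.signedTssDist <- function(pos, genes) {
  ifelse(as.character(strand(genes)) == "-",
         .tssPos(genes) - pos,
         pos - .tssPos(genes))
}
.signedTesDist <- function(pos, genes) {
  ifelse(as.character(strand(genes)) == "-",
         .tesPos(genes) - pos,
         pos - .tesPos(genes))
}

## The eight region classes, in reporting order.
REGION_CLASSES <- c("promoter", "five_prime_distal_I", "five_prime_distal_II",
                    "within_gene", "three_prime_proximal",
                    "three_prime_distal_I", "three_prime_distal_II",
                    "gene_desert")
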