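#' SimBundle: a complete synthetic input bundle with planted truth
#'
#' Container for one simulated study condition: genome sequence, gene
#' models, ChIP peaks with planted region classes and motifs, a per-base
#' conservation track, an expression table with planted knockdown
#' responses, enhancer-mark interval sets, and the truth manifest that
#' records every planted parameter and label.
#'
#' @slot genome a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes a [GenomicRanges::GRanges] of transcripts with metadata
#'   columns `gene_id` (character) and `exons` (an `IRangesList`, absolute
#'   genomic coordinates, sorted, disjoint, within the transcript).
#' @slot peaks a `GRanges` with metadata columns `peak_id` and `enrichment`.
#' @slot track an [IRanges::RleList] of per-base conservation scores in
#'   `[0, 1]`; positions absent from the track score 0.
#' @slot expr a `data.frame` with columns `gene_id`, `fpkm_control`,
#'   `fpkm_sh1`, `fpkm_sh2`.
#' @slot marks a named `list` of `GRanges`, one per chromatin mark.
#' @slot truth a `list`: the simulation config plus per-peak and per-gene
#'   planted labels (see [simulateBundle()]).
#'
#' @seealso [simulateBundle()], [writeBundle()], [verifyTruth()]
#' @exportClass SimBundle
setClass("SimBundle",
  representation(
    genome = "DNAStringSet",
    genes  = "GRanges",
    peaks  = "GRanges",
    track  = "ANY",
    expr   = "data.frame",
    marks  = "list",
    truth  = "list"
  )
)

setValidity("SimBundle", function(object) {
  msg <- character(0)
  g <- object@genes
  if (length(g) && !all(c("gene_id", "exons") %in% names(mcols(g))))
    msg <- c(msg, "genes must carry 'gene_id' and 'exons' metadata columns")
  if (length(g) && anyDuplicated(mcols(g)$gene_id))
    msg <- c(msg, "gene_id values must be unique")
  p <- object@peaks
  if (length(p) && !all(c("peak_id", "enrichment") %in% names(mcols(p))))
    msg <- c(msg, "peaks must carry 'peak_id' and 'enrichment' metadata columns")
  if (length(p) && any(mcols(p)$enrichment < 0, na.rm = TRUE))
    msg <- c(msg, "peak enrichment must be nonnegative")
  if (!is(object@track, "RleList"))
    msg <- c(msg, "track must be an RleList")
  else {
    rng <- suppressWarnings(range(unlist(lapply(object@track,
                                                function(r) range(runValue(r))))))
    if (length(object@track) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "track scores must lie in [0, 1]")
  }
  e <- object@expr
  need <- c("gene_id", "fpkm_control", "fpkm_sh1", "fpkm_sh2")
  if (nrow(e) && !all(need %in% names(e)))
    msg <- c(msg, paste("expr must have columns", paste(need, collapse = ", ")))
  if (nrow(e) && any(unlist(e[, intersect(need[-1], names(e))]) < 0))
    msg <- c(msg, "FPKM values must be nonnegative")
  if (length(object@marks) && is.null(names(object@marks)))
    msg <- c(msg, "marks must be a named list")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimBundle genome sequences
#' @param x a `SimBundle`.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @describeIn SimBundle gene models
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @describeIn SimBundle peak ranges
#' @export
setGeneric("peakSet", function(x) standardGeneric("peakSet"))
#' @describeIn SimBundle conservation track
#' @export
setGeneric("consTrack", function(x) standardGeneric("consTrack"))
#' @describeIn SimBundle expression table
#' @export
setGeneric("exprTable", function(x) standardGeneric("exprTable"))
#' @describeIn SimBundle named list of mark interval sets
#' @export
setGeneric("markSets", function(x) standardGeneric("markSets"))
#' @describeIn SimBundle planted-truth manifest
#' @export
setGeneric("truthManifest", function(x) standardGeneric("truthManifest"))

#' @exportMethod genomeSeq
setMethod("genomeSeq", "SimBundle", function(x) x@genome)
#' @exportMethod geneModels
setMethod("geneModels", "SimBundle", function(x) x@genes)
#' @exportMethod peakSet
setMethod("peakSet", "SimBundle", function(x) x@peaks)
#' @exportMethod consTrack
setMethod("consTrack", "SimBundle", function(x) x@track)
#' @exportMethod exprTable
setMethod("exprTable", "SimBundle", function(x) x@expr)
#' @exportMethod markSets
setMethod("markSets", "SimBundle", function(x) x@marks)
#' @exportMethod truthManifest
setMethod("truthManifest", "SimBundle", function(x) x@truth)

#' @exportMethod show
setMethod("show", "SimBundle", function(object) {
  cat("SimBundle object\n")
  cat(sprintf("  genome : %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(width(object@genome)), big.mark = ",")))
  cat(sprintf("  genes  : %d gene model(s)\n", length(object@genes)))
  cat(sprintf("  peaks  : %d peak(s)\n", length(object@peaks)))
  cat(sprintf("  track  : %d chromosome(s) covered\n", length(object@track)))
  cat(sprintf("  expr   : %d gene(s) x 3 conditions\n", nrow(object@expr)))
  cat(sprintf("  marks  : %s\n",
              if (length(object@marks)) paste(names(object@marks), collapse = ", ")
              else "none"))
  if (!is.null(object@truth$config$seed))
    cat(sprintf("  seed   : %s\n", object@truth$config$seed))
})
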