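## Orchestration: annotate -> scan -> integrate -> conserve -> marks, with
## one consolidated report. Every percentage in the report is accompanied
## by its numerator and denominator, and every threshold actually used is
## logged in report$params.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline on a bundle of inputs
#'
#' Executes peak annotation, repeat-element scanning, knockdown
#' integration, conservation comparison and mark co-localization, and
#' returns one report mirroring the analysis's standard summaries
#' (region-class distribution, proximal-promoter fraction, knockdown Venn
#' counts and direction split, promoter-cohort shift test, stratified
#' motif frequency tables with proximal-vs-distal comparison,
#' peak-vs-control conservation, per-mark co-localization). A missing
#' stage input (e.g. no marks) skips that stage with a notice rather than
#' aborting.
#'
#' @param bundle a [SimBundle-class] (from [simulateBundle()] or
#'   [readBundle()]); alternatively pass `dir` to read one from disk.
#' @param dir directory holding a written bundle (ignored when `bundle`
#'   is given).
#' @param params named overrides of the analysis thresholds:
#'   `fcThreshold` (2), `fpkmMin` (0.1), `eps` (0.01), `proximalWindow`
#'   (1000), `scanWidth` (250), `maxMismatchPerHalf` (1),
#'   `maxTotalMismatch` (2), `flank` (2000), `gcTol` (0.02),
#'   `consWidth` (250), `profileHalfWidth` (250).
#' @param seed seed for the conservation-control sampling.
#' @param outDir if non-`NULL`, write `report.json` plus per-stage TSVs
#'   there.
#' @return a named list (the report); stage tables are attached under
#'   `tables`.
#' @export
runPipeline <- function(bundle = NULL, dir = NULL, params = list(),
                        seed = 1L, outDir = NULL) {
  if (is.null(bundle)) {
    if (is.null(dir)) .stopf("provide a bundle or a bundle directory")
    bundle <- .stage("read", readBundle(dir))
  }
  p <- modifyList(list(fcThreshold = 2, fpkmMin = 0.1, eps = 0.01,
                       proximalWindow = 1000, scanWidth = 250,
                       maxMismatchPerHalf = 1L, maxTotalMismatch = 2L,
                       flank = 2000, gcTol = 0.02, consWidth = 250,
                       profileHalfWidth = 250), params)
  peaks <- peakSet(bundle)
  genes <- geneModels(bundle)
  genome <- genomeSeq(bundle)
  notices <- character(0)

  ## annotate
  ann <- .stage("annotate", annotatePeaks(peaks, genes,
                                          proximalWindow = p$proximalWindow))
  dist <- summarizeDistribution(ann)
  pp <- attr(dist, "proximal_promoter")
  distalSel <- ann$region_class %in% c("five_prime_distal_II",
                                       "three_prime_distal_II", "gene_desert")

  ## motif scan
  model <- halfSiteModel(maxMismatchPerHalf = p$maxMismatchPerHalf,
                         maxTotalMismatch = p$maxTotalMismatch)
  best <- .stage("scan", scanPeaks(peaks, genome, model,
                                   width = p$scanWidth))
  freqAll <- motifFrequencyTable(best)
  freqProx <- if (any(ann$proximal_promoter))
    motifFrequencyTable(best[ann$proximal_promoter, ]) else NULL
  freqDistal <- if (any(distalSel))
    motifFrequencyTable(best[distalSel, ]) else NULL
  strataCmp <- if (!is.null(freqProx) && !is.null(freqDistal))
    compareStrata(freqProx, freqDistal) else NULL

  ## expression integration
  de <- .stage("integrate", callDE(exprTable(bundle),
                                   fcThreshold = p$fcThreshold,
                                   fpkmMin = p$fpkmMin, eps = p$eps))
  venn <- intersectKnockdowns(de)
  cohort <- unique(ann$gene_id[ann$proximal_promoter & !is.na(ann$gene_id)])
  shift <- NULL
  if (length(intersect(cohort, de$gene_id[de$expressed])) >= 2) {
    shift <- list(sh1 = cohortShiftTest(de, cohort, "sh1"),
                  sh2 = cohortShiftTest(de, cohort, "sh2"))
    shift <- lapply(shift, function(s)
      s[c("t", "p_value", "df", "n_cohort", "n_background")])
  } else notices <- c(notices, "cohort shift test skipped: cohort < 2 expressed genes")
  distalAsg <- if (any(distalSel) && any(de$common)) {
    .stage("integrate", assignDistalToDE(peaks[distalSel], de, genes))
  } else {
    notices <- c(notices, "distal-to-DE assignment skipped")
    NULL
  }

  ## conservation
  set.seed(seed)
  strata <- list(proximal_promoter = peaks[ann$proximal_promoter],
                 distal = peaks[distalSel],
                 all = peaks)
  cons <- .stage("conserve",
                 conservationComparison(strata, consTrack(bundle), genome,
                                        width = p$consWidth, gcTol = p$gcTol,
                                        exclude = peaks))
  prof <- .stage("conserve",
                 positionalProfile(peaks[ann$proximal_promoter], consTrack(bundle),
                                   halfWidth = p$profileHalfWidth))

  ## marks
  marksTab <- if (length(markSets(bundle)) && any(distalSel)) {
    .stage("marks", multiMarkSummary(peaks[distalSel], markSets(bundle),
                                     flank = p$flank))
  } else {
    notices <- c(notices, "mark co-localization skipped: no marks or no distal peaks")
    NULL
  }

  report <- list(
    params = c(p, seed = seed),
    n_peaks = length(peaks), n_genes = length(genes),
    region_distribution = dist,
    proximal_promoter = pp,
    distal_fraction = list(count = sum(distalSel),
                           total = nrow(ann),
                           percent = .pct(sum(distalSel), nrow(ann))),
    knockdown = venn,
    cohort_shift = shift,
    distal_assignment = if (!is.null(distalAsg)) distalAsg$summary else NULL,
    motif_comparison = strataCmp,
    conservation = cons,
    marks = marksTab,
    notices = notices,
    tables = list(annotation = ann, best_elements = best,
                  motif_all = freqAll, motif_proximal = freqProx,
                  motif_distal = freqDistal, de = de,
                  distal_assignments = if (!is.null(distalAsg))
                    distalAsg$assignments else NULL,
                  conservation_profile = prof)
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report$tables)) {
      tb <- report$tables[[nm]]
      if (!is.null(tb))
        write.table(tb, file.path(outDir, paste0(nm, ".tsv")), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    write_json(report[setdiff(names(report), "tables")],
               file.path(outDir, "report.json"), auto_unbox = TRUE,
               digits = NA, na = "null", pretty = TRUE)
  }
  report
}
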