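## Knockdown differential-expression integration.
##
## Fold change is a pseudocount log-ratio on FPKM:
##   fc = (fpkm_kd + eps) / (fpkm_ctrl + eps),   eps = 0.01 by default.
## A gene is called responsive to one shRNA when the double cutoff holds:
##   (fc >= threshold or fc <= 1/threshold)  and  max(fpkm_kd, fpkm_ctrl)
##   >= the FPKM floor (0.1).
## "Expressed" means FPKM >= 0.1 in at least one of the three datasets.
## The common set is the intersection of both shRNA calls; direction
## vocabulary is post-knockdown ("induced" = up after knockdown, which is
## the factor-repressed class), with the factor-centric label carried
## alongside to prevent sign confusion.

#' Call knockdown-responsive genes with double cutoffs
#'
#' @param expr a `data.frame` with columns `gene_id`, `fpkm_control`,
#'   `fpkm_sh1`, `fpkm_sh2` (see [readExpression()]).
#' @param fcThreshold fold-change cutoff, applied symmetrically
#'   (`>= fcThreshold` or `<= 1/fcThreshold`); default 2.
#' @param fpkmMin FPKM floor: at least one of knockdown/control must reach
#'   it for a DE call, and at least one of the three datasets for the
#'   `expressed` flag; default 0.1.
#' @param eps pseudocount added to both FPKM values before the ratio;
#'   default 0.01.
#' @return a `data.frame`, one row per gene: the input FPKM columns plus
#'   `log2fc_sh1`, `log2fc_sh2`, `expressed`, `de_sh1`, `de_sh2`,
#'   `common`, `direction` (`induced`/`repressed`/`discordant`/`none`,
#'   post-knockdown) and `tr4_direction` (the factor-centric flip:
#'   induced-after-knockdown = `"factor_repressed"`).
#' @export
callDE <- function(expr, fcThreshold = 2, fpkmMin = 0.1, eps = 0.01) {
  need <- c("gene_id", "fpkm_control", "fpkm_sh1", "fpkm_sh2")
  stopifnot(all(need %in% names(expr)))
  ctrl <- expr$fpkm_control; s1 <- expr$fpkm_sh1; s2 <- expr$fpkm_sh2
  if (any(c(ctrl, s1, s2) < 0)) .stopf("callDE: negative FPKM")
  fc1 <- (s1 + eps) / (ctrl + eps)
  fc2 <- (s2 + eps) / (ctrl + eps)
  de <- function(fc, kd) (fc >= fcThreshold | fc <= 1 / fcThreshold) &
    pmax(kd, ctrl) >= fpkmMin
  out <- data.frame(gene_id = expr$gene_id,
                    fpkm_control = ctrl, fpkm_sh1 = s1, fpkm_sh2 = s2,
                    log2fc_sh1 = log2(fc1), log2fc_sh2 = log2(fc2),
                    expressed = pmax(ctrl, s1, s2) >= fpkmMin,
                    de_sh1 = de(fc1, s1), de_sh2 = de(fc2, s2),
                    stringsAsFactors = FALSE)
  out$common <- out$de_sh1 & out$de_sh2
  dir <- rep("none", nrow(out))
  dir[out$common & out$log2fc_sh1 > 0 & out$log2fc_sh2 > 0] <- "induced"
  dir[out$common & out$log2fc_sh1 < 0 & out$log2fc_sh2 < 0] <- "repressed"
  dir[out$common & sign(out$log2fc_sh1) != sign(out$log2fc_sh2)] <- "discordant"
  out$direction <- dir
  out$tr4_direction <- c(induced = "factor_repressed",
                         repressed = "factor_activated",
                         discordant = "discordant", none = "none")[dir]
  out
}

#' Intersect the two shRNA knockdown call sets
#'
#' Summarizes the Venn structure of the two per-shRNA DE sets and the
#' direction split of the common set.
#'
#' @param de a `data.frame` from [callDE()] (both shRNA calls share one
#'   gene universe by construction).
#' @return a list: `n_sh1`, `n_sh2`, `n_common`, `pct_common_of_sh1`,
#'   `pct_common_of_sh2`, `n_induced`, `n_repressed`, `n_discordant`,
#'   `pct_induced`, `pct_repressed` (integer percentages, half away from
#'   zero; direction percentages are over the common set).
#' @export
intersectKnockdowns <- function(de) {
  n1 <- sum(de$de_sh1); n2 <- sum(de$de_sh2); nc <- sum(de$common)
  ni <- sum(de$direction == "induced")
  nr <- sum(de$direction == "repressed")
  nd <- sum(de$direction == "discordant")
  list(n_sh1 = n1, n_sh2 = n2, n_common = nc,
       pct_common_of_sh1 = if (n1) .pct(nc, n1) else NA_real_,
       pct_common_of_sh2 = if (n2) .pct(nc, n2) else NA_real_,
       n_induced = ni, n_repressed = nr, n_discordant = nd,
       pct_induced = if (nc) .pct(ni, nc) else NA_real_,
       pct_repressed = if (nc) .pct(nr, nc) else NA_real_)
}

#' Test whether a gene cohort's fold-change distribution is shifted
#'
#' Two-sample two-tailed t-test of the cohort's log2 fold changes against
#' those of all expressed genes (Welch by default).
#'
#' @param de a `data.frame` from [callDE()].
#' @param cohort character vector of gene ids (must be expressed genes;
#'   at least 2).
#' @param shrna `"sh1"` or `"sh2"`: which knockdown's fold changes to test.
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @return a list: `t`, `p_value`, `df`, `cohort_log2fc`,
#'   `background_log2fc`, `n_cohort`, `n_background`.
#' @export
cohortShiftTest <- function(de, cohort, shrna = c("sh1", "sh2"),
                            varEqual = FALSE) {
  shrna <- match.arg(shrna)
  bg <- de[de$expressed, , drop = FALSE]
  cohort <- intersect(cohort, bg$gene_id)
  if (length(cohort) < 2L)
    .stopf("cohortShiftTest: fewer than 2 expressed cohort genes")
  col <- paste0("log2fc_", shrna)
  x <- bg[[col]][match(cohort, bg$gene_id)]
  y <- bg[[col]]
  tt <- t.test(x, y, alternative = "two.sided", var.equal = varEqual)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       cohort_log2fc = x, background_log2fc = y,
       n_cohort = length(x), n_background = length(y))
}

#' Assign distal peaks to the nearest differentially expressed gene
#'
#' For peaks lying >10 kb from the nearest gene, the putative target is
#' taken to be the common-DE gene with the closest TSS (rather than the
#' physically nearest gene). Ties break as in [assignNearestGene()].
#'
#' @param distalPeaks a `GRanges` of distal peaks (the caller filters by
#'   region class; see [annotatePeaks()]).
#' @param de a `data.frame` from [callDE()].
#' @param genes gene models (`GRanges`) providing TSS positions; genes in
#'   the DE table without a model are ignored.
#' @return a list with `assignments` (a `data.frame`: `peak_id`,
#'   `gene_id`, `distance` = unsigned center-to-TSS bp, `direction`) and
#'   `summary` (`n_peaks`, `n_genes` distinct, `median_distance` bp,
#'   `n_induced`, `pct_induced` over distinct genes — the fraction of
#'   assigned genes induced after knockdown).
#' @export
assignDistalToDE <- function(distalPeaks, de, genes) {
  deGenes <- de$gene_id[de$common]
  keep <- mcols(genes)$gene_id %in% deGenes
  if (!any(keep)) .stopf("assignDistalToDE: no common-DE gene has a gene model")
  g <- genes[keep]
  asg <- assignNearestGene(distalPeaks, g)
  asg$distance <- abs(asg$tss_distance)
  asg$direction <- de$direction[match(asg$gene_id, de$gene_id)]
  asg <- asg[, c("peak_id", "gene_id", "distance", "direction")]
  ug <- unique(asg$gene_id[!is.na(asg$gene_id)])
  ui <- de$direction[match(ug, de$gene_id)] == "induced"
  list(assignments = asg,
       summary = list(n_peaks = nrow(asg), n_genes = length(ug),
                      median_distance = median(asg$distance, na.rm = TRUE),
                      n_induced = sum(ui),
                      pct_induced = .pct(sum(ui), length(ug))))
}
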