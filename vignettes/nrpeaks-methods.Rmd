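---
title: "Methods: peak annotation, repeat-element scanning and knockdown integration"
author: "nrpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, repeat-element scanning and knockdown integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrpeaks)
```

## The problem

Orphan nuclear receptors such as TR4 (NR2C2) bind hexameric half-sites —
AGGTCA, AGTTCA or AGAACA — arranged as direct (DR), everted (ER) or
inverted (IR) repeats separated by 0–8 spacer nucleotides. In
differentiating erythroid cells, where a ChIP'd factor of this family
binds relative to genes, which repeat grammar it prefers at promoters
versus distal sites, and how its knockdown propagates to expression are
the questions this package operationalizes. It provides five analysis
stages — peak annotation, repeat-element scanning, knockdown
differential-expression integration, conservation profiling with matched
backgrounds, and enhancer-mark co-localization — plus a seeded synthetic
data generator so every stage can be exercised against planted ground
truth with no external downloads.

## Coordinate conventions

All on-disk dialects are converted in the readers and nowhere else. BED
and refFlat are 0-based half-open, fixed-step WIG is 1-based; internally
everything is a 1-based closed `GRanges` (or a per-base `RleList` for
tracks), the native Bioconductor convention. Distances and band
classifications are differences of positions and therefore identical in
either convention. Interval centers use `start + floor(width/2)`: even
intervals have no exact midpoint, and the floor rule keeps the arithmetic
integral and matches BED-style center computation. Track positions absent
from a conservation file score 0, the UCSC convention for unscored bases.

## Peak annotation

Each peak is assigned to the gene with the *nearest TSS* (unsigned
distance from the peak center), then classified relative to that gene:

| class | band (signed TSS distance d, or TES distance e) |
|---|---|
| within_gene | center between TSS and TES, inclusive |
| promoter | d in [−2000, −1] |
| 5′ distal I | d in (−10000, −2000) |
| 5′ distal II | d in [−100000, −10000] |
| 3′ proximal | e in [1, 2000] |
| 3′ distal I | e in (2000, 10000) |
| 3′ distal II | e in [10000, 100000] |
| gene desert | min(|d|, |e|) > 100000, or no gene on the chromosome |

Signs are taken in the gene's orientation (upstream negative), so the
taxonomy is strand-antisymmetric: mirroring the genome and flipping all
strands leaves every class unchanged (a property test asserts this). The
source material does not state whether band edges are open or closed; the
edges above were chosen once so that the bands tile the integers exactly,
and d = 0 is `within_gene` because the promoter band starts strictly
upstream. Nearest-TSS ties break by smaller |TES distance| then
lexicographic gene id — deterministic and data-order-independent. The
*proximal promoter* flag (|d| ≤ 1 kb, restricted to promoter/within-gene
peaks) is deliberately orthogonal to the 2-kb promoter *class*: summary
figures use the 1-kb flag while the distribution table uses the 2-kb
band. Within-gene peaks are mapped to exon/intron indices counted 5′→3′
in the gene's orientation. When a gene has multiple isoforms in the
annotation, each row is treated as one assignable unit.

Reported percentages are integers rounded *half away from zero*
(`roundHalfAway()`), matching how such tables are conventionally printed
(e.g. 166/490 → 34); class percentages therefore sum to 100 ± 1.

## Repeat-element scanning

Peak windows are the 250 nt around the center, `[center−125, center+125)`.
The scanner is an explicit consensus-with-mismatches grammar rather than
an HMM: each half-site is matched against the closest member of
{AGGTCA, AGTTCA, AGAACA} (a flag restricts to AG(G/T)TCA), with at most
1 mismatch per half and 2 in total by default; positions containing N
never match. In window coordinates the families read

* DRn (+): `h1 · N^n · h2`; DRn (−): `rc(h2) · N^n · rc(h1)`
* IRn: `h1 · N^n · rc(h2)`; ERn: `rc(h1) · N^n · h2`

IR and ER instances coincide with their own reverse complements and are
reported once, on "+". The grammar is deterministic and brute-force
verifiable: the test suite checks equivalence against an independent
exhaustive enumerator on 100+ seeded random windows, reverse-complement
invariance of the call multiset, and monotonicity in the mismatch budget.

Per-peak summaries are *best-hit-exclusive*: each peak contributes one
element (minimal mismatches; ties break DR < IR < ER, then smaller
spacer, then leftmost, then "+"), or "none". This convention was chosen
because per-type percentages in this kind of analysis sum below 100 and
more than half of peaks typically carry no recognizable element; it is a
declared stand-in for the scoring of dedicated half-site HMM tools, whose
cutoff conventions are not published, and is validated against the
qualitative ordering (DR1 dominant proximally; DR4/ER6/IR1 enriched
distally). Spacer lengths 0–8 cover the general nuclear-receptor
convention rather than the narrower DR0–DR5 range reported for TR4
binding alone. Proximal-vs-distal frequency differences get a pooled
two-proportion z-test, two-sided, with a +0.5 continuity correction on
zero or saturated counts.

## Knockdown integration

The expression unit is FPKM; fold change is a pseudocount log-ratio
`(FPKM_kd + ε) / (FPKM_ctrl + ε)` with ε = 0.01 (config-exposed, since
the upstream convention leaves the pseudocount and input scale
unstated). A gene responds to one shRNA when fc ≥ 2 *or* fc ≤ 1/2
(symmetric, since both induced and repressed genes are called from one
rule) *and* max(FPKM_kd, FPKM_ctrl) ≥ 0.1; "expressed" means FPKM ≥ 0.1
in any of the three datasets. The negative-binomial machinery of
count-based DE packages is intentionally out of scope here — the cutoff
rule is defined on FPKM. The common set is the intersection of both
shRNA calls, partitioned exactly into induced / repressed / discordant
by post-knockdown sign. Because "induced after knockdown" means
"repressed by the factor", both vocabularies are carried in the output
(`direction`, `tr4_direction`) to prevent sign confusion.

The promoter-cohort shift test compares the cohort's log2 fold changes
against all expressed genes with a two-sided t-test; the flavor was an
open choice and defaults to Welch (a pooled-variance flag exists).
Distal peaks (>10 kb from the nearest gene) are reassigned to the
*nearest common-DE gene's TSS*, with the same tie-break as annotation,
and summarized as distinct-gene count, median distance and
induced-after-knockdown fraction.

## Conservation

Two window widths coexist deliberately: positional profiles use ±250 nt
(a 500-bp view around the center at offset 0), per-peak averages use
250 nt with a *fixed* denominator of 250 so unscored bases count as 0.
Each peak gets a GC- and length-matched random control from the same
chromosome: uniform random starts are drawn until GC matches within
±0.02 (the source convention says "same GC content" without a tolerance;
0.02 is two GC-units out of 250) and the control overlaps no peak
window. The exclusion is our addition — a control inside another peak
would contaminate the null — and is flag-reversible. After 1000 failed
draws the tolerance doubles, with a message, and the tolerance actually
in force is recorded per control; seeded runs are bit-exact. Peak versus
control mean scores are compared per stratum by Welch's t, with an
explicit t = 0, p = 1 branch when a constant track makes both groups
degenerate.

## Mark co-localization

A distal peak co-localizes with a mark when the peak interval extended
by ±2 kb intersects at least one mark interval, under half-open
semantics (a mark starting exactly at `end + 2000` does not count).
"±2 kb of the peak" was read as flanking the *interval* ("immediately
adjacent"); a `mode = "center"` flag flanks the center instead. Marks
are evaluated independently (rows are not exclusive) and an "any mark"
union row is appended, which is always ≥ the per-mark maximum.

## The synthetic-data generator

`simulateBundle()` emulates the downstream products of a
ChIP-seq + knockdown RNA-seq study of this design, with defaults fixed
at the early-differentiation study condition:

* **Genome**: 3 chromosomes × 2 Mb, GC 0.41. Background sequence is
  rejection-scrubbed of every *exact* half-site hexamer (forward or
  reverse complement). This is slightly stronger than removing complete
  exact elements: a surviving lone exact hexamer could pair with a
  planted exact half across a 0–8 nt gap and spoof a competing
  0-mismatch element, breaking best-element recovery. Residual ≥1-mismatch
  background hits remain — scrubbing at the full mismatch budget is
  infeasible at genome scale (~12,000 such elements per 2 Mb) and
  unrealistic — so genome-level motif frequencies carry a small
  background-call floor, which is why rate-recovery acceptance runs use
  the window-level generator below.
* **Genes**: 60 transcripts (2–8 exons) packed into the first ~55% of
  each chromosome with 25–45 kb gaps, leaving the remainder empty so
  gene deserts exist.
* **Peaks**: 180 peaks, widths 300–600 bp, placed so the planted class
  holds ≥1 bp inside its band *and* the planted gene is strictly the
  nearest TSS (placement rejection-samples until both hold; an
  unplaceable class raises an error naming it). The class mixture
  (13% promoter, 32% within gene, 48% >10 kb from genes, 20% desert)
  reproduces the early-stage condition: 45% promoter+gene body and the
  published distal fractions. 60% of within-gene peaks sit within 1 kb
  of the TSS, giving a ~25% proximal-promoter fraction. Distal peaks
  keep ≥12 kb mutual separation so a planted mark can never leak into a
  neighboring flank; all peaks keep ≥700 bp so windows never overlap.
  Enrichment decays with TSS distance,
  `(5 + 45·exp(−|d|/20 kb)) × lognormal(σ=0.3)`.
* **Motifs**: planted per stratum at the published proximal/distal rates
  (DR1 0.28/0.08, DR4 0.03/0.16, ER6 0.03/0.11, IR1 0.08/0.16; an
  intermediate "other" stratum at all-peaks-like rates), as
  exact-consensus elements centered on the peak, DR1 spacers biased to
  A/G (the enriched variant in vivo). An element whose spacer or
  straddle accidentally forms a stray exact hexamer is redrawn, so the
  planted element is provably each window's unique 0-mismatch call.
* **Conservation**: truncated Gaussian bumps at peak centers (sd 60 bp,
  height 0.50/0.35/0.42 for proximal/distal/other strata — proximal
  most conserved, as observed) over a zero background, ±0.02 uniform
  noise, scores clamped to [0, 1] and rounded to 3 decimals for exact
  bedGraph round trips.
* **Expression**: control FPKM log-normal(0, 1.5); 15% of genes planted
  responsive to both shRNAs and 4.5% to each alone (≈76% concordance, as
  published), fold change 4 (reciprocal for the repressed class) with
  multiplicative log-normal σ = 0.1 noise, induced:repressed 80:20,
  responsive genes forced to control FPKM ≥ 1; non-responsive fold
  changes inside [1/1.2, 1.2]. Under these conditions the double cutoff
  recovers planted calls with sensitivity ≥ 0.99 and FPR ≤ 0.01.
* **Marks**: per-mark fractions of distal peaks (0.06/0.07/0.12/0.34 for
  P300/H3K27ac/H3K4me1/H3K27me3, the early-stage co-localization rates)
  receive a 500-bp interval inside their flank; background intervals are
  kept clear of every distal flank.

Everything funnels through one seeded RNG: a (config, seed) pair
reproduces the bundle bit-exactly, on disk too. `verifyTruth()` re-derives
every planted fact from the written files and localizes injected faults
to single failing facts. `simMotifWindows()` is the window-level
generator for motif-rate recovery; its background is rejection-sampled
against the scanner's *full* mismatch budget (see the scrub discussion
above) so planted rates are the only signal, making recovered
frequencies fall inside binomial confidence intervals at n = 500 per
stratum.

**What the generator does not emulate**: read-level noise and peak-caller
artifacts (fragment pileup shapes, duplicate reads), realistic
half-site degeneracy (planted elements are exact consensus),
inter-gene expression correlation, chromatin-state spatial
autocorrelation, assembly gaps and repeats. Passing recovery tests
therefore demonstrates the correctness of the analysis logic under the
declared generative model, not robustness to every artifact of real
sequencing data.

## Numerical and testing choices

Percentages round half away from zero throughout. The two-proportion z
uses the pooled standard error and is cross-checked against
`prop.test(correct = FALSE)`. The cohort shift test's null calibration
is checked by simulation (1000 seeded replicates; KS test against
uniform at α = 0.01) and its power at a −0.5 log2 shift, n = 130 versus
15,000 background genes at σ = 1, exceeds 95% at p < 0.01 — the
simulated analogue of the published cohort comparison. Problem sizes in
the test and acceptance suites (default bundle 3 × 2 Mb / 180 peaks,
500 windows per motif stratum, 40 conservation replicates, 1000
expression tables) were chosen once so the full loop completes in
minutes on a laptop while keeping every statistical check well-powered.

## Known limitations

* The nearest-TSS rule assigns exactly one gene per peak; peaks inside a
  non-nearest gene's body are still classified relative to the
  nearest-TSS gene (declared convention).
* Best-hit-exclusive motif percentages are not comparable to
  all-hits-per-peak reporting conventions.
* The DE rule applies no multiple-testing correction (none exists in the
  upstream convention it reproduces); it is a cutoff classifier, not an
  inference procedure.
* bigWig/BAM ingestion, liftOver and GTF parsing are out of scope;
  conservation tracks must fit in memory as per-chromosome runs.
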