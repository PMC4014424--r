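# nrpeaks

Downstream analysis of nuclear-receptor ChIP-seq peak calls in a
differentiating cell system, for genomicists who have peak calls, gene
models, expression tables and conservation tracks in hand and want the
standard post-peak-calling questions answered reproducibly:

* **Where does the factor bind?** Each peak is assigned to the gene with
  the nearest transcription start site (TSS) and classified into a
  promoter / 5′–3′ distal / within-gene / gene-desert taxonomy, with
  TSS-centered and distance histograms and a proximal-promoter
  (±1 kb) fraction.
* **What repeat grammar does it bind?** Nuclear receptors recognize the
  hexameric half-sites AGGTCA / AGTTCA / AGAACA arranged as direct,
  everted or inverted repeats (DRn/ERn/IRn) with spacers n = 0…8. A
  deterministic consensus-with-mismatches scanner (≤1 mismatch per
  half-site, ≤2 total, configurable) scans the 250 nt around each peak
  center, reports each peak's single best element, and compares
  per-motif frequencies between proximal and distal peak strata with
  two-proportion z-tests.
* **Which genes respond to knockdown?** Two independent shRNA
  knockdowns against one control are integrated with the double cutoff
  fold change ≥ 2 (symmetric) and FPKM ≥ 0.1, using a pseudocount
  log-ratio `(FPKM_kd + ε)/(FPKM_ctrl + ε)`; the two call sets are
  intersected, split into induced/repressed after knockdown, the
  promoter-bound cohort's fold-change shift is tested against all
  expressed genes (Welch t), and distal peaks are reassigned to the
  nearest differentially expressed gene.
* **Are distal sites conserved and enhancer-like?** Positional
  per-base conservation profiles around peak centers, per-peak mean
  scores over a fixed 250-bp denominator, GC- and length-matched random
  genomic controls, and co-localization counts of distal peaks (±2 kb
  flanks, half-open overlap) with enhancer marks (P300, H3K27ac,
  H3K4me1, H3K27me3).

A seeded synthetic-data generator (`simulateBundle()`) produces a
complete ground-truthed input bundle — genome FASTA, refFlat gene
models, BED peaks with planted region classes and planted repeat
elements, a bedGraph conservation track with bumps under peak centers,
an expression table with planted knockdown responses, and mark interval
sets — so the whole pipeline closes the loop against known truth with no
downloads. `verifyTruth()` re-derives every planted fact from the
written files.

## Worked example

```r
library(nrpeaks)

bundle <- simulateBundle(simConfig(), seed = 1)
bundle
#> SimBundle object
#>   genome : 3 chromosome(s), 6,000,000 bp total
#>   genes  : 60 gene model(s)
#>   peaks  : 180 peak(s)
#>   track  : 3 chromosome(s) covered
#>   expr   : 60 gene(s) x 3 conditions
#>   marks  : P300, H3K27ac, H3K4me1, H3K27me3
#>   seed   : 1

report <- runPipeline(bundle = bundle, seed = 1)
report$region_distribution
#>            region_class count percent
#> 1              promoter    23      13
#> 2   five_prime_distal_I     7       4
#> 3  five_prime_distal_II    32      18
#> 4           within_gene    58      32
#> 5  three_prime_proximal     4       2
#> 6  three_prime_distal_I     2       1
#> 7 three_prime_distal_II    18      10
#> 8           gene_desert    36      20
```

49/180 peaks (27%) sit in the proximal promoter (±1 kb of a TSS) and
86/180 (48%) lie more than 10 kb from the nearest gene — the planted
mixture recovered exactly (every peak's recovered class equals its
planted class). The proximal-vs-distal motif comparison shows the
planted reversal, DR1 depleted distally and DR4/ER6/IR1 enriched:

```r
report$motif_comparison[report$motif_comparison$motif %in%
                          c("DR1", "DR4", "ER6", "IR1"), ]
#>  motif   p_a   p_b  delta     z p_value
#>    DR1 0.347 0.140 -0.207 -2.82  0.0048
#>    DR4 0.102 0.209  0.107  1.59  0.1109
#>    IR1 0.082 0.163  0.081  1.33  0.1822
#>    ER6 0.020 0.105  0.084  1.80  0.0723
```

(`p_a` proximal, `p_b` distal; at this bundle's n of 49 vs 86 peaks only
the largest difference is individually significant — the n = 500
recovery runs in the test suite resolve all four.) Conservation bumps
planted under peak centers beat their GC-matched random controls in
every stratum (mean peak score ≈ 0.29/0.20 proximal/distal vs ≈ 0 for
controls), and the mark table recovers the planted overlap fractions:

```r
report$marks
#>      mark n_overlapping n_total percent
#>      P300             5      86       6
#>   H3K27ac             6      86       7
#>   H3K4me1            10      86      12
#>  H3K27me3            29      86      34
#>       any            40      86      47
```

`runPipeline(..., outDir = "out")` additionally writes per-stage TSVs
and a consolidated `report.json` in which every percentage carries its
numerator and denominator. To run on your own data, write the inputs in
the bundle layout (`genome.fa`, `genes.refflat`, `peaks.bed`,
`conservation.bedgraph`, `expression.tsv`, `marks_<name>.bed`) and use
`runPipeline(dir = ...)`, or call the stage functions
(`annotatePeaks()`, `scanPeaks()`, `callDE()`,
`conservationComparison()`, `multiMarkSummary()`) directly. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

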