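# spliceCascade

Detection of differentially alternatively spliced (DAS) exon candidates from
probeset-level exon-array data over a differentiation time course.

Exon arrays (e.g. the GeneChip Exon 1.0 ST design) measure one summarized
intensity per probeset, with each probeset approximating one exon, alongside
a gene-level intensity summarized over the whole transcript. A change in
exon usage — rather than a change in overall gene expression — shows up as a
change in the **normalized intensity**

    NI = probeset intensity / gene intensity,

and is scored per probeset by the **splicing index**

    SI_t = log2( mean_r NI_t,r / mean_r NI_d0,r ),

the log2 ratio of the replicate-averaged NI at timepoint *t* (day 7 or day
10 of neuronal differentiation) over day 0. Most probesets interrogate
constitutive exons and sit near SI = 0; a large |SI_d7| flags a candidate
alternative exon.

`spliceCascade` implements the full candidate-extraction procedure as a
nine-stage filter cascade over all annotated probesets, with a per-stage
audit of surviving probeset and gene counts:

1. remove the first and last probeset of each gene (outermost probesets
   often lie on potential exons outside the gene body);
2. remove probesets whose target-sequence length is ≥ 500 nt (mostly UTRs);
3. remove probesets flagged for cross-hybridization;
4. keep genes "expressed" on both day 0 and day 7 (≥ 50% of a gene's
   probesets with DABG *p* ≤ 0.05 in both replicates);
5. keep probesets detected (DABG *p* ≤ 0.05, both replicates) on day 0 or 7;
6. keep probesets with |SI_d7| ≥ 1.35 (a 2.55-fold NI change);
7. remove a probeset when all of its nearest detectable neighbor probesets
   changed too (|SI_d7| ≥ 0.667) — a surviving probeset marks a border
   between alternative and constitutive exons;
8. keep probesets predicted *alternative* against transcript models (exon
   contained in one transcript, absent or truncated in another), with the
   event type called: exon skip, alternative 5′/3′ splice site, retained
   intron, mutually exclusive exons, alternative promoter/terminator;
9. keep probesets whose day-7 effect exceeds the day-10 effect (or strongly
   reverses sign), isolating neuronal-stage-specific events.

Candidates are labeled DAS-up or DAS-down by the sign of SI_d7. The package
also classifies gene-level trajectories (DEX-up: 2–10-fold rise to day 7
then decrease; DEX-down mirrored), scores semiquantitative RT-PCR
densitometry validation experiments (−/+/++ by the fold change of the
alternative product's relative amount), and ships a synthetic-data
generator that fabricates annotation, transcript models, intensities and
DABG p-values with embedded ground-truth DAS exons, so the whole cascade is
testable end to end without array data.

## Worked example

```r
library(spliceCascade)

ds  <- simulate_dataset(sim_config(n_genes = 200, seed = 3))
res <- run_cascade(ds$annotation, ds$panel, ds$models)
res
#> DAS extraction cascade: 1727 probesets -> 24 candidates in 20 genes
#>  stage                                                 description n_probesets n_genes
#>      0                                            input probesets        1727     200
#>      1                     remove first/last probeset of each gene        1327     200
#>      2              remove probesets with sequence length >= 500 nt       1260     200
#>      3                          remove cross-hybridizing probesets        1199     200
#>      4                keep genes expressed on both day 0 and day 7        1134     188
#>      5                   keep probesets detected on day 0 or day 7        1129     188
#>      6                                        keep |si_d7| >= 1.35          30      20
#>      7  remove probesets whose detectable neighbors all changed ...          24      20
#>      8  keep probesets predicted alternative against transcript ...          24      20
#>      9            keep probesets whose day-7 effect exceeds day 10          24      20

head(res$candidates, 3)[, c("probeset_id", "si_d7", "as_types", "das_direction")]
#>   probeset_id     si_d7  as_types das_direction
#> 1 g00005_ps03 -2.175958 exon_skip          down
#> 2 g00020_ps04  2.097891 exon_skip            up
#> 3 g00036_ps05 -1.992480 exon_skip          down

evaluate_recovery(res$candidates$probeset_id, ds$truth,
                  ds$annotation$probeset_id)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 0.8
#> $precision
#> [1] 1
```

The audit shows where probesets fall: the annotation filters (1–3) trim
terminal, long and cross-hybridizing probesets; the expression gates (4–5)
drop genes/probesets without reliable signal; the splicing-index threshold
(6) does most of the work; and stages 7–9 remove border artifacts,
constitutive exons and non-specific (non-day-7) changes. Here 24 of the 30
embedded cassette-exon probesets are recovered with no false positives.

The losses are the neighbor rule working as designed: when a cassette exon
carries two probesets and its flanking exon's only probeset was already
removed as a terminal probeset, one of the pair sees a single detectable
neighbor — the other changed cassette probeset — and is removed at stage 7.
Recovery is per probeset; per gene all embedded events remain represented
(20 of 20 DAS genes here).

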