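---
title: "Extracting differentially alternatively spliced exons with spliceCascade"
author: "spliceCascade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting differentially alternatively spliced exons with spliceCascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceCascade)
```

## The model

Exon arrays summarize two intensities: one per probeset (approximating one
exon) and one per gene. During a differentiation time course — here day 0
(undifferentiated), day 7 (neuronal) and day 10 (early glial), each with
two biological replicates — a change in overall gene expression moves both
quantities together, while a change in *exon usage* moves a probeset
relative to its gene. The normalized intensity of probeset $p$ of gene $g$
in replicate $r$ at timepoint $t$,

$$\mathrm{NI}_{p,t,r} = \frac{I_{p,t,r}}{I_{g,t,r}},$$

cancels gene-level change. The splicing index compares replicate-averaged
NIs between a timepoint and day 0 on the log2 scale:

$$\mathrm{SI}_{t}(p) = \log_2
  \frac{\overline{\mathrm{NI}}_{p,t}}{\overline{\mathrm{NI}}_{p,d0}}.$$

The ratio is formed per replicate and then averaged ("averaged NIs"), not
the other way round; with duplicate arrays the two orders differ, and the
per-replicate ratio keeps each array's probeset/gene pairing intact. The
A-value — the x-axis of the SI–A scatter of all scored probesets — is the
mean of $\log_2 I_{p,t,r}$ over the four day-0/day-7 cells, the MA-plot
convention. (Whether the original screen averaged log or linear
intensities for its A-value is not derivable from its one-line definition;
the pooled log2 mean is this package's choice and only affects a display
axis, never a filter.)

Undefined quantities are never smoothed away: there are no pseudocounts.
A probeset whose NI or A-value is undefined at day 0/7 is itemized with a
reason by `score_all()` rather than scored, because the detection filters
below are the pipeline's own mechanism for removing unreliable signal. For
the same reason the panel constructor tolerates a zero gene intensity
instead of refusing it: such probesets must reach the scorer to be
itemized.

## The nine-stage cascade

`run_cascade()` applies nine filters in a fixed order and audits surviving
probeset and gene counts after every stage; survivor sets are nested by
construction and each single filter is idempotent. The thresholds live in
`cascade_config()`:

| parameter            | default | units      | role |
|----------------------|---------|------------|------|
| `si_threshold`       | 1.35    | log2 NI    | stage 6 keep bound (2.55-fold); also the stage-9 reversal bound |
| `neighbor_threshold` | 0.667   | log2 NI    | stage 7 neighbor "changed" bound |
| `dabg_alpha`         | 0.05    | p-value    | detection cutoff, inclusive, both replicates |
| `max_seq_length`     | 500     | nt         | stage 2 bound, exclusive |
| `expressed_fraction` | 0.5     | proportion | detected-probeset fraction for a gene to count expressed |

Decisions that the rules' prose leaves open, resolved here once:

* **Stage 1 ties and reference set.** All probesets sharing a gene's
  extreme (minimum or maximum) start coordinate are removed — the
  conservative reading — and the extremes are computed from the full
  annotation rather than the current survivor set. The latter matters:
  extremes recomputed from survivors would strip a new outermost layer on
  every application, and the filter would not be idempotent. Genomic start
  is used on both strands; the array's probeset identifiers are laid out
  in genomic order, and nothing downstream depends on transcription-order
  numbering here.
* **Stage 2 boundary.** A length of exactly 500 nt is removed: the keep
  condition is `< 500`.
* **Stages 4–5 detection.** "Detected" always means DABG $p \le 0.05$ in
  *both* biological replicates, applied uniformly to the exon-level gate
  and to the gene-expressed fraction. A one-replicate reading of the
  exon-level gate would be laxer; using one rule everywhere keeps the two
  gates consistent. The gene-expressed denominator is all annotated
  probesets of the gene, pre-cascade: the expressed-gene definition exists
  independently of the filtering.
* **Stage 6/9 boundaries.** $|SI_{d7}| \ge 1.35$ is inclusive. Stage 9
  keeps a probeset when $|SI_{d7}| > |SI_{d10}|$ (strict) or when the
  effect strongly reverses sign ($SI_{d7} < 0$ with $SI_{d10} \ge 1.35$,
  or mirrored) — both patterns mark a neuronal-stage-specific event rather
  than a monotone drift into the glial stage. A probeset whose day-10 SI
  is undefined cannot satisfy either clause and is removed with a logged
  reason.
* **Stage 7 search space and boundaries.** Neighbors are searched among
  the gene's probesets that survived stages 1–3 *and* are detectable — not
  among stage-6 survivors, where every remaining probeset has a large SI
  and no unchanged neighbor could ever exist. The nearest detectable
  probeset on each side (by start; ties broken by probeset id) is the
  neighbor; $|SI_{d7}| \ge 0.667$ counts as changed (the boundary value
  counts as changed), a neighbor with undefined SI counts as unchanged (no
  evidence), and a probeset with no detectable neighbor at all is kept.
  Removal requires *every* existing neighbor to have changed; requiring
  both sides to be unchanged instead would discard complex events where
  consecutive exons change together.
* **Stage 8 substrate.** The original screen predicted alternative exons
  by aligning probeset sequences against transcript/EST evidence (blat and
  BLAST) with manual curation of contradictions. That evidence base is not
  reconstructible; `spliceCascade` substitutes a user-supplied GTF of
  transcript models and the annotation-based classifier below. This is
  the package's largest substitution, and absolute survivor counts at this
  stage are therefore not comparable with the original screen's. Probesets
  of genes with no transcript model cannot be predicted and are removed
  with a logged reason.

Candidates are labeled DAS-up when $SI_{d7} \ge$ `si_threshold`, DAS-down
when $\le -$`si_threshold`; after stage 6 every survivor satisfies one of
the two.

## The event-type classifier

`classify_probeset_splicing()` calls a probeset *alternative* when its
interval is contained in an exon of at least one transcript of its gene
and absent from (or only partially overlapping) at least one other. Event
types are then read off the geometry of the containing exon against each
excluding transcript:

* **exon_skip** — the containing exon overlaps no exon of the other
  transcript while its flanking exons (where they exist) are present
  there with identical coordinates;
* **mutually_exclusive** — exon_skip holds in both directions for a
  non-overlapping exon pair;
* **alt_5ss / alt_3ss** — an exon of the other transcript shares exactly
  one boundary with the containing exon. Naming follows the donor/acceptor
  convention: the 5′ splice site is the donor at the transcription-order
  end of the exon (genomic right on `+`, genomic left on `-`), so a
  shifted genomic-right boundary is `alt_5ss` on `+` and `alt_3ss` on `-`;
* **retained_intron** — the containing exon spans an intron of the other
  transcript, i.e. both exons flanking that intron fall within the
  containing exon's span;
* **alt_promoter / alt_terminator** — the containing exon is the
  transcript's first/last exon in transcription order and the other
  transcript's corresponding terminal exon does not overlap it.

Two symmetries pin the conventions down and are enforced by tests:
mirroring all coordinates while flipping strand is the same gene seen from
the opposite strand, and leaves every call unchanged; mirroring *without*
the strand flip swaps `alt_5ss` with `alt_3ss` and `alt_promoter` with
`alt_terminator` while fixing the strand-free types.

A complex pattern can satisfy the presence rule without matching any named
geometry (e.g. a skipped exon whose flanks are themselves shifted). Such
calls fall back to `exon_skip`, the coarsest inclusion/exclusion label, so
that an alternative verdict always carries at least one type and the
verdict itself remains exactly the presence rule — which is also what the
brute-force oracle in the test suite recomputes. Multi-type probesets are
kept as sets; `summarize_as_types()` attributes a probeset with $k$ types
at $1/k$ per type, so the composition percentages sum to 100.

## Gene-level classes and RT-PCR validation

`classify_dex()` is purely ratio-based: DEX-up requires a 2- to 10-fold
(inclusive) rise from day 0 to day 7 and a strict decrease to day 10,
DEX-down the mirror image; equality at day 10 is `none`, and the class is
only assigned to genes expressed on day 0 or day 7. The 10-fold cap
excludes on/off artifacts.

`classify_validation()` reproduces the densitometry-based three-way call
on the fold change of the alternative product's relative amount at day 7:
below 2-fold (or a day-10 change exceeding day 7) is `minus`, above
10-fold is `plusplus`, in between `plus`. The published rule's strict
inequalities leave folds of exactly 2 and exactly 10 unassigned; both are
mapped to `plus`, which cannot disturb the published class counts because
no printed fold sits on a boundary. On the packaged panel of 30 published
folds this yields 4/16/10 (minus/plus/plusplus) and a validation rate of
26/30 = 86.7%, reported as 87 after rounding half-up.

## The synthetic-data generator

`simulate_dataset()` fabricates everything the cascade consumes, with
known ground truth. Its structure mirrors the quantity the detector
thresholds: effects are injected on NI, not on raw intensity.

* Gene intensity = baseline × trajectory × log-normal noise. Baselines are
  log-normal (median 100, $\sigma_{\log} = 1.5$), a realistic array
  dynamic range that leaves a small tail of undetectable genes for the
  expression gates to remove. DEX trajectories rise (or fall) 2.5–8-fold
  to day 7 and partially revert.
* Probeset intensity = gene intensity × probeset affinity × NI
  multiplier × log-normal noise. The NI multiplier is 1 everywhere for
  constitutive probesets; probesets on a true DAS exon shift by
  $2^{\pm\delta}$ at day 7 (default $\delta = 2$ log2 units) with 30% of
  the effect retained at day 10 — large enough to clear the 1.35 threshold
  reliably at the default noise level, and the day-10 retention below 1
  guarantees the stage-9 comparison holds in expectation.
* Noise is multiplicative log-normal with unit mean and CV `noise_cv`
  (default 0.1, a typical replicate-level CV for summarized array
  signals); `noise_cv = 0` reproduces every SI exactly.
* DABG p-values are simulated directly (the package never sees background
  probes): Uniform(0, 0.01) when the noise-free signal is at or above
  `detect_floor`, Uniform(0.1, 1) otherwise, keeping the 0.05 cutoff
  meaningful in both regimes.
* Every DAS gene carries a full transcript plus one skipping the
  alternative (internal) exon, so stage 8 can rediscover the event;
  constitutive genes get one or two identical-structure transcripts, which
  the classifier correctly refuses to call alternative. Terminal probesets
  exist in every gene by construction, and configured fractions of
  *non-DAS* probesets are flagged cross-hybridizing or long so stages 1–3
  have work to do. DAS probesets are exempt from those flags — the
  generator's contract is that its embedded truth is recoverable, and a
  flagged truth probeset would be undetectable by design.
* The whole dataset is a deterministic function of the configuration,
  including its seed; identical configurations write byte-identical files.

What the generator does **not** emulate: probe-level summarization
artifacts, correlated noise between probesets of one exon,
cross-hybridization *signal* (only the flag), partial isoform mixtures
(the NI shift is a step, not a dosage), non-cassette true events, and
annotation error. Passing the recovery tests therefore demonstrates that
the cascade's logic is faithful and self-consistent, not that its
sensitivity/precision transfer to real arrays.

In the standard evaluation regime (500 genes, 10% DAS, $\delta = 2$, CV
0.1) the cascade recovers embedded events with sensitivity ≥ 0.85 and
precision ≥ 0.8; observed runs sit near 0.9 and 1.0. The main loss mode is
the neighbor rule removing one of two co-changed probesets on the same
cassette exon when the flanking exon contributes no detectable neighbor —
per gene, events remain represented.

## Numerical and interface choices

* Coordinates are 1-based inclusive end to end, the R/Bioconductor
  convention shared by the external formats (GTF, annotation tables), so
  readers and writers perform no conversion and interval arithmetic
  follows IRanges semantics.
* GTF reading/writing goes through `rtracklayer`; only `exon` features are
  consulted. Overlapping exons within a transcript are an error;
  transcripts that appear without exon features are skipped with a
  warning.
* Tables are tab-delimited (the annotation reader also sniffs commas);
  numeric columns are written via `%.17g` so write/read round trips are
  bit-exact.
* Problem sizes in the test suite are deliberately small — datasets of
  15–60 genes for rule-level and oracle checks, 200 for effect-size
  calibration, one 500-gene run for recovery, and 500 random gene models
  for classifier/oracle equivalence — enough for every property to be
  exercised at tight tolerances while the whole suite runs in well under a
  minute.

## Known limitations

* The published screen's absolute per-stage counts (221,336 input
  probesets down to 262 candidates) are not reproducible from this
  package: they depend on the original CEL files, PLIER/Iter-PLIER
  summarization, the array's core annotation release, and a
  contemporaneous transcript/EST evidence base with manual curation. The
  packaged copy of those counts supports derived summaries (e.g. 309/1107
  = 27.9% predicted alternative at stage 8), not re-derivation.
* Stage 8 is only as good as the supplied GTF: events absent from the
  transcript models are invisible, and the manual-curation step of the
  original procedure is not modeled.
* The cascade is a deterministic rule set, not a statistical test: no
  variance model, no multiple-testing control. That is faithful to the
  procedure it implements; probesets near any boundary flip with noise.
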