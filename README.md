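# splicescape

Alternative-splicing event detection and differential-splicing analysis
for replicated two-condition transcriptome studies, in base R.

Transcript assemblers produce, per gene, a set of isoforms whose exon
structures differ at localized variable regions. splicescape classifies
those regions into the four basic alternative-splicing (AS) event types —
intron retention (IR), exon skipping (ES), alternative acceptor (AA) and
alternative donor (AD), with complex combinations collected as *other* —
and tests each event for condition-dependent changes in isoform usage.
It was built around a salt-stress study layout (root/leaf x control/salt
x five timepoints x two replicates, FPKM isoform abundances), but any
comparable replicated design fits.

The pipeline, stage by stage:

1. **Transcript models** (`read_gtf`, `gene_models`) — validated
   1-based exon/intron structures from a GTF.
2. **Expression** (`calibrate_cutoff`, `filter_isoforms`) — an empirical
   FPKM cutoff chosen where the false-positive curve of decoy transcripts
   crosses the false-negative curve of known ones; isoforms retained only
   when both biological replicates reach the cutoff at some timepoint.
3. **Event catalog** (`classify_pair`, `build_catalog`) — pairwise
   splice-chain comparison: variable regions between consecutive shared
   splice sites are typed strand-aware (the donor is the 5' intron end in
   transcription direction), deduplicated gene-wide, and flagged per
   sample group.
4. **Differential splicing** (`das_test`, `das_scan`, `change_frequency`)
   — per event, tissue and timepoint, a two-sided Fisher exact test on
   the 2x2 table [constitutive, alternative] x [control, salt] of
   rounded, replicate-averaged FPKM sums, plus the change frequency
   Δψ = (alt/total)_salt − (alt/total)_control in [−1, 1].
5. **Characterisation** (`frame_class`, `frame_spectrum`,
   `length_histogram`, `compare_lengths`, `overlap_summary`,
   `specificity_test`, `term_enrichment`) — reading-frame classes
   (length mod 3: AS_0/AS_1/AS_2), length distributions against
   genome-wide exon/intron baselines, Venn-style group overlaps, and
   generic Fisher+BH term enrichment.
6. **Synthetic truth** (`simulation_config`, `simulate_splicing`,
   `evaluate_recovery`) — a deterministic generator that injects known
   events and usage shifts so every stage can be scored against ground
   truth.

See `vignettes/splicescape-methods.Rmd` for the model, its assumptions
and the design decisions.

## Worked example

Simulate a 200-gene transcriptome with injected events, run the full
pipeline at the 2.6 FPKM cutoff, and score recovery:

```r
library(splicescape)
cf  <- simulation_config(n_genes = 200, seed = 7,
                         abund_meanlog = log(30), abund_sdlog = 1.0)
sim <- simulate_splicing(cf, dir = "simdir")
res <- run_pipeline(sim$paths$gtf, sim$paths$expression, "simdir/out")
catalog_summary(res$catalog)$by_type
```

```
   type events event_rate_pct genes gene_rate_pct as_per_gene
1    IR     40          30.30    36         39.56        1.11
2    ES     10           7.58     9          9.89        1.11
3    AA     36          27.27    35         38.46        1.03
4    AD     18          13.64    17         18.68        1.06
5 other     28          21.21    26         28.57        1.08
6 Total    132         100.00    91        135.16        1.45
```

132 deduplicated events were found in 91 genes; `event_rate_pct` is each
type's share of events, `gene_rate_pct` the share of AS genes carrying
that type (a gene may carry several types, so the total exceeds 100%),
and `as_per_gene` the events-per-gene ratio within a type. Scoring
against the generator's truth:

```r
truth <- jsonlite::fromJSON(sim$paths$truth)
evaluate_recovery(truth, res$catalog, res$das, res$filter)$by_type
```

```
   type truth_events matched    recall catalog_events precision
1    IR           40      40 1.0000000             40 1.0000000
2    AD           17      17 1.0000000             18 0.9444444
3 other           22      21 0.9545455             28 0.7500000
4    AA           35      35 1.0000000             36 0.9722222
5    ES           10      10 1.0000000             10 1.0000000
```

All injected basic-type events are recovered with exact labels; one
composite event is missed because its isoform falls below the expression
filter at this abundance level, and the extra catalog entries are real
pairwise consequences of comparing two derived isoforms with each other
(composites and cross-pair retentions), which is why precision for
*other* sits below 1.

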