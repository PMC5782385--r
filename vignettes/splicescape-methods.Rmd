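---
title: "Detecting and testing alternative splicing events with splicescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and testing alternative splicing events with splicescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

## The problem

A gene with several annotated isoforms differs between them at specific
variable regions: an intron retained in one isoform and spliced in another
(IR), an internal exon present in one and skipped in the other (ES), or a
shared intron whose 3' or 5' boundary moves by a few bases (alternative
acceptor, AA, and alternative donor, AD). Stress treatments can shift the
relative abundance of the isoforms on the two sides of such an event:
differential alternative splicing (DAS). splicescape implements the full
desk-side analysis for a replicated two-condition transcriptome study of
this kind: it reads assembled transcript models (GTF) and an isoform
FPKM table, calibrates an expression cutoff against decoy transcripts,
filters isoforms by replicate-concordant expression, detects and
classifies AS events, tests each event for a condition-dependent usage
shift, and summarises event types, lengths, reading-frame classes and
group overlaps. A synthetic-data generator with recorded ground truth
makes every stage testable without any external data.

The package is organised around the study design it was built for: two
tissues (root, leaf) x two conditions (control, salt) x five timepoints
(12-144 h) x two biological replicates, i.e. 40 libraries, pooled into
four groups RC/RS/LC/LS (tissue x condition).

## Event detection

Two isoforms of a gene are compared over their mutual span. The splice
chain of each isoform is its ordered set of intron boundaries; boundaries
present in both chains are *common splice sites*. Positions where the two
isoforms' exonic coverage differs are grouped into *bubbles*: maximal
variable regions between consecutive common splice sites, with virtual
anchors at the mutual-span boundaries. Each bubble is matched against the
four basic patterns:

* **IR** — one chain contributes exactly one intron and the other isoform
  is exonic across it; length = retained intron length.
* **ES** — one chain contributes complete exons strictly inside a single
  intron of the other isoform, so the outer splice sites of the flanking
  introns are shared; length = summed skipped-exon length.
* **AA / AD** — both chains contribute exactly one boundary of the same
  kind at different positions, the opposite intron boundary being shared;
  length = boundary shift in bp. Donor and acceptor are assigned
  strand-aware: the donor is the 5' intron end in transcription direction,
  so on the minus strand the genomic right intron edge is the donor.

Anything else — several retained introns in one bubble, mutually exclusive
exons, boundary shifts on both intron edges — is a combined pattern and
classified **other**. Variable regions that touch the mutual-span boundary
reflect differing transcript starts or ends; those are transcription, not
splicing, and are never emitted. The `inclusion` isoforms of an event are
the ones carrying the variant region as exonic sequence (the
intron-retaining, exon-including, shorter-intron side); the `exclusion`
isoforms splice it out.

`build_catalog()` applies `classify_pair()` to every isoform pair of every
gene and deduplicates events on (gene, type, region, flanks), merging the
isoform sets; a gene can therefore carry several events of one type at
different positions, and complex multi-isoform structures resolve into the
pairwise events plus "other" composites. An event is flagged present in a
group when at least one inclusion and one exclusion isoform pass the
expression filter in that group. Pairwise comparison with post-hoc
deduplication reproduces basic-type pair granularity without a full
multi-way bubble grammar; the cost is that composite regions are a
catch-all whose sub-structure is not typed further.

The classifier is verified against an independent per-base oracle (coverage
vectors, run-length encoding, direct per-base predicates) on an exhaustive
sweep of random small gene structures; the test suite runs 10,000 such
cases.

## Expression handling

**Abundance cutoff.** `calibrate_cutoff()` scans candidate cutoffs (default
1-10 FPKM in steps of 0.1, matching the one-decimal resolution at which
such cutoffs are conventionally reported) and computes, per cutoff, the
false negative rate (known isoforms with positive expression whose maximum
FPKM over all libraries falls below it) and the false positive rate (decoy
isoforms whose maximum reaches it). The chosen cutoff is the smallest grid
value where the FP curve drops to or below the FN curve. The crossing rule
is one defensible reading of the empirical-threshold idea; both curves are
returned so users can apply a different rule. Decoys are intergenic
single-exon transcripts quantified like real isoforms; the generator emits
them with near-zero exponential abundance.

**Replicate-concordant filtering.** `filter_isoforms()` retains an isoform
in a group if there is at least one timepoint of that group at which
*both* replicates reach the cutoff — the strictest reading of requiring
detection in each biological replicate; averaging replicates or accepting
either replicate would admit isoforms seen only once. Retention overall
means retention in at least one group. Raising the cutoff can only shrink
the retained set (tested as a property).

## Differential splicing

For an event in one sample context (tissue, condition, timepoint), FPKM is
averaged over the two replicates and summed over the inclusion isoforms
("alternative" side), the exclusion isoforms ("constitutive" side) and all
isoforms of the gene ("total"). `das_test()` builds the 2x2 table
[constitutive, alternative] x [control, salt] and applies a two-sided
Fisher exact test at alpha = 0.05.

Fisher's test requires integer counts, but the measured quantities are
FPKM. The package takes the minimal-transformation reading: sum, average
over replicates, round half-up to integers. This is a pragmatic device,
not a sampling model: when true FPKMs are large and replicate noise is
multiplicative, the rounded values are overdispersed relative to the
hypergeometric null, and the test can be strongly anticonservative; when
most FPKMs are below 1, it is ultraconservative. The generator's
`noise_model = "poisson"` option draws each cell as a Poisson count, the
regime in which the test is exactly calibrated; the type-I and power
properties in the test suite are established there, and the vignette's
advice for real data is to treat per-event p-values as a ranking device,
as the original design does. No multiple-testing correction is applied to
the event-level test (the significance rule is a raw p < 0.05);
`term_enrichment()`, by contrast, reports Benjamini-Hochberg FDR because
it tests many terms jointly.

Tests are run per timepoint with matched tissue; an event is DAS in a
tissue if significant at one or more timepoints (`das_rollup()`). The
**change frequency** of an event,

$$\Delta\psi \;=\; \left(\frac{\mathrm{FPKM}_{\text{alt}}}{\mathrm{FPKM}_{\text{total}}}\right)_{\text{salt}} - \left(\frac{\mathrm{FPKM}_{\text{alt}}}{\mathrm{FPKM}_{\text{total}}}\right)_{\text{control}},$$

lies in [-1, 1], is undefined when either context has zero total, and
measures the direction and size of the usage shift independently of the
significance call. `das_expression_correlation()` relates per-timepoint
change frequencies to gene-level log2 fold changes by Pearson correlation
(at least three paired timepoints, non-constant series), the conventional
choice for short paired series.

## Lengths and reading frame

Event length determines whether splicing preserves the downstream reading
frame: length mod 3 = 0 (class AS_0) preserves it, remainders 1 and 2
(AS_1, AS_2) shift it and can introduce premature termination codons.
`frame_spectrum()` reports the three fractions per basic event type;
"other" events mix heterogeneous structures and are excluded from frame
and length analyses. `length_histogram()` bins at 1 bp for the short
boundary-shift events and 3 bp for IR/ES, and reports the modal exact
length (ties resolve to the smallest). `compare_lengths()` uses Welch's
unequal-variance t test: where a plain Student test is reported without a
variance assumption, Welch is the robust default and leaves the direction
of any difference unchanged.

## Group overlaps

`overlap_summary()` reduces the four group flags along two axes — tissue
(root = RC or RS; leaf = LC or LS) and condition (control = RC or LC;
salt = RS or LS) — and reports shared and specific counts per axis,
pairwise intersections and the events present in all four groups.
`specificity_test()` asks whether events are more tissue- than
condition-specific via a two-sided Fisher test on
[shared, specific] x [tissue axis, condition axis]; the contingency
construction is declared here because the comparison is usually stated
without one, and pooling the two one-sided cells per axis is the most
direct reading.

## The synthetic-data generator

`simulate_splicing()` emulates the statistical structure the analysis
assumes, with recorded ground truth:

* **Gene structure.** Base isoforms with 3-8 exons; exon lengths
  log-normal (median 170 bp, floored at 30), intron lengths log-normal
  (median 300 bp, floored at 60) — typical plant-genome scales.
* **Event injection.** Each event derives one alternative isoform by a
  local edit of the base isoform (retain an intron, drop an internal
  exon, move one boundary, retain two consecutive introns for the
  composite "other" class), so the classifier has a unique correct
  answer, recorded with coordinates, length and frame class. Default type
  probabilities (IR .36, AA .29, other .14, AD .13, ES .08) follow the
  type mix reported for cotton; AA/AD shift sizes favour 3 and 4 bp with
  a geometric tail, echoing the modal acceptor/donor shifts.
* **Abundance.** Per-isoform mean FPKM is log-normal with mu = -1.595,
  sigma = 3.041 on the natural-log scale, placing 70/20/10% of values
  below 1 / in 1-10 / above 10 FPKM, the survey profile of assembled
  transcriptomes. Replicate cells are the mean times log-normal noise
  (sigma = 0.15), or Poisson counts under `noise_model = "poisson"`.
* **Usage shifts.** A configurable fraction of events (one per gene, where
  the shifted inclusion share stays inside (0.02, 0.95)) moves from
  inclusion ratio r under control to r + delta (default 0.25) in the salt
  libraries of the configured tissue and timepoints, implemented by
  adjusting the derived isoform's mean so sibling isoforms keep their
  abundance.
* **Decoys.** Intergenic single-exon transcripts (default 20% of genes)
  with exponential near-zero abundance, for cutoff calibration.

Everything is deterministic given the seed, and FPKMs are serialised at
six significant digits so files round-trip exactly.

What the generator does **not** emulate: read-level sampling and mapping
artifacts, splice-site sequence motifs, correlated expression across genes,
library-size differences, partially degraded or mis-assembled transcript
models, and real FPKM overdispersion. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical structure, not
robustness to assembler noise in real data.

## Numerical choices

* Coordinates are 1-based inclusive (GTF convention) everywhere a user
  sees them; interval arithmetic is integer throughout.
* Reported percentages round half away from zero (`round_half_up()`), the
  convention of the published tables; banker's rounding would differ at
  exact halves.
* Fisher tables round FPKM half-up with minimum count 0; all-zero tables
  yield an undefined p-value and the event-context is reported skipped.
* In a composite ("other") event the inclusion side is the isoform with
  more exonic bases in the region (ties to the first); an isoform seen on
  both sides across pairs stays on the inclusion side.
* Degenerate inputs fail loudly: overlapping exons, mixed
  chromosome/strand within a transcript, incomplete replicate pairs and
  malformed GTF lines (named by line number) are errors, not warnings.

## Problem sizes in the test suite

The suite exercises the classifier-oracle sweep at 10,000 random pairs,
recovery at 500 genes (seed 42), type-I calibration at 2,500 null tables,
enrichment at 500 null runs and the Welch null at 1,000 runs — sizes at
which the stochastic assertions have comfortable margins while the whole
suite stays fast on one CPU.

## Limitations

* "Other" events are a catch-all; their internal structure, and frame
  analysis for them, are out of scope.
* Events touching transcript termini (alternative first/last exons) are
  deliberately not detected.
* The Fisher-on-FPKM device inherits the calibration caveats above; for
  count-based designs a count-aware model would be preferable.
* Group presence requires inclusion and exclusion isoforms to pass the
  filter in the *same* group — one reading of a rule the original design
  leaves unstated.
* GO-style enrichment is generic: the gene-to-term mapping is entirely
  caller-supplied.

## A minimal session

```{r example, eval = FALSE}
cf <- simulation_config(n_genes = 200, seed = 7)
sim <- simulate_splicing(cf, dir = "simdir")
res <- run_pipeline(sim$paths$gtf, sim$paths$expression, "simdir/out")
catalog_summary(res$catalog)$by_type
evaluate_recovery(sim$truth, res$catalog, res$das, res$filter)$by_type
```
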