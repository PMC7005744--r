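---
title: "The splicing-index pipeline: model, parameters and design choices"
author: "spliceSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The splicing-index pipeline: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceSI)
```

# The quantity being estimated

For a cassette exon, let $A_i$ be the abundance of the inclusion isoform
and $A_s$ the abundance of the skipping isoform. The percent spliced in is
$\mathrm{PSI} = A_i / (A_i + A_s)$. Junction reads estimate it directly:
reads crossing either inclusion junction arrive at a per-junction rate
proportional to $A_i$, and reads crossing the skipping junction at a rate
proportional to $A_s$, so the **splicing index**

$$\mathrm{SI} \;=\; \frac{\text{inclusion junction reads}}
  {\text{inclusion junction reads} + \text{skipping junction reads}}$$

is an unbiased plug-in estimator of PSI when the inclusion count is put on
the per-junction scale. That is why the cassette-exon inclusion count is
the **rounded mean of the two flanking inclusion-junction counts**: each
inclusion transcript contributes reads to both junctions, and averaging
returns to the one-junction scale on which the skipping count lives.
Summing instead would double-count inclusion evidence relative to
skipping and bias SI upward; the `combiner` argument of
`quantify_events()` still offers `"sum"` and `"min"` for users who want
the alternative conventions.

Per event type:

* **cassette exon** — inclusion = rounded mean of the two flanking
  junction counts, skipping = skip-junction count;
* **alternative 5'/3' splice site** — inclusion = the event-defining
  (longer-exon, shorter-intron) junction, skipping = the alternative
  junction;
* **intron retention** — inclusion = rounded mean of the bridging counts
  at the two intron boundaries, skipping = the spliced-junction count.
  Fully intronic reads never enter SI; they produce the
  `covered_fraction`/`mean_depth` side-car fields so retention calls can
  be gated on uniform intron coverage downstream.

Rounding is half-to-even and exists only so the counts stay integral for
the Fisher table. It makes SI invariant under count scaling except at
half-integer means, where the deviation is at most half a read.

# Read classification

Alignments are classified with precedence junction > bridging >
intronic:

* a spliced read (CIGAR `N`) whose gap is an annotated junction, or at
  least a plausible one (donor strictly left of acceptor), is a junction
  read; its per-junction anchors must each reach `min_overhang`
  nucleotides (default 6) to be counted;
* an unspliced read covering an annotated exon–intron boundary with at
  least `min_overhang` aligned nucleotides on both sides is a bridging
  read;
* an unspliced read entirely inside an annotated intron is intronic.

Default QC (all configurable in `count_sample()`): primary alignments
only, duplicates dropped, MAPQ ≥ 20. Counting is fragment-level: a
junction supported by both mates of a pair counts once. These filters are
the package's own defaults — standard junction-QC practice — because the
level of filtering applied upstream of a published screen is rarely
recoverable from text.

# The differential test and its assumptions

Within a contrast, replicate samples are pooled by summing inclusion and
skipping counts per event. The pooled 2×2 table
(treatment/control × inclusion/skipping) is tested with a two-sided
Fisher exact test under the minimum-likelihood convention (sum over all
tables with the observed margins whose conditional probability does not
exceed the observed one, ties compared at 1e-7 relative tolerance). The
test is implemented in-package as a vectorized sweep of the conditional
support, which makes an exhaustive oracle comparison over all margins
≤ 40 cheap; `stats::fisher.test` serves as an independent cross-check in
the test suite.

Fisher's test conditions on total counts and assumes reads are
independent draws — it ignores biological replicate variability. Pooling
is therefore anticonservative under overdispersion; this is a property of
the screening design itself, not an implementation choice. The generator
exposes exactly this risk through its `overdispersion` parameter
(beta-binomial, default 0), and the per-replicate path (one
`call_contrast()` per replicate joined with sign agreement in
`join_bidirectional()`) is the conservative alternative.

FDR is Benjamini–Hochberg via `stats::p.adjust`, taken across **all
tested events of a contrast jointly** (all event types in one list):
the screen is one experiment, and splitting by type would make the
threshold depend on an arbitrary partition.

## The screening thresholds

An event passes a contrast when

| parameter | default | meaning |
|---|---|---|
| `t_reads` | 15 | total junction reads; by default the **minimum over the two arms** must reach it (each arm must carry evidence); `total_rule = "sum"` relaxes this |
| `t_dsi` | 0.10 | \|ΔSI\| in SI units (10 percentage points), boundary included |
| `t_fdr` | 0.2 | BH-adjusted p, boundary excluded (strict `<`) |

Boundary arithmetic: ΔSI values produced from integer counts can land on
the 0.10 boundary only up to double-precision representation
(`60/100 - 50/100` is one ulp below 0.1), so the ≥ comparison carries a
1e-9 epsilon. The same guard is used for the >5-percentage-point rule in
`classify_pairs()`. The FDR comparison is exact because 0.2 is a printed
strict inequality.

## Bidirectionality

`join_bidirectional()` implements the defining filter of the
perturbation design: knockdown and overexpression must move an event in
opposite directions. Strict mode (used for the high-confidence set)
requires every supplied KD and OE contrast to pass its filters with all
KD ΔSI of one sign and all OE ΔSI of the opposite sign; relaxed mode
(used to build the motif positive set) requires one opposite-signed
passing pair. ΔSI of exactly zero has no sign and is never called.

# The synthetic-data generator

`sim_config()` / `generate_annotation()` / `sim_truth()` /
`simulate_counts()` emulate the study design: a panel of multi-exon genes
(default 200; 4–8 exons of 90–300 nt, introns 150–400 nt) each carrying
one cassette exon with an inclusion and a skipping isoform; one knockdown
and one overexpression sample per regulator, each against its own control
(scramble / empty vector); a designated subset of events (default 20)
shifted by ±`delta_psi` (default 0.3) with the knockdown direction drawn
at random and the overexpression direction forced opposite. Depth is
Poisson around 100 junction fragments per event per arm — a typical
junction depth for a well-expressed exon in a standard bulk library —
and inclusion counts are binomial (or beta-binomial) around the true PSI.
Because one inclusion transcript spans two junctions, the generator emits
$2\times$ the inclusion draw split binomially between the two flanking
junctions; the rounded mean used by the quantifier is then exactly the
binomial proportion, which is what makes the calibration test a clean
binomial-coverage statement.

Everything is a deterministic function of `seed`. SAM emission
(`write_sim_sam()`) reproduces the count tables read for read — spliced
reads anchored half-and-half across each junction, unspliced reads
centered on boundaries, intronic reads at recorded positions — so the
extraction/counting path can be checked for exact round-trip equality.

What the generator deliberately does **not** model: sequencing error,
positional/GC bias, multi-mapping ambiguity, gene-level expression
differences between arms, correlated events within a gene, or isoform
structures beyond one cassette per gene. Passing tests on this generator
therefore demonstrate correctness of counting, estimation and the
decision cascade under the stated sampling model — not robustness to
alignment artifacts or expression confounding in real libraries. One
realistic feature does emerge and is worth knowing about: alternative
splice-site candidates that share junctions with a shifted cassette also
shift, so calls on real data should be interpreted per junction ratio,
not per gene.

The end-to-end recovery computation (in `scripts/acceptance.R` and the
acceptance tests) uses 2,000 genes with 100 shifted events at depth 100
per arm, and takes the 2,000 cassette events as the truth universe for
recall/false-call accounting — the coupled alternative-site calls above
are neither hits nor false calls in that accounting. These problem sizes
were chosen as the smallest panel on which 5% recall differences and a
1-in-1,900 false-call rate are resolvable.

# Event enumeration

Candidates come from annotation: every internal exon of any isoform is a
cassette candidate (deduplicated per gene across isoforms), with
`annotated = TRUE` when some isoform of the gene actually skips it; every
annotated intron is a retention candidate; and junction pairs of a gene
sharing one boundary are alternative 5'/3' candidates (which of the two
depends on strand). Event identifiers are pure functions of coordinates,
so enumeration is deterministic and re-runs are byte-identical. Junctions
observed in reads but absent from annotation are flagged rather than
discarded at the counting stage; they simply do not form events unless
the annotation supports them. Coordinates are 0-based half-open
everywhere inside the package; GTF and SJ-table readers and all writers
convert at the boundary, which confines off-by-one risk to two functions.

Overlapping genes are handled independently; a junction matching several
genes' splice sites would be assigned to the gene with more matching
sites, ties broken lexicographically — a deterministic rule chosen
because no principled one is available without expression modelling.

# Motif context

`build_motif_sets()` reproduces the motif-analysis input convention:
regulated cassette exons (relaxed-mode calls) with 250 nt flanks on both
sides, sense strand (minus-strand windows reverse-complemented), against
a size-matched seeded random sample of cassette exons with |ΔSI| < 10%
in every overexpression contrast. De novo motif discovery is out of
scope (it belongs to dedicated external tools); what the package provides
is a transparent **GA-rich scanner**: windows of width 6–9 containing
only purines with at least two G and two A, taken greedily and
non-overlapping from the left, widest window first. The composition rule
is the package's own operationalization of "GA-rich" — it accepts
elements such as `GAAGGAGA` while rejecting homopolymer runs — and all
four numbers are exposed as arguments. Fractions of events carrying at
least one hit (`motif_fraction()`) are comparable between positive and
control sets; on random sequence the hit probability depends strongly on
purine content, so only the positive-minus-control difference is
meaningful, never the absolute fraction.

# The AS-NMD rule

`project_skip()` rebuilds the mature mRNA after skipping one internal
exon and `call_nmd()` translates from the annotated start codon to the
first in-frame stop. The transcript is predicted NMD-sensitive when that
stop lies more than 50 nt upstream of the last exon–exon junction — the
canonical exon-junction-complex rule; the threshold is an argument
because reported boundary cases vary. A stop in the last exon has
non-positive distance and is never NMD-sensitive. Degenerate inputs are
explicit: skipping the start-codon exon yields a projection with
`cds_lost = TRUE` that refuses to call; a transcript with no in-frame
stop returns a flagged, insensitive call. `synthetic_asnmd_transcript()`
constructs, entirely in code and with internal verification, a six-exon
transcript whose frameshifting exon-3 skip creates its first stop near
the start of exon 5, exactly 368 nt upstream of the last junction — the
geometry of the RELL2-type skip — as a reproducible worked example of
the whole computation.

# Clinical rules

`classify_pairs()` applies the printed tumor/normal grouping: a pair is
regulator-high at ≥ 1.5-fold expression (boundary included), inclusion is
up/down at strictly more than 5 percentage points of PSI change. The
"5%" is absolute PSI percentage points, matching how PSI axes are drawn,
not a relative change. `rip_percent_input()` is
$2^{-\Delta Ct} \times 100$ with
$\Delta Ct = Ct_{RIP} - (Ct_{input} - \text{dilution factor})$, the
dilution factor in Ct units (log2 of the input dilution).
`tumor_volume()` is $0.5 \times L \times W^2$ with the convention that
length is the longer axis (violations are swapped with a warning).

# Known limitations

* Fisher on pooled counts understates uncertainty under replicate
  overdispersion (see above); the package exposes the risk rather than
  replacing the test, because the screen's defining statistic *is* the
  plain Fisher exact test.
* Intron-retention SI depends on bridging-read depth, which is lower per
  site than junction depth; retention calls at moderate coverage are
  noisier than cassette calls and should lean on the coverage gate.
* The annotation-driven enumerator does not invent novel exons; a
  junction combination absent from the annotation is only flagged.
* The GA-rich scanner is a composition rule, not a learned motif; it is
  meant for set-level enrichment comparisons and for exporting
  MEME-ready FASTA, not for single-site claims.
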