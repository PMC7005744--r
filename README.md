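# spliceSI

Junction-read quantification of alternative splicing and differential
splicing calls for regulator perturbation designs (knockdown plus
overexpression), in R.

## The problem

RNA-binding regulators such as the A-to-I editing enzymes ADAR1 and ADAR2
can change how cassette exons, retained introns and alternative 5'/3'
splice sites are used. A robust screen for such effects perturbs the
regulator in both directions — silence it and overexpress it — and keeps
only splicing events that move in **opposite directions** under the two
perturbations. spliceSI implements that screen from spliced RNA-seq
alignments:

1. **Read classification.** Mapped reads are sorted into three groups:
   exon–exon junction reads (spliced, CIGAR `N`), exon–intron bridging
   reads, and fully intronic reads. Groups 1–2 quantify splicing; group 3
   drives intron-retention coverage/depth summaries.
2. **Splicing index.** For each event and sample,
   `SI = inclusion / (inclusion + skipping)` where the counts are
   junction reads adjusted per event type (cassette exons combine their
   two flanking inclusion junctions by rounded mean; intron retention uses
   boundary bridging reads as inclusion evidence). SI is the junction-read
   analogue of PSI (percent spliced in).
3. **Differential calling.** Per contrast, replicates are pooled, ΔSI =
   SI(treatment) − SI(control) is computed, a two-sided Fisher exact test
   is run on the pooled 2×2 inclusion/skipping table, and
   Benjamini–Hochberg FDR is taken across all tested events. An event
   passes when **total junction reads ≥ 15**, **|ΔSI| ≥ 10%** and
   **FDR < 0.2**.
4. **Bidirectional join.** A high-confidence call requires knockdown and
   overexpression ΔSI of opposite sign (strict mode: every contrast
   passes; relaxed mode: at least one opposite-signed KD/OE pair).

Around this core the package provides: GA-rich motif-context extraction
(event ± 250 nt flanks, sense strand, positive vs |ΔSI| < 10% control
sets), an AS-NMD rule (first in-frame stop of a frameshifted skip isoform
more than 50 nt upstream of the last exon–exon junction), closed-form
clinical rules (tumor/normal pair classification at ≥1.5-fold expression
and >5-percentage-point inclusion change, RIP %input = 2^−ΔCt × 100,
xenograft volume 0.5·L·W²), and a fully seeded synthetic-data generator
that emulates the perturbation design with known truth.

## Worked example

Simulate a small perturbation study (60 cassette genes, 10 truly
regulated with |ΔPSI| = 0.3 in opposite KD/OE directions, ~100 junction
fragments per event per sample) and run the screen:

```r
library(spliceSI)

cfg    <- sim_config(seed = 42, n_genes = 60, n_events_shifted = 10,
                     regulators = "ADAR1")
ann    <- generate_annotation(cfg)
truth  <- sim_truth(cfg, ann)
counts <- simulate_counts(cfg, ann, truth)

events <- enumerate_events(ann$models)
events
#> splicing_events: 809 event(s)
#>          alt_3ss          alt_5ss    cassette_exon intron_retention
#>               60               60              329              360

quants <- lapply(counts, function(tab) quantify_events(events, tab))
kd <- call_contrast(quants[["ADAR1_KD"]], quants[["scr"]], "ADAR1-KD-vs-ctrl")
oe <- call_contrast(quants[["ADAR1_OE"]], quants[["EV"]], "ADAR1-OE-vs-ctrl")
summary(kd)
#> Contrast ADAR1-KD-vs-ctrl - 30 of 809 tested events pass filters
#>       alt_3ss       alt_5ss cassette_exon
#>            10            11             9
#> dSI range among passing events: [-0.398, 0.346]

calls <- join_bidirectional(kd, oe, mode = "strict")
calls
#> bidirectional_calls (strict mode): 28 high-confidence event(s) of 809 candidates

shifted <- unique(truth$event_id[truth$shifted])
sum(shifted %in% calls$event_id)
#> [1] 9
```

Nine of the ten injected cassette events survive the full cascade at this
depth. The remaining calls are alternative-splice-site events that share
junctions with a shifted cassette exon and therefore genuinely change
with it — the screen reports every event whose junction ratio moved
bidirectionally, not only the designated cassettes.

A YAML-driven end-to-end run (`run_pipeline()`), an AS-NMD report
(`project_skip()` + `call_nmd()`), motif-context extraction
(`build_motif_sets()` + `scan_ga_rich()`), and the clinical rules
(`classify_pairs()`, `rip_percent_input()`, `tumor_volume()`) are
documented in the methods vignette
(`vignettes/splicing-index-pipeline.Rmd`). A thin command-line wrapper
with `simulate`, `run`, `nmd` and `classify` subcommands is installed at
`inst/scripts/splicesi.R`.

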