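---
title: "Nominating CRISPR-Cas9 cleavage sites from CIRCLE-seq data"
author: "circlenom authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating CRISPR-Cas9 cleavage sites from CIRCLE-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlenom)
```

## The assay and the computational problem

CIRCLE-seq is a cell-free, genome-wide assay for CRISPR-Cas9 off-target
activity. Genomic DNA is sheared to an average length of about 300 bp,
circularized, and digested in vitro with a Cas9/sgRNA ribonucleoprotein.
Circles carrying a sequence the nuclease can cleave are linearized; after
adapter ligation they are sequenced as 75 bp paired-end reads. Because only
linearized circles enter the library efficiently, read pairs pile up at
cleavage sites, and the genome-wide set of coverage peaks nominates
candidate on- and off-target loci. A matched negative control (the same
library preparation with no Cas9/sgRNA treatment) identifies loci that
produce peaks for assay-intrinsic reasons, and duplicate experiments guard
against run-specific noise.

`circlenom` implements the read-level and interval-level analysis of that
assay as a reusable pipeline:

1. **Read-pair filtering.** A pair is dropped if either mate's mean base
   quality is below 20 (strict `<`); kept pairs must carry exactly the SAM
   flag pair {83, 163} or {99, 147} (concordant, opposite orientations,
   first-in-pair on either strand); finally the pair's deleted region —
   by default the largest single CIGAR `D` operation across both mates —
   must be smaller than 20 bp.
2. **Coverage and peaks.** Depth counts every reference base consumed by a
   kept mate's CIGAR (`M/D/N/=/X`); a peak is a maximal interval with depth
   at or above `min_height` (default 1), and its height is the maximum
   depth inside. The track and peaks are bedGraph-style 0-based half-open
   intervals.
3. **Negative-control subtraction.** Any sample peak overlapping a control
   peak by at least one base is removed whole (the `bedtools intersect -v`
   semantics); surviving peaks are not trimmed.
4. **Replicate intersection.** The candidate set is the base-wise
   intersection of the replicates' subtracted peaks; each intersection's
   height is the minimum of its parents — a conservative choice that makes
   the operation commutative and idempotent and lets more than two
   replicates be folded pairwise.
5. **Ranking and annotation.** Candidates are ordered by height
   (descending, ties broken by genomic coordinate so output is
   deterministic) with `log10(height)` attached, then annotated with the
   best-matching PAM-adjacent 20-mer on either strand, its mismatch count
   to the spacer, and an on-target label.

## Design choices where the procedure was genuinely open

Several steps admit more than one reasonable reading; the package fixes
them as follows and exposes the alternatives as parameters.

* **Quality screen.** "Quality below 20" is applied as the mean Phred
  score per mate, with a strict `<` (a mean of exactly 20 is kept). A
  whole-read mean is the simplest self-contained screen that does not
  depend on a trimming tool's window heuristics.
* **Deleted region.** The deleted region of a pair is read as the largest
  single `D` operation rather than the sum of all deletions — a junction
  artifact presents as one gap. `deletion_metric = "sum"` switches to the
  total.
* **Flag pairs are matched exactly.** {83, 163} and {99, 147} only; a
  "properly paired" test would also admit pairs such as {97, 145}, which
  are deliberately rejected. Secondary and supplementary alignments
  (0x100/0x800) are discarded before pairing.
* **Subtraction removes peaks, not coverage.** The control defines
  excluded loci; heights are never decremented.
* **Replicate height = min.** The evidence for a common site is the weaker
  of the two replicates.
* **Cut-site geometry.** Cleavage is modelled blunt, 3 bp 5′ of the PAM
  (between spacer positions 17 and 18) — standard SpCas9 geometry,
  adjustable via `cut_offset`.
* **Annotation.** The protospacer search scans both strands of the peak
  extended by `flank = 25` bp, so a peak covering one side of a cut still
  reaches the protospacer. Ties on mismatch count are broken by distance
  to the peak's depth apex, then coordinate, then `+` strand. A peak is
  labelled on-target when its inferred cut lies within 5 bp (inclusive) of
  the known cut.
* **Peak monotonicity.** Raising `min_height` can split a peak in two but
  never extends one: the covered base set only shrinks, and every
  higher-threshold peak is contained in exactly one lower-threshold peak.
  This is the form in which the property is tested.

## What the simulator emulates

Every stage is testable without sequencing data because the package ships
a ground-truthed generative model of the assay (`make_genome`,
`plant_sites`, `simulate_reads`, `simulate_negative_control`). The
simulator emits three molecule classes:

* **Cut-derived pairs.** Each planted site draws
  `Binomial(depth_per_site, cleave_prob)` pairs. A pair's fragment length
  comes from a truncated normal (mean 300 bp, sd 30 bp, minimum the read
  length); the fragment is placed to contain the cut, and the pair's truth
  flags are drawn uniformly from {(99, 147), (83, 163)}. These pairs pass
  every filter by construction.
* **Background pairs.** Placed uniformly; half carry flag pairs outside
  the accepted set ((97, 145) or (65, 129)), half carry an accepted flag
  pair but a CIGAR deletion of 20–40 bp; a configurable fraction
  additionally gets mean base quality below 20. Every background pair
  fails at least one filter.
* **Artifact pairs.** Filter-passing pairs at loci shared between a sample
  and its matched negative control — the molecules that only control
  subtraction can remove.

Two deliberate simplifications matter when interpreting test results.
First, real CIRCLE-seq junction reads map back-to-back around the cut
after alignment; the simulator instead emits concordant
forward–reverse pairs centred on the cut, so that the accepted flag set is
literally satisfiable by truth flags. The simulator encodes the
post-alignment contract of the pipeline, not the aligner: mapping
behaviour (soft-clips, multi-mapping, chimeric splits) is out of scope,
and passing tests say nothing about it. Second, cleavage probability is a
per-site input — by default `max(0.05, 1 − 0.15 · mismatches)` — not a
mechanistic model of mismatch tolerance; the convenient monotone default
only has to order sites plausibly.

Artifact loci are drawn outside ±2 × (mean + 5 sd) fragment lengths
(900 bp at the defaults) of planted cuts and of each other. A read
footprint extends up to roughly one maximal fragment length either side of
its locus, so this is the smallest margin at which an artifact's footprint
cannot touch a genuine site's peak. On a genome-scale reference the
coincidence of an assay artifact with a true cleavage site is vanishingly
rare; a 50 kb miniature genome would otherwise manufacture such collisions
— and subtraction would then delete true sites — for reasons that are
purely an artifact of the toy scale.

### Reference study conditions

The test suite and the acceptance script use one fixed configuration: a
single 50 kb contig; one on-target (`cleave_prob` 1.0) and eight
off-targets carrying 1–6 mismatches (`cleave_prob` 0.85 down to 0.10 by
the default map); 200 pairs attempted per site; 100 background pairs; two
shared artifact loci at 50 pairs each; two replicates, each with a matched
negative control. These sizes keep a full 100-seed recovery study in the
order of a minute on one CPU while leaving every stage non-trivially
exercised (roughly 1,400 pairs per library). Under these conditions the
top-ranked candidate is the on-target in ≈96% of seeds — the remainder are
genuine binomial/coverage noise in which the 0.85-probability off-target
out-peaks the on-target — every site with `cleave_prob ≥ 0.2` is recovered
in every run, and no artifact-only locus survives subtraction plus
intersection.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally and in BED/bedGraph output;
  SAM records are 1-based as the format requires.
* All randomness flows through a seed-scoped RNG helper; identical
  configuration and seed give byte-identical FASTQ, SAM, bedGraph, TSV and
  JSON outputs, and the caller's RNG state is never disturbed.
* Empty inputs are legal everywhere: an empty site list yields an empty
  library; an empty SAM body yields zero counts and an empty candidate
  table; subtracting an empty control is the identity.
* A pair whose mate is never seen is counted separately and excluded from
  the pair total; a SAM without `@SQ` lines is a format error.
* `skipping_efficiency` is undefined (an error) when both amounts are
  zero; `ddpcr_copy_loss` clamps negative losses to 0 with a warning, as
  sampling noise can put the target amplicon above the reference.

## Assay metrics

Three scalar computations accompany the pipeline. Exon-skipping
efficiency is `100 × skipped / (skipped + unskipped)` — scale-invariant,
so any shared unit works. Reading-frame arithmetic: removing exons whose
lengths sum to a multiple of 3 preserves the reading frame; the dystrophin
example is a transcript lacking the 148 bp exon 44 (out of frame, shift 1)
restored by additionally skipping the 176 bp exon 45 (148 + 176 = 324 ≡ 0
mod 3). ddPCR copy loss is `100 × (1 − target/reference)` over droplet
concentrations of an amplicon spanning the cut versus an uncut reference
amplicon; the ratio form is this package's choice of quantification, and
outputs should be read with that convention in mind.

## A complete run

```{r run, eval = FALSE}
cfg <- run_config(
  sgrna_spec("ACGTTGCAGATTACGGCTAA"),
  simulate = list(contig_length = 50000L,
                  mismatch_counts = c(0L, 1:6, 2L, 3L)),
  seed = 1L)
res <- run_pipeline(cfg)
head(res$ranked)
write_report(res, "circlenom_out")
```

The same run is available from a shell through the thin wrapper at
`inst/cli/circlenom.R` (`run`, `simulate` and `metrics` subcommands over a
YAML config).

## Known limitations

* The pipeline consumes alignments; trimming, demultiplexing and mapping
  are upstream concerns, and the simulator's truth SAM stands in for an
  aligner's output, not for the aligner.
* No statistical enrichment test is attached to peaks — no null model is
  defined for the assay here; ranking is by raw height.
* Protospacer annotation considers substitutions only; DNA/RNA-bulge
  alignments and non-NGG PAM discovery beyond the configured IUPAC
  pattern are not searched.
* How many top-ranked candidates to carry into validation is left to the
  user; the package ranks but does not threshold.
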