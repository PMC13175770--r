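---
title: "Off-target nomination, confirmation, and KO calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target nomination, confirmation, and KO calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otsentry)
```

# Overview

`otsentry` implements the computational arm of a CRISPR-Cas9 off-target
safety assessment: nomination of candidate cut sites from tag-integration
sequencing, an independent in silico genome search, multi-method
prioritization into a confirmation panel, amplicon deep-sequencing
confirmation, and ddPCR knockout-efficiency calibration. Because clinical
sequencing data of this kind is rarely shareable, the package treats its
synthetic-data generator as a first-class module: every stage can be run,
tested, and audited against planted ground truth.

This vignette records the statistical model behind each stage, the
tunable parameters with their defaults and units, what the simulator does
and does not emulate, and the design decisions taken where the problem
was genuinely open.

# Tag-integration nomination

## Read model and preprocessing

Read 1 is declared as `"<u>M+T"`: a `u`-base UMI prefix (default 8),
then — for break-derived reads — the dsODN junction tag, then genomic
sequence. The tag is located by a mismatch-tolerant scan of the post-UMI
body (tolerance: one mismatch per 10 tag bases, configurable); reads
without a tag are kept as background. Neither a dsODN sequence nor a UMI design is standardized across labs, so both are configuration
values with documented defaults (`default_tag()`, a synthetic 16-mer)
rather than guesses at proprietary reagents.

Mapping uses a deliberately naive built-in mapper — exact 31-mer seed at
the read start on both strands, ungapped extension, unique-best rule,
ties flagged ambiguous. Its contract is correctness on low-error
synthetic reads, which the test suite enforces against an exhaustive
full-scan oracle; real-data users supply external alignments through the
SAM-subset reader. UMI families (grouped by position, strand, and UMI)
collapse to single-strand consensus reads with minimum family size 1; the
consensus base is the quality-weighted majority, with ties broken toward
the first (reference-agreeing, on clean input) base for reproducibility.

Tag junctions imply a cut-site estimate: the mapped start for +-strand
placements and the mapped end for −-strand placements. Junctions within
5 bp merge by single linkage (`cluster_window`; junction positions jitter
by end resection; the window value is the package's own choice).

## Glocal alignment and the Levenshtein criterion

Each cluster is searched in a ±40 bp flanked window. The guide spacer is
aligned *glocally*: end-to-end in the guide, free end gaps in the window,
both strands. The dynamic program minimizes edit distance, and the
reported Levenshtein distance is the mismatch+insertion+deletion count of
the traceback; the Needleman–Wunsch score (match +1, mismatch −1, gap −2)
of that alignment is reported alongside. We deliberately made edit
distance the primary objective rather than the score: the nomination
rule (`distance < 7`) and the package's oracle-equivalence property are
both defined on the distance, and a score-optimal alignment can carry
more edits than the true minimum (four mismatches outscore three
guide-side gaps but lose on edits), which would make the reported
distance depend on scoring arbitrariness. Ties break toward lower
distance, then the leftmost window offset, then the + strand.

The PAM (NGG by default; a relaxed NGG|NAG mode exists) is checked
immediately 3′ of the aligned protospacer and recorded as a flag; PAM
bases are never counted in the Levenshtein distance. The cut site is
placed 3 bp 5′ of the PAM (`cut_offset = -3`), the standard blunt SpCas9
position.

## Enrichment statistics

For each candidate site, each treatment sample is tested against the
pooled controls with a one-sided hypergeometric test on the 2×2 table
(site reads vs sample totals). Benjamini–Hochberg runs across all
(site × treatment sample) tests of a run; a site's adjusted p is the
minimum across its treatment samples, consistent with a nomination rule
that any single sample may carry a site. The representation denominator is each sample's total
consensus-read count. (Counting only tag-bearing consensus reads is
offered conceptually but is degenerate on clean controls, which carry no
tag reads at all — the pooled-control margin would vanish; totals over
all consensus reads keep the table well-defined in both arms.)

A site is **nominated** iff all three criteria hold: bidirectional tag
evidence in at least one sample, Levenshtein distance < 7, and adjusted
p < 0.05. Replicate support counts the treatment samples that
individually satisfy all three.

## Tiers

Tier definitions for assays of this kind are typically not published in
full, so the package ships an explicit, configurable stand-in
(`default_tier_rules()`), evaluated in order over nominated sites:
tier 1 — exonic or supported by every replicate; tier 2 —
intronic/flanking with support ≥ 2; tier 3 — support ≥ 2 or distance ≤ 3;
tier 4 — the rest. Any ordered list of predicates can be substituted.

# In silico search

`search_genome()` computes, for every end position on both strands, the
best semi-global edit distance of the spacer (a compiled two-row DP over
the whole contig). Every end with distance ≤ `max_distance` and a valid
PAM becomes a hit, re-traced with the aligner anchored at that end;
same-strand hits within 3 bp collapse to the best-distance one. This
full-column scan replaced an earlier seed-filter design: with a 20-nt
spacer and distance cap 5 a pigeonhole partition yields 3-mer seeds that
filter essentially nothing, while the exhaustive DP is complete by
construction and fast in compiled code. Completeness is enforced in the
tests against a substring-enumeration oracle. The default
`max_distance = 5` is a package choice (the prioritization rule only
fixes < 3); it is configurable.

Variant-aware expansion substitutes each qualifying allele (AF > 0.01,
the usual >1%-in-any-super-population rule reduced to a single
precomputed maximum-AF field) into its local neighborhood, re-searches, and reports
hits absent from the reference as population-dependent with the
supporting variant recorded. Haplotype phasing and multi-variant
combinations are out of scope.

# Prioritization and panel dedup

The five panel rules are the union: tag-integration tiers 1–3; any
Abnoba-seq nomination; CAST-seq nominations reproduced in ≥ 2 replicates
(reproducibility is rarely quantified in published descriptions; ≥ 2
mirrors the convention used for tag-integration replicates); in silico
sites with distance < 3; in silico exonic sites.
CAST-seq records are filtered at ingest at the published OMT cut-off
p < 0.005. COSMID sites have no written rule of their own yet appear in
confirmation panels of this kind, so a pass-through rule (`cosmid`,
default on) admits them; it is flagged in output provenance and can be
disabled.

Deduplication merges cut positions within 10 bp (strand-agnostic,
single-linkage; cut estimates differ by a few bases between methods) and
takes the evidence-weighted median as the representative cut. The merge
is idempotent — single-linkage separation guarantees representative
positions of distinct panel sites stay more than one merge distance
apart — and member nominations partition exactly across panel sites; both
are property-tested.

# Amplicon confirmation

A read counts as edited iff its alignment to the amplicon reference
contains at least one insertion or deletion overlapping the ±2 bp window
around the cut (`window_halfwidth = 2`, configurable): blunt-cut repair
indels start at the cut, while a tight window limits background;
substitutions never count; an indel is counted once per read and counts
if any base touches the window. Reads are expected to span the amplicon
(merged or full-length amplicon sequencing); alignment is a banded global
edit-distance DP.

Coverage classes use the 100/1,000/10,000× thresholds on each site's
minimum per-sample depth; sites under 1,000× are excluded from testing
(configurable) and can never be significant. Control samples
characterize the background indel rate per site (median and IQR
reported), with sites overlapping declared homopolymer tracts flagged —
homopolymers are a known motif for elevated short-read indel error, and
the error model multiplies their background accordingly.

The confirmation test pools donors: one-sided exact test of pooled
treatment (indel, total) against pooled control counts — the same audited
kernel as the nomination statistic — BH across tested sites, and a
donor-independence guard requiring every donor's frequency to exceed the
pooled control frequency. A per-donor mode (minimum adjusted p over
donors) is available behind a flag; which pooling a given study used is
rarely stated, and pooled+guard operationalizes "donor independent"
while keeping one statistical core.

# ddPCR knockout calibration

Template copies partition into droplets with Poisson occupancy, so
λ = −ln(1 − positives/total) per channel; a fully positive channel is a
saturated sentinel, not an estimate. Raw KO is the concentration ratio
100·(1 − λ_WT/λ_ref) — the WT probe spans the cut and detects only
unedited alleles — clipped to [0, 100] with a flag. Calibration fits an
ordinary least-squares line of measured raw KO on the nominal 50/75/100%
controls (a three-point curve with no stated functional form; linear with
free intercept is the minimal choice) and is accepted only if every
control deviates by at most 10 percentage points. The tolerance is read
as absolute percentage points, which matches the 50/75/100 scale; a
relative reading would allow a 10-point miss at 100% but only 5 at 50%,
which the package flags as the less natural interpretation. Sample
estimates invert the accepted curve and clip to [0, 100].

# The synthetic-data generator

The generator emulates the statistical structure the analysis relies on,
under fixed seeds (every output is byte-identical given config + seed):

* random contigs at 41% GC with homopolymer tracts planted verbatim and
  simple multi-exon gene models (defaults: one 1-Mb contig);
* protospacer+PAM cassettes written at exact requested Levenshtein
  distances (re-verified against an independent DP before acceptance),
  on either strand, in requested region classes;
* tag-integration runs of 3 treatment + 3 control samples at 50,000 read
  pairs each: treatment junction reads start at the cut, carry the tag in
  either orientation with site-specific integration rates; controls (and
  the remainder of treatment depth) are random genomic fragments; UMIs
  are uniform random; substitution noise and a Gaussian quality profile
  apply throughout;
* amplicon assays in counts mode (indel ∼ Binomial(depth, editing +
  background)) or reads mode (planted 1–3 bp indels at the cut, spurious
  1-bp indels at the per-read background rate, ×5 over homopolymer
  tracts); the default per-read background of 0.0012 reproduces a
  control indel frequency with median near 0.12%;
* ddPCR wells with binomially sampled positive droplets at
  1 − exp(−λ·(1 − KO)) in the WT channel.

`simulate_confirmation_study()` encodes the confirmation-study
conditions: a 255-site panel at 200,000× with per-site log-normal
backgrounds (median 0.12%; sdlog 1.0, giving an interquartile range of
roughly 0.06–0.24%, matching the observed variability to within the
precision such a summary supports) and four true signal sites whose raw
treatment frequencies (0.40%, 0.44%, 0.025%, 0.055%) mirror the four
confirmed off-target signals. The two low-frequency signals sit far
below the *median* background, so their own site-specific backgrounds
are set low (0.005% and 0.01%) — as they must have been in reality for
those signals to reach significance at this depth. These values are
study conditions fixed once, not tuning knobs.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: realistic fragment-size distributions, PCR
duplicate structure beyond UMIs, instrument-specific quality and error
profiles, chimeric reads, translocations, large deletions, and
repeat-rich genome structure that stresses mapping sensitivity. Recovery
results on synthetic data certify the pipeline's logic, not the
sensitivity of any particular wet-lab assay.

# Numerical choices and degenerate inputs

* Alignment tie-breaks: lower distance, then leftmost offset, then
  + strand; traceback preference diagonal > guide-gap > window-gap.
* Windows shorter than half the spacer return an infinite-distance
  sentinel rather than an exception.
* `enrichment_test(0, ...)` is exactly 1; empty record lists propagate as
  empty outputs; a site with zero aligned amplicon reads is flagged with
  an undefined-frequency sentinel.
* Consensus ties break deterministically; weighted medians use the lower
  median.
* Saturated ddPCR channels (all droplets positive) return `Inf`
  concentration and are unusable for calibration by construction.

# Problem sizes used by the test suite

The suite runs the full pipeline end-to-end on reduced synthetic scales
(genomes of 60–200 kb, 2,500–8,000 read pairs per sample) chosen to keep
the default test run fast while exercising every code path; the
statistical checks (binomial calibration, FDR control, ddPCR round trip,
255-site confirmation recovery) run at their stated full designs. The
package defaults remain the full synthetic scale (1 Mb, 50,000 pairs per
sample).

# Known limitations

* The built-in mapper is exact-seed based and will miss reads whose first
  31 bases contain errors; on real data, external alignments should be
  supplied.
* The variant-aware search evaluates one variant at a time; nearby
  co-occurring variants are not combined.
* Tier definitions and the COSMID panel rule are documented stand-ins for
  non-public supplementary definitions and are fully configurable.
* Intron ordinals assume exons tile the transcript interval; unusual
  models (UTR-only leading regions) may produce off-by-one ordinals.
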