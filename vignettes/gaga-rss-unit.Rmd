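---
title: "The GAGA/RSS recombination unit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GAGA/RSS recombination unit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagarec)
```

## Scope and model

V(D)J recombination at J gene segments requires more than a recombination
signal sequence (RSS). Functional murine Jk segments pair a 23-bp-spacer RSS
with a GA-rich "GAGA" element a few tens to a few hundred bp further 5′;
this element positions a nucleosome immediately upstream of the RSS and
keeps the RSS accessible, and segments lacking it (Jk3) do not recombine.
`gagarec` implements the computational layer of that analysis: motif
scanning and pairing, fragment-size-resolved ATAC signal construction and
quantification, V-J repertoire classification, ΔΔCt quantification, and a
synthetic-data module that makes every stage testable against planted ground
truth.

Coordinates are 0-based half-open throughout, matching BED. Interval formats
are read and written as plain text with that convention preserved (BED is
trivially tab-separated; converting through 1-based range containers and
back would only add off-by-one surface).

## Motif scanning

An RSS hit is heptamer + spacer + nonamer. The consensus sequences
(`CACAGTG`, `ACAAAAACC`) and tolerances are not locus-specific measurements
but the canonical V(D)J ones, so they are defaults, not constants: the first
three heptamer bases must match exactly (they are the functionally critical
`CAC`), the heptamer remainder tolerates 1 mismatch, the nonamer 2, and the
spacer is 12 or 23 ± 1 bp. Both strands are scanned; a minus-strand hit is
reported at its plus-strand footprint. Hit enumeration was verified against
an exhaustive brute-force oracle (every position × every spacer length,
plain string comparison) on sequences up to 10 kb.

GAGA elements are reported in three tiers, reflecting GAGA-factor binding
biology: the canonical `GAGAG` pentamer (primary; overlapping matches are
merged), maximal GA runs (default ≥ 5 nt with ≥ 80% of overlapping
dinucleotides being `GA`/`AG` — a homopolymer A-run does not qualify), and
the minimal `GAG` trinucleotide, which is off by default and exploratory
only. The exact grammar behind published "GAGA motif domain" calls is not
fixed anywhere; the pentamer is the documented default for functional calls
and the run tier is available for sensitivity analyses.

`annotate_segments` pairs each gene body with the nearest upstream RSS
(nonamer end within 150 bp of the body start) and the nearest qualifying
GAGA hit within a 1000 bp window 5′ of the nonamer. The window default
accommodates both the ~80 bp spacing at Jk-like loci and spacings up to
~980 bp seen at Ja segments. Distance convention: 3′ end of the GAGA hit to
the 5′ start of the nonamer, in the segment's coding orientation; positive
means upstream. Nearest means smallest positive distance, ties broken by
longer run, then leftmost. A 3′-only motif is recorded with negative
distance but only satisfies the functional call in `ja_mode` (two Ja
segments carry exclusively 3′ motifs). The functional call itself is strict:
RSS **and** 5′ GAGA. Minus-strand segments are annotated by reflection —
the scan runs on the reverse complement and maps back — which makes the
strand-reflection invariant hold by construction.

## Synthetic loci and the planted-truth oracle

`build_locus` draws an i.i.d. background at a configured GC fraction
(default 0.42) and plants, per functional segment, the exact-consensus
heptamer, a random spacer, the exact nonamer ending 2 bp before the gene
body, and the GAGA pattern with its 3′ end exactly `gaga_distance` bp 5′ of
the nonamer. The layout follows the scanner's left-to-right
heptamer/spacer/nonamer convention; every downstream distance is defined
relative to the nonamer, so the construction is internally consistent.

For the planted truth to be an *exact* oracle, accidental motifs must not
exist: a chance `GAGAG` between the planted motif and the nonamer would
become the nearest hit. The generator therefore rejection-resamples any
accidental exact pentamer (either strand) and any accidental near-consensus
RSS hit outside the planted footprints, iterating until the sequence is
clean (in practice 1–3 sweeps). This is deliberately broader than cleaning
only each motif's flank: it guarantees recovery across arbitrary seeds and
window sizes at negligible cost. The whole construction is deterministic
given the spec's seed; the test suite checks exact truth recovery over 100
seeds.

## ATAC fragment signals

The published signals distinguish "large insert" (nucleosome-spanning) from
"short insert" (open chromatin) read pairs without stating cutoffs; the
package adopts NucleoATAC-convention defaults — sub-nucleosomal < 100 bp,
nucleosomal 180–620 bp — all configurable in `track_config()`. The Tn5
+4/−5 end shift is applied before midpoints and cut sites are computed
(toggleable).

**Occupancy** is interpreted as a smoothed dyad-density difference: Gaussian
kernel (sd 20 bp, truncated at 4 sd) over shifted midpoints of nucleosomal
fragments, scaled per million nucleosomal fragments, minus the identical
construction over sub-nucleosomal fragments scaled per million
sub-nucleosomal fragments. Per-class scaling makes the difference
scale-balanced: multiplying all counts by any factor changes no value, and
if both classes share one positional distribution the expected track is 0
(both properties are tested). The original pipeline's "simulated signal" is
not restated in the source material; this kernel interpretation is a
documented design choice validated by parameter recovery (a planted dyad at
fuzziness 10 bp with 1000 fragments is recovered within ±10 bp in ≥ 90% of
50 seeded runs) rather than by matching original tracks. The kernel sd of
20 bp trades positional sharpness against shot noise at realistic per-dyad
coverage.

**Accessibility** counts Tn5 cut sites (both shifted fragment ends) of
sub-nucleosomal fragments per base, scaled to tags per million total library
fragments. Whether the original region averages used all fragments or the
short class only is unstated; cut sites of the short class match the "open
chromatin track" semantics and are the default, with a full-fragment
coverage mode behind a flag. Accessibility is nonnegative and monotone in
added sub-nucleosomal fragments; occupancy may be negative.

`quantify_regions` is a plain per-base arithmetic mean over each region
divided by the same mean over a housekeeping region (the Gapdh-style
normalisation used for between-sample comparison). A housekeeping mean ≤ 0
cannot normalise; raw means are returned with `NA` normalised values and a
warning. `call_nucleosomes` takes the occupancy argmax in the 250 bp window
5′ of the anchor, requires it to exceed 0 (signal above background), and
breaks ties toward the anchor.

The fragment simulator draws nucleosomal fragments with midpoints
`Normal(dyad, fuzziness)` and inserts `Normal(200, 15)`, and sub-nucleosomal
fragments uniform over accessible windows with inserts `Normal(60, 5)` —
conventional values, since no empirical insert-size distributions are
published for these libraries, truncated to ≥ 1 bp by resampling (exactness
of the truncation is irrelevant at these means). It models neither
sequencing error, PCR duplicates, nor Tn5 insertion bias: passing tests
demonstrate the correctness of the signal arithmetic and the recoverability
of planted structure, not robustness to those artefacts in real libraries.

## Repertoire classification

Jk assignment aligns each reference locally against the clone
(Smith–Waterman, +1/−1 match/mismatch, gap open 2, extend 1 — invented but
conventional defaults; the original analysis used external alignment
tooling) and accepts the best score at identity ≥ 0.8 over ≥ 15 aligned nt.
Score ties between references give `ambiguous`; threshold failures give
`unassigned`; both are excluded from usage-frequency denominators by default
(frequencies are over uniquely assigned sequences), toggleable.

Frame calls assume the clone's reading frame starts at position 0 (the V
prefix in frame) and each reference carries its codon phase in config
(`frame_phase`), supplied rather than inferred so it is auditable. The
in-frame test is anchored at the **3′ end** of the aligned Jk region:
`jk_end_in_clone mod 3 == (frame_phase + ref_aln_end) mod 3`. For a gapless
alignment this is identical to checking the junction itself, but the 5′
alignment edge is genuinely ambiguous when the V tail happens to resemble
the trimmed J prefix (the aligner may extend across the junction, with
gaps), whereas what productivity requires — the J phase carried into the
downstream constant region — is pinned by the 3′ end. With this anchor,
planted-truth recovery of labels and frames on noise-free simulated clones
is exact. A stop codon (TAA/TAG/TGA) in frame anywhere from the clone start
through the aligned Jk end vetoes productivity; the constant region is not
modelled, and whether published "productive" calls add criteria beyond
in-frame-and-stop-free (e.g. splice-donor integrity) is unstated — this
package uses exactly that definition.

The clone simulator trims the chosen Jk by an offset uniform on
`0..junction_offset_max` (default 14, equidistributed mod 3) with no
selection, so the expected in-frame fraction is exactly 1/3 — the basis for
comparing against the observed ~35% productive fraction at the 3 × 24-clone
scale of the sequencing experiment, where the binomial standard error is
about 5.6 percentage points. The built-in demonstration references are
constructed with no `TA`/`TG` dinucleotide (hence stop-free in every frame
and across junctions, since the V ends in `CC`) and mutual divergence far
below the assignment threshold.

`compare_usage` wraps the unpaired two-sample t-test (equal-variance
default, Welch optional) on per-mouse frequencies. The degenerate case of
zero variance in both groups returns t = 0, p = 1 for equal means and errors
with guidance toward Welch-plus-variance-floor for unequal means, since the
equal-variance statistic is undefined there.

## ΔΔCt

`ddct_fold_change` is the closed form
2^−[(Ct\_KO,test − Ct\_KO,hk) − (Ct\_WT,test − Ct\_WT,hk)] with B2m the
conventional housekeeping gene in the originating assay. Replicate
(triplicate) Ct values are averaged per group × gene before the difference
is taken (`ddct_from_table`); the alternative — fold changes per replicate,
then averaging — is not what the formula states and is not offered. The
function is reciprocal under swapping KO and WT and monotone decreasing in
the KO test Ct, both tested. No amplification-efficiency (Pfaffl) correction
is applied.

## Problem sizes and determinism

Every stochastic component takes an explicit integer seed and restores the
caller's RNG state; identical seeds give byte-identical FASTA/BED output.
The validation suite uses sizes at which the tested statistics are sharp:
oracle equivalence on 100 × 2 kb decoy-bearing sequences plus single 10 kb
cases, truth recovery on 100 × 6 kb loci, occupancy-null and dyad-recovery
simulations at 1000–2000 fragments over 50–100 seeds, and repertoire checks
at 72–10,000 clones. These are the package's chosen validation conditions;
the generators scale to larger regions and libraries linearly.

## Known limitations

* The insert-size cutoffs and the kernel-density occupancy construction are
  conventions, not fitted to any particular library; real analyses should
  inspect their fragment-size distributions before trusting defaults.
* The synthetic background is i.i.d.; real flanking sequence has repeats and
  composition structure that can create near-consensus RSS hits and GA runs
  the cleaner would have removed, so specificity on real genomes is lower
  than on synthetic loci.
* No position-weight-matrix / RIC scoring of RSS quality; hits are
  mismatch-threshold calls.
* Species comparisons are per-locus scans, not multiple alignments; V-gene
  family assignment, CDR3 annotation and hypermutation analysis are out of
  scope.
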