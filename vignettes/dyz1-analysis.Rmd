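---
title: "Characterizing DYZ1 satellite arrays in silico: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing DYZ1 satellite arrays in silico: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyz1kit)
```

## The biological problem

DYZ1 is a tandemly repeated satellite of the human Y-chromosome
heterochromatin. Its repeat monomer — the HaeIII unit, ~3.4–3.56 kb,
delimited by HaeIII (`GG/CC`) sites — is built largely of the
pentanucleotide `TTCCA` and mutated derivatives of it, and a normal Y
carries thousands of copies. Because the male-specific region of the Y
(MSY) escapes recombination, deletion mapping with sequence-tagged sites
(STSs, the sY markers) is the standard way to ask whether Y material is
structurally intact, while the heterochromatic DYZ1 block is better probed
by sequence decomposition, virtual restriction digestion and absolute
copy-number qPCR. This package provides those desk-top analyses as tested,
reusable functions, together with a seeded synthetic-data generator that
emulates each input class so that every analysis can be validated against
planted ground truth.

## Pentamer spectra

A 5-base motif is classified by its Hamming distance from `TTCCA`
(`classify_pentamer()`); there are exactly fifteen distinct 1-base
derivatives. `pentamer_spectrum()` tiles a unit into non-overlapping
pentamers plus unassigned *residue* bases and counts motifs per distance
class, preserving the invariant

> 5 × (number of pentamers) + residue bases = unit length.

Published derivative tables for DYZ1 leave a small number of bases
unassigned per unit and do not state the tiling rule, so the segmentation
rule here is explicit and configurable (`segmentation_params()`):

* **fixed** mode tiles in frame from position 1 and leaves `length %% 5`
  trailing residue bases — fully transparent, but a single indel shifts
  the frame of everything downstream;
* **dynamic** mode (default) minimizes *total cost* = Σ pentamer distances
  + `skip_penalty` × (residue bases) over all tilings by dynamic
  programming, letting the frame re-anchor after indels. The default
  `skip_penalty = 3` means a pentamer at distance ≤ 2 is always preferred
  to skipping its five bases; ties resolve toward assigning a pentamer
  rather than skipping (leftmost-pentamer preference), so results are
  deterministic.

The dynamic program is checked in the test suite against exhaustive
enumeration of every pentamer/skip tiling for sequences up to 30 bases,
and dynamic cost is verified never to exceed fixed-frame cost. Because the
published counts derive from an unstated rule, the package asserts
internal consistency of the published table (the fifteen 1-base derivative
counts sum to their printed aggregate) but does not claim cell-by-cell
reproduction of published spectra from sequence.

```{r spectrum}
arr <- generate_array(array_spec(seed = 1))
pentamer_spectrum(arr$record)
```

## Virtual digestion

Recognition patterns are IUPAC-aware (`compile_iupac()`), including
interior N runs (`GATNNNNATC`). The site-counting policy is explicit,
since "frequency of cut sites" is tool-dependent: all overlapping
occurrences count; a palindromic pattern (equal to its own IUPAC reverse
complement) is one double-stranded site and is counted once on the forward
strand; non-palindromic patterns are additionally sought on the reverse
strand and reported at forward-strand coordinates. `compare_frequencies()`
separates *presence transitions* (an enzyme losing its last site, or
gaining a first one) from mere count changes — the distinction that makes
"6 sites lost, Eco57I gained" a well-defined statement even when other
enzymes change 1→2.

Fragmentation (`digest_fragments()`) needs a cut offset: `cut_top` counts
the bases of (or beyond) the recognition pattern preceding the top-strand
cut, so type IIS enzymes cutting downstream (Eco57I `CTGAAG(16/14)`) have
offsets past the pattern end. A hit whose cut falls outside a linear
molecule still counts as a site but contributes no fragment boundary;
fragment lengths always sum to the molecule length. Only linear topology
is supported. The bundled 65-enzyme panel ships as an editable TSV; where
an offset was not curated the enzyme is countable but not fragmentable.
PCR-RFLP allele calling (`predict_rflp()`) is the gel analogue: "uncut"
means a single full-length fragment.

## Substitutions and indels

`align_global()` produces an end-to-end pairwise alignment (match +1,
mismatch −1, and an affine gap cost of `gap_open + gap_extend × L` for a
run of L gaps; defaults −5/−1). The optimization is delegated to
`Biostrings::pairwiseAlignment()`, a C implementation of Needleman–Wunsch
with affine gaps; score optimality is verified in the tests against
exhaustive enumeration of all alignments of short sequences. One design
consequence: the tie-break among co-optimal alignments is the library's
own (deterministic, but not a documented preference order). The default
gap costs make multi-base indels align as single runs rather than
scattered gaps, which is what the event-merging tally expects.

`tally_from_alignment()` defines a substitution as a column with two
differing non-gap bases (a base opposite a gap is never a substitution)
and merges each maximal gap run into one event — a reference-row gap is an
insertion, a sample-row gap a deletion — reporting positions in reference
coordinates and the signed net length change (Σ insertions − Σ deletions).
Ingested alignments (gapped FASTA or CLUSTAL via `read_alignment()`) are
treated as authoritative when reproducing published counts; computed
alignments may legitimately place ambiguous gaps elsewhere in repetitive
sequence.

**Known limitation.** In tandem-repeat context an indel's *position* is
alignment-ambiguous (a gap can slide within a repeat), so recovery tests
assert event counts, kinds and lengths, not exact coordinates. Further,
two large opposite-sign indels placed close together can be scored more
cheaply as a block of mismatches than as two long gap runs; exact event
recovery is therefore only guaranteed when events are well separated
(hundreds of matched bases), and the recovery tests plant events
accordingly.

## STS profiling and deletion signatures

In-silico PCR (`predict_amplicon()`) is the strict end-point analogue:
forward primer on the forward strand, the reverse primer's reverse
complement fully downstream, exact matching by default (mismatch tolerance
is opt-in), smallest product reported. Amplicon arithmetic from printed
primer coordinates is `rev.end − fwd.start + 1` on 1-based inclusive
intervals.

Deletion calling is signature-driven: a `deletion_signature` names the
markers that must be absent and the flanks that must be present, and
`classify_deletions()` reports *all* matching classes (no masking). Flank
requirements are the disambiguation mechanism for nested patterns — e.g. a
partial-deletion signature (gr/gr: the distal-boundary marker absent)
requires a marker that the full AZFc deletion removes, so an AZFc profile
calls only AZFc. The shipped signature file is a curated, editable
approximation of recurrent Y-microdeletion patterns expressed over the
bundled 51-marker panel; it is configuration, not hard-coded truth, and
was curated so that each class round-trips (a profile generated from a
class classifies as exactly that class). Adapt it to your own marker set.

## Absolute quantification

The standard curve regresses Ct on log10(known copies) — the direction in
which a ten-fold series at 100% efficiency has slope −1/log10(2) = −3.3219
(printed −3.32) — with replicates as individual points. Efficiency is
`10^(−1/slope) − 1`; R² below 0.99 or a slope outside [−3.6, −3.1] sets a
warning flag rather than an error. Unknowns extrapolate as
`copies = 10^((ct − intercept)/slope)` and normalize to copies per genome
equivalent (3.3 pg, one haploid human genome, configurable). Ct values are
inputs; no fluorescence-trace processing is attempted. Published absolute
copy numbers for specific cell lines are not recomputable without the
underlying Ct measurements, so the package validates the quantification
machinery by round-trip and noisy-recovery properties instead.

```{r qpcr}
curve <- fit_standard_curve(simulate_dilution_series(series_spec()))
curve
round(curve$slope, 2)
```

## What the synthetic generator emulates — and what it does not

* `generate_array()` draws each pentamer unit independently: intact with
  the leftover probability, otherwise a derivative at distance d with the
  configured rate, substituting d distinct positions with uniform
  alternative bases (so a class-d draw is at distance exactly d and the
  truth spectrum is exact). Defaults are 712 units (~3.56 kb scale) with
  rates 0.410/0.199/0.052/0.0126/0.0014 for classes 1–5 — the reference
  DYZ1 composition (292/142/37/9/1 per 712 unit slots). Real satellite
  units have positional correlation and homogenization structure that
  independent draws do not reproduce; passing recovery tests therefore
  shows the *bookkeeping* is exact, not that real arrays segment
  unambiguously.
* `inject_variants()` places seeded substitutions at least
  `min_event_spacing` (default 20) bases from every other event and
  applies planned indels right-to-left in reference coordinates; truth is
  recorded in the same form the tally reports.
* `simulate_dilution_series()` uses
  `ct = ct_at_1_copy − log(copies)/log(1 + efficiency)` plus Gaussian
  cycle-scale noise (the usual qPCR noise assumption; real replicate
  noise is heteroscedastic at low copy). The intercept default of 40
  cycles is a typical single-copy detection limit — the published work
  does not state one.
* `generate_sts_dataset()` builds profiles absent exactly at a signature's
  markers and, optionally, a mock template of primer–spacer–primer
  cassettes with synthetic 20-mer primers. The mock is a functional PCR
  target, not genomic sequence; real STS primers and their genomic context
  are not modelled.

All generators take explicit seeds, restore the caller's RNG state, and
are deterministic across processes.

## Numerical and scale choices

Coordinates are 1-based inclusive throughout. Segmentation ties prefer
pentamer assignment; alignment ties follow the alignment library;
fragment boundaries use top-strand cut positions (reverse-strand hits of
asymmetric cutters mirror via `cut_bottom`). Property tests run at
reduced scale — alignments mostly on 1.5 kb arrays with a handful of full
3.56 kb cases, 200 simulated standard curves, exhaustive oracles capped
at 30 bases (segmentation) and 6 bases (alignment) — sizes chosen so the
whole suite runs in well under a minute while still exercising every
contract.

## Limitations

* No methylation sensitivity, circular topology, or enzyme-vendor
  database synchronization in the digest module.
* No true multiple-sequence alignment: three-way comparisons are pairwise.
* No thermodynamic PCR model (melting temperatures, dimers); presence
  calling is sequence-match only.
* No Ct calling from raw fluorescence, and no relative (ΔΔCt)
  quantification.
* Deletion-signature content is a curated approximation and should be
  reviewed against current microdeletion literature before clinical-style
  interpretation.
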