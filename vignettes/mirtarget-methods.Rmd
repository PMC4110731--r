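---
title: "Whole-gene miRNA target prediction: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-gene miRNA target prediction: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarget)
```

## The problem and the modeling stance

Animal miRNAs repress genes largely through short "seed" pairing between
miRNA positions 2–7/2–8 and the target mRNA.  Most prediction tools restrict
the search to conserved canonical seed matches in 3'UTRs, which misses
experimentally supported sites in CDSs, 5'UTRs and promoters, non-canonical
sites with G:U wobbles, and species-specific (unconserved) interactions.
`mirtarget` takes the opposite stance: scan **all four gene regions** for
**five seed-match types**, then let two data-driven layers separate signal
from noise — per-cell enrichment weights estimated against a shuffled
background, and thermodynamic site scoring with an accessibility correction.
Conservation is deliberately not used.

## Seed-match semantics

Every position of a region sequence anchors an 8-nt *frame*: the target
window whose 3'-most nucleotide is opposite miRNA position 1 (strands
antiparallel, both 5'→3').  A frame is classified once:

1. `2t8A1` — miRNA positions 2–8 Watson–Crick paired *and* an adenine
   opposite position 1;
2. `2t8` — positions 2–8 Watson–Crick;
3. `2t7A1` — positions 2–7 Watson–Crick plus the adenine anchor;
4. `2t7` — positions 2–7 Watson–Crick;
5. `1t8GU` — positions 1–8 all paired, exactly one of them a G:U wobble.

Design notes, each the package's own resolution of a genuinely open point:

* **Precedence.**  A frame often satisfies several definitions (every `2t8A1`
  frame is also a `2t8` frame).  Each frame is counted once under the most
  stringent canonical type, and `1t8GU` is tested only when no canonical type
  applies.  The two families can otherwise collide: positions 2–8
  Watson–Crick with a wobble opposite position 1 satisfies the raw `1t8GU`
  definition *and* `2t8`.  Unique typing keeps per-cell counts well defined;
  the canonical-first order reflects that canonical matches are the stronger
  prior signal.
* **The A1 anchor** is a property of the target nucleotide (adenine opposite
  miRNA position 1), not of pairing — an adenine counts even when miRNA
  position 1 is not U.
* **Boundary frames.**  A match whose frame would extend past the region end
  (e.g. positions 2–8 pair but the nucleotide opposite position 1 falls
  outside the sequence) is not reported: the frame's context is undecidable.
* **Spans.**  Reported site spans cover the target nucleotides implied by the
  type (8 nt for `2t8A1`/`1t8GU`, 7 for `2t8`/`2t7A1`, 6 for `2t7`), 0-based
  half-open on the region's sense strand.  Overlapping sites at different
  offsets are all reported.
* **Promoters** are treated as transcribed-sense RNA (T→U); `N` bases never
  pair and never satisfy the anchor.

Insertion/deletion and mismatch seed variants have no fixed format and are
out of scope, as is 3'-compensatory pairing.

## Weight calibration

Given verified pairs, `count_matches()` tallies sites per (type, region) —
**per site occurrence, not per gene**: a corpus of hundreds of miRNAs against
thousands of genes yields thousands of counts per cell only under per-site
semantics, and per-site counting is what makes the totals below linear in
the sites.  `shuffle_background()` repeats the count after independently
shuffling every region sequence (each replicate reshuffles every gene once,
shared across the pairs that use it) and averages over replicates; 50
replicates is the reference protocol.  Then

$$\mathrm{SNR}_{ij} = \frac{\text{observed}_{ij}}{\text{background}_{ij}},
\qquad
W_{ij} = \frac{\mathrm{SNR}_{ij} - 1}{\mathrm{SNR}_{\mathrm{ref}} - 1},$$

with the reference cell (`2t8A1`, 3'UTR) fixed at weight 1 — in the bundled
calibration it is the most enriched cell, and the fit refuses to proceed if
its SNR does not exceed 1.

* **Shuffle model.**  Uniform mononucleotide permutation (Fisher–Yates) is
  the default: it matches the i.i.d. null and is the straightforward reading
  of "random shuffling".  A dinucleotide-preserving shuffle (random Eulerian
  path on the dinucleotide graph) is available via `shuffle =
  "dinucleotide"` for users who consider stacking composition part of the
  null; it is not the default and the bundled calibration does not use it.
* **Depleted cells.**  SNR < 1 would give a negative weight, letting a
  depleted site type *strengthen* a call through a negative-times-negative
  product.  Such cells are clamped to 0 (with a warning); zero-background
  cells are undefined (`NA`) and scoring a site there is an error.
* **Reproducibility.**  One user-visible seed; each (replicate, gene,
  region) shuffle derives a stable child seed by hashing, so results are
  independent of pair iteration order and parallelizable in principle.
* **Determinism caveat of the published counts.**  The bundled calibration
  stores the corpus counts with the background means printed as integers;
  the third decimal of a few derived weights is therefore not exactly
  recoverable, and the test suite asserts those cells to ±0.002 instead.

## Energetics

Each site is scored on its flanked window: up to 30 nt 5' of the site, the
site, and up to 20 nt 3', truncated at region ends — 58 nt for an 8-nt site
with full flanks.  The blanket "58 nt" window is taken as the 8-nt-site
case; 7- and 6-nt sites get 57/56-nt windows under the literal flank rule
rather than padded ones.

Two nearest-neighbor dynamic programs (Rcpp) score the window:

* **Duplex MFE** (`duplex_energy()`): all antiparallel intermolecular
  structures of the full miRNA against the window, Watson–Crick and G:U
  pairs, stack energies from a 6×6 pair-type table, affine bulge and
  interior-loop penalties, a duplex initiation term, and *no* intramolecular
  pairing — the defining property of hybridization-style scoring.  The empty
  duplex scores 0, so reported values are ≤ 0.
* **Opening cost** (`opening_energy()`): `dG_open` = MFE of the window with
  the site nucleotides constrained unpaired minus the unconstrained MFE,
  from an intramolecular fold with hairpins (minimum loop 3), stacks,
  bulge/interior loops and affine multiloops.  The constrained space is a
  subset of the unconstrained one, so `dG_open ≥ 0` identically.  MFE (not
  ensemble) energies are used throughout; partition-function accessibility
  is out of scope.

The bundled parameter file (`nn-reduced-1.0`) carries the classic published
Watson–Crick stack free energies at 37 °C exactly, approximate G:U wobble
stacks, and linear loop penalties.  Absolute kcal/mol values therefore
differ from any specific external folding engine; correctness is instead
guaranteed *structurally*: the test suite proves both programs equal to
exhaustive enumeration over all legal structures on short instances (≤ 10 nt
strands for the duplex, ≤ 14 nt windows for the fold), plus the `dG_open ≥
0` and flank-monotonicity properties.  Any alternative engine plugged behind
the same interface must satisfy the same properties.  `N` in a window is
simply unpairable.

## Scoring and calls

`score_pair()` forms `Total dG_duplex = Σ W_ij·dG_duplex(site)` and
`Total ddG = Σ W_ij·ddG(site)` over **all** sites of the pair (per-site
summation; duplicating a site exactly doubles its contribution).  Weight-0
sites stay in the breakdown with zero contribution so `n_sites` remains
informative.  `call_target()` requires **both** totals strictly below their
cutoffs ("less than"; boundary equality is a non-call).  The `default`
preset (−15.0, −10.0 kcal/mol) was chosen to yield prediction counts
comparable to established 3'UTR tools; `stringent` (−25.0, −14.0) trades
coverage for precision, and on any fixed corpus its call set is a subset of
the default's (both totals only get harder to reach).  Ranking is by
`Total ddG`, then `Total dG_duplex`, then gene id — stable and
deterministic.

## The synthetic generator

`generate_corpus()` draws i.i.d. background sequences (default uniform
composition; lengths promoter 200, 5'UTR 150, CDS 300, 3'UTR 300 nt — UTR
and CDS lengths in the realistic range for compact transcripts, and ≥ 60 nt
so every site has a full flanked window) and plants exact seed frames at
non-overlapping offsets, recording every planted site in a ledger.  Frames
are constructed to classify to exactly the requested type: e.g. a planted
`2t8` draws its anchor position from {C, G, U}, a planted `2t7` additionally
breaks pairing at position 8, and a planted `1t8GU` puts its single wobble
at positions 2–7 so no canonical type can claim the frame.  Because
classification is frame-local, flanking bases can never upgrade a planted
site, so the ledger is an exact truth set.

`enrichment_factor` is defined as the intended fold-excess over the
background baseline: each `planted` row plants `round(count ×
(enrichment_factor − 1))` copies per pair, so factor 1 is a pure-null corpus
(ledger empty, SNR → 1) and factor 3 with `count = 1` plants two exact sites
per pair.  What the generator does **not** emulate: dinucleotide/codon
structure, isoform families, region-specific composition, expression levels,
or site clustering — so passing the calibration-recovery tests shows the
estimator is consistent under its own null, not that real corpora are this
clean.

## Validation problem sizes

The package validates itself at these scales, chosen to exercise every code
path while keeping the suite quick: scanner vs naive oracle on 1,000 random
(miRNA, ≤ 200 nt sequence) instances; duplex DP vs enumeration on 500
instances (strands ≤ 10 nt); fold/opening DP vs enumeration on 200 windows
(≤ 14 nt); planted-cell weight recovery on 40 corpora of 200 pairs with 10
shuffle replicates each (the planted `2t8A1`/3'UTR cell must receive the
maximum weight in ≥ 95% of corpora); and the bundled-calibration weight and
proportion tables reproduced from their raw counts.

## Known limitations

* Energies are a reduced nearest-neighbor model: no dangling ends, no
  special hairpin/tetraloop bonuses, no temperature dependence (37 °C only),
  linear loop penalties.  Scores are comparable *within* a run, and the dual
  cutoffs are calibrated to this engine; mixing weight tables or cutoffs
  across engines is not meaningful.
* The per-region longest-isoform rule resolves isoforms independently per
  region, which can mix isoforms of the same gene across regions.
* Promoter scanning assumes the transcribed-sense strand; antisense promoter
  interactions are invisible.
* The weight estimator needs a corpus large enough that the reference cell's
  background is non-zero; for small corpora, use the bundled calibration
  instead of fitting.
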