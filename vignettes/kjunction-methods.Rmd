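---
title: "Geometric k-turn search: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric k-turn search: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kjunction)
```

This vignette is the package's own account of the methods it implements: the
geometric model behind the motif search, the thermodynamic model behind the
ITC module, the parameters that matter, and the choices made where the design
was genuinely open.

## The geometric model

A k-turn juxtaposes two helices — canonical (C) and non-canonical (NC) — at a
tight, characteristic kink. The search does not look at sequence at all; it
asks whether any two double-helical segments of a structure sit at the same
*relative position and orientation* as the C and NC helices of a reference
k-turn.

**Base pairs.** `detectBasePairs()` identifies A–U, G–C and the G•U wobble
from coordinates. A pair requires: C1′–C1′ distance in [8.9, 11.9] Å; at
least two base–base donor–acceptor heavy-atom contacts at ≤ 3.5 Å (for the
wobble, exactly its two canonical contacts O6···N3 and N1···O2); and base
planes within 65° of parallel. Conflicts are resolved greedily, one pair per
nucleotide, by summed hydrogen-bond score. These are standard geometric
pairing heuristics; all thresholds live in `ktConfig()` and none is
load-bearing for ideal geometry (an A-form duplex passes each criterion with
a wide margin — C1′–C1′ ≈ 10.7 Å, contacts ≈ 2.9–3.0 Å, coplanar bases).

**Helix segments and frames.** Two pairs form a minimal segment when their
C1′-midpoints are ≤ 5.5 Å apart with an inter-pair twist in [10°, 60°].
Pairs need *not* be sequence-adjacent: stacking across a strand exchange is
exactly what a junction produces, so excluding it would blind the scan to
the motifs it exists to find. Each segment yields a frame: origin at the
first pair's C1′ midpoint; unit axis toward the second pair's midpoint; the
strand1→strand2 C1′ direction projected perpendicular to the axis; and their
cross product. The triad is orthonormal and right-handed by construction
(checked by a validity method at every construction). Frames are emitted in
both pair orders during scanning, so helix polarity never has to be guessed.

**Relative transforms and matching.** A candidate segment is expressed in a
reference segment's coordinates: translation `t = Tᵀ(o_cand − o_ref)`,
rotation `R = Tᵀ T_cand`. Both are invariant under any global rigid motion —
the property the whole method rests on, and the one the test suite checks to
1e-6 over hundreds of random poses. Deviations from a pattern entry use the
two simplest bi-invariant metrics: Euclidean distance between translation
vectors and the angle of the composed rotation `R_obs R*ᵀ`. The rotation
angle is computed with the `atan2` form rather than `acos((tr−1)/2)`, which
loses half the working precision near the identity.

**Tolerances.** Defaults are 4 Å and 25°. No published thresholds exist for
this search; these were chosen once, generously, so that natural k-turn
variation (bending, twist differences of a helical step) still matches while
coaxial or unrelated geometry — which differs by far more than 25° of kink —
does not. Both are CLI flags and `searchPattern()` arguments. Multi-entry
patterns are OR-matched and the best entry wins; overlapping hits (sharing a
nucleotide on both the C and NC side) are merged keeping the smallest
tolerance-normalised combined deviation, which makes output order
deterministic.

## Role assignment and contacts

Roles are assigned by position in three dimensions, not by position in
sequence. The anchor is the tandem non-Watson–Crick purine•purine pairs that
open the NC helix: candidates are coplanar purine pairs (centre offset along
either base normal ≤ 2.5 Å — this is what separates a *pairing* purine from
a *stacked* one) with at least one base–base N/O contact in hydrogen-bond
reach. The pair nearest the C segment becomes 1b•1n; its non-bulged member
1n is recognised by having a sequence neighbour inside the C segment (the
non-bulged strand runs …−1n, 1n, 2n…). The loop is whatever lies between
the last C-helix pair and 1b on the bulged strand — three nucleotides are
labelled L1/L2/L3, four are L1/L1.1/L2/L3, anything else is reported as a
diagnostic rather than forced. Gaps between 1b and 2b are tolerated because
junction variants interpose extra nucleotides there. An explicit override
map always wins, which is also the escape hatch for "out of sequence"
complex topologies that no local heuristic can recover.

The contact report always contains the full standard set — the two conserved
cross-strand hydrogen bonds (L1 O2′ → 1n N1/N3, −1n O2′ → 2b N1/N3), the
2b N6 ↔ 2n N3/N7 distances, −2n O2′ ↔ 3b O2′, and L3 O2′ to the loop
phosphate pro-S oxygen — with unmeasurable entries flagged `missing` rather
than dropped. The N1/N3 class is simply whichever 2b nitrogen is nearer the
−1n O2′ donor; ties or missing atoms give `undetermined`. Narrative labels
call ≤ 3.5 Å "bonded" and ≤ 4.0 Å "borderline"; they are descriptions, never
assertions.

Superposition is least-squares rigid (Kabsch, via `bio3d::fit.xyz`) over the
atoms of the requested roles. "Backbone" is genuinely ambiguous, so both a
full set (P, OP1, OP2, O5′, C5′, C4′, C3′, O3′ plus ribose C2′, C1′, O4′)
and a phosphate/sugar trace are provided, and comparisons should report
which was used — the numeric RMSD between two given structures depends on
the choice. Note that removing atoms and re-fitting does *not* provably
lower the RMSD (the removed atoms may have been the best-fitting ones); the
package makes no such claim.

## The one-site ITC model

Per injection *i*, cumulative injected volume `dV` updates the cell totals
with the displaced-volume bookkeeping used by MicroCal ORIGIN
(`Mt = M0 (1−f)/(1+f)`, `Xt = Ls (dV/V0)/(1+f)`, `f = dV/2V0`); bound ligand
comes from the one-site quadratic with site concentration `n·Mt`; the heat
content is `Q = V0·ΔH·[bound]` and the differential heat carries the
conventional correction `ΔQᵢ = Qᵢ − Qᵢ₋₁ + (vᵢ/V0)(Qᵢ + Qᵢ₋₁)/2`. With the
correction disabled (`displacementCorrection = FALSE`) the increments
telescope exactly to `V0·ΔH·[bound]_final`, which is how the conservation
property is tested; the corrected series intentionally does not telescope,
because it accounts for heat carried out with the expelled volume.

Default protocol: 1.4 ml cell at 15 µM, 150 µM syringe, one 1 µl priming
injection followed by 24 × 8 µl, 303.15 K. The priming injection is excluded
from fits by default, as is standard practice. Fits run over (n, ΔH, Kₐ)
with `minpack.lm::nlsLM`, started at n = 1, ΔH from the largest early heat
per mole injected, and Kₐ = 1/cell concentration; non-convergence and
all-zero heats return flagged results, not exceptions. Heats are in
microjoules when ΔH is in kJ/mol; the unit label is carried on the
parameters object and nothing is converted silently.

Entropies follow the calorimetric-table convention: milli-units of the
energy unit per kelvin (J/K/mol next to kJ/mol). `deriveThermodynamics()`
always attaches the mass-action audit −RT ln Kₐ on both the kJ and kcal
scales. On the bundled TPP riboswitch table (`tppItcParams()`) the
tabulated ΔG column is consistent with ΔH − TΔS under its printed kJ/J
headers to within 0.006 kJ/mol, while −RT ln Kₐ reproduces the same numbers
only on a kcal scale — an internal unit inconsistency of the published
table that the audit reports on both scales rather than resolving by fiat.

## What the synthetic generators do and do not emulate

`buildIdealDuplex()` stacks idealized base-pair templates (planar bases in
the standard nucleic-acid base reference frame, an approximate
sugar-phosphate backbone) with rise 2.81 Å and twist 32.7°/bp about a
central axis. Wobble and sheared (trans sugar/Hoogsteen G•A) pair templates
are solved once, numerically, for their canonical contact distances.
`buildTwoHelixScene()` poses a second helix at any prescribed relative
transform exactly (loop closure through the full detect→frame→measure
pipeline is verified to 1e-3 after a PDB round trip), and
`buildSyntheticKTurn()` assembles a C helix, loop and sheared-pair NC helix
at a tight kink (~125° between outgoing axes, ~2.8 Å closest approach) with
a known ground-truth role map. The built-in reference pattern
(`kturnReferencePattern()`, also shipped as
`inst/extdata/kturn_pattern.json`) is *defined* by this scene, so planted
searches are exact by construction.

What this shows: the detection, framing, scanning, deduplication,
annotation and superposition machinery is correct on geometry where the
answer is known. What it does not show: performance on real crystallographic
coordinates, with their sugar puckers, sequence-dependent helical
parameters, modified residues and experimental noise. In particular the
synthetic k-turn realizes k-turn *architecture* but not the atomic
hydrogen-bond network — its cross-strand O2′ contacts are long, and its
N-class is whatever the rigid construction happens to give — so tests assert
the classifier's internal consistency (the class equals the nearer
nitrogen, and moving the donor flips it), never a particular class for the
fixture. Patterns for production scanning should be built from real
reference coordinates with `patternFromReference()`; structures named in
the literature (riboswitch and ribosomal entries) are ordinary inputs to
`loadStructure()` once downloaded.

Scene sampling in the specificity tests rejects a candidate "non-matching"
scene if *any* ordered segment pair falls within twice the tolerances
(`countPatternMatches()`): because both segment orientations are scanned, a
scene planted far from the pattern can still contain genuinely matching
geometry in another orientation, and counting that as a false positive
would test the sampler, not the scanner.

## Numerical and degenerate-input choices

* Frames reject axes shorter than 0.5 Å and hydrogen-bond vectors within 1°
  of the axis (`kjDegenerateFrame`), rather than returning ill-conditioned
  triads.
* Alternate locations resolve per atom by highest occupancy, ties to label
  "A"; only the first model of multi-model files is read (the motif search
  targets crystal structures).
* A nucleotide is *complete* when all heavy atoms of its parent
  ribonucleotide are present, exempting the 5′ phosphate group of a chain's
  first residue and OP3 always; models need ≥ 10 complete nucleotides to be
  scanned. "Complete" has no standard definition, and this matches common
  deposition practice.
* Modified residues map to parent bases through a small lookup (PSU→U,
  1MA→A, OMG→G, …); unknown residue names are dropped with a warning, never
  guessed.
* Alignment columns treat IUPAC ambiguity codes as gaps rather than
  fractional counts — the simplest defensible choice, and flagged in the
  output; frequencies are over non-gap symbols with the gap fraction
  reported separately so either denominator can be reconstructed.
  Information content is `2 + Σ f log2 f` bits with no small-sample
  correction by default (intended for alignments with thousands of
  sequences; a flag adds the standard `3/(2 ln2 N)` correction).
* All randomness (simulation noise, scene poses) flows from explicit seeds;
  requesting noise without a seed is an error, not a silent default.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
problems — 6–12 bp fixtures, 50-scene recall/specificity studies, 100-seed
Monte-Carlo ITC recovery, 200-pose invariance checks — chosen as the
smallest sizes at which the properties being asserted are meaningful. The
operations themselves are O(n²) in nucleotides (pair detection) and in
detected pairs (segments, scanning) with no further scaling assumptions,
and are routinely applicable to full riboswitch- and ribosome-sized models.

## Known limitations

* The role heuristic assumes the non-bulged strand is sequence-contiguous
  around 1n; S-turn ("out of sequence") topologies need an explicit role
  override, by design.
* Wobble detection requires both canonical contacts, so severely distorted
  G•U pairs are missed rather than mis-kinded.
* Only the trans sugar/Hoogsteen-style purine•purine check needed for role
  anchoring is implemented; this is not a general base-pair family
  annotator.
* The ITC module fits integrated per-injection heats; it does not integrate
  raw power traces, and it implements no multi-site or sequential models.
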