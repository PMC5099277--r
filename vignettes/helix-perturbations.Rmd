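---
title: "Helix perturbations in TM helices: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix perturbations in TM helices: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HelixScan)
```

HelixScan quantifies how transmembrane (TM) helices deviate from ideal
α-helical geometry: curvature, kinks, and interspersed 3₁₀- or π-helical
stretches, together with the backbone hydrogen bonds these perturbations
break and the interactions that compensate for them. This vignette is the
package's own account of the underlying models, the tunable parameters, and
the decisions taken where the design was genuinely open.

## Local helix parameters

All geometry starts from windows of four consecutive Cα atoms. With
difference vectors $B_1 = p_2 - p_1$, $B_2 = p_3 - p_2$, $B_3 = p_4 - p_3$,
the unit bisectors $V_1$ (of the angle at $p_2$) and $V_2$ (at $p_3$) point
from the backbone toward the local helix axis. The per-window parameters
are:

* **twist** $\Omega = \arccos(V_1 \cdot V_2)$ — rotation per residue,
  degrees;
* **axis** $u = V_1 \times V_2 / |V_1 \times V_2|$, sign-fixed so
  $u \cdot B_2 \ge 0$ (hence rise is non-negative when the trace is walked
  N→C, matching the convention of published per-step listings);
* **rise** $h = B_2 \cdot u$ — translation per residue, Å;
* **radius** $r = |B_2 - (B_2 \cdot u)u| \,/\, 2\sin(\Omega/2)$ — the
  circumradius implied by the projected chord. This chord-projection form
  uses only window-local quantities, unlike a point-to-axis distance, which
  would need a global axis estimate;
* **virtual torsion** — the signed dihedral of the four Cαs;
* **bend** — the angle between the axes of window $i$ and window
  $i+\mathrm{offset}$.

On exact parametric helices all of these recover the generator values to
machine precision; the test suite asserts recovery to $10^{-6}$ and
invariance under rigid motion to $10^{-9}$. Arccos arguments are always
clamped to $[-1, 1]$; windows with (near-)collinear points are flagged
undefined and excluded downstream, never zero-filled.

### Bend offsets and MaxBA

`bendingAngles()` defaults to offset 1 (successive windows), the
granularity of per-step tables. The *maximum local bending angle* (MaxBA)
search in `geometryClass()`, however, evaluates bends at a **bracketing
offset of 4 windows**. The reason is measurement, not convention: a sharp
hinge distorts every window that straddles it, so successive-window bends
underestimate the hinge angle (a planted 25° hinge reads ≈21° at offset 1),
while pairs four windows apart bracket the hinge with one clean window on
each side and recover planted hinges of 15–40° within +1°. A smooth arc
likewise accumulates ≈4× more turning at offset 4, lifting genuine
curvature above noise. The MaxBA *locus* is taken from the offset-1 series
(Cα₂ of the later window of the sharpest successive pair), which pins the
hinge residue exactly on synthetic ground truth. The first and last windows
of a series carry boundary artifacts (their bisector geometry is one-sided)
and are excluded from MaxBA searches and axis averaging.

## Helix typing

Windows are labelled α / 3₁₀ / π when twist and rise fall inside the class
bands (defaults, degrees and Å):

| class | twist | rise | typical radius |
|-------|-----------|------------|------|
| α | [93, 108) | [1.30, 1.70] | 2.3 |
| 3₁₀ | [108, 130] | [1.70, 2.30] | 1.9 |
| π | [70, 93) | [0.70, 1.45] | 2.7 |

The exact cut-offs of the established assignment programs are not
published; these bands were calibrated once against the packaged per-step
fixture (the TM2 region of mitochondrial cytochrome-c oxidase, 1v55:A,
residues 51–87) and are exposed in `typingThresholds()` so any analysis can
be pinned. Bands are half-open at shared boundaries so a window cannot
match two classes; if a user configures overlapping bands, the class whose
typical radius is nearest wins.

### Segment merging

`mergeSegments()` turns window labels into residue-bounded segments in four
steps:

1. **Smoothing.** A single window whose label disagrees with the nearest
   classified windows on both sides (which must agree with each other) is
   absorbed into that class when its twist lies within the class band
   widened by 8°. Real π stretches frequently contain one α-parameter
   window (e.g. window 77 of the packaged fixture, twist 99.7° inside an
   otherwise π run); without smoothing every such outlier would split the
   segment.
2. **Boundary anchoring.** A segment may not *terminate* on a window that
   is an isolated raw occurrence of its class — a window whose raw label
   matches the segment but which has no raw same-class neighbour window.
   Such terminal windows are trimmed back to unassigned. The rationale:
   near segment boundaries the parameter series oscillates (windows mix
   residues of both conformations), and a lone in-band window amid that
   oscillation is boundary noise, not evidence that the segment extends.
   Interior outliers absorbed by smoothing are untouched. A consequence is
   that a perturbed segment needs two consecutive raw windows to exist at
   all, which matches the minimum π length below.
3. **Minimum spans.** Segments must span ≥4 (α), ≥3 (3₁₀), ≥5 (π)
   residues; shorter runs are absorbed into the longer twist-compatible
   neighbour, else unassigned.
4. **Residue claims.** A run of windows $i..j$ claims residues $i..j{+}3$
   (a 4-Cα window claims all four residues). Where adjacent claims overlap,
   the *perturbed* class keeps the contested residues (π > 3₁₀ > α). This
   captures how assignments are reported in practice: the π segment of the
   fixture claims Val64–Leu82 in full, and the flanking α helices yield,
   giving `51–63=α, 64–82=π, 83–87=α`.

The packaged fixture is the calibration anchor: it must reproduce that
segmentation exactly, and a unit test enforces this without any downloaded
coordinates.

## Perturbation taxonomy

`perturbationType()` assigns one of 11 classes by priority: interspersed π
segment → interspersed or terminal 3₁₀ segment → kink → curvature →
linear. Priority mirrors the mutual exclusivity of the classes: a π-bulge
always bends the helix, so a bulged helix would otherwise double-count as
kinked.

* A π/3₁₀ segment is **proline-mediated** when a proline lies in
  `[first − 1, last + prolineWindow]` (default window 4 residues
  downstream; prolines just past the segment end commonly terminate it).
* A kink is **P1** when the proline sits at MaxBA or MaxBA+1, **P2** when
  it lies elsewhere within `[MaxBA − 4, MaxBA + 5]`, and non-proline when
  no proline falls in that window. The P1/P2 distinction is not published
  as a formula; this MaxBA-relative rule is the package's documented
  convention, with upstream prolines (−4..−1) deliberately grouped into P2.
* Curved/linear helices split only on proline presence.

Geometric classes use: KINKED iff max interior bend ≥ 20°; else CURVED iff
mean interior bend ≥ 6° *and* the mean axes of the first and last quarters
of the helix differ by ≥ 15° (the direction-consistency requirement
separates a coherent arc from accumulated noise); else LINEAR. All four
numbers live in `pipelineConfig()`.

## Hydrogen bonds and unpaired carbonyls

Criteria (config defaults in `hbondCriteria()`; the original non-bonded
analysis software does not print its cut-offs):

* backbone N–H···O: N···O ≤ 3.5 Å and N–H···O angle ≥ 120°, with the amide
  H built geometrically (in the C(i−1)/N/CA plane, N–H 1.0 Å, opposite the
  bisector). Separations 3/4/5 categorise bonds as 3₁₀/α/π-type; prolines
  never donate; bifurcated acceptors are allowed.
* A carbonyl O(i) is **unpaired** when no backbone bond reaches it from
  N(i+3), N(i+4) or N(i+5) inside the helix. Residues within four positions
  of the helix C-terminus are excluded: their canonical α partner N(i+4)
  lies outside the helix, so a missing bond there is a boundary artifact —
  with this bound an ideal α-helix reports exactly zero unpaired interior
  carbonyls.
* **Stabilisers** of an unpaired carbonyl: side-chain N/O donors within
  3.5 Å (intra- or inter-helical); Cα/Cβ–H···O with heavy-atom C···O ≤
  4.0 Å, counted **inter-helically only** — inside a helix the i+2..i+4
  Cα/Cβ atoms sit within 4 Å of every carbonyl by construction, so
  intra-helical C–H···O contacts carry no signal; and proline Cδ/Cγ within
  3.8 Å. Scope (intra/inter) is decided by TM-segment membership, not chain
  identity, since one chain contributes many helices.

The synthetic φ–ψ presets — α (−63, −42), 3₁₀ (−49, −26), π (−57, −70) —
were chosen to land inside the typing bands *and* to produce mutually
exclusive ladders under exactly these criteria (verified: 20-residue ideal
backbones give only i+4, only i+3, only i+5 bonds respectively), which
makes the brute-force all-pairs oracle comparison in the tests sharp.

## Crossing angles

A helix's overall axis is the unit mean of its interior window axes,
oriented N→C (a best-fit-line alternative is available via
`overallAxis(..., method = "fit")`; the two agree within 0.5° on ideal
helices). The crossing angle is `atan2(|a×b|, a·b)`, kept unfolded in
[0°, 180°] because antiparallel TM pairs are reported as obtuse angles in
the field's tables. "Vicinity" is a minimum CA–CA distance ≤ 8 Å — a
documented proxy, since published interaction calls do not state their
criterion.

## The synthetic generator

`makeParametricCA()`, `makeBackbone()`, `insertKink()`, `makeCurvedCA()`
and `generateBundle()` produce structures whose every relevant property is
known by construction: exact twist/rise/radius, planted hinge angles and
loci, planted π/3₁₀ stretches, pairwise placement angles, and a ledger
recording all of it. Kinks are rigid hinges (no smoothing); curvature is
distributed per-residue rotation about a fixed perpendicular axis. The
generator emulates the geometric regimes of real TM helices but *not* their
thermal noise, side-chain packing, sequence-dependent φ–ψ scatter, or
lattice contacts. Passing tests therefore demonstrate correctness of the
computations on clean geometry and exact bookkeeping of planted features;
they do not by themselves establish detection rates on experimental
coordinates, where band boundaries blur. Full backbones carry Cβ at the
ideal tetrahedral position (needed for Cβ–H···O checks) but no further
side-chain atoms; proline ring atoms are not built, so Cδ/Cγ stabilisation
is exercised with explicitly constructed test geometry.

## Numerical choices and degenerate inputs

* Arccos clamping everywhere; unit-axis tolerance 10⁻⁹.
* Collinear or duplicated Cα windows → flagged undefined; chain breaks
  (CA–CA outside (2.0, 4.5] Å) split a series with a warning and flag the
  affected windows.
* Torsions at chain termini or across missing atoms are absent (NA), never
  zero.
* Half-open typing bands remove boundary double-matches; the radius
  tie-break only engages for user-configured overlapping bands.
* All pipeline stages are deterministic; `generateBundle()` randomises only
  helix phases, under an explicit seed. Reports embed the package version
  and an FNV-1a hash of the full configuration, and reruns are
  byte-identical.

## Problem sizes

The test suite works at desk scale by design: helices of 16–32 residues,
bundles of 2–7 helices, 100 seeded random backbones for the oracle
equivalence property, and 25–30 replicates for rigid-motion and recovery
properties. These sizes were chosen because every property being tested is
window-local or per-helix, so longer helices add replication, not new
geometry.

## Known limitations

* Typing bands are calibrated on one fixture; against other assignment
  programs, boundary residues of 3₁₀/π segments can differ by one or two
  positions (hydrogen-bond-energy based assignments end the fixture's π
  helix at Gly79 rather than Leu82).
* Poly-proline II detection is not implemented (the window-parameter route
  would need a dedicated band and left-handed twist handling).
* The curved/linear boundary uses the direction-consistency rule rather
  than an arc-fit quality statistic; gently S-shaped helices fall to
  LINEAR.
* Dataset-scale statistics (occurrence tables across protein families)
  require a curated structure set that the package does not ship; the
  pipeline produces the per-structure rows from which such tables are
  aggregated.
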