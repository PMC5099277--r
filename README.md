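# HelixScan

Transmembrane (TM) helices of membrane proteins are rarely the ideal, linear
α-helices of textbooks. They curve, kink at prolines (and sometimes without
them), and locally relax into 3₁₀- or π-helical stretches. Each of these
perturbations changes the backbone hydrogen-bonding register, leaving
carbonyl groups without their helical N–H···O partner — free valences that
helices use for inter-helical contacts, and that shift how a helix sits in
the bilayer. HelixScan is an R package for structural bioinformaticians who
want to detect, classify and account for these perturbations directly from
Cα coordinates.

## What it computes

**Local helix parameters.** For every window of four consecutive Cα atoms
(CA₁…CA₄) with difference vectors B₁, B₂, B₃, the package forms the angle
bisectors V₁ (at CA₂) and V₂ (at CA₃) and derives

- twist Ω = arccos(V₁·V₂),
- local axis **u** = (V₁×V₂)/|V₁×V₂|, sign-fixed so **u**·B₂ ≥ 0,
- rise per residue h = B₂·**u**,
- radius r = |B₂ − (B₂·**u**)**u**| / (2 sin(Ω/2)),
- the virtual torsion of the four Cαs, and local bending angles between
  window axes.

On an exact circular helix these recover the generator parameters to machine
precision.

**Helix typing.** Per-window (twist, rise, radius) bands assign each window
to α (≈100°, ≈1.5 Å), 3₁₀ (≈111–120°, ≈2.0 Å) or π (≈85°, ≈1.2 Å); a merging
pass with outlier smoothing and boundary anchoring turns window labels into
residue-bounded segments such as `51–63=α, 64–82=π, 83–87=α`.

**Perturbation classification.** Each TM helix receives one of 9
perturbation types (plus the Linear/Curved references): LINEAR(_PRO),
CURVED(_PRO), KINKED_PRO_P1, KINKED_PRO_P2, KINKED_NONPRO, G310_PRO/NONPRO,
PI_PRO/NONPRO — combining the maximum local bending angle (MaxBA), the typed
segments, and proline positions.

**Hydrogen-bond accounting.** Backbone N–H···O bonds at separations i+3 /
i+4 / i+5, the unpaired carbonyls a perturbation leaves behind, and their
stabilisation by side-chain donors, inter-helical Cα/Cβ–H···O contacts, or
proline Cδ/Cγ atoms — each tagged intra- vs inter-helical.

**Crossing angles.** Pairwise inter-helical crossing angles from the mean
interior window axes (unfolded to [0°, 180°], so antiparallel pairs read
≈155–175°), with a CA-distance vicinity flag.

**Synthetic ground truth.** A generator for parametric Cα helices, full
backbones at preset φ–ψ (α: −63/−42, 3₁₀: −49/−26, π: −57/−70), planted
kinks, π-bulges/3₁₀-runs, and multi-helix bundles with a ledger of every
planted feature — the package's test substrate.

## Worked example

```r
library(HelixScan)

## 1. Type the packaged per-step parameter series (cytochrome-c oxidase
##    1v55 chain A, TM2 region, residues 51-87)
fx <- readStepFixture(system.file("extdata", "1v55A_tm2_assp_steps.tsv",
                                  package = "HelixScan"))
segs <- mergeSegments(classifySteps(fx), fx, region = c(51, 87))
segs
#> HelixSegments: region 51-87, 3 segment(s)
#>   51-63=α, 64-82=π, 83-87=α
```

The 36 windows resolve into a 19-residue interspersed π-helix (Val64–Leu82)
flanked by two α segments — the hallmark long π-helix of the heme-copper
oxidase TM2.

```r
## 2. Scan a synthetic pi-bulge helix end to end
pp <- perturbedPhiPsi(26, insert = "PI", at = 12, length = 3)
helix <- makeBackbone(pp$phi, pp$psi, 26, chain = "A")
scan <- scanHelix(helix, tmSegments("A", 1, 26, "TM1"))
scan$perturbations
#>   helix chain first last     class maxba_res maxba_deg pro_res segment
#> 1   TM1     A     1   26 PI_NONPRO        15      21.9      NA   11-16
scan$carbonyls
#>   chain seqnum stabilized helix     class anchor_offset
#> 1     A     12      FALSE   TM1 PI_NONPRO            -5
```

The planted 3-residue π stretch is found as a PI_NONPRO perturbation
(segment 11–16); it bends the helix by ~22° and frees the carbonyl of
residue 12, five positions upstream of the perturbation anchor.

```r
## 3. Crossing angle of two helices placed at 25 degrees
b <- generateBundle(list(
  list(n = 22),
  list(n = 22, centroid = c(10, 0, 0),
       direction = c(sin(25 * pi / 180), 0, cos(25 * pi / 180)))), seed = 1)
crossingAngle(overallAxis(stepSeries(b$structure, chain = "A")),
              overallAxis(stepSeries(b$structure, chain = "B")))
#> [1] 25
```

For real structures, start from `readStructure("file.pdb")` plus a
`tmSegments()` table of helical-region bounds (OPM-oriented files also work
with the membrane-slab mode of `selectSegments()`).

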