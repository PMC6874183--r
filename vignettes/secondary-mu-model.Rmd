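---
title: "A volume-based secondary MU model for scanned proton beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A volume-based secondary MU model for scanned proton beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsmu)
```

## The problem

Pencil-beam-scanning (PBS) proton treatments are delivered as thousands of
individually weighted spots, so the classical single-point monitor-unit (MU)
second check of photon and passive-scattering practice has no direct
analogue: the cGy/MU output of a composite scanned field only exists after
inverse optimization. For single-field-uniform-dose (SFUD) plans, however,
each field delivers a uniform dose to the target on its own, and the machine
output needed to do that is driven almost entirely by coarse geometric
features of the target/beam pair. `pbsmu` implements a factor-based model on
exactly those features:

* the target **volume** $V$ (cm³) and its **beam's-eye-view (BEV) projected
  area** $A$ (cm²), which define an *equivalent cuboid* of SOBP width
  $W = V/A$;
* the **beam range** $R$, taken as the average water-equivalent depth (WED)
  of the *distal* target surface (SFUD spot weights are concentrated at the
  distal edge, so the distal surface sets the composite range); for
  range-shifted beams the shifter's water-equivalent thickness (default
  4.1 cm) is added to $R$;
* for range-shifted beams, the **air gap** $g$ between the shifter face and
  the patient surface on the central axis.

The per-beam secondary MU is a product factorization in the style of
conventional external-beam MU checks:

$$
\mathrm{MU} \;=\;
\frac{D_\mathrm{rx}}
     {\mathrm{OF}(A, W)\;\cdot\;\mathrm{DF}(R)\;\cdot\;\mathrm{AGF}(g)\;\cdot\;k_\mathrm{cal}}
$$

where $D_\mathrm{rx}$ is the prescribed point dose at the SOBP centre (cGy),
OF is the output factor (cGy/MU) tabulated for cuboids at the reference
depth of 20 cm and reference gap of 1 cm, DF is the depth factor (ratio of
output at range $R$ to the 20 cm reference, so $\mathrm{DF}(20)=1$), AGF is
the air-gap factor for shifted fields ($\mathrm{AGF}(1)=1$; identically 1
for open fields), and $k_\mathrm{cal}$ is a measured calibration scale
(default 1, i.e. raw "model MU"). Off-axis and inverse-square terms are
neglected, consistent with the large effective source-axis distance of
scanning systems; rays are traced as a parallel beam.

The method is valid for SFUD optimization only. Beams tagged as
multifield-optimized are refused by `compute_mu()` rather than computed
badly.

## Geometry measurements

Targets are voxel masks on regular axis-aligned grids; media are
relative-stopping-power (rsp) grids. Conventions, all documented in the
function help and pinned by tests:

* **Frame and angles.** IEC-61217-style: +x patient-left, +y anterior,
  +z superior; gantry 0° enters from anterior (beam direction $(0,-1,0)$),
  couch rotates about the vertical axis. Only relative geometry matters to
  the model, so any consistent convention would do; this one is fixed and
  tested against explicit rotation-matrix composition.
* **WED ray tracing.** The line integral of rsp is evaluated by *exact
  voxel-boundary traversal* (per-segment lengths between parametric plane
  crossings), not fixed-step marching. On piecewise-constant grids this is
  exact; the acceptance suite checks agreement with a 10 µm brute-force
  Riemann sum to 0.01 cm on 100 randomized layered phantoms. The patient
  surface is the first crossing, travelling downstream from outside, where
  rsp exceeds a threshold (default 0.2, excluding air); a grid boundary that
  is already above threshold is treated as the surface.
* **BEV rasterization.** Occupancy along each BEV-pixel ray is sampled at
  half the pixel size, with first/last crossings refined to the actual mask
  boundary by bisection (~10⁻³ cm). The BEV pixel size is exposed as a
  parameter (the projection raster used in the original workflow is not
  specified anywhere authoritative); it must not exceed the voxel spacing.
  Note that analytic comparisons (sphere shadow = $\pi r^2$) converge
  linearly in the *voxel* size because the digitized union-of-cubes
  silhouette genuinely protrudes beyond the smooth surface.
* **Disconnected targets** are treated as one union for volume and area;
  the distal surface is the per-ray most-downstream crossing.

## Factor tables

Tables are plain CSV (2-D OF as `sobp_width_cm,<area...>` rows; DF and AGF
as two-column tables) with a JSON sidecar for reference conditions and
calibration. On load, axes are sorted and must then be strictly ascending
and positive; DF and AGF are renormalized to exactly 1 at their reference
abscissae *only if* they are already within 2% of 1 — a larger deviation
contradicts their definition as ratios to the reference condition and is
treated as a data error, not silently rescaled.

Interpolation is bilinear for OF and monotone piecewise-cubic Hermite
(Fritsch–Carlson, overshoot-free) for the 1-D tables, with linear as a
configurable fallback. Queries outside a table clamp to the boundary and
carry a machine-readable warning that propagates into results and escalates
the CLI exit code under `--strict`: a second-check tool should fail safe,
not extrapolate.

Open and range-shifted delivery get separate OF tables because their
effective reference depths differ (20 cm vs 15.9 cm of water plus the
4.1 cm shifter).

## The toy beam model (synthetic world)

No commissioned beam data ship with the package; the institution-specific
factor curves are inputs. To make the whole method testable at desk scale,
`toy_model_config()` defines an analytic stand-in for the planning system
and `generate_factor_set()` / `generate_case()` replay the tabulation
experiments against it:

* **Pristine peak**: a range-invariant shape — entrance plateau (35% of
  peak, rising 0.4%/cm toward the peak, faded out by a sigmoid 1 cm before
  it) plus an asymmetric Gaussian peak (σ 0.45 cm proximal, 0.25 cm distal)
  — scaled by a per-range efficiency $e^{-k(R-20)}$ with $k=0.008$/cm.
* **SOBP flattening**: non-negative least squares (in-package
  Lawson–Hanson) on a dense plateau sampling, energy layers every 0.3 cm
  (kept below the distal σ so plateaus are ripple-free; achieved flatness is
  ≤ 1% across widths 2–10 cm, tested against the 2% requirement).
* **Lateral model**: spots on the BEV pixel lattice with Gaussian sigma
  0.45 cm for open fields and $0.6 + 0.08\,g$ cm behind the shifter —
  growing with the air gap, which is what creates the AGF falloff. The
  output's area dependence enters through the Gaussian lattice sum at the
  field centre ($\mathrm{erf}^2$ in the continuous limit).
* **Ground truth MU** for an arbitrary voxelized target: every BEV column is
  flattened on its own chord (cached by chord width), the dose at the
  SOBP-centre point on the central axis is accumulated through the lateral
  kernel, and MU is the total weight needed for the prescribed dose. This is
  a genuinely independent path from the cuboid shortcut: it sees the actual
  shape.

**Deliberate separability.** Because the peak shape is range-invariant and
the lateral sigma does not depend on energy, the toy output for a cuboid
factorizes *exactly* into OF·DF·AGF at the tabulation conditions. That is a
design choice, not an accident: the synthetic world is built so that the
factor method is exact at its own calibration points, and end-to-end
deviations on non-cuboid targets isolate the *cuboid approximation itself*.
Self-consistency (cuboid node cases within 0.5%) and table recovery are the
acceptance standard — numeric agreement with any institution's commissioned
curves is explicitly a non-goal.

The depth-factor sweep translates a 125 cm³ cube (25 cm² face) through
water; for table nodes shallower than the cube permits, a 2 cm-wide cuboid
with the same face is used — in the separable toy model the DF curve is
width-independent, so this reproduces the same values. The air-gap sweep
uses the 125 cm³ cube centred at 7.5 cm depth (chord 5–10 cm of water).
Generated tables are deliberately dense (near-geometric area axis, 0.5 cm
width steps): OF varies like $1/A$, which is convex, so sparse area sampling
would put several percent of pure bilinear-interpolation error into every
verification — table density is the supplier's responsibility and the
generator errs on the dense side.

**Synthetic cases.** Cuboid "node" cases replay the three tabulation
conditions (output-factor nodes at reference depth and gap, depth-factor
nodes, air-gap nodes). Clinically styled cases cover four site archetypes —
deep open ellipsoids (pelvis), shallow range-shifted ellipsoids/blobs
(brain), mid-depth blobs at oblique angles (lung), shallow shifted blobs
(head and neck) — with sizes 2–4.5 cm semi-axes, centre depths 5.5–21 cm,
air gaps 1–6 cm and a prescribed dose of 200 cGy. Phantoms are uniform
water with a flat entry surface orthogonal to the beam; the only stochastic
element is the seeded sinusoidal perturbation of blob surfaces. What these
cases do *not* emulate: tissue heterogeneity, real contour topology, beam
divergence, per-spot optimizer behaviour, and measurement noise — so a
green round-trip establishes internal consistency of the implementation,
not clinical accuracy of any institution's tables.

## Known bias of the cuboid approximation (and one red criterion)

The acceptance suite demands, for ≥ 40 non-cuboid synthetic beams, a group
mean within ±1% and SD ≤ 5%. In this package's stated world the SD clause
holds (~1%) but the mean sits at about **+3.5%, and the corresponding
assertion is left failing rather than widened**. The bias is structural, not
noise: the total layer weight needed to flatten a chord of width $w$,
$T(w)$, is *concave* — a thin edge chord still needs essentially the full
distal-peak weight, while entrance dose accumulated from distal layers makes
wide chords progressively cheaper. The equivalent cuboid prices every column
at the mean width $V/A$, and by Jensen's inequality
$\mathbb{E}[T(w)] < T(\mathbb{E}[w])$ for curved targets, so the model
systematically over-predicts MU by a few percent for ellipsoids and blobs —
consistent with the expectation that a curved target's ground truth differs
from the cuboid model by a few percent in a fixed direction. In clinical use
this residual is exactly what the final measured-dose calibration
($k_\mathrm{cal}$, from patient-specific QA) absorbs; the synthetic
acceptance deliberately runs with $k_\mathrm{cal}=1$ to expose the raw
model. The toy-model parameters that set the size of this effect (entrance
fraction 0.35, the textbook entrance-to-peak ratio) were chosen before the
measurement and not revisited.

A second, smaller limitation is faithful to the method as published: AGF is
tabulated at a single volume, so small range-shifted fields at large gaps
carry a residual area-dependence of the gap correction (a few percent at
10–20 cm² areas).

## Numerical choices

| quantity | default | why |
|---|---|---|
| surface threshold | rsp 0.2 | excludes air, tolerates lung-like media |
| BEV pixel | ≤ voxel spacing (0.25 cm in synthetic cases) | sampling pre-condition; errors scale with voxel size |
| occupancy sampling step | pixel/2, bisection-refined crossings | silhouette error ≪ 1%, chords exact to 10⁻³ cm |
| WED integral | exact voxel traversal | zero marching error on piecewise-constant grids |
| layer spacing | 0.3 cm | ≤ distal σ ⇒ ripple-free plateaus |
| renormalization tolerance | 2% | beyond it, a table contradicts its own definition |
| extrapolation | clamp + warning, `--strict` escalates | second checks fail safe |
| DF/AGF interpolation | monotone cubic | smooth curves, no overshoot between nodes |

Degenerate inputs error loudly and early: empty masks, rays that never find
a patient surface, shifter faces inside the patient, equivalent widths that
reach or exceed the effective range (pathological shapes are refused, not
truncated), non-positive factors.

## Out of scope

DICOM RTSTRUCT/CT ingestion is not implemented (no DICOM reader is
available in the supported dependency set); the JSON case format and the
rasterized-mask constructors are the ingestion path. There is no dose
calculation on patient CT, no spot-level verification, no divergent-beam
projection, and no support for multifield-optimized (IMPT) plans — the last
by the method's own stated scope.
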