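---
title: "Design-based stereology of synovial joints: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of synovial joints: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the estimators it
implements, the phantom and virtual-sectioning model used to validate them,
the numerical and design choices made where the construction was genuinely
open, and what the validation does and does not demonstrate.

## The estimation model

All estimators operate on a tidy per-section counts table — one row per
section, one specimen per `specimen_id` — plus four probe constants carried
as columns: the section spacing `t_spacing_um` (T), the grid area per point
`area_per_point_um2` (a/p), the cycloid curve length per test point
`length_per_point_um` (l/p), and the counting-frame area `frame_area_um2`
(Af).

**Cavalieri volume.** Sections are parallel planes at spacing T with a
uniform random start; a square point grid with pitch `sqrt(a/p)` and a
uniform random offset is overlaid on each. The estimator
`V = ΣP · T · (a/p)` is design-unbiased for any object shape. Computation
is in µm³ and reported in mm³ (1 mm³ = 10⁹ µm³).

**Delesse volume fractions.** On the same point totals,
`Vv = ΣP_comp / ΣP_ref` estimates each compartment's volume fraction, and
`Vv · V` its absolute volume. The pipeline keeps the Cavalieri reference
total and the Delesse reference total as one column; this assumes both
probes share the reference point count, which the package's simulator
enforces by construction (the raw-count schema would accept imported counts
with the same convention).

**Vertical-design surfaces.** Sections all contain a fixed "vertical" axis
and are randomly rotated about it. That design biases plane orientations,
so straight test lines would bias surface estimates; cycloid arcs with
their minor axis parallel to the vertical direction have a sine-weighted
tangent distribution that exactly cancels the orientation bias. With
intersection counts I between arcs and a compartment interface,
`Sv = 2ΣI / (ΣP · l/p)` (reported in mm⁻¹) and the absolute surface is
`Sv · V` (mm²; the product of mm⁻¹ and mm³, which is the unit the study's
tables use). Note the identity `Sv · V = 2ΣI · T · (a/p) / (l/p)`: the
point total cancels, which is why the absolute surface is exactly unbiased
while `Sv` alone is a (slightly biased, asymptotically consistent) ratio
estimator.

**Chondrocyte profile densities.** A purely 2-D quantity: profiles per mm²
of section area, counted in unbiased frames with the half-open rule — a
profile counts if it lies in the frame's interior or on its top or right
(acceptance) edge, never on the left or bottom (forbidden) edge. Under
this rule frames tiling a region count each profile exactly once, a
property the tests assert exactly. Isolated profiles, profiles belonging
to isogenous groups, their sum ("total"), and the number of groups are
reported separately; a group is counted when at least one of its member
profiles is counted (so a group clipped by a frame can contribute a single
counted cell).

**Coefficient of error.** The printed source expression for the Cavalieri
CE is typographically ambiguous, so the package implements two readings
and records which was used. The default, `gundersen_noise`,
`CE = sqrt(0.0724 · (B/√A) · √n / (ΣP)^{3/2})`, is the Gundersen–Jensen
point-counting noise prediction; it reproduces the empirical scaling
CE ∝ n^(−1/2) when points grow proportionally with sections, which matches
the observed decrease of the efficiency curves. The alternative reading
`0.0724 · (B/√A) · √(n/ΣP)` is selectable via `ce_control(variant =
"sqrt_ratio")`. The shape coefficient B/√A defaults to the circle value
`2√π ≈ 3.545`: it is the theoretical minimum (enforced as a validity
bound), it is exact for the spherical phantoms' circular profiles, and
`shape_coefficient()` lets users estimate it from measured profile
boundaries and areas when geometry is available. Every output echoes the
variant and coefficient used.

## The phantom

The joint is idealized as five nested compartments delimited by radii
r₁ < … < r₅: bone core, cartilage shell, synovial space, synovial
membrane, capsule. Anatomical realism is deliberately not the goal — exact
ground truth is. Two controlled departures from sphericity exist precisely
to stress the estimators where isotropic phantoms cannot:

- a **prolate stretch** along the vertical axis (`axis_scale`), making the
  tracked surfaces anisotropic — the decisive test of the cycloid
  orientation weighting, since an isotropic probe persuades on spheres for
  the wrong reasons;
- a **villous perturbation** of the membrane inner boundary,
  `r₃(θ) = r₃ + A·cos(fθ)`, mimicking inflamed synovial villi. Amplitude
  is bounded (`A < (r₃−r₂)/2` and `r₃+A < r₄`) so compartments never
  self-intersect; truth converges to the smooth values as A → 0 (tested at
  A = 0.1 µm against a 10⁻⁴ relative gap).

Truth volumes and surfaces use closed forms for the spherical case and 1-D
quadrature (axisymmetric profile integrals, relative tolerance 1e-9) for
stretched or villous cases; quadrature failure raises an error rather than
falling back silently. The two tracked surfaces are the cartilage edge in
contact with the synovial space (the r₂ interface) and the membrane inner
boundary (r₃) — the package tracks exactly those interfaces and documents
that choice here, since "cartilage surface" could in principle mean either
side of the shell.

**Group calibration.** The synthetic study's defaults are the published
group means and SDs of the five-group experiment it emulates (joint and
compartment volumes in mm³; chondrocyte and isogenous-group intensities
per mm²). The printed compartment means do not sum to the printed joint
volume, so the calibration solves bone, cartilage, synovial-space and
membrane radii from cumulative compartment targets and the outer radius
from the joint total, letting the capsule absorb the remainder. This keeps
the joint-volume effect sizes — the quantity the group comparisons test —
exactly on target, at the cost of a capsule mean slightly above its
printed value. Per-specimen targets are normal draws with the printed SDs
(truncated positive, redrawn if the capsule remainder closes); with
`sd_scale = 0` phantoms are deterministic and recovered truth equals the
targets to 1e-9.

**Chondrocyte field.** Profiles are simulated directly as planar point
processes on each section's cartilage profile — isolated cells as a
Poisson process, isogenous groups as a Poisson cluster process whose
parents carry `2 + Poisson(offspring_mean − 2)` members within
`cluster_radius` — because the estimator itself is explicitly 2-D
(profiles/mm²); a 3-D nucleus model would add assumptions nothing in the
pipeline could check. Defaults: `offspring_mean = 2.5` and
`cluster_radius = 15` µm, a plausible lacuna scale; the published total
chondrocyte column is not internally consistent with "isolated + at least
two cells per group", so the simulated total is the sum of its parts
rather than a forced match to that column.

## Virtual sectioning and probes

One azimuth per specimen (the physical block is rotated once), uniform on
[0, π); systematic plane positions with a single uniform start covering
the phantom's horizontal extent, so a stack at T = 50 µm over a ~900 µm
radius joint yields 35 or 36 sections depending on the start — the same
mechanism that gives the real protocol its 10-to-11-section stacks.
Sections are treated as geometric planes: the formulas contain no
thickness term, and modelling 5 µm physical sections (overprojection) is
out of scope.

Probe randomization is a fresh uniform offset per section, independent
across sections and probes, which systematic-sampling unbiasedness
requires. RNG streams split hierarchically (study → specimen → section →
probe) via a deterministic seed mix, so adding sections or switching off a
probe never perturbs other draws, and identical seeds give byte-identical
counts files.

Implementation choices worth recording:

- **Shared reference points.** The cycloid system spaces one arc per a/p
  tile (rather than the contiguous πr × 2r tiling, which `cycloid_system()`
  also offers), so the point grid's reference total ΣP is the correct
  denominator for the surface formula — the classical combined
  points-and-curves test system. The source does not state its l/p; the
  default is 100 µm (arc generating radius 25 µm), configurable and echoed
  in all outputs.
- **Polyline discretization.** Arcs are rendered with chord (sagitta)
  error below `polyline_tolerance` (default 0.25 µm, far below the
  phantom's feature scale); at that tolerance the rendered length is
  within 0.1% of l/p, and halving the tolerance leaves intersection
  counts unchanged on ≥ 90% of random sections (convergence is tested).
  Intersections are transversal crossings — sign changes of the
  inside/outside indicator along the polyline — so a tangential graze
  within tolerance counts once.
- **Boundary tie-breaks.** Membership on a compartment's outer boundary
  belongs to the inner compartment (half-open, measure-zero but kept
  deterministic for bit-reproducibility); the frame rule is half-open in
  the complementary sense (top/right in, left/bottom out).
- **Frame placement.** Frames are placed only inside the cartilage
  profile, at systematic angular positions around the ring with a random
  rotational start, rejecting positions that leave the cartilage or
  overlap frames already placed. Thin profiles near the cartilage rim
  host fewer than the requested six frames; the per-section `frames_used`
  records what was achieved, and the density estimator divides by it.
  Because a homogeneous Poisson field has intensity λ in any frame
  wherever it sits, this placement does not bias the density estimate.
- **Degenerate inputs.** Zero reference points make CE, Vv and Sv
  undefined (classed errors in the single-purpose functions; `NA` with a
  warning in the batch estimator, except the all-zero specimen, which
  reports all-zero estimates). A single section leaves the CE undefined
  (n ≥ 2 is required). Missing component counts are zeros by schema;
  there is no silent imputation.

## Section-reduction analysis

`subsample_sections()` keeps every k-th section (0-based start, T
multiplied by k), so a subsample is again a valid systematic stack. Its
key identity — the mean over the k possible starts of the subsampled
Cavalieri volume equals the full-stack volume exactly — is algebraic, and
`reduction_report()` exhibits it alongside the predicted CE and the
empirical CE across starts. On a 28-section pilot-style phantom the
empirical CE on the {28, 14, ~10} schedule grows as sections drop but
stays within a factor of two of the 28-section error, which is the
quantitative content of "ten sections are nearly as good as twenty-eight".

## Group statistics

The inferential battery is deliberately standard plumbing around the
stereology core: one-way ANOVA with Sidak-adjusted pairwise comparisons
when a Bartlett diagnostic (α = 0.05) accepts variance homogeneity,
otherwise a Brown–Forsythe heteroscedastic F* with Dunnett-T3-type
pairwise tests (Welch t with a Sidak-type correction approximating the
studentized maximum modulus — no pre-packaged T3 implementation is
available to the package, so the statistic is implemented directly and
checked against closed-form cases), plus pairwise Mann–Whitney as a
nonparametric fallback. Only one-way comparisons of morphometric
quantities are implemented; the source study's two-way ANOVA applies to
paw-volume kinetics, which is outside this package's scope, as are the
cytokine and biochemistry analyses and its trend test.

## What the validation shows — and does not

The acceptance suite and `scripts/acceptance.R` recompute, from scratch,
at these problem sizes (chosen so each check resolves its tolerance with
Monte-Carlo error to spare):

- Cavalieri bias on the calibrated ~3 mm³ phantom: 2000 replicates
  against a 1% bound;
- per-compartment Vv recovery: 500 replicates against 0.01 absolute;
- cartilage surface on the prolate (axis ratio 2) phantom: 2000
  replicates against 2% of quadrature truth;
- profile-density recovery at 1500 profiles/mm²: 1000 replicates against
  2%, plus the exact tiling identity;
- the reduction schedule: exact subsample identity plus 1000-replicate
  empirical CEs;
- CE adequacy: predicted-to-empirical ratio within a factor of two over
  four (n, ΣP) regimes at 400 replicates each;
- effect recovery: 500 simulated five-group studies (n = 4 per group),
  requiring the arthritis vs treated-joint comparison significant and the
  four-group mean ordering reproduced in ≥ 95% of studies;
- determinism and exact agreement with independent brute-force oracles on
  1000 random count tables.

Passing these shows the estimators are correctly constructed and unbiased
under the design's assumptions — it does not show that real joints meet
those assumptions. The phantoms are concentric shells: no marginal
osteophytes, no cartilage erosion geometry, no section deformation,
shrinkage, decalcification artifacts or staining noise, and no observer
error in point and intersection classification. Profile counts are 2-D
throughout; converting them to 3-D number would need a disector, which
the package intentionally does not provide. Real count tables imported
through `read_counts()` inherit all of these caveats from the histology
that produced them.
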