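---
title: "Volumetric tooth-face superimposition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric tooth-face superimposition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `toothface`, the choices made
where the underlying protocol leaves room, and what the synthetic data do
and do not establish.

## The measurement model

The quantity of interest is the volumetric correspondence between the
buccal surface of the maxillary central incisor (MCI) and the facial
surface of the same subject. The protocol turns two open surface scans
into two solids and intersects them:

* **Tooth operand.** The buccal patch (selected with a smoothed boundary)
  is extruded a preset 6 mm along the inward mean vertex normal — toward
  the face, so the overlap measures congruent anatomy — and the patch,
  its offset copy and a boundary side wall are stitched into a watertight
  solid. The solid is then magnified by the preset 15.56, the mean
  bizygomatic-to-tooth width ratio, which brings an ~8.5 mm crown to
  facial scale. Both presets are `pipeline_config()` defaults and can be
  overridden.
* **Face operand.** A facial scan is an open shell; Boolean volumetry
  needs a solid, so the shell's single outer boundary is swept straight
  back to a cap plane `z = -cap_depth` and capped. Any cap behind the
  tooth's posterior extent gives identical metrics (asserted by a test);
  the default is twice the scaled tooth depth.
* **Alignment.** One right-handed frame is used throughout: X transverse
  (mesio-distal), Y vertical (cervico-incisal / facial midline, up
  positive), Z anteroposterior (anterior positive). The source protocol
  mixes its axis names between steps; fixing a single frame and
  documenting every operation against it was the only consistent reading.
  The tooth is centred at its centre of volume and rotated so the incisal
  midpoint lies on the vertical axis with the proximal-edge midpoints
  placed symmetrically; the face is centred at its area-weighted surface
  centroid with the glabella-pogonion line vertical and the midline
  landmarks in the X = 0 plane. Because the centre of volume of the
  extruded solid lies behind the landmark plane, this alignment pitches
  the solid forward by ~25 degrees; that is a property of the protocol
  itself, not an artefact.
* **Placement.** "Tangency" is operationalised as equating a landmark's
  coordinate with the extreme coordinate of the relevant span. The two
  vertical constraints (incisal to menton, cervical to glabella) are in
  general not jointly satisfiable by one translation, so a least-squares
  translation is used and the residual reported. Transversely the tooth's
  extreme points are centred on the zygion span (or the alare span — the
  protocol states "or" with no rule, so it is a mode parameter; on a
  symmetric face both agree). In depth the tooth's anterior-most vertex
  is brought to the face's anterior-most point; the placement is pure
  translation because the rotations are already fixed by the alignments.
* **Outcome.** `RTV = V_total - V_superimposed` and
  `%SI = V_superimposed / V_total x 100`, with
  `V_superimposed = volume(tooth ∩ face)`. The protocol describes both an
  "intersection" and a "face minus tooth" subtraction; the intersection
  reading is the one consistent with the stated formulas and with
  "smaller remaining volume = closer fit", and is what is implemented.

## Geometry engine and numerical choices

* Meshes are welded at 1e-6 mm and watertightness (every edge shared by
  exactly two opposed half-edges) is enforced, not assumed, before any
  volume is computed. Volumes are exact signed-tetrahedron sums
  (divergence theorem).
* The Boolean intersection is a BSP-tree CSG (mutual clipping of the two
  polygon sets) in C++, with a plane-side tolerance of 1e-5 mm. Polygon
  insertion order is shuffled with a fixed-seed generator: structured
  scan meshes arrive in grid order, which degenerates the tree; the
  shuffle keeps it balanced (about a tenfold speedup) while staying fully
  deterministic.
* Clipping introduces T-junction vertices, so the intersection output is
  geometrically closed but can fail the strict edge-pairing test; its
  volume is taken from the divergence sum over the clipped polygons,
  which is exact for a closed surface. This is why
  `signed_volume(..., check_watertight = FALSE)` exists.
* An independent voxel-column oracle (vertical line crossings on a grid
  of pitch 1/100 of the bounding-box diagonal, with deterministic jitter
  and retry at grazing hits) validates both the exact volumes and every
  Boolean volume to within 1%. It shares no code path with the CSG.
* Extrusion offsets can fold where the offset depth exceeds the local
  curvature radius. On any curved mesh a few micro-slivers flip
  numerically, so the failure criterion is the *total flipped offset
  area* exceeding 0.1% of the patch area — which cleanly separates the
  6 mm preset (flipped fraction ~1e-4 on the synthetic crown) from
  genuinely folding depths.
* Offset directions are vertex normals averaged over the *undirected*
  1-ring and the wall quads are fanned through their centre points. Both
  choices exist for the same reason: a directed stencil or a fixed quad
  diagonal depends on face orientation or on the world frame, which
  silently breaks the mirror symmetry and rotation equivariance that the
  alignment tests rely on.

## The synthetic data

No per-subject data are deposited, so generators stand in for the scans,
calibrated only to printed summaries.

* `gen_tooth()` builds a rounded-rectangle buccal patch (defaults
  8.5 x 11 mm, corner radius 1.5 mm) carrying an elliptic-paraboloid
  convexity (`sag`, default 0.8 mm). The paraboloid has no cross
  curvature, so its minimum curvature radius (~11 mm) stays above the
  6 mm extrusion everywhere. Landmarks are boundary vertices at the four
  edge midpoints.
* `gen_face()` builds a superelliptical facial shell (164 x 230 mm,
  dome depth 55 mm) with a Gaussian nasal ridge, and blends its mid-face
  toward the tooth surface *as the pipeline will actually place it*
  (evaluated by height queries against the placed solid) with weight
  kappa. Landmarks sit on the unblended base shell, midline points at
  x = 0 and glabella/pogonion at equal depth, so the landmark alignment
  of a generated face is an exact translation. Two deliberate details:
  the blend keeps full weight over a margin shelf outside the tooth
  footprint (so face triangles straddling the footprint edge do not cut
  the corner), and the nasal ridge is excluded from the blend so the
  face keeps a fixed anterior-most point at every kappa — making the
  depth-tangency placement congruence-independent, which is what makes
  %SI provably monotone in kappa. At kappa = 1 with zero noise the two
  meshes sample the same smooth surface and the pipeline returns
  %SI > 99; the residual below 100 is pure discretisation.
* `gen_cohort_table()` works directly on volumes rather than meshes:
  mesh Booleans at n = 98 across hundreds of replicates would dominate
  test time, and the statistical layer only consumes the volumes. Total
  volume is drawn from sex-specific normals (printed means/SDs; the
  64/34 descriptive split is the composition default, while the 69/29
  split printed alongside the comparative analyses parameterises the
  effect-size recomputations). The %SI marginal is simulated through the
  remaining-volume fraction `f = 1 - %SI/100`. The default makes `f`
  lognormal, moment-matched to %SI mean 82.64 / SD 7.36: a truncated
  normal %SI cannot reproduce the published remaining-volume tail (a
  maximum ~4.9 SDs above the mean) nor reliably trip the Shapiro-Wilk
  gate at n = 98, whereas the lognormal fraction gives the right-skewed,
  non-normal remaining volume actually reported; a
  `si_family = "truncnorm"` option keeps the simpler marginal available.
  The requested Spearman correlation couples total and *remaining*
  volume, but remaining volume is derived (`v x f`), so the Gaussian
  copula parameter between the latent drivers is calibrated numerically
  (fixed-seed pilot of 20,000 draws, monotone root finding); targets
  outside the achievable range raise a feasibility error.

What passing tests show — and do not show — about real data: the
generators prove that the pipeline is exact on known geometry, calibrated
at the published marginals, and monotone in a controlled congruence
parameter. They do not imitate scanner noise beyond additive Gaussian
surface noise, soft-tissue variation, asymmetric faces, or landmark
placement error; results on real scans inherit none of these guarantees.

## Statistics layer

The battery mirrors the published plan: Shapiro-Wilk gating at
alpha = 0.05 selects the parametric (Levene-gated Student *t*) or
non-parametric (Mann-Whitney U) branch per variable; Spearman's rho uses
ranked Pearson with average ranks; the Mann-Whitney p-value is exact by
enumeration for untied samples with `n1 x n2 <= 400`, otherwise normally
approximated with tie and continuity correction; no multiplicity
correction is applied anywhere, matching the source plan. Achieved power
uses the noncentral *t* for the paired and two-sample tests and the
Fisher-*z* normal approximation for the correlation — no method is named
in the source, and these are the standard choices that reproduce all
three printed powers. Two-sample summary-statistic input defaults to the
pooled (Student) form.

One calibration check deserves a note: the "rejection rate matches
predicted power" test simulates the two sex groups at the printed means
under a *common* SD (the pooled SD of the printed sex summaries). With
the printed unequal SDs the pooled noncentral-*t* prediction is biased by
construction — the pooled SE overestimates the true SE of the mean
difference when the larger group has the larger variance — so only the
homoscedastic model gives a self-consistent prediction to test against.

## Problem sizes and determinism

The test suite runs the full mesh pipeline at a tooth patch of ~1,100
triangles and a facial shell of ~2,500 triangles (a five-point kappa
sweep plus file-based end-to-end runs), validates 30 Boolean/oracle solid
pairs, and sizes the statistical simulations at 1,000 null cohorts for
test levels and CI coverage, 500 replicates for power consistency, and
200 replicates for parameter recovery — large enough for binomial 95%
bands around the nominal rates to be informative, small enough that the
whole suite runs in about a minute. Every stochastic component takes an
explicit integer seed; identical inputs give bitwise-identical outputs,
including the STL/JSON fixtures.

## Known limitations

* The BSP Boolean targets scan-sized meshes (thousands of triangles);
  it is exact in topology but not in floating point, and its output may
  carry T-junctions (see above). Inputs with near-degenerate or
  self-intersecting geometry are not repaired.
* Landmarks are supplied, never detected; automated landmarking is out
  of scope.
* The placement uses translation only, by design; a free rigid fit would
  be a different protocol.
* Binary STL stores 32-bit floats, so round-trips are exact only to
  ~1e-7 relative; sidecar landmarks are stored at full precision in
  JSON.
* The synthetic face is a smooth parametric shell, not a statistical
  shape model of real anatomy; kappa controls congruence, not realism.
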