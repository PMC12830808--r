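---
title: "Growth-line analysis on 4D stage-mesh models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-line analysis on 4D stage-mesh models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthlines)
```

# The problem

Fate mapping asks where cells at an early embryonic stage end up later.
In the early chick forebrain, compact groups of labelled neuroepithelial
cells grow into characteristically shaped territories — "growth lines" —
whose elongation, orientation and convergence reveal strongly anisotropic,
region-specific tissue growth: directional growth toward the eye, more
isometric expansion of other territories, and anterior displacement of
ventral midline cells.  A practical way to formalise such observations is
a *4D model*: one surface mesh per developmental stage, all sharing a
single topology so that vertex *i* is the "same" piece of tissue at every
stage.  Blending the per-stage vertex arrays (shape keys) morphs the
surface continuously; painting a patch of faces at an early stage and
re-evaluating its geometry at a later one yields an in-silico analogue of
a lipophilic dye injection ("digital dye").

`growthlines` implements that pipeline end to end, together with the
measurement machinery that turns in-vivo or in-silico dye patterns into
numbers: growth-line metrics and shape calls, outcome-region scoring and
per-zone frequency matrices, landmark morphometry with explicit
statistical tests, thresholded expression-area quantification, and a
single-cell gene-set scoring stage.  Because the imaging and sequencing
data behind such studies are rarely reusable directly, the package also
contains a first-class synthetic-embryo generator that produces every
input with known ground truth; all tests run against that generator.

# The 4D model

## Stage series and shape-key interpolation

A `stage_series` is an ordered list of `stage_mesh` objects with an
identical face list and vertex count.  The stage parameter $s \in [0,
n-1]$ indexes the series; `interpolate_series()` returns the
piecewise-linear blend

$$V(s) = (1-t)\,V_k + t\,V_{k+1}, \qquad k = \lfloor s \rfloor,\; t = s-k,$$

with faces unchanged.  Integer $s$ returns the stored stage bit-exactly.
$s$ is deliberately *ordinal*: the four modelled stages correspond to
staged embryos, and nothing in the data calibrates the interval between
them in hours, so $s$ must not be reported as developmental time.

Quads are allowed in input meshes and triangulated internally by the
fixed (1,2,3)/(1,3,4) split.  Because the split depends only on the face
list, which is shared across stages, triangulation commutes with
interpolation and correspondence survives.

## Digital dye and the no-mixing property

A dye patch is *face-granular*: a face is in or out, mirroring the
painted-face workflow the model emulates.  `inject_dye()` takes all
faces whose vertices lie within a geodesic radius of a seed point
(plus the seed face, so a patch is never empty), restricted to the
connected component of the seed.  `propagate_dye()` keeps the face set
and the per-face barycentric sample points fixed and re-evaluates only
their coordinates on the interpolated mesh.  Transport is therefore a
bijection on face labels by construction: disjoint patches can never
merge, connected patches stay connected, and propagating to $s_1$ and
then $s_2$ equals propagating directly to $s_2$.  This is the model's
intended behaviour — a mesh correspondence cannot represent cell
mixing — and it is asserted, not merely assumed, in the test suite
(1,000 random disjoint patch pairs).  The flip side, documented rather
than compensated: real dye spreads slightly, so digital growth lines are
a little smaller and cleaner than in-vivo ones.

Each member face carries 10 uniformly drawn barycentric sample points
(seeded).  Metrics are computed from these samples rather than from
vertices, which decouples metric precision from mesh resolution.

## Geodesic distances

Geodesics drive dye-disc injection and the synthetic attractor field.
They are computed as graph shortest paths, but on a *Steiner-augmented*
graph rather than the bare vertex/edge graph: each edge receives
`n_steiner` (default 3) evenly spaced auxiliary nodes, and all boundary
nodes of each triangle are pairwise connected by straight in-face
segments.  The bare edge graph overestimates distances by up to ~15%
(and ~10% on average) on a structured triangulation because paths must
zigzag along lattice directions; the Steiner graph cuts across faces and
converges to the true polyhedral geodesic as the density grows.  On a
subdivision-5 icosphere with 3 Steiner points per edge, antipodal
distances are accurate to ~0.01% and geodesic-disc areas match the
analytic spherical cap $2\pi(1-\cos r)$ to within 2% for $r \ge 2$.

Two discretisation effects set that tolerance and are worth knowing
about.  First, residual graph-metric anisotropy contributes a fraction
of a percent at the default density.  Second, the all-vertices-inside
face rule omits a half-edge-wide boundary band, biasing disc areas low
by roughly $0.5\,h\cot(r/2)$ relative (with $h$ the edge length); the
sphere checks therefore use a refined mesh and radii where this bias is
well below the stated 2%, and coarser meshes are tested at
correspondingly looser, $O(h)$ tolerances.  Closest-point projection
(`locate_point()`) is an exhaustive per-triangle search with ties broken
by lowest index, so results are deterministic.

# The synthetic embryo

`deformation_spec()` + `generate_stage_series()` emulate the three
growth modes the model is built around, as additive displacement fields
linear in the normalised stage $\tau = k/(n-1)$:

* **directional growth toward an attractor** ("the eye"):
  $d(v) = g\,w(v)\,\widehat{(a - v)}$ with weight
  $w(v) = \max(0, 1 - d_{\mathrm{geo}}(v, \mathrm{optic})/R)$ decaying
  linearly with geodesic distance from a marked vertex set.  The linear
  decay is the simplest field whose Jacobian produces convergent,
  direction-dependent stretch;
* **region-wise isotropic expansion**: $v \mapsto c_z + s_k (v - c_z)$
  about the zone centroid;
* **anterior translation of a midline band** along a stated axis.

Magnitudes are free parameters, not claims about chick growth — the
source model was sculpted to imaging templates, which published no
quantitative deformation magnitudes.  A zero-parameter spec yields an
identity series, and identical spec + seed is bit-identical, which the
tests rely on.  On a flat sheet with a distant attractor the field has a
closed-form Jacobian (uniform compression $1 - g/R$ along the attractor
axis), giving analytic truth for elongation ($(1-g/R)^{-1}$),
orientation (transverse) and area ratio; this is the oracle behind the
metric-recovery checks.

The default stage count is 4, mirroring the four modelled stages
(HH10/11/14/20).  Injections target a 12-zone partition of the stage-0
tube (4 axial x 3 circumferential bins), with per-zone seeds at the
area-weighted zone centroid projection (jitter 0) or drawn from faces
within a geodesic jitter radius.  Synthetic images are two-level frames
with isolated single-pixel salt outliers (no two adjacent, so a median
despeckle can remove every one without touching signal).  Synthetic
expression matrices are Poisson counts around lognormal gene means with
role-aware baselines: retention markers broadly expressed (~1.2 expected
counts per cell), exclusion markers silent unless explicitly planted, so
planted filter hits are exact by construction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: imaging noise beyond salt, segmentation and
registration error, non-affine local tissue deformation between stages,
dye diffusion and dilution, doublets/ambient RNA in counts, and any
biologically calibrated growth rate.

# Growth-line metrics

`measure_growth()` compares one patch at two stages:

* **area ratio**: patch face area at $t_1$ over $t_0$ (exactly $k^2$
  under uniform scaling by $k$);
* **elongation**: sample points at $t_1$ are projected onto their
  best-fit plane (total least squares — full 3D PCA would conflate
  surface curvature with elongation, since patches are thin shells);
  elongation is $\sqrt{\lambda_1/\lambda_2}$ of the in-plane covariance;
* **orientation**: the angle in $[0, 180)$ between the major principal
  axis and the A-P reference tangent nearest the patch centroid.  A
  subtlety: in-plane angles are only defined up to reflection of the
  plane basis, so the basis is made right-handed against the patch's
  outward mean face normal (from the mesh winding order).  Orientation
  is then invariant under rigid rotation, and flips consistently under
  reflection, as an oriented surface should.  It is an axis, not a
  vector, because growth lines are undirected; it is reported only when
  elongation exceeds $1 + \varepsilon$ ($\varepsilon = 10^{-3}$);
* **convergence distance**: perpendicular in-plane distance from a named
  target point ("eye") to the major-axis line;
* **shape class**: spot / line / V.

The shape taxonomy is visual in origin; the quantitative surrogate uses
thresholds stored in one config object (`shape_thresholds()`): `t_line =
2.5` (minimum elongation of a non-spot), `t_v = 150` degrees (maximum
interior angle of a V), `t_arm = 25%` (minimum arm share of skeleton
length).  The classifier traces a skeleton by binning tangent-plane
points along the major axis (15 bins) and splitting at the vertex of
maximal turning.  One design choice needs stating: the V test is applied
*arm-wise*.  A folded thin shape has low global elongation — a
90-degree chevron has exactly 2.0, below `t_line` — so gating the V
check on global elongation would misread every wide-angle chevron as a
spot.  Instead a patch is a V when the interior angle is below `t_v`,
both arms carry at least `t_arm` of the skeleton, and *each arm* is
itself line-like (per-arm elongation at least `t_line`); otherwise the
global elongation decides spot versus line.  The tricorn-like shapes
produced by some zone injections are reported as V or line under these
rules; a dedicated fourth class was considered and deferred.

# Outcome scoring

Outcomes are scored against seventeen named areas grouped as T1–T2
(telencephalon), D1–D7 (diencephalon excluding hypothalamus), H1–H5
(hypothalamus) and Hm1–Hm3 (hypothalamic midline).  The vocabulary is
fixed; the geometry is a user-editable face-set annotation
(`read_outcome_regions()`).  The package ships
`synthetic_outcome_regions()`, an explicitly synthetic overlapping-band
layout that exists so the scoring machinery can be exercised without
annotation files — it is not a claim about real region geometry.

`assign_outcomes()` includes an area when the patch's face-area overlap
fraction reaches `min_overlap` (default 0.05; the manual scoring it
replaces had no stated threshold, so the value is configurable and
echoed).  When nothing passes, the best-overlap area is returned
flagged, so a patch always lands somewhere.  Conformity judgements
compare the measured shape class with each area's expected shape; calls
whose elongation falls in a configured grey band (default 2.25–2.75,
straddling `t_line`) are "indeterminate" and pooled with non-conforming
calls in summaries, mirroring how ambiguous shapes are scored by eye.
Frequency matrices report exact percentages with per-cell *n*; zone
intersections are encoded as sorted label pairs ("4+5").  Samples
carrying several injections contribute one record holding all zones
(splitting per injection is available at record-construction time).
Thumbnails colour each area white at zero frequency — "no examples
recorded" is visually distinct from "rarely" — with a monotone ramp to
full colour at 100%.

# Morphometry and statistics

**Line ratio (B:A).**  Line A joins two trackable landmarks X → Y (Y
posterior).  A perpendicular to A is positioned to touch the posterior
optic margin; geometrically the foot of that perpendicular is the A-axis
projection of the margin's posterior-most point, so
$B = |A| - \max_i \langle m_i - X, \hat{u} \rangle$ over margin vertices
$m_i$.  The construction uses only projections and is invariant under
rigid motion and reflection; a margin that no in-segment perpendicular
can reach is reported as a named geometry error rather than clamped
silently.

**Log trend.**  `fit_log_trend()` fits ratio $= a \ln(\mathrm{stage}) +
b$ by ordinary least squares via `lm()`.  Stage values are the given
ordinals (HH10 entered as 10): the published x-axis usage, with no
invented time calibration.

**Angles.**  `zli_angles()` measures the angle in $[0, 180]$ between the
ZLI direction and the base→landmark segments via the normalised dot
product.  The ZLI direction defaults to the polyline endpoints (the
measurements it reproduces drew straight lines); `fit = "tls"` switches
to a total-least-squares line for curved annotations.

**Expression area.**  `area_positive()` fixes the pipeline order:
bright-outlier median despeckle, then binarisation, then ROI count.  The
despeckle replaces a pixel by the median of its radius-$r$ Euclidean
disk only when it *exceeds* that median by more than `outlier_threshold`
— an emulation of the documented semantics of median-based
remove-outliers tools, not a bit-compatible port.  Dark pixels are never
touched, so signal is preserved provided the outlier threshold exceeds
the signal-background step; with isolated salt this recovers the planted
pixel count exactly, which the tests assert.  Threshold and radius have
no defaults: the measurements this emulates used unstated values, and a
default would masquerade as theirs.

**t tests.**  `two_sample_t()` implements Student's pooled and Welch's
unequal-variance statistics directly from the closed-form formulas, with
Welch–Satterthwaite degrees of freedom and two-sided p from the t
distribution.  The suite cross-checks both variants against
`stats::t.test()` to $10^{-9}$ on random group pairs — the reference
implementation serves as oracle, never as the implementation.  Identical
groups return $t = 0, p = 1$; zero variance in both groups with unequal
means is an explicit error (the statistic is undefined).  Note that
Welch's p is *not* always larger than Student's; the invariant tested
instead is $\mathrm{df}_\mathrm{Welch} \le n_A + n_B - 2$.

# Gene-set stage

The filter retains cells expressing *Otp* and/or *Sim1* (count > 0), or
flagged as NPCs via an input column — the NPC definition lives upstream
of this package and is never inferred — and excludes any cell with > 0
counts of *Foxa1, Foxa2, Pitx2, Shh* or expressing *Nr5a1, Foxb1, Tbr1,
Agrp, Pomc*.  Both exclusion lists use the same count > 0 reading (no
alternative cutoff is stated anywhere), so retention and exclusion
commute and their order cannot matter; the report still counts removals
rule by rule.  Missing filter genes are a hard error listing the names.

Module scores are set mean minus control mean on log1p counts-per-10k
expression (the normalisation is this package's stated choice — the
upstream processing defers to prior work, so the choice is ours and is
echoed in outputs).  Genes are ranked by dataset-mean expression and cut
into `n_bins` equal-size bins (default 24, matching the documented
defaults of the standard single-cell module-scoring tools, as does
`n_ctrl = 100`); each set gene draws `n_ctrl` seeded
controls without replacement from its bin, excluding the set's own
genes so planted shifts cannot contaminate their own controls.  The
pooled unique controls form the control mean.  Underfull bins reduce the
draw with a warning.  Two exact properties anchor the tests: a matrix
whose genes are all identical scores zero, and adding a constant to
every gene leaves scores unchanged.  Cluster summaries report per-cluster
means, full rankings, and the top cluster per score with ties listed,
never silently broken.  Reclustering and embedding are out of scope:
cluster labels are inputs (or synthetic).

# Reproducibility, problem sizes, interfaces

Every stochastic step takes an explicit integer seed, and the demo
pipeline (`run_demo()`) serialises its effective configuration next to
its outputs; identical config + seed reproduces byte-identical files.
Unknown configuration keys are rejected by name, so typos cannot
silently fall back to defaults.

The suite's problem sizes are chosen to make discretisation error small
relative to each check's tolerance while keeping the whole suite fast:
icosphere subdivision 5 with 3 Steiner points per edge for the 2%
disc-area check (subdivision 3–4 with $O(h)$ tolerances elsewhere); a
41 x 41 flat grid, 12 injections of radius 1.6 for metric recovery; an
18 x 12 tube with 4 stages and 36 injections for the demo loop; 100
seeded runs of 220 cells x 220 genes for planted-cluster recovery.

File interfaces use the field's plain formats throughout: OBJ/ascii-PLY
meshes with a JSON series manifest (strict mode rejects series whose
face blocks differ), CSV/TSV patches, records, landmarks and region
annotations, MTX + genes/barcodes/metadata for counts, YAML gene sets
and pipeline configs, 16-bit TIFF images.  The package's functions are
its interface; `run_demo()` and `validate_inputs()` cover orchestration,
and every operation is scriptable from Rscript.

# Known limitations

* Correspondence is *given*, as in the hand-built model this package
  algorithmifies; there is no automatic correspondence estimation,
  remeshing or image-to-mesh reconstruction.
* Geodesics are graph-based; tolerances are documented but exact
  polyhedral geodesics are not computed.
* Patch membership is face-granular; sub-face dye gradients and
  diffusion are out of scope.
* The synthetic outcome-region layout and all generator magnitudes are
  test scaffolding, not biology; conclusions about real embryos require
  real annotations and meshes.
* Metrics are per-patch; no whole-mesh strain-tensor field is estimated.
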