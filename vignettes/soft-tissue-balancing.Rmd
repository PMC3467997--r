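---
title: "A laxity-based sensitivity map for soft-tissue balancing in bicruciate-retaining knee arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A laxity-based sensitivity map for soft-tissue balancing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneelax)
```

## The problem

Bicruciate-retaining total knee arthroplasty preserves both cruciate
ligaments, which promises more physiological kinematics but makes
intraoperative soft-tissue balancing much harder: the surgeon must adjust the
tensions of six ligament groups while only being able to *feel* the joint's
laxity — its translation or rotation under a manually applied drawer force or
moment. Which laxity examinations (direction x flexion angle) are actually
informative about which ligament bundles, and in what order should the bundles
be adjusted so that early releases do not confound later assessments?

`kneelax` answers this with a simulation study: a quasistatic rigid-body knee
model with multi-bundle nonlinear ligament springs is subjected to the
standard clinical laxity battery (anterior-posterior drawer at 100 N,
internal-external rotation at 8 Nm, varus-valgus at 30 Nm, each at 0, 30, 60,
90 and 120 degrees of flexion) while a three-level orthogonal-array design of
experiments perturbs all 40 soft-tissue parameters at once. An ANOVA
relative-importance statistic turns the 81 x 15 laxity table into a
sensitivity map, from which the informative laxity tests and an ordered
balancing sequence are derived.

## The knee model

### Articular geometry

The articular surfaces are analytic primitives chosen to reproduce the
qualitative congruence asymmetry of a natural (or bicruciate-retaining
prosthetic) knee:

* two femoral condylar spheres (medial radius 22 mm, lateral 20 mm) centred
  on the fixed flexion axis;
* a concave medial tibial dish (radius = medial condyle + 8 mm clearance) —
  the more congruent, stabilizing compartment;
* a flat lateral tibial patch — the less congruent compartment that permits
  the physiological anterior-posterior shift and pivoting of the lateral
  side.

Because the condylar spheres are centred on the flexion axis, articular
contact is flexion-neutral and the flexion dependence of the laxities is
carried entirely by the ligaments, which keeps the model well conditioned
across the whole 0-150 degree range. Contact is evaluated *analytically* on
these primitives (sphere-in-socket and sphere-on-plane signed distances);
the triangulated meshes produced by `build_surfaces()` / `write_surfaces()`
are generated from the same primitives and exist for STL export, import of
user-supplied surfaces, and visualisation. Evaluating distance on the
primitives is exact and orders of magnitude faster than mesh proximity
queries, which is what makes the 1215-simulation campaign tractable in pure
R. The patellofemoral joint is excluded: intraoperatively the everted patella
does not contribute to passive laxity.

### Ligament apparatus

Six ligament groups are modelled with 31 spring bundles:

| ligament | bundles (regions) | group stiffness k (N) | reference strain(s) |
|---|---|---|---|
| ACL  | 10 (4 anterior / 3 middle / 3 posterior) | 5000 | 0.160 / 0.100 / 0.100 |
| PCL  | 9 (3 / 3 / 3) | 9000 | -0.068 / -0.169 / -0.169 |
| sMCL | 4 (2 anterior / 2 posterior) | 2750 | 0.180 |
| dMCL | 2 (anterior, posterior) | 1000 | 0.030 |
| LCL  | 4 (2 / 2) | 2000 | 0.050 |
| PMC  | 2 (anterior, posterior) | 1000 | 0.030 |

Group stiffness is split equally among the bundles of the group. Each bundle
obeys the standard piecewise tension-strain law with a quadratic toe region,

$$f(\varepsilon) = \tfrac14 k\,\varepsilon^2/c \;\; (0 \le \varepsilon \le 2c),
\qquad f = k(\varepsilon - c) \;\; (\varepsilon > 2c),
\qquad f = 0 \;\; (\varepsilon < 0),$$

with $c = 0.03$; both branches equal $kc$ at $\varepsilon = 2c$, so the law
is C1. Strain is measured from the zero-load length,
$\varepsilon = (L - L_0)/L_0$, and $L_0$ is fixed by the *reference strain*
$\varepsilon_i$ at full extension: $L_0 = L_i/(1+\varepsilon_i)$ with $L_i$
the full-extension path length. Surgical release or retensioning of a bundle
region is modelled as a change of $\varepsilon_i$.

Attachment footprints are placed from published anatomic descriptions scaled
to the synthetic bone: the cruciate femoral attachments sit close to the
flexion axis (which makes them near-isometric, with the ACL slackening and
the PCL engaging as flexion proceeds), the collaterals at the epicondyles
(tautest near extension), the PMC posteromedially (taut in extension). Each
footprint carries a planar frame (origin at the centroid, in-plane X/Y axes);
bundles are laid out on a regular grid within the footprint with
anterior/middle/posterior ordering. Exact footprint sizes and bundle spacing
are not anatomical measurements; they are configuration-exposed stand-ins
(`geometry$footprint_u`, `geometry$footprint_v`).

The superficial and deep MCL wrap around the medial edge of the tibial
plateau, modelled as an analytic cylinder section on the medial aspect of the
tibia. Wrapping uses a single via point: a 1 mm probe sphere at the midpoint
of the straight segment is pushed radially to the obstacle surface whenever
it penetrates. This keeps the path length C0-continuous, never shorter than
the chord, and within a few percent of the true cylinder geodesic for the
shallow wrap angles that occur here (the test suite checks this against the
closed-form geodesic). Frictionless sliding of the wrap point is assumed.

### Kinematics and loads

Joint poses use the Grood-Suntay joint coordinate system: flexion about the
femur-fixed medial-lateral axis, internal-external rotation about the
tibia-fixed long axis, varus-valgus about the floating axis, and the three
translations along those (generally non-orthogonal) axes. Right-knee signs:
anterior, internal, varus and distraction positive. During a laxity test
flexion is prescribed and the remaining five coordinates are free.

Loads are applied as generalized forces conjugate to the JCS coordinates:
the AP drawer force (conjugate to the AP translation) acts along the floating
axis through the joint centre — the centre of the tibial plateau — and
therefore exerts no moment about it; the IE and VV moments are pure couples
about the tibial long axis and the floating axis. This gives every load case
a well-defined potential, so equilibrium is a minimization problem. A
sinusoidal manual load sweep is represented by its two quasistatic extremes
+A and -A: laxity is defined as total excursion, so only the endpoints of
the sweep matter in a rate-independent model.

### Equilibrium

`solve_equilibrium()` minimizes the total potential — ligament strain energy,
a smooth unilateral contact penalty (stiffness 1e4 N/mm, quadratic force
smoothing over 0.01 mm, so contact force is zero at zero penetration and
never adhesive), a light 10 N compressive preload that keeps the surfaces
engaged at zero applied load (mimicking the light compression present during
intraoperative laxity assessment), minus the work of the applied generalized
load — over the five free coordinates with L-BFGS and central-difference
gradients, followed by a damped-Newton polish with a numeric Hessian whenever
the quasi-Newton stage stalls. A pose is accepted only when every component
of the residual generalized force is below 0.1 N (translations) / 0.01 Nm
(rotations); otherwise an error reports the final residual. Penetrations
beyond 1 mm abort the solve. The solver is deterministic: repeated runs are
bitwise identical.

Typical nominal-model laxities (printed by the worked example in the README)
are a few mm of AP drawer at extension growing with flexion, 20-50 degrees of
IE rotation, and 5-16 degrees of VV — consistent in character with passive
intraoperative laxity, which is the regime the model targets.

## The study design

40 parameters describe the soft tissues: 20 attachment-coordinate offsets
(TX, TY on the tibia, FX, FY on the femur, for ACL, PCL, sMCL, LCL and one
shared block for dMCL+PMC, which share an attachment region), 6 group
stiffnesses, and 14 region reference strains (ACL and PCL in three regions,
the four other ligaments in two). The three levels are:

* attachments: nominal + {-1, 0, +1} mm (a plausible localisation
  uncertainty);
* stiffness: nominal x {0.95, 1.00, 1.05};
* reference strains: nominal + {-0.05, 0, +0.05}. A strain step of 0.05 on a
  bundle of about 20 mm corresponds to a 1 mm change of ligament length,
  which is a realistic increment of controlled surgical release; the step is
  configuration-exposed (`doe$strain_step`) for users who want finer
  perturbations.

Attachment offsets are applied in the footprint's own planar frame to all
bundles of the ligament simultaneously, and are *strain-preserving*: the
full-extension length and the zero-load length are recomputed so that
$\varepsilon_i$ is untouched — moving an attachment is a geometric
uncertainty, not a release. Stiffness perturbations act on the group value,
re-split equally.

The design is the standard L81(3^40) orthogonal array, built by the
Rao-Hamming construction over GF(3)^4: 81 rows indexed by the vectors of
GF(3)^4, 40 columns by the canonical representatives of its one-dimensional
directions (first nonzero coordinate 1, lexicographic), entries
$(r \cdot c \bmod 3) + 1$. Every level appears 27 times per column and every
column pair is orthogonal (all 9 combinations, 9 times each) — verified
exhaustively in the tests. Any valid L81 would do: the analysis relies only
on these balance properties. The full campaign is 81 rows x 3 tests x 5
flexion angles = 1215 laxity simulations, each itself two equilibrium solves
around a shared zero-load solve.

## The analysis

For each laxity test (column of the 81 x 15 response table) and each factor,
the relative importance is the main-effect ANOVA ratio

$$\mathrm{RIM}_A = \frac{SS_A}{TSS}, \qquad
SS_A = 27\sum_{j=1}^{3}(m_{Aj}-m)^2, \qquad
TSS = \sum_{i=1}^{81}(\eta_i - m)^2,$$

with $m_{Aj}$ the mean laxity at level $j$ of factor $A$ and $m$ the grand
mean. On the orthogonal array the main-effect sums of squares are
sub-additive ($\sum_A \mathrm{RIM}_A \le 1$, with equality for noise-free
additive responses) — both properties are tested, and the implementation is
checked against a brute-force group-partition oracle to 1e-12.

Within each factor row the 15 RIM values are linearly rescaled to integer
ranks 1-5 (`rank = 1 + round(4 (RIM - min)/(max - min))`, rounding half-up;
a constant row gets the midpoint 3 with a warning). Ranks — not raw RIMs —
are then averaged over each ligament's bundle-region factors, and a laxity
test is *selected* when any ligament's mean rank reaches the threshold
(default 3, inclusive, configuration-exposed as `analysis$rank_threshold`;
the rescaled 1-5 rank is the only scale on which a threshold of 3 is
meaningful).

The balancing sequence is a greedy cover: among the selected tests not yet
used, take the one whose high-sensitivity groups (rank >= 3) contain the
fewest still-unadjusted bundle groups (ties broken by earlier flexion angle,
then AP < IE < VV), adjust those groups, repeat until all 14 groups are
assigned. Starting from the tests sensitive to few bundles means the broadly
sensitive tests are reached when most other tensions are already set, so
each examination isolates as few unknowns as possible. Each group is
adjusted exactly once; a group with no high-rank selected test is reported
as uncoverable rather than dropped.

## What the synthetic knee does and does not show

The generator emulates the *structure* of a cadaver-derived model — the
congruence asymmetry, the bundle census, the stiffness and reference-strain
table, planar attachment frames, MCL wrapping — but not any individual
specimen's morphology. Surfaces are ideal spheres and planes; menisci,
cartilage compliance, friction, viscoelasticity and muscle loads are absent.
Consequently the *numerical* cell values of the sensitivity map depend on
this synthetic geometry, and passing tests demonstrate the correctness and
internal consistency of the machinery (balance of the design, the RIM
algebra, convergence and determinism of the solver, strain-preserving
perturbations) and qualitative mechanics (primary-restraint behaviour,
congruence ordering, wrap lengthening) — not agreement with any particular
cadaver experiment.

One instructive model behaviour: with the sMCL's nominal reference strain of
0.18, the ligament operates deep in the linear branch across the entire
+/-30 Nm varus-valgus excursion, so adding pretension shifts the VV neutral
point (about 0.4 degrees varus-ward per +0.05 strain) while leaving the VV
stiffness — and hence the total excursion — essentially unchanged (it
changes by well under 1%, and can move in either direction through
second-order geometry). Pretension only reduces a laxity when the excursion
crosses a slack/taut or toe/linear transition of that ligament, as it does
for the ACL in AP drawer and the LCL in varus. This is a genuine property of
highly pretensioned linear-region ligaments, and a caution against assuming
that every "tightening" visibly stiffens its laxity direction.

## Numerical choices and problem sizes

* Contact penalty 1e4 N/mm with 0.01 mm force smoothing: penetrations stay
  near 0.1 mm under the largest campaign loads, far below the 1 mm cap, and
  the energy is C1 so quasi-Newton minimization is reliable.
* Gradient step 1e-5 (mm / rad): central differences give residual noise
  orders of magnitude below the 0.1 N / 0.01 Nm acceptance tolerances.
* Warm starting: zero-load equilibria chain across flexion angles; both load
  extremes start from the current zero-load pose. Final poses are
  warm-start independent to better than 1e-4 mm/deg (tested).
* Degenerate inputs: zero-length bundle paths, non-positive radii, a
  lateral compartment more congruent than the medial, unbalanced RIM
  columns, constant responses and uncoverable bundle groups are all rejected
  with explicit errors rather than silently handled.
* Tie-breaks: rank rounding is half-up; sequence ties prefer earlier flexion
  and AP < IE < VV — both stated so the pipeline is reproducible.
* Problem sizes: the test suite exercises the full L81 algebra exhaustively
  (all 780 column pairs), runs a 20-row x 15-test reduced campaign for the
  convergence properties, and uses 100-1000-case property sweeps elsewhere;
  the acceptance script runs the complete 81-row campaign (1215
  simulations). These sizes were chosen so the whole study reruns in a few
  minutes on a single core.

## Limitations

Beyond the synthetic geometry: laxity is reported as JCS-coordinate
excursion between the two load extremes (not a path integral); IE/VV loads
are pure couples (a surgeon's grip also applies off-axis forces); the
balancing sequence is a combinatorial consequence of the sensitivity map and
carries no claim of clinical validity — it is the kind of hypothesis such a
model can generate, to be tested against cadaveric or navigated
intraoperative measurements.
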