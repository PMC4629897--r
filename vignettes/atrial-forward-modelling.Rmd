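---
title: "Multiscale atrial electrophysiology with AtriaSim: models, calibration and forward computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale atrial electrophysiology with AtriaSim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

AtriaSim links three scales of atrial electrical activity: ionic dynamics of
single human atrial myocytes, anisotropic wave propagation through labelled
atrial tissue, and the extracellular potentials those waves project onto the
torso surface. This vignette describes the models implemented at each scale,
the parameters that matter, the numerical choices, and what the packaged
desk-scale geometries can and cannot say about full anatomical models.

## The cellular model and its regional variants

The membrane model is a Maleckar-type human atrial myocyte: a
Nygren-lineage formulation with reformulated transient-outward and
ultrarapid potassium currents, intracellular and cleft ion pools, SERCA
uptake and calcium-induced calcium release, with no constant inward sodium
leak and the stimulus charge booked to the intracellular potassium pool so
that long pacing conserves ionic content. The full constant set is exposed
by `maleckarConstants()` and is the package's versioned reference parameter
file; `maleckarInitialState()` holds the resting state. Membrane voltage is
in mV, time in ms, currents in pA, concentrations in mM.

Regional electrophysiological heterogeneity is expressed as multipliers on
three maximum conductances — the transient outward current
($g_{to}$), the L-type calcium current ($g_{CaL}$) and the rapid delayed
rectifier ($g_{Kr}$) — giving eight regional variants
(`regionalScalingTable()`): general right atrium / pectinate muscles
(the unscaled baseline), crista terminalis / Bachmann bundle, right
appendage, tricuspid ring, general left atrium, pulmonary veins, left
appendage and mitral ring. Raising $g_{Kr}$ or lowering $g_{CaL}$ shortens
the action potential; halving $g_{to}$ and $g_{Kr}$ lengthens it. Under
1 Hz pacing the variants span steady-state APD90 values from roughly
158 ms (mitral ring) to 228 ms (crista terminalis / Bachmann bundle) —
the package's tests verify the whole table.

```{r}
library(AtriaSim)
cell <- makeRegionalCell("CT/BB")
trace <- paceSingleCell(cell, pacingProtocol(nBeats = 3600L),
                        stopWhenConverged = TRUE)
measureAPD(trace, fraction = 0.9)
```

**Pacing and steady state.** The reference stabilization protocol is a
train of 3600 stimuli (1 ms, 52 pA/pF) at a cycle length of 1000 ms,
integrated with forward Euler at dt = 0.02 ms and Rush–Larsen updates for
the twelve gating variables. Because the model reaches its limit cycle in
roughly ten minutes of pacing, runs may stop early once the APD90 drift
across a 20-beat window falls below 0.05 ms, never before 600 beats. Steady state is
checked on the ionic side by `checkSteadyState()`: the pre-stimulus
(end-diastolic) intracellular Na\(^+\), K\(^+\) and Ca\(^{2+}\) between
the first and last of the final 60 beats must differ by less than 2 %.
"Variation" is read as *relative* change per species — the only
unit-consistent interpretation — and both the per-species maximum and the
mean are reported.

**APD definition.** APD at fraction $f$ is measured from the activation
onset (time of maximum dV/dt within the beat — a conventional, robust
choice) to the first crossing of $V_{peak} - f\,(V_{peak} - V_{rest})$,
with $V_{rest}$ the pre-stimulus diastolic potential and crossings located
by linear interpolation. Traces whose depolarization stays within 10 mV of
rest raise a "no beat detected" error rather than returning a number.

## Tissue: monodomain propagation on labelled hexahedral meshes

Propagation follows the monodomain reaction–diffusion model with an
equivalent conductivity tensor
$D = \sigma_T I + (\sigma_L - \sigma_T)\, f f^{T}$ built from the local
unit fibre direction $f$, and no-flux boundaries. The package takes the
"equivalent" in equivalent conductivity at face value: the
surface-to-volume and capacitance scaling is absorbed into $\sigma$ by
fixing $\beta C_m$ at 1 µF/cm³, so a conductivity in mS/cm acts as a
diffusivity of $10^{-3}\sigma$ cm²/ms. The absolute $\sigma$ values are
therefore *calibration outputs* — fixed by conduction-velocity targets —
not literal tissue conductivities.

Discretization is trilinear finite elements on congruent hexahedra
(300 µm spacing for the reference slab) with a consistent mass matrix —
mass lumping was measured to depress slow transverse conduction by almost
10 % where the wavefront spans only a couple of elements, while the
consistent form stays within 1 % of the continuum
$\sqrt{\sigma_T/\sigma_L}$ velocity ratio;
integration is Godunov operator splitting at dt = 0.02 ms: one reaction
step per node with its regional ionic model (compiled kernel), then one
implicit backward-Euler diffusion step solved with a prefactorized sparse
Cholesky decomposition, which is unconditionally stable at this step size.
Stimuli are added depolarizing currents (pA/pF) in the reaction step.
Activation times are tracked during integration as the first upward
crossing of −40 mV — a threshold robust across the whole action-potential
range of these models — interpolated inside the 0.02 ms step, which makes
conduction-velocity measurements independent of the coarser output grid.

**Fibre fields.** Each region carries one principal direction vector; the
longitudinal fibre direction of an element is the normalized cross product
of that vector with the element's outward surface normal
(`assignFibres()`), which by construction is tangent to the wall. A
principal vector parallel to the local normal has no well-defined fibre
and is reported as an error naming the offending elements.

**Conduction-velocity calibration.** `tuneSigmaLongitudinal()` adjusts
$\sigma_L$ until a planar wave in the 50×50×3, 300 µm slab (fibres along
the propagation axis, one face stimulated four node-layers deep at
52 pA/pF to guarantee capture at bundle-level conductivities, myocytes
pre-paced to steady state) travels at the target velocity, measured
between probes at 30 % and 70 % of the slab length on the mid line —
clear of both the stimulus and the far boundary. Monodomain theory makes
CV proportional to $\sqrt{\sigma_L}$, so the tuner uses that law as its
update rule with log-space bisection as a safeguard; it converges in two
or three simulations to a 1 % tolerance. The calibrated classes are:
general atrial tissue 63.3 cm/s (anisotropy ratio $\sigma_T/\sigma_L$
0.35), isthmus 75.0 cm/s (isotropic), pulmonary veins 76.6 cm/s (0.5),
fast bundles 116.0 cm/s (0.15) and coronary sinus 99.5 cm/s (0.5). The
assignment of the ends of the printed fast-bundle range (99.5–116.0 cm/s)
to specific bundles is not uniquely determined by the available
information; mapping 116.0 to the crista/Bachmann/pectinate group and
99.5 to the coronary sinus is a documented surrogate choice
(`defaultCvTargets()`). The calibrated table ships as
`inst/extdata/conductivity-table.csv` and is regenerated by
`calibrateConductivities()`.

The expected $\mathrm{CV}_T/\mathrm{CV}_L = \sqrt{\sigma_T/\sigma_L}$
relationship, the $\sqrt{k}$ response to scaling $\sigma_L$ by $k$, and
direction independence under isotropy are all verified as properties in
the test suite.

## The desk-scale geometric surrogates

The package does not reproduce any full anatomical atrial or torso mesh.
Instead, two parametric fixtures are generated in code:

**Idealized bi-atrial surrogate** (`buildIdealizedAtria()`): two
ellipsoidal shells of one-element wall thickness (default 900 µm, the
upper end of the physiological 600–900 µm band, at matching 900 µm
spacing), with vein and valve ostia opened as angular holes, the 21
anatomical region labels painted by angular sectors, a crista terminalis
strip with a sinoatrial patch at its top, pectinate bands, and the
Bachmann bundle as a tube across the roof joining the chambers. Region
shapes, bundle paths and the per-region principal fibre directions are
plausible *surrogates*, not measured anatomy. The bundle radius default
(0.14 cm) is a conduction-safety choice: a thicker tube presents too much
downstream load for the one-voxel shell to excite, and the junction
blocks — the same source–sink physics that governs real tissue
expansions, here amplified by the coarse wall. At the default resolution
the surrogate produces the expected sinus ordering: the sinoatrial node
fires first and the left atrium starts activating roughly 50 ms later
through the Bachmann bundle, fully depolarizing within the beat. The
printed full-organ activation times (first left-atrial activation at
38 ms, latest right and left activations at 109 and 132 ms) belong to the
reference anatomical mesh and are **not** targets for this surrogate;
only their ordering is.

**Simplified torso** (`buildSimplifiedTorso()`): a box tetrahedralized
into conforming Kuhn (six-per-cube) tetrahedra at 2 cm default element
size, with embedded simplified organs — two lung ellipsoids, a liver
block, a spine column, a passive ventricular ellipsoid, and a
blood/myocardium shell around the atrial cavity — carrying the organ
conductivities myocardium 4.589, bone 0.200, liver 0.277, lung 0.389,
general chest 2.390 and blood 7.0 mS/cm. The inner source layer is the
node set nearest the nominal 0.8 mm offset surface outside the atrial
boundary (within half an element size — the offset concept survives even
though a 2 cm mesh cannot resolve 0.8 mm literally). Kuhn tetrahedra are
nonobtuse, so the assembled stiffness matrix is an M-matrix and the
discrete maximum principle holds, which the tests assert.

## Forward models

Two forward models compute extracellular potentials from a monodomain run:

*Infinite homogeneous medium (pseudo-ECG).* The potential at an
observation point $r$ is the volume integral of
$\nabla V_m \cdot \nabla' (1/|r'-r|)$ over the tissue, scaled by
$-\gamma \sigma_i / (4\pi\sigma_e)$. Gradients are taken constant per
element at centroids (exact for trilinear elements at the centre); the
kernel gradient is analytic. $\gamma$ and $\sigma_i/\sigma_e$ default to
1: they only scale amplitude, so every amplitude-sensitive statement in
the package is a ratio, ordering or sign. Useful exact properties follow
from the form of the integral and are enforced by tests: uniform $V_m$
gives zero, the map is linear in $V_m$ and $\gamma$, and — because any
smooth compactly supported source has zero net gradient integral — a
uniformly depolarized region strictly inside the mesh produces no far
field at all. The analytic dipole check therefore places a depolarized
ball on the mesh boundary, whose clipped half carries the net moment
$\Delta V \pi R^2$ and shows the expected $1/r^2$ decay.

*Heterogeneous torso.* Under the quasi-static assumption each output time
step (1 ms) is independent: pseudo-ECG potentials evaluated at the inner
source layer are imposed as Dirichlet data, and the Laplace equation with
the heterogeneous organ conductivities and zero-flux skin is solved by
P1 finite elements with a prefactorized sparse Cholesky (`forwardTorso()`,
`solveTorsoLaplace()`). Leads are linear (barycentric) interpolants of the
node potentials; the standard bipolar limb leads are the printed
differences of the limb-equivalent points.

## Signal analyses

`computeLATMap()` (first −40 mV upcrossing per node), `computeAPDMap()`
(the cell-level APD definition applied per node, with per-region mean/SD
tables and explicit exclusion counts), `computeBRMSMap()` (per-point RMS
over the analysis window, no baseline removal — no detrending step is
part of the definition), `extractPWaveFeatures()` (duration as the span
where |V| exceeds 5 % of the absolute peak; peak-to-peak amplitude;
morphology classes monophasic±, biphasic, M-shaped, indeterminate from
signed-lobe analysis with a 25 % lobe/notch gate; both gates are exposed
arguments, as the class definitions are inherently qualitative), and
`decomposeRegionContributions()`.

The decomposition is the package's central analysis: restricting the
pseudo-ECG integral to one region's elements isolates that region's
contribution, and linearity makes the per-region traces sum *exactly* to
the whole-tissue trace — verified to machine precision — while shares of
summed RMS add to 100 %. In torso mode the same masking is approximate
only through the identical linear solves, so the decomposition is defined
in pseudo-ECG mode. Stability of the contribution *ranking* under mesh
refinement is tested with a prescribed analytic activation painted on two
resolutions of the surrogate (rank correlation > 0.9); using a prescribed
wave rather than two solver runs isolates the decomposition's mesh
sensitivity from resolution-dependent conduction physics, so the check
measures the quantity it claims to.

## What the tests do and do not show

Everything quantitative that the package asserts is at desk scale: the
cellular APD90 table and its regional ratios, the slab CV calibration and
anisotropy relationships, the analytic properties of both forward models,
and exact superposition of regional sources. The full-organ figures of a
reference anatomical model — absolute activation times, regional APD
means after 3D coupling at 300 µm, the percentage P-wave changes under
isotropy or torso homogenization, and any specific region-contribution
split — require the reference meshes and are represented here only by
their qualitative counterparts: orderings, effect directions and
stability statements. Passing tests demonstrate that the machinery is
correct and calibrated, not that the surrogate geometry is anatomically
faithful.

## Problem sizes and determinism

Default problem sizes were chosen so a complete analysis runs on one CPU
core: the reference slab has 7,500 elements (10,404 nodes), the 900 µm
surrogate atria about 9,000 elements (22,000 nodes), and the toy torso
about 31,000 tetrahedra. A convergence-stopped cellular stabilization
takes seconds; a slab CV evaluation tens of seconds; a full sinus beat on
the surrogate atria a few minutes. All solvers are deterministic; the
only randomness anywhere is in user-seeded fixture jitter, so identical
configurations reproduce results bit for bit (the pipeline manifest
records a configuration hash to make this checkable).

## Known limitations

Single ionic model family (no alternative atrial models, no pathology
variants); no bidomain electrics, mechanics or adaptive time stepping; a
one-voxel wall with no transmural heterogeneity and no wall-thickness
variability; surrogate fibre directions; no boundary-element torso and no
inverse problem. The torso ventricle is a passive labelled conductor
during atrial activation.
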