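# AtriaSim

Multiscale simulation of human atrial electrophysiology and its
body-surface signature, in R.

Atrial arrhythmias appear on the torso as abnormal P-waves and body-surface
potential maps, but relating what the atria do to what the electrodes see
requires crossing three scales: ionic currents in single myocytes, wave
propagation through heterogeneous and fibre-anisotropic tissue, and volume
conduction to the body surface. AtriaSim implements that chain as a
reusable simulator for computational electrophysiologists:

- **Cell scale** — a Maleckar-type human atrial myocyte model
  (Nygren-lineage formulation, 29 state variables) with eight regional
  variants defined by rescaling g_to, g_CaL and g_Kr; pacing protocols,
  APD measurement and ionic steady-state diagnostics.
- **Tissue scale** — the anisotropic monodomain model
  `∇·(D∇Vm) = Cm ∂Vm/∂t + Iion`, `D = σT I + (σL − σT) f fᵀ`, solved by
  operator splitting (compiled reaction kernel + implicit FEM diffusion,
  dt = 0.02 ms) on regular hexahedral meshes; fibre fields from regional
  principal directions via the cross-product rule; conduction-velocity
  calibration of σL per tissue class in a 50×50×3 slab at 300 µm.
- **Body scale** — the infinite-medium pseudo-ECG integral
  `V(r) = −(γ/4π)(σi/σe) ∫ ∇Vm·∇'(1/|r'−r|) dv` and a heterogeneous-torso
  Laplace solve (organ conductivities, Dirichlet source layer at a nominal
  0.8 mm offset, zero-flux skin); lead extraction, B-RMS maps, P-wave
  morphology features and exact per-region source-contribution
  decomposition.

Desk-scale geometry generators (tissue slabs, an idealized 21-region
bi-atrial surrogate, a simplified organ-bearing torso) are part of the
package, so no external data is required.

## Worked example

Pace the crista-terminalis regional myocyte to steady state and measure
its APD90, then calibrate general atrial tissue conductivity:

```r
library(AtriaSim)

cell  <- makeRegionalCell("CT/BB")
trace <- paceSingleCell(cell, pacingProtocol(nBeats = 3600L),
                        stopWhenConverged = TRUE)
measureAPD(trace, fraction = 0.9)
#> [1] 228.1362
checkSteadyState(trace, windowBeats = 60L)
#> [1] 0.0339378          # max % drift of Na+/K+/Ca2+, well under 2 %

fit <- tuneSigmaLongitudinal(63.3, anisotropyRatio = 0.35,
                             cellModel = makeRegionalCell("RA/PM"))
c(sigmaL = fit$sigmaL, achievedCv = fit$achievedCv)
#>     sigmaL achievedCv
#>   2.306264  63.421359   # cm/s, within 1 % of the 63.3 cm/s target
```

The APD90 (228.1 ms) is the long-action-potential crista/Bachmann variant;
the baseline RA/PM model gives 199–201 ms at the same cycle length, and the
calibrated σL reproduces the target conduction velocity on a verification
run. A full sinus beat on the idealized atria:

```r
at    <- buildIdealizedAtria()                  # 21 labelled regions
cond  <- regionConductivity(at$labels, at$fibres)
cells <- ...                                    # region -> cell model map
run   <- runMonodomain(at$mesh, at$labels, cond, cells,
                       stimulusSet(sanNodes, amplitude = 30), duration = 230)
lat   <- computeLATMap(run, useSolverLat = TRUE)
dec   <- decomposeRegionContributions(run, at$labels, points)
```

gives activation beginning in the sinoatrial node and reaching the left
atrium through the Bachmann bundle ~50 ms later, and per-region
contribution traces that sum to the whole-atria signal to machine
precision (see `vignettes/atrial-forward-modelling.Rmd` for the complete
workflow, including the torso stage, and `inst/cli/atriasim` for a shell
front end).

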