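# aneufsi

Fluid–structure interaction (FSI) modelling of intracranial-aneurysm
haemodynamics on an idealized, fully reproducible benchmark: a spherical
aneurysm sac seated on a toroidal parent vessel, sized like a
carotid-artery sidewall aneurysm.  The package is aimed at researchers in
vascular biomechanics who want a controlled setting in which rigid-wall
CFD and compliant-wall FSI can be compared on the standard haemodynamic
risk indicators.

## What it computes

* **Geometry and meshing** — parametric construction of the benchmark
  (4 mm inlet, 0.25 mm wall, sphere-on-torus sac with a smoothed neck) and
  structured tetrahedral meshes with geometric boundary-layer grading;
  conforming fluid/solid interfaces; Gmsh MSH 4.1 and VTU input/output.
* **Fluid** — transient incompressible Navier–Stokes in an ALE frame:
  stabilized equal-order P1–P1 elements (SUPG/PSPG/grad-div with
  quasi-static subscales), BDF2 time stepping, Picard-linearized
  convection, parabolic pulsatile inlet

  $$v(x,t) = V(t)\left(1-\frac{\lVert x - x_c\rVert^2}{r^2}\right)e_y,$$

  and a resistance outlet $P = P_0 + R_d Q$ ($P_0=-3.7$ kPa,
  $R_d=1.31$ kPa·s/mL) treated implicitly.
* **Solid** — mixed displacement–pressure neo-Hookean wall with the
  volumetric law $U(J)=\tfrac{\kappa}{4}(J^2-1)-\tfrac{\kappa}{2}\ln J$,
  so $p_s = U'(J) = \tfrac{\kappa}{2}(J - J^{-1})$, and deviatoric Cauchy
  stress $\mathrm{dev}\,\sigma = \mu J^{-5/3}\,\mathrm{dev}(FF^T)$;
  consistent tangent, BDF2 inertia; bulge $E=0.75$ MPa, artery $10\times$
  stiffer, $\nu=0.45$.
* **Coupling** — partitioned Dirichlet-to-Neumann sub-iterations with
  Aitken $\Delta^2$ dynamic relaxation
  ($\omega_k = -\omega_{k-1}\, r_{k-1}^T (r_k - r_{k-1}) / \lVert r_k -
  r_{k-1}\rVert^2$, $\omega_0 = 0.1$), a linear displacement predictor,
  and a node-scaled interface tolerance of $10^{-5}$ mm.
* **Haemodynamics** — wall shear stress
  $\tau_{WSS} = \sigma_f n - (n^T\sigma_f n)\,n$, TAWSS, OSI
  $=\tfrac12\left(1-\lVert\int\tau\,dt\rVert/\int\lVert\tau\rVert dt\right)$,
  bulge-averaged WSS, intrasaccular swirl rate (upward flux through the
  plane through the sac centre), sac volume variation, peak delays.
* **Pipeline** — configuration-driven rigid and compliant runs over two
  cardiac cycles with metrics recorded on the second cycle
  ($t \in [1.0, 1.8]$ s), a verification harness with analytic oracles
  (Poiseuille, Womersley, thin-shell inflation, Aitken secant identity,
  elastic-tube pressure wave, OSI limits), and a rigid-vs-compliant
  comparison report.

## Worked example

```r
library(aneufsi)

wf <- build_waveform()                      # calibrated ICA-like pulse
waveform_stats(wf)$Wo                       # 2.802  (parent-vessel Womersley)
waveform_stats(wf)$Re_peak                  # 518.8  (peak Reynolds)
outlet_pressure(waveform_flow(wf, 1.12))    # 4.84 kPa near systole

model <- build_case_r()                     # sphere-on-torus benchmark
fl <- mesh_fluid(model, mesh_params(core_size = 0.9,
                                    bl_first_layer = 0.3, bl_total = 0.45))
sl <- mesh_solid(fl, model)                 # conforming wall shell
print(fl)
# tagged_mesh: 748 vertices, 3591 cells
#   boundary tags: inlet (57), interface (378), outlet (57)

cfg <- case_config(mode = "rigid", t_end = 0.06, t0 = 0.03, period = 0.03)
b <- run_case(cfg)                          # short demonstration run
print(b)
# result_bundle (rigid, desk profile): 16 metric samples on [0.03, 0.06] s
# peak inflow 0.961 mL/s | peak outlet pressure -2.441 kPa | peak bulge WSS 0.155 Pa
```

A full benchmark comparison (several minutes per mode on one core at desk
resolution):

```r
cfg <- case_config(mode = "compliant", store_every = 2L)
ms  <- aneufsi:::build_case_meshes(cfg)
bc  <- run_case(cfg, meshes = ms)
br  <- run_case(case_config(mode = "rigid", store_every = 2L), meshes = ms)
compare_modes(br, bc)
```

or, from a shell, `exec/aneufsi compare --out results/`.

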