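---
title: "Methods: fluid-structure interaction modelling of a sidewall aneurysm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluid-structure interaction modelling of a sidewall aneurysm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Intracranial aneurysms are pathological outpouchings of cerebral arteries.
Their haemodynamic environment — above all the wall shear stress (WSS) the
blood exerts on the sac and its oscillatory character (OSI) — is the
standard mechanistic currency for reasoning about growth and rupture risk.
Most computational studies treat the arterial wall as rigid; the package
implements the coupled alternative, where a hyperelastic wall deforms under
the flow and feeds its motion back into the fluid, and provides an
idealized, fully reproducible benchmark on which the two modelling choices
can be compared: a spherical sac seated on a toroidal parent vessel,
sized like a carotid-artery sidewall aneurysm.

# Geometry and meshing

The parent vessel is a half-torus: the centreline is a semicircle of radius
6 mm in the plane z = 0, so both the inlet and the outlet disc lie in the
plane y = 0; the lumen radius is 2 mm (inlet diameter 4 mm).  The sac is a
sphere of radius 2.5 mm centred at (0, 10, 0) mm, on the symmetry plane.
The torus major radius and the sphere radius are not dictated by any
physical constraint; they were fixed once so that the apex of the parent
lumen touches y = 8 mm, making the half-space y > 8 mm contain exactly the
sac — the same plane that separates the soft bulge material from the
stiffer artery and that is used for the bulge-volume metric.  The wall has
uniform thickness 0.25 mm.

The lumen surface is represented as a star-shaped radial graph over the
centreline: along each ray from a centreline point, the surface radius is
the larger of the tube radius and the exit distance through the sac sphere
(where the sphere is open to the lumen).  The raw union has sharp neck
angles and, near the sphere's silhouette, is not a single-valued radial
graph; both are regularized by smoothing the radius function over the
parametric grid with a Gaussian kernel of 0.5 mm arc length.  This is the
package's realization of the "smoothed neck" of the benchmark: a rolling
ball fillet is not expressible in a radial graph, so a blend of the same
length scale is used instead.  The smoothing slightly rounds the sac
(its apex sits at y = 11.9 mm rather than 12.5 mm); every consumer of the
geometry sees the same smoothed surface, so the benchmark remains
self-consistent.

Meshes are structured: a disc lattice (optionally graded toward the wall in
geometric progression — factor 1.2 from a 0.02 mm first layer to a 0.3 mm
total at the reference resolution, the layer count being the smallest whose
cumulative thickness reaches the total, i.e. 8 layers) is swept along the
centreline and mapped radially onto the lumen surface.  Prisms are split
into tetrahedra with the minimum-global-index rule, which guarantees
matching diagonals on shared faces.  The wall mesh is extruded from the
fluid wall triangulation along outward vertex normals in equal layers
(6 layers of 0.042 mm at reference resolution), so the fluid and solid
interface triangulations are vertex-identical by construction.  Cells whose
centroid lies above y = 8 mm are labelled bulge material.

Two resolution profiles exist.  The *desk* profile (the default, used by
the test suite) uses a ~0.9 mm core size with extra azimuthal resolution
(0.7 mm) and axial sections concentrated around the sac, and one solid
layer: about 3 000 fluid and 2 000 solid tetrahedra.  The *full* profile
reproduces the reference meshing rules and is intended for cluster-scale
replication; its element counts are in the hundreds of thousands.

# Fluid model

Blood is a Newtonian fluid with viscosity 0.004 Pa s and density
1000 kg/m^3 (the standard value; it also makes the Womersley number of the
4 mm vessel at period 0.8 s equal 2.8).  The incompressible Navier-Stokes
equations are written in an arbitrary Lagrangian-Eulerian (ALE) frame, so
the convective velocity is v - vm with vm the mesh velocity.  Space is
discretized with equal-order P1-P1 tetrahedra and residual-based
stabilization of the variational-multiscale family: SUPG and PSPG terms
with quasi-static subscales plus a grad-div term, with

tau_M = (rho a0/dt + 4 mu/h^2 + 2 rho |a|/h)^-1,  tau_C = h^2/(4 tau_M),

where a0/dt is the BDF coefficient, h the equivalent regular-tet edge and
a the convective velocity.  Time stepping is BDF2 with a BDF1 first step.
Convection is Picard-linearized; iterations stop at a relative velocity
increment of 1e-6 (or at the linear-solver noise floor, detected by a
stalled contraction).

The inlet velocity is the parabolic profile V(t)(1 - (r/R)^2) e_y; V(t) is
the pulse described below.  The outlet carries the resistance condition
P = P0 + Rd Q with P0 = -3.7 kPa and Rd = 1.31 kPa s/mL, applied weakly as
the traction -P n.  Because the hydraulic response of the short vessel is
stiff, the lagged fixed point P(Q) diverges at millisecond steps; the
resistance is therefore folded into the matrix as the rank-one boundary
term Rd w w^T (w being the discrete outlet-flux functional), which makes
the pressure-flow feedback unconditionally stable and costs nothing.  Walls
(or the FSI interface) carry strongly enforced Dirichlet data.

The mesh motion solves the diffusion problem div(gamma grad .) = 0 for the
displacement, component-wise, with gamma the inverse squared distance to
the interface (computed once on the reference mesh by exact point-triangle
distance and floored at the smallest positive cell-centroid distance), zero
on the non-interface boundaries.  The mesh velocity is the BDF derivative
of the extension, which for this time-independent linear operator is
identical to extending the interface velocity directly.

Wall tractions are evaluated two ways: per-face direct-gradient evaluation
(used as the Neumann load handed to the solid), and variationally
consistent nodal reactions (the pre-Dirichlet momentum residual), which
are superconvergent and are used for the WSS metrics.

# Solid model

The wall is a neo-Hookean solid with the volumetric law
U(J) = kappa/4 (J^2 - 1) - kappa/2 ln J, deviatoric energy
W = mu/2 (I1bar - 3).  The pressure-like variable satisfies ps = U'(J) =
kappa/2 (J - 1/J) — note that this is the derivative of U; a printed form
with a plus sign would not vanish in the reference state.  The mixed u-ps
system is discretized with P1-P1 tetrahedra; with linear displacement the
deformation gradient is element-wise constant, so the only mixed-order
terms are those coupling the linear ps field, which are integrated
consistently; the constraint row is scaled by kappa to balance physical
units, and stabilized with a pressure-gradient term kappa tau grad ps with
tau = h^2/(4 mu).  Inertia uses BDF2 applied to both displacement and
velocity histories.  The consistent tangent (including the full deviatoric
dP/dF and the volumetric coupling blocks) is verified against central
finite differences in the test suite to 1e-6 relative.

Engineering constants are E = 0.75 MPa in the bulge, ten times stiffer in
the artery, nu = 0.45, density 1000 kg/m^3.  Newton iterations are damped
when a step would exceed a quarter of the smallest element size (a guard
against transient overshoot in thin shells) and stop on a load-scaled
residual of 1e-8 (1e-6 within FSI sub-iterations, where the outer loop
provides further iteration).  There is no structural damping and no
pre-stress; consistent with the benchmark's design, the diastolic outlet
pressure is lowered instead (the corridor is 0 to 40 mmHg rather than
80 to 120 mmHg).

Solid nodes on the inflow/outflow plane y = 0 are fully fixed; the
exterior surface is traction-free.

# Coupling

The partitioned loop is Dirichlet-to-Neumann: predict the solid
displacement (linear extrapolation of the two previous converged levels),
move the fluid mesh, solve the fluid with the interface velocity from the
BDF2 stencil of the prediction, hand the interface traction to the solid
(with the sign flip of the outward normals), solve the solid, and form the
residual r = u - u_pred over all solid nodes.  Its norm is the Euclidean
norm divided by the node count, reported in mm; the step is accepted below
1e-5 mm.  The first two sub-increments relax with a fixed omega = 0.1;
afterwards the Aitken formula updates omega, clamped to [0.01, 2] against
degenerate spikes.  Note that the node-count scaling makes the effective
per-node tolerance stricter on coarser meshes, so the desk profile enforces
a somewhat tighter interface match than a fine-mesh run would.

Warm starts (the previous sub-iteration's fluid and solid states) make
late sub-iterations cheap; with the linear predictor, a settled pulsatile
step converges in 2-4 sub-iterations.

# Linear algebra

All discrete systems are solved iteratively with preconditioning, in
keeping with the solver design of large-scale FSI codes.  Unknowns are
permuted to node-interleaved order; each mesh topology builds its symbolic
CSR pattern once; systems are solved by restarted GMRES preconditioned
with a frozen sparse LU factorization that is refreshed only when the
iteration count degrades (the matrices drift slowly across Picard/Newton
iterations, sub-iterations and time steps).  The mesh-motion operator is
constant, so its factorization is exact and permanent.  An
ILU(0)-preconditioned BiCGSTAB/GMRES path with Ruiz equilibration is also
provided and is used for standalone solves.  Tolerances are 1e-8 relative
(1e-6 inside FSI sub-iterations).

# Inflow pulse and calibration

The literature waveform the benchmark uses is published only graphically,
so the package ships a smooth analytic stand-in: on the unit cycle,
baseline 0.75 plus a systolic Gaussian at phase 0.15 (width 0.08) and a
dicrotic bump at 0.45 (width 0.12).  The systolic amplitude (0.7123125)
was calibrated once so the unit-mean shape has peak factor 1.63, which
puts the peak parent-vessel Reynolds number at about 520 and keeps the
resistance-outlet pressure between roughly 5 and 36 mmHg for the 4 mL/s
mean flow; the constants are frozen in code and the shape can be replaced
by any digitized curve via CSV import.  The pulse is prefixed with a 0.2 s
linear ramp from zero; cycles start at the end of the ramp, so the metric
window [1.0, 1.8] s is exactly the second cardiac cycle.  Calibration is
exact by construction: the shape samples are normalized to unit mean of
their periodic linear interpolant and the centreline scale is 2Q/A.

# Haemodynamic metrics

WSS is the tangential projection of the wall traction; TAWSS its
time-averaged magnitude and OSI = (1 - |mean vector| / mean magnitude)/2,
both per vertex with trapezoidal time integration over the metric window,
OSI defined as 0 where the shear vanishes.  The bulge-averaged WSS is the
area-weighted mean of |tau| over wall vertices above y = 8 mm.  The swirl
rate is the integral of max(v_y, 0) over the cut of the plane y = 10 mm
with the deformed lumen (exact per-tetrahedron slicing with clipping of
the linear integrand; the signed net flux is available behind a flag but
would be near zero inside a closed recirculation and is not used).  The
sac volume is the exact lumen volume above y = 8 mm on the deformed mesh;
its variation is reported against the diastolic reference, taken at the
minimum-inflow instant within the window.  Peak delays between series use
parabolic sub-sample refinement.  The maximum displacement is the largest
nodal displacement norm over the window.

# Problem sizes and numerical choices

The test suite runs everything at desk scale: the tube oracles use a few
thousand cells (the Poiseuille check drives the discrete inlet flux to
exactly 4 mL/s before comparing the wall shear with 4 mu Q/(pi a^3), since
a polygonal disc otherwise carries a quadrature deficit; the Womersley
check initializes from the analytic solution and compares one period at 40
steps); the inflation fixture is an octant of a spherical shell with
symmetry conditions; the sidewall-aneurysm comparison runs both wall
models for the full 1.8 s at dt = 2 ms on the desk mesh with metric
sampling every other step.  The full-resolution profile with dt = 1 ms
reproduces the reference settings and is provided for cluster-scale runs.

What the desk-scale comparison does and does not show: at ~5x coarsening
the absolute WSS levels and delays are not mesh-converged; the package
asserts only the robust qualitative signature of wall compliance — lower
peak bulge-averaged WSS, earlier swirl development, a positive
outlet-pressure lag after peak inflow, and the distal shift of the neck
jet — not the printed fine-mesh magnitudes.

# Known limitations

Newtonian rheology only; no pre-stress of the diastolic configuration; a
single outlet with a pure resistance (no compliance/inertance elements);
isotropic neo-Hookean wall (no fibre models or viscoelasticity);
structured meshes only (arbitrary patient geometries can be imported as
tagged MSH files but are not generated here); the neck blend approximates
a fillet of the same length scale rather than a rolling-ball surface.
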