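---
title: "Simulating dielectrophoretic cell separation in a two-stage lab-on-chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dielectrophoretic cell separation in a two-stage lab-on-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

depchip simulates a planar two-stage Y-channel microfluidic separator that
sorts circulating tumor cells (CTCs), white blood cells (WBCs) and
platelets (PLTs) out of an RBC-depleted, diluted blood sample by negative
dielectrophoresis (DEP). This vignette is the package's account of the
model: the governing equations, the assumptions and tunable parameters,
the numerical choices, the calibration of the free operating
parameters, and the limits of what the simulations demonstrate.

## Device and physical model

The device is a compact (about 919 um x 440 um footprint at a 40 um
channel width, 100 um depth) planar network: two 45-degree inlet branches
(blood sample above, faster sheath buffer below) merge into a main channel
whose upper wall carries 2 or 4 rectangular electrodes protruding 16 um
into the flow; a first Y-split sends the lower stream to the WBC outlet
while the upper stream continues through a short secondary channel to a
second Y-split separating CTCs (middle outlet) from PLTs (upper outlet,
electrode side).

Three fields are solved sequentially, matching the separable physics:

1. **Creeping flow.** Steady incompressible Stokes flow,
   $0 = \nabla\cdot[-p\,\mathbf I + \mu(\nabla\mathbf u)]$,
   $\nabla\cdot\mathbf u = 0$: inertia is negligible at these Reynolds
   numbers ($\mathrm{Re}\sim 10^{-2}$). Inlets impose a plug velocity at
   the stated mean (a fully developed parabolic profile is available as
   an option), walls and electrode faces are no-slip, and the outlets
   carry the do-nothing outflow condition, which realizes the 0 Pa static
   outlet pressure.
2. **Electric potential.** The buffer is ohmic and the drive quasi-static:
   $\nabla\cdot(\sigma_m\nabla V) = 0$ with Dirichlet values $\pm V_a$ on
   the exposed faces of the electrode notches (alternating polarity) and
   zero normal current elsewhere; $\mathbf E = -\nabla V$,
   $\mathbf J = \sigma_m \mathbf E$. The signal frequency does not enter
   the spatial solve; it only sets the polarization contrast below.
3. **Cell transport.** Each cell is a point particle with excluded
   volume (radius $R_p$) advected by the flow and driven by the DEP force
   $$\mathbf F_{DEP} = 2\pi\,\varepsilon_m R_p^3\,
     \mathrm{Re}[K(\omega)]\, \nabla|\mathbf E|^2 ,$$
   where $\mathrm{Re}[K]$ is the real part of the Clausius-Mossotti
   factor of the single-shell cell model (below). Because the Stokes
   relaxation time of a $\le 15$ um cell in an aqueous buffer is
   $\sim 10^{-5}$ s against a seconds-long transit, the default dynamics
   are overdamped,
   $\dot{\mathbf x} = \mathbf u(\mathbf x) + \mathbf F_{DEP}/(6\pi\mu R_p)$;
   an inertial mode integrating
   $m\dot{\mathbf v} = 6\pi\mu R_p(\mathbf u - \mathbf v) + \mathbf F_{DEP}$
   is retained for sensitivity checks (it is costly, since the fast
   relaxation is integrated explicitly). Cell-cell interactions and
   two-way coupling to the fluid are neglected throughout.

### AC time-averaging of the DEP force

The potential is solved once with the electrode *amplitudes* $\pm V_a$.
The force a cell feels from an AC drive is the time average,
$\langle \mathbf F_{DEP}\rangle = 2\pi\varepsilon_m R_p^3
\mathrm{Re}[K]\,\nabla|\mathbf E_{rms}|^2 = \tfrac12\, 2\pi\varepsilon_m
R_p^3 \mathrm{Re}[K]\,\nabla|\mathbf E_{amp}|^2$: the tracer therefore
applies a factor 1/2 to the amplitude-based drive field. `dep_force()`
itself implements the instantaneous force law verbatim so that field-level
identities (uniform-field zero force, $R_p^3$ and $V_a^2$ scalings) hold
exactly. The distinction matters quantitatively: without time-averaging,
the platelet deflection at $\pm 2$ V provably exceeds what complete
separation allows for *any* admissible buffer/frequency pair, because
$\mathrm{Re}[K_{PLT}]$ is pinned near $-0.5$ across the whole nDEP band.

## The single-shell cell model

Each species is a cytoplasm sphere (radius $R$, conductivity
$\sigma_{cyt}$, relative permittivity $\varepsilon_{cyt}$) covered by a
thin membrane (thickness $t$, $\sigma_{mem}$, $\varepsilon_{mem}$),
homogenized into one complex permittivity
$$\varepsilon^*_{eff} = \varepsilon^*_{mem}
  \frac{\gamma^3 + 2\Delta}{\gamma^3 - \Delta},\qquad
  \gamma = \frac{R}{R-t},\qquad
  \Delta = \frac{\varepsilon^*_{cyt}-\varepsilon^*_{mem}}
  {\varepsilon^*_{cyt}+2\varepsilon^*_{mem}},$$
with $\varepsilon^* = \varepsilon - i\sigma/\omega$, and
$$\mathrm{Re}[K(\omega)] = \mathrm{Re}\!\left[
  \frac{\varepsilon^*_{eff}-\varepsilon^*_m}
  {\varepsilon^*_{eff}+2\varepsilon^*_m}\right] \in [-0.5, 1].$$
The DC case is implemented as the conductivity-only limit, never as a
division by $\omega$. The species catalog (diameters 15/12/1.8 um,
membrane thicknesses 7/7/8 nm, and the measured conductivities and
permittivities for CTC/WBC/PLT) ships as a versioned JSON table in
`inst/extdata/cell_catalog.json`.

## Calibration of the free operating parameters

The buffer's electrical properties and the drive frequency are free
parameters of the model (the separation physics constrains them only
jointly). The package fixes them once, as its default operating point, by
requiring that

* all three species are nDEP (pushed away from the electrodes, matching
  the observed outlet routing: PLTs closest to the electrodes exit the
  upper outlet, WBCs are deflected furthest to the lower outlet, CTCs
  exit in between),
* the force magnitudes order $|F_{WBC}| > |F_{CTC}| > |F_{PLT}|$,
* the reference design points achieve complete separation while the
  low-buffer case (350 um/s) does not.

With $\sigma_m = 55$ mS/m and $\varepsilon_{m,r} = 80$ (a typical
low-conductivity DEP buffer) the admissible frequency window is narrow --
the CTC crossover sits near 105 kHz, so
$\mathrm{Re}[K_{CTC}]$ sweeps from strongly negative to positive across
80-105 kHz while $\mathrm{Re}[K_{WBC}]\approx -0.19$ and
$\mathrm{Re}[K_{PLT}]\approx -0.50$ barely move. A scan over the three
reference designs leaves $f \in [96, 98]$ kHz; the default is frozen at
**98 kHz** ($\mathrm{Re}[K]$: CTC $-0.021$, WBC $-0.175$, PLT $-0.496$).
`check_force_ordering()` re-validates any user-supplied configuration and
warns when the ordering is violated. Every report echoes the full
resolved configuration, including the calibrated pair.

## Geometry layout constants

The reference dimensions fix the channel lengths and widths but not how
branch lengths relate to the junction interiors. In this family of
layouts the bounding-box length minus its height identically equals the
main-channel length, whereas the reference footprint implies a 479 um
difference against a 500 um main channel; no single measurement
convention reconciles both extents. The package therefore fixes
per-branch-class junction clearances once -- inlets measured from the
junction nose (clearance CW/2), the WBC outlet 5CW/4 and the CTC/PLT
outlets 3CW/5 beyond their junction centres -- so that the default
dimensions reproduce the 919 um x 440 um footprint within the 2 um
tolerance. These constants scale with CW and are never tuned per design.
Only the 90-degree branch layout (each branch at 45 degrees to the local
axis) is implemented.

## Discretization and numerics

* **Meshing.** The channel network is decomposed into mapped transfinite
  quadrilateral patches (branches, the main channel with its notch
  columns, and five-quad midpoint subdivisions of the three junction
  pentagons), split into positively oriented triangles and merged into a
  conforming mesh. Characteristic sizes are 8/4/2 um for the
  coarse/normal/fine levels. Around the electrode faces -- where
  $\nabla|\mathbf E|^2$ is singular at the reentrant notch corners and
  the cells pass within a few um -- three cascaded red-green refinement
  passes (radii 6/3/1.5 um) take the local size down 8-fold. An
  all-triangle mesh is used; mesh-area conservation against the polygon
  area (shoelace) is enforced to $10^{-6}$ relative at generation time.
* **Stokes.** Taylor-Hood elements (quadratic velocity, linear pressure;
  inf-sup stable) assembled in the gradient (Laplacian) form so the
  natural outflow condition reproduces fully developed channel flow
  exactly; one direct sparse solve. With coordinates in um, velocities in
  um/s and pressure in Pa the saddle system needs no unit factors. The
  plane-Poiseuille oracle is reproduced to machine precision on a
  rectangular fixture; discrete mass conservation holds to round-off.
* **Potential.** Quadratic elements on the same mesh; one Laplace solve
  per drive. $|\mathbf E|^2$ is evaluated per element at its corners from
  the P2 gradient and recovered to nodes by area-weighted averaging; the
  element-wise gradient of that recovered field, recovered once more,
  gives a continuous piecewise-linear $\nabla|\mathbf E|^2$ with an
  evaluation contract at arbitrary interior points. A manufactured
  quadratic potential reproduces its closed-form drive field to 1%.
  (Corner-vertex evaluation replaced element averaging during
  development: the averaged variant was measurably more diffusive next to
  the electrode faces and dominated the mesh-convergence error of the
  traced outlet speeds.)
* **Tracing.** Embedded Cash-Karp RK45 with per-particle adaptive steps
  (default relative tolerance $10^{-6}$; tightening it 10x moves exit
  points by well under 0.1 um). Outlet crossings are located by
  chord-segment intersection, including steps whose intermediate stages
  leave the domain; exit speeds are sampled a fixed small distance inside
  the crossing point so they are mesh- and step-independent. Trajectories
  end on outlet crossing, wall contact or at the 8 s window.

## Wall contact model

Cells interact with solid boundaries (walls *and* electrode faces) as
rigid spheres: when the centre comes within $R_p$ of a boundary it is
placed back at one radius and continues -- frictionless sliding, no
adhesion. This excluded-volume default replaces freeze-on-contact for two
reasons. First, the release protocol spans 80% of the inlet width, so
edge stations sit 4 um from the wall -- inside the 7.5 um CTC radius --
and freezing would immobilize large cells at release. Second, under the
protruding electrodes the 24 um gap forces 12-15 um cells within a
point-particle's reach of the faces, where the recovered field has a
local minimum directly beneath each face centre; point particles hover
there indefinitely, an artifact with no physical counterpart. Sliding
reproduces the physical squeezing of large cells through the gap. The
freeze rule is retained as `tracer_settings(contact = "freeze")` for
penalization studies of designs that drive cells into walls.

## Release ensembles

`generate_ensemble()` emulates the pre-processed sample (buffy coat plus
platelets after RBC depletion): by default 20 cells per species released
simultaneously at t = 0 across the blood-inlet face, evenly spaced over
the central 80% of the width (margin 0.1), with all species at identical
stations so that any outlet difference is attributable solely to cell
size and dielectric properties. Twenty cells give 5% efficiency
granularity -- enough to certify complete against incomplete separation;
the count is configurable upward. Equal counts per species are
deliberate: physiological abundances (1-10 CTCs per mL against millions
of other cells) would starve the CTC statistics; a random placement mode
(reproducible from a seed) is available for robustness studies. The
generator does not emulate residual RBCs, cell-size dispersion within a
species, non-spherical shapes, or inlet concentration profiles -- passing
tests certify the deterministic separation mechanism, not robustness to
biological variability.

## Metrics, sweep and grid independence

Separation efficiency (per species) is the percentage of injected cells
recovered at the designated outlet; lost cells (frozen or unresolved at
t_end) stay in the denominator. Purity (per outlet) is the percentage of
cells at that outlet belonging to the intended species; lost cells never
reach an outlet and are excluded; empty outlets are reported absent
rather than zero. Throughput is the outlet-normal flux integral times the
100 um depth; outlet throughputs reproduce the injected volumetric rate
to 0.1%. `run_sweep()` runs the full factorial over widths, voltages,
electrode counts and inlet speeds, flagging complete-separation
combinations; individual failures are recorded without aborting the
sweep.

Grid independence follows the mesh-refinement protocol of the study: the
per-species mean cell speed at the target outlet is compared between
successive refinement levels and the relative error must fall below 1%
for the finest pair. On the reference design the package meets the
criterion (normal-vs-fine maximum error 0.64%, dominated by the platelet
paths that skim the electrode faces) while the coarse level fails it by a
wide margin -- the expected pattern for a corner-singular drive field.
Coarse-level error magnitudes are solver-specific and not meaningful
beyond their order.

## Problem sizes

Default study sizes, chosen to keep a laptop-scale workflow: fine-mesh
runs (about 52k triangles, 215k Stokes unknowns) complete in under a
minute each; the acceptance design points use the fine mesh with 60
cells; the parametric sweep driver uses the normal mesh with 10 cells per
species over 120 combinations; the convergence study spans all three
levels. The `analysis/` scripts state their sizes in place.

## Known limitations

* 2D plane model: the depth enters only through volumetric throughput;
  top/bottom-wall drag and 3D field fringing are absent.
* No Brownian motion, lift forces, deformation, electrode fouling, AC
  electro-osmosis or electrothermal flow.
* The drive frequency/buffer pair is calibrated, not measured; the
  reported outcomes should be read as "there exists a standard buffer and
  drive for which the reference separation outcomes are reproduced", not as a
  first-principles prediction at an independently known operating point.
* The exposure-time profile of the DEP force along a trajectory depends
  on the transit speed implied by the stated inlet velocities;
  force-versus-time curves with much longer exposure
  windows are not
  reproducible from those velocities and are not used as verification
  surfaces here.
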