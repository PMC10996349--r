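---
title: "Modelling tDCS-driven interstitial water flux: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tDCS-driven interstitial water flux: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsflow)
```

## The problem

Transcranial direct current stimulation (tDCS) passes a few milliamperes
through scalp electrodes, producing brain electric fields of order 0.3 V/m.
Those fields are dramatically amplified where current crosses the
blood-brain barrier (BBB): the capillary wall is orders of magnitude more
resistive than the surrounding parenchyma, and nearly all of its resistance
is concentrated in the nanometre-scale tight junctions (TJs) between
endothelial cells. Inside a TJ the field can reach hundreds of volts per
metre. Because the TJ is a charged slit channel a few nanometres wide, an
axial field there drives electroosmotic water flow. `tdcsflow` chains these
effects across scales — brain voxel, capillary network, tight junction —
and predicts the net interstitial water exchange per unit tissue volume
that a given stimulation dose produces.

Because every stage is linear in the applied current (Laplace conduction,
field-to-flow coupling, flux aggregation), the end product per condition is
a single scaling factor $k$ (m$^2\,$(A$\cdot$min)$^{-1}$) that converts a
brain current-density map (A/m$^2$) into an exchange-rate map (min$^{-1}$).

## Electroosmosis in the tight junction

The TJ is idealised as a slit of width $2h = 2$ nm between parallel charged
walls with zeta potential $\zeta = -21.1$ mV. Counter-ions form diffuse
double layers of Debye thickness $\kappa^{-1} = 0.905$ nm; at this
$h/\kappa^{-1}$ ratio the layers overlap, so the equilibrium potential is
non-zero across the whole channel. We use the weak-overlap superposition of
the two single-wall Gouy-Chapman profiles:

$$\psi(y) = \frac{4kT}{ze}\,\mathrm{atanh}\!\left[\tanh\!\left(\frac{ze\zeta}{4kT}\right)e^{-\kappa y}\right]
          + \frac{4kT}{ze}\,\mathrm{atanh}\!\left[\tanh\!\left(\frac{ze\zeta}{4kT}\right)e^{-\kappa(2h-y)}\right]$$

and the electroosmotic velocity
$u(y) = -\frac{\varepsilon\zeta E}{\mu}\left(1 - \psi(y)/\zeta\right)$,
with $T = 310$ K, $z = 1$, $\varepsilon = 7.08\times10^{-10}$ F/m and
$\mu = 7.80\times10^{-4}$ Pa s. The superposition slightly overestimates
$|\psi|$ near the walls (it exceeds $|\zeta|$ at $y = 0$ by about 10%),
which is the known cost of the weak-overlap approximation; the profile is
smooth and finite everywhere, so endpoints are evaluated directly.

Averaging $u$ over the channel at unit field gives the linear coefficient
relating the mean TJ water velocity to the TJ field. Composite-trapezoid
quadrature on a uniform 1001-point grid, refined by doubling until
successive estimates agree to 0.1%, yields

```{r}
co <- fit_coefficients(double_layer_params())
co
```

i.e. an average-velocity coefficient of $3.85\times10^{-9}$ (m/s)/(V/m) and
a midline maximum of $6.61\times10^{-9}$. The coefficient is computed at
$E = 1$ V/m and asserted linear rather than fitted over a field sweep,
because the velocity relation is exactly linear in $E$. Multiplying the
average coefficient by the opening $2h$ and the junction length per unit
vessel wall $L_{TJ} = 150\,000$ m/m$^2$ gives the volumetric flux
coefficient

```{r}
flux_coefficient(co, tj_geometry())
```

about $1.15\times10^{-12}$ (m$^3$/s per m$^2$) per (V/m). Two consistency
checks support these numerics: the midline coefficient reproduces all four
reference maximum-velocity/field pairs to better than 1%, and in the
thin-double-layer limit ($\kappa h \gg 1$) the solution recovers the
Helmholtz-Smoluchowski plateau $\varepsilon\zeta E/\mu$ to 1%.

## TEER and membrane conductivities

Transendothelial electrical resistance (TEER, $\Omega\,$cm$^2$) is the
experimentally constrained handle on wall tightness. Two conversions are
used, one per scale:

* micrometre scale, uniform wall: $\sigma_{wall} = \ell_{wall}/\mathrm{TEER}$
  ($10^{-5}$ S/m at 1000 $\Omega\,$cm$^2$ with a 1 um wall);
* nanoscale, all resistance in the TJ:
  $\sigma_{TJ} = \ell_{TJ}/(\mathrm{TEER}\cdot 2h\cdot L_{TJ})$
  ($3.67\times10^{-4}$ S/m at 1000 $\Omega\,$cm$^2$).

TEER appears in the literature in both $\Omega\,$cm$^2$ and $\Omega\,$m$^2$;
the reference conductivities are only consistent with $\Omega\,$cm$^2$, so
bare numbers are interpreted in that unit and an explicit `teer()` tag is
available for SI input. The per-compartment conductivity table is shipped
as a versioned YAML file rather than hard-coded, so individual compartments
can be overridden without touching code.

## The coupling constant C

The map from wall-normal current density to TJ field, $E_{TJ} = C J_{vi}$,
is the nanoscale model's only downstream product. The package provides the
reference values $C = 2.73\times10^6$ V m/A (1000 $\Omega\,$cm$^2$) and
$3.83\times10^6$ (5000), and a reduced-order model that exposes the
physics: the paracellular pathway is a series chain (glycocalyx, cleft
segment before the TJ, the TJ itself, cleft segment after, basement
membrane, astrocytic channel), each segment contributing
$\sigma\cdot a/\ell$ per unit vessel area with $a$ the open-area fraction
($2h\,L_{TJ} = 3\times10^{-4}$ at the TJ constriction,
$20\,\mathrm{nm}\times L_{TJ} = 3\times10^{-3}$ in the wide cleft); the
transcellular shunt is $\sigma_{ins}/\ell_{wall}$. With the current
fraction $f$ through the paracellular branch,
$C = f\cdot\mathrm{TEER}/(\ell_{TJ}\cdot 2.04)$, where 2.04 is the
parenchyma-to-astro-endothelial area ratio of the radially converging
current. Three segment thicknesses are not constrained by the reference
geometry and were fixed once at physiologically typical values: glycocalyx
100 nm, basement membrane 50 nm, astrocytic channel length 1 um. They are
uncritical — each contributes less than 1% of the chain resistance, which
the TJ dominates. The model reproduces both reference constants well
within 30%:

```{r}
c(model_1000 = coupling_constant(teer = 1000, mode = "model")$C,
  model_5000 = coupling_constant(teer = 5000, mode = "model")$C)
```

The stated area ratio is quoted in its source as $3.71\times10^{-10}/
1.57\times10^{-10} = 2.04$, which is not arithmetically consistent; the
factor 2.04 itself is taken as authoritative and is overridable.
`n_tight_junctions > 1` multiplies the TJ series resistance and should be
read as an extrapolation beyond the single-junction reference case.

## The capillary network stage

The reference geometry for the voxel-scale conduction problem is an
image-derived capillary network that is not publicly available, so the
package generates a synthetic stand-in: a seeded branching random walk with
anastomosis inside a $0.15\times0.16\times0.43$ mm voxel, grown until the
vessel length density reaches 557 mm/mm$^3$ (within 10%), with outer
diameters uniform in 8-10 um and 1 um walls. The generated beds reproduce
the in vivo length density and lumen volume fraction (0.021) by
construction. The quoted surface density of 22.5 mm$^2$/mm$^3$ is mutually
inconsistent with those two (it implies 13 um vessels), so the generator
prioritises length density and diameter range and reports achieved values.
What the synthetic network does **not** emulate: the anisotropy, diameter
correlations and boundary-crossing topology of real cortical beds. All
network-dependent results are therefore checked against tolerance bands
(factor of 3 on peak wall current density, one order of magnitude on net
exchange), not point values.

Steady-state conduction $\nabla\cdot(\sigma\nabla V) = 0$ is discretised as
a resistor network: a regular finite-difference grid for the parenchyma
(0.276 S/m), a 1D chain of axial conductors per vessel segment for the
lumen (0.7 S/m times the lumen cross-section), and a membrane conductance
$\sigma_{wall}/\ell_{wall}$ per unit area coupling each lumen node to the
grid cells within one grid spacing of it (wall area split equally among
them). This embedded-membrane formulation is the standard thin-interface
treatment for high-resistance membranes and avoids conforming meshes, which
are not feasible for 9 um vessels inside a 0.15 mm voxel at this scale.
The default grid is $48\times52\times140$ cells (about 3 um spacing), so
several cells span a typical inter-vessel gap; halving the resolution moves
the peak wall current density by less than 10%.

Boundary conditions follow the two vascular-return idealisations: a
*closed* network applies a uniform inward current density to the top face,
grounds the bottom face and insulates the sides, so all current entering a
vessel must exit it elsewhere locally; an *open* network additionally
grounds the lumen nodes of the four largest-diameter segments (a seeded,
deterministic rule — the reference work does not enumerate which interior
surfaces were grounded), representing collection by larger vessels outside
the voxel. The assembled system is symmetric positive definite and is
solved by Jacobi-preconditioned conjugate gradients to a relative residual
of $10^{-10}$; current is conserved globally and at every node to near
machine precision, which also validates the area-apportionment scheme. At
the default conditions (0.082 A/m$^2$ influx, closed, 1000
$\Omega\,$cm$^2$) the solver yields peak wall current densities within the factor-of-three
band around the reference $3.2\times10^{-4}$ A/m$^2$, and
reproduces the qualitative orderings exactly: higher TEER lowers the peak,
and opening the network raises it.

## Flux aggregation and brain-wide maps

Each wall element's signed current density becomes a volumetric flux
through $Q/A = J_{norm}\times 1.15\times10^{-12}\times C$. Net exchange per
tissue volume sums $|Q/A|$ times element area over the network, divides by
the voxel volume, and converts to per-minute. Summing magnitudes counts
both water entering and leaving the vessels, following the convention that
net fluid exchange includes both directions; a `convention = "half"` option
divides by two for readers who prefer counting each exchanged volume once.
The solver's true per-element areas are used rather than assuming equal
node areas; an `equal_area` compatibility flag restores the equal-area
convention. Dividing the exchange by the applied current density gives the
scaling factor $k$; multiplying any non-negative brain current-density map
by $k$ (voxelwise) yields the exchange map, and dose changes (montage,
intensity) are pure rescalings.

The bundled `synthetic_brain_field()` stands in for a head-scale
volume-conductor model: smooth Gaussian lobes under the electrode
positions, a little seeded noise, peak-normalised to 0.082 A/m$^2$ per mA —
the reference peak brain current density. It is a stand-in for plumbing and
dose-scaling work, not an anatomical prediction.

## Problem sizes, tolerances and degenerate inputs

* Quadrature: 1001 points, doubled until successive means differ by
  <0.1%; converged values change by <$10^{-4}$ on further refinement.
* Linear solver: CG with Jacobi preconditioning, relative residual
  $10^{-10}$, hard error with the residual if not converged; a system with
  no grounded node is rejected explicitly.
* Default network solves use the full $48\times52\times140$ grid; the unit
  tests exercise the same code on coarser grids, and the
  default-resolution checks live in the acceptance suite.
* Degenerate inputs: zero zeta potential, zero applied field or zero
  applied current give exact zeros throughout; an empty vessel graph
  reduces the voxel solve to the analytic uniform slab; a zero length
  -density target returns an empty graph.
* Determinism: all stochastic components (network growth, synthetic brain
  field) are pure functions of an integer seed, and repeated pipeline runs
  with the same configuration produce byte-identical tables.

## Known limitations

* The electroosmosis model assumes smooth parallel walls; protruding
  junction proteins are not modelled. The weak-overlap superposition, not
  a full Poisson-Boltzmann solve, defines the potential.
* DC steady state only: no frequency-dependent impedance, no biphasic
  waveforms.
* No intraluminal pressure-driven flow, hematocrit, or solute transport;
  exchange rates quantify water flux only.
* The nanoscale conductance network reproduces the coupling constant to
  tens of percent, not the full 3D field structure of the BBB
  ultrastructure.
* Passing the tolerance bands with the synthetic network shows the
  transport physics and aggregation are right at realistic morphometry; it
  does not validate any particular anatomical geometry.
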