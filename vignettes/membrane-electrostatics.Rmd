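---
title: "Equilibrium electrostatics of a four-region neuronal membrane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium electrostatics of a four-region neuronal membrane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`membranepb` computes the equilibrium electric potential $\psi(x)$ along
the axis perpendicular to a planar neuronal membrane, from the
extracellular bath to the bulk cytoplasm.  The membrane is modeled as
four homogeneous regions: the extracellular electrolyte ($e$), the
glycocalyx ($g$, a slab of width $h_g$ carrying a fixed volumetric
charge density $\rho_{f,g}\le 0$), the hydrophobic lipid bilayer ($b$,
charge free, thickness $h_b$) and the cytoplasm ($c$, with fixed protein
charge $\rho_{f,c}\le 0$).  The three interfaces $S_1$ (bath/glycocalyx,
at $x=0$), $S_2$ (glycocalyx/bilayer, $x=h_g$) and $S_3$
(bilayer/cytoplasm, $x=h_g+h_b$) carry surface charge densities
$\sigma_1,\sigma_2,\sigma_3$.

Mobile ions are a symmetric electrolyte truncated to monovalent and
divalent pairs, Boltzmann distributed relative to a reference pair
$(\bar C_{ij}, \bar\psi_j)$ per region: in the bath the bulk values with
$\bar\psi_e=0$, on $S_1$ for the glycocalyx (with all species assigned
the $S_1$ boundary concentrations, since the fixed-charge term dominates
the small asymmetry this ignores), and the bulk cytoplasmic values with
$\bar\psi_c=\delta\psi$, the transmembrane potential.

In Gaussian CGS units the mean-field Poisson–Boltzmann equation in each
aqueous region admits the first integral

$$\left(\frac{d\psi}{dx}\right)^2
  = \frac{8\pi}{\varepsilon_j}\Big(\alpha_j\cosh u + \beta_j\cosh 2u
     - \rho_{f,j}\,\psi\Big) + K_j,
  \qquad u=\frac{q(\psi-\bar\psi_j)}{kT},$$

with $\alpha_j = 2N_AkT\,\bar C_{1j}$ and $\beta_j = 2N_AkT\,\bar
C_{2j}$ carrying the mono- and divalent boundary concentrations.  $K_e$
and $K_c$ are fixed by the flat-bulk conditions
($d\psi/dx\to 0$ as $\psi\to 0$ or $\psi\to\delta\psi$); $K_g$ is
anchored at a surface where the potential and the glycocalyx-side field
are both known.  Across the bilayer the potential is exactly linear with
field $E_m=-(\psi_3-\psi_2)/h_b$.

The surface potentials close the system.  $\psi_1$ comes from the
electrophoretic mobility $\mu_e$ through the Helmholtz–Smoluchowski
relation $\zeta = 4\pi\eta\mu_e/\varepsilon$ with $\psi_1=\zeta$ (the
bath potential being the zero reference).  $\psi_2$ and $\psi_3$ solve
the two Gauss-law jump conditions at $S_2$ and $S_3$,

$$\varepsilon_b E_m-\varepsilon_g E_g(S_2)=4\pi\sigma_2,\qquad
  \varepsilon_c E_c(S_3)-\varepsilon_b E_m=4\pi\sigma_3,$$

where the aqueous-side field magnitudes come from the first integrals
(the glycocalyx one anchored at $S_1$ through the analogous $S_1$ jump
from the diffuse-layer field in the bath).  Written as
$\psi_2=G(\psi_3)$ and $\psi_3=F(\psi_2)$ this is a two-variable
nonlinear system solved by a scan-and-iterate fixed point (successive
substitution with a 20 mV initial acceptance band that shrinks to the
$10^{-4}$ mV convergence tolerance, restarting from scanned initial
values on divergence), with a deterministic bracketed root solve on
$h(\psi_3)=F(G(\psi_3))-\psi_3$ as a fallback.  After nominal
convergence a few extra substitution sweeps polish the root to
$\sim 10^{-9}$ mV so the Gauss conditions close to $10^{-8}$ of the
field scale.

## Parameters that matter

| quantity | symbol | default | unit (internal) |
|---|---|---|---|
| glycocalyx width | $h_g$ | 2.5e-7 (2.5 nm) | cm |
| bilayer thickness | $h_b$ | 7.5e-7 (7.5 nm) | cm |
| aqueous dielectric | $\varepsilon_{e,g,c}$ | 81 | — |
| bilayer dielectric | $\varepsilon_b$ | 2 | — |
| monovalent bulk conc. | $\bar C_1$ | 1.54e-4 (0.154 M) | mol/cm³ |
| divalent conc. (bath / cytopl.) | $\bar C_2$ | 2e-6 / 4e-7 | mol/cm³ |
| temperature | $T$ | 310 | K |
| viscosity | $\eta$ | 1 (0.1 Pa·s) | poise |
| fixed charges | $\rho_{f,g},\rho_{f,c},\sigma_{1..3}$ | preset-specific | statC/cm³, statC/cm² |
| transmembrane potential | $\delta\psi_{R/A}$ | preset-specific | statV |

At 0.154 M and 310 K the Debye screening length is about 0.80 nm
(monovalent only), so the glycocalyx spans roughly three screening
lengths and bulk truncation at max(10 Debye lengths, 20 nm) loses
nothing measurable.

## The cell presets

The shared rows above are standard literature values.  The
cell-specific charge densities, mobilities and transmembrane potentials
are **synthetic reconstructions** (the preset files are named
`*_synthetic.cfg`): the published cell-specific table is not available
to this implementation, so the presets were constructed once, before
any test was written, to realize the documented qualitative
electrostatics of each cell type:

* **ganglion** (healthy spinal ganglion neuron): moderate zeta potential
  ($\psi_1=-15$ mV), charge distributed through the glycocalyx volume
  ($\rho_{f,g}=-4\times10^{10}$ statC/cm³, a Donnan shift of about
  $-12$ mV), small $\sigma_1$.  The $S_1$ entry field is set a few
  percent above the homoclinic threshold of the glycocalyx first
  integral, so the trajectory crosses the slab while lingering near the
  Donnan level — a substantial, gradual potential drop across the
  glycocalyx.
* **neuroblastoma** (tumorous cell): strong zeta potential
  ($\psi_1=-30$ mV) with the charge sitting *on* the outer surface
  (large $|\sigma_1|$ terminating the diffuse-layer field, erythrocyte
  like) and a weakly charged glycocalyx volume — the potential is
  nearly flat across the glycocalyx.
* resting/action transmembrane potentials: $-70/+35$ mV (ganglion) and
  $-55/+20$ mV (neuroblastoma, reflecting weaker polarization and the
  reported deficient depolarizing response of undifferentiated
  neuroblastoma cells).
* $\sigma_3=-3000$ statC/cm² ($\approx-0.01$ C/m², phosphatidylserine
  inner leaflet) for both cells, producing the characteristic resting
  minimum of $\psi$ at $S_3$ about 11 mV below the bulk cytoplasmic
  value; $\rho_{f,c}=-2.5\times10^{7}$ statC/cm³ (see *Known
  limitations* for why it must be this small).

$\sigma_2$ was chosen *width-consistently*: the $S_1$-anchored
glycocalyx trajectory is integrated across the actual slab width and
$\sigma_2$ is set so the $S_2$ jump condition matches the field the
trajectory really has there.  Without this, the surface system — which
constrains energies but not widths — and the spatial profile would be
mutually inconsistent by construction.

A green test on these presets therefore establishes that the solver and
integrator faithfully realize the *model* and its documented qualitative
behavior, not that any particular millivolt value matches a published
measurement.

## Numerical choices

* Internal units are Gaussian CGS (statV, statC, erg); SI is accepted
  and emitted only at I/O boundaries.  `convert_units()` round-trips to
  1e-12 relative.
* Profiles use classical fixed-step RK4 with 2000 steps per region by
  default.  (1000 steps leaves a step-halving difference of 1.9e-8 mV
  in the steep extracellular layer, marginally above the 1e-8 mV
  reproducibility target; 2000 gives 1.2e-9 mV.)
* The square-root argument of the first integral is clamped to zero
  when it is negative by less than 1e-12 of the local energy scale
  (turning-point tolerance); larger deficits raise a branch error.
* Root finding in $F$ and $G$: a 0.1 mV vectorized residual scan
  locates sign changes, `uniroot` refines to 1e-9 mV, and exact
  tangential roots at reference candidates (needed for the charge-free
  flat solution) are accepted directly.  If several roots remain the
  one nearest the previous iterate (else the region's reference
  potential) is selected and a multiplicity warning is recorded.
* Branch filters: $F$ rejects roots whose required $S_3$ field points
  away from the bulk cytoplasmic value (they cannot connect to the bulk
  boundary condition); $G$ rejects the mirror root that the squared
  jump relation always admits on the far side of $\psi_1$, keeping the
  monotone-slab branch.  The independent 2-D grid oracle used in the
  tests applies the same masks.
* The assembled profile anchors the glycocalyx at $S_1$ and integrates
  forward: that direction is contracting toward the slow Donnan
  manifold, while backward integration from $S_2$ exponentially
  amplifies any rounding (gaps of tens of mV were observed).  The
  forward-landed value at $S_2$ starts the bilayer chord, keeping the
  profile continuous by construction; the width-consistency gap
  $|\psi_g(S_2)-\psi_2|$ is reported in `diagnostics$delta_S2_model`
  (about 0–3 mV for the presets, state dependent), and the backward
  anchoring is retained as a secondary diagnostic.

## Known limitations

* **Width overdetermination.**  The surface-potential system uses only
  the energy (first-integral) relation, so $\psi_2$ carries no
  information about $h_g$.  The model is honest about the resulting
  inconsistency through `delta_S2_model` instead of hiding it.
* **State-independent $S_3$ dip.**  The diffuse dip of $\psi$ below the
  bulk cytoplasmic value at $S_3$ is set by $\sigma_3$ (weakly modified
  by the bilayer field) and is therefore nearly identical in the
  resting and action states.  Any $\sigma_3$ large enough to produce
  the documented resting-state minimum (~11 mV here) produces the same
  dip at the action-potential peak; a cytoplasmic segment flat to
  0.5 mV at the AP state would require $|\sigma_3|\lesssim 10^{2}$
  statC/cm², contradicting the dominance of the inner-leaflet charge.
  The corresponding acceptance assertion is kept as specified and is
  expected to fail.
* **No sweep asymptote within a decade.**  Under the cytoplasmic
  fixed-charge sweep, the dip deepens linearly in the ratio while the
  fixed-charge term is small and like $(kT/q)\log r$ once it dominates;
  on a log-spaced grid over $r\in[1,10]$ the per-interval change of
  $\psi_3$ is non-decreasing, so the "flattens to <10% of the first
  interval" acceptance clause cannot be met by any parameterization
  that also satisfies the bulk-limit checks.  A true asymptote exists
  only where the bilayer field cancels $4\pi\sigma_3$, at dips of order
  volts.  The strict monotone decrease does hold and is asserted.
* **Bulk electroneutrality wart.**  With a symmetric mobile electrolyte
  referenced to the bulk, a nonzero $\rho_{f,c}$ leaves the bulk
  cytoplasm non-neutral; the first integral then makes a band of width
  $s^* = 2|\rho_{f,c}|(kT/q)^2/\alpha_c$ below $\delta\psi$
  unreachable, and profiles plateau at $\delta\psi-s^*$.  Keeping the
  0.1% bulk-limit contract for all four preset states bounds
  $|\rho_{f,c}|\lesssim 3\times10^{7}$ statC/cm³ (~0.1 mM of fixed
  charge).  Larger cytoplasmic protein charge is simply outside what
  this model can represent while still reaching its own boundary
  condition.
* No Stern layer, ion-specific adsorption or activity corrections; no
  time dependence (the action state is a stationary boundary condition
  at the AP peak); strictly planar geometry.
* The $\psi_2$ response to the $\sigma_2$ sweep is not asserted to be
  monotone: the coexisting descending/ascending first-integral branches
  make the selected root hop once the required $S_2$ field exceeds the
  descending branch's range, an artifact of root selection rather than
  of the physics.

## Reproducing the figures' computations

```r
library(membranepb)

# surface potentials and profile, one cell and state
inp  <- load_preset("ganglion", "resting")
sol  <- solve_surface_potentials(inp)
prof <- assemble_profile(inp, sol)
validate_profile(prof, inp)
write_profile_csv(prof, "ganglion_resting.csv")

# charge-ratio sensitivity sweeps
sw <- run_sweep(sweep_spec("rho_fc_ratio"))
write_sweep_csv(sw, "rho_fc_sweep.csv")

# all four validated profiles with the glycocalyx-drop comparison
profs <- run_profiles()
attr(profs, "summary")
```
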