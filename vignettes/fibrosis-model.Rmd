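---
title: "The fibrosim model: kinetics, homogenization, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fibrosim model: kinetics, homogenization, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fibrosim` simulates the progression of idiopathic pulmonary fibrosis (IPF)
as a deterministic reaction--diffusion--chemotaxis system on a 1 cm³ block of
homogenized lung tissue.  This vignette is the package's account of the
science: the model and its assumptions, the parameters that matter, the
calibration of the healthy baseline, the numerical scheme, and the design
choices made where the published description left the design open.

## The cell--cytokine network

Fourteen dynamic species, all in g/cm³, interact through mass-action and
saturating (Michaelis--Menten) kinetics:

* **Cells** — pro-inflammatory M1 and pro-fibrotic M2 macrophages; resting
  (`E0`) and activated (`E`) alveolar epithelial cells (AECs); fibroblasts
  (`f`) and myofibroblasts (`m`).
* **Matrix** — extracellular matrix density `rho`; the diagnostic scar
  density is the clamped excess `S = lambda_S (rho - rho*)₊` over the
  healthy ECM density `rho*`.
* **Mediators** — MCP-1 (`P`), PDGF (`G`), activated TGF-β (`Tb`),
  MMP (`Q`), TIMP (`Qr`), TNF-α (`Ta`), IL-13 (`I13`).

The wiring follows the fibrosis literature: damaged epithelium activates and
undergoes EMT; activated AECs secrete MCP-1, which both recruits M1
macrophages from the blood (a volumetric influx `beta(P)(M0 - M1)` with
`beta(P) = beta·P/(K_P + P)`, the boundary influx folded into a source term)
and attracts them chemotactically; TNF-α repolarizes M2→M1 while IL-13
resists it and `lambda_M1` drives M1→M2; M2 macrophages secrete PDGF,
TGF-β (enhanced by IL-13), MMP, TIMP and IL-13; TGF-β and PDGF convert
fibroblasts to myofibroblasts, and both mesenchymal populations deposit ECM,
with TGF-β enhancement and MMP-mediated degradation; MMP and TIMP deplete
each other by binding.  The fibroblast ECM production carries the logistic
clamp `(1 - rho/rho_0)₊` — the single non-smooth point of the kinetics.
Intracellular signalling, bFGF as a separate species and TH2 cells are
deliberately folded into effective terms.

Three switching terms are gated by the damage indicator `I_D` (1 inside the
damaged region): AEC activation `lambda_E0·E0·I_D`, EMT `lambda_EM·E·I_D`
and the fibrocyte repair term `A_E0·lambda_1·E0·I_D/(K_D + E0·I_D)`.  The
oxidative-stress apoptosis excess `delta` is likewise active only inside the
damage (switchable via the `delta_with_damage` option): at homeostasis the
model explicitly has `I_D = 0` and `delta = 0`, and tying `delta` to `I_D`
is the only reading that makes the healthy state well defined without a
separate disease clock.

Four constants appear in the equations but have no published value.  They
are shipped with provenance tag `"unvalued"` and conservative defaults:
`K_D = 1e-2` g/cm³ (the order of the other cell-density saturations),
`lambda_MTalpha = lambda_MT` (TNF-α consumed at the same rate it drives
repolarization), `lambda_TbetaI13 = 1` (order-unity enhancement) and
`lambda_S = 1` (scar reported in units of ECM excess).  All four are
configuration-exposed.

## Homogenized alveolar geometry

The alveolar microstructure is idealized as a periodic array of unit cells,
each containing a concentric cubic air hole of edge `1 - theta` with
`theta = 1/7` (a 140 µm alveolus with 10 µm walls).  The tissue volume
fraction is

```
gamma = 1 - (1 - theta)^3 = 127/343 ≈ 0.370.
```

Averaging over the microstructure turns each diffusion operator
`D_X ∇²` into `(D_X/gamma) Σ a_ij ∂²/∂x_i∂x_j`, where the dimensionless
tensor `a` comes from the corrector problem on the unit cell: harmonic
`chi_i` in the tissue shell, `(∇chi_i + e_i)·n = 0` on the hole boundary,
periodic across the outer faces, and
`a_ij = ∫ (δ_ij + ∂chi_j/∂y_i) dy`.  Reactions are *not* rescaled: `gamma`
multiplies both the time derivative and the reaction terms, so only
transport feels the geometry.  The chemotactic flux is rescaled by the same
`a_11/gamma` factor as diffusion, since both are flux-divergence transport
terms of the microscopic equations.

`solve_cell_problem()` discretizes the corrector by finite volumes on a
voxelized cell: unit conductance on faces interior to the tissue, closed
faces on the hole (the no-flux condition is then exact, and the axis-aligned
geometry means no staircase error when the resolution is a multiple of 14,
which places the hole faces on voxel boundaries).  The corrector is fixed to
zero mean (a pure gauge choice — the tensor depends only on gradients) and
the tensor is assembled from the discrete energy identity
`a_ij = ∫(e_i + ∇chi_i)·(e_j + ∇chi_j)`, which is symmetric positive
semi-definite by construction.

**A discrepancy, on the record.**  The published value for this geometry is
`a_ii = 0.11`.  The faithful solve converges to `a_ii ≈ 0.274` (0.2699 at
resolution 14, 0.2729 at 28, 0.2742 at 56; Richardson limit ≈ 0.2755), and
the published value is in fact unreachable for the stated problem: the
divergence-free trial current equal to `e_1` on the straight tissue channels
that miss the hole and zero elsewhere is admissible, and the dual
variational principle then forces `a_11 ≥ 1 - (6/7)² = 13/49 ≈ 0.265`.  The
0.11 was evidently carried over from an earlier model with a different
microgeometry.  The package therefore keeps both: `solve_cell_problem()`
reports the faithful converged tensor, while `reference_tensor()` returns
`diag(0.11)` — the value the original disease simulations actually used —
and the packaged disease scenarios default to the latter so their outputs
remain comparable with the published ones.

## The healthy baseline and its calibration

Homeostasis is the spatially uniform steady state with no damage and a
standing residual inflammation: the MCP-1 production term is held at
`1e-10` g/(cm³ day) (equivalently, a background of activated AEC of
`1e-10/lambda_PE = 0.01` g/cm³ maintains baseline monocyte influx).  During
disease the activated-AEC production `lambda_PE·E` adds on top of this
standing source.

The published healthy baseline — `E0 = 0.79`, `f = 4.75e-3`,
`rho = 3.26e-3` g/cm³, `Ta = 2.5e-8`, `Tb = 2.51e-12` g/ml — is not a
steady state of the raw parameter table (for example `A_E0/d_E0 = 0.501`,
not 0.79, and `lambda_Ef = 0.25` overproduces fibroblasts roughly
2000-fold).  Treating the printed baseline as primary,
`calibrate_parameters()` re-solves five constants, each appearing linearly
in exactly one anchored balance, in closed form:

| freed constant | balance | calibrated value |
|---|---|---|
| `lambda_M1` | M2 level implied by the TGF-β anchor | `1.698e-4`/day |
| `lambda_TalphaE` | TNF-α balance | `1.755e-6`/day |
| `A_E0` | resting-AEC balance | `1.304e-2` g/(cm³ day) |
| `lambda_Ef` | fibroblast balance | `1.175e-4`/day |
| `d_rho` | ECM balance | `4.478e-3`/day |

Three calibration choices deserve comment.  First, the TNF-α source
`lambda_TalphaE` is attributed to the *total* epithelium `E + E0` (AECs
secrete TNF-α whether or not injury-activated); with the source restricted
to activated AECs, which vanish at rest, no parameter choice can reach the
printed `Ta` level.  Second, the M1→M2 polarization rate `lambda_M1` — an
estimated parameter — is the only dial that reaches the printed TGF-β level
through the resting M2 population.  Third, `d_rho` is the one freed constant
whose table value carries a citation; no estimated production constant
exists in the ECM balance, and the calibrated turnover (≈ 220 days) is, if
anything, more plausible for interstitial collagen than the tabulated
0.37/day.  The fibroblast proliferation rate `lambda_fE` cannot be
calibrated at rest (its term carries the factor `E/(K_E+E)`, zero at rest)
and the calibration errors out, by design, if it is requested.

`solve_homeostasis()` polishes the anchored state with a damped Newton
iteration (finite-difference Jacobian, residuals scaled by each species'
gross turnover, long-time ODE relaxation as fallback) to a scaled residual
below `1e-12`.  The same root is recovered from starting guesses perturbed
by ±50%.  The rest IL-13 level is an output, not an anchor: the closed-form
ratio `lambda_I13/d_I13 ≈ 1.70e-8` g/ml, consistent with one of the two
(mutually inconsistent) printed values; neither is asserted.

## Disease scenarios

A simulation starts from the calibrated homeostasis everywhere and switches
on a centered damage cube at day 0.  The packaged presets are the baseline
disease (edge 0.3 cm, table value `lambda_E0 = 0.25`/day), the mild
treatment case (0.3 cm, `lambda_E0 = 2.5e-3`) and the severe case (0.5 cm,
`lambda_E0 = 3e-3`) — each section's own printed activation rate is used
for its scenarios, and the two-factor size notations are read as cubes.
Boxes are rasterized by cell-center membership; on the default 20³ grid the
0.3-cm cube covers exactly 6³ = 216 of 8000 cells (volume fraction 0.027).

Drugs enter as multiplicative inhibitions ramped linearly over 20 days from
day 100: anti-TNF-α divides `lambda_MT` by `1+B1`; anti-PDGF divides
`lambda_mfG` by `1+B2`; anti-IL-13 divides `lambda_TbetaI13` by `1+B3`;
anti-TGF-β divides the production rates `lambda_TbetaM`, `lambda_Tbetaf` by
`1+A` and replaces `Tb` by `Tb/(1+B)` in every fibrosis-promoting
saturation factor — the myofibroblast transition, fibroblast proliferation
and ECM enhancement, and (switchable via `tgfb_apoptosis_treated`, on by
default) the TGF-β-driven AEC apoptosis, which promotes disease if not
literally fibrosis.  TGF-β's own degradation is never rescaled.
Combinations apply all components simultaneously.

## Numerics

**Spatial discretization.**  Cell-centered finite differences on the unit
cube, `K` cells per axis, with zero-flux boundaries realized by mirror ghost
cells: the second-difference stencil `K²(u₊ + u₋ - 2u)` then telescopes, so
the discrete diffusion operator conserves mass to rounding, and the operator
is diagonalized *exactly* by the orthonormal DCT-II basis (eigenvalues
`-4K² sin²(π l/2K)` per axis).  Chemotaxis is discretized in conservative
flux form with donor-cell (upwind) face densities by default (a central
option exists for convergence studies); boundary faces carry no flux, so
chemotaxis moves mass without creating it.  ECM, like the two epithelial
populations, has no transport term and evolves pointwise.

**Time stepping.**  Two interchangeable schemes advance the
method-of-lines system:

* `"rk4"` — classical explicit Runge--Kutta on the full right-hand side.
  The step is limited by the stiffest linear decay (TGF-β, 333/day) and the
  diffusion CFL; the default is half the tighter bound (≈ 2.3e-3 day at
  20³).  This is the reference scheme.
* `"etd"` (default) — a two-stage exponential integrator (ETD2RK) in the
  cosine eigenbasis.  Diffusion and each species' constant linear decay are
  integrated exactly (the scheme is steady-state preserving, which is what
  keeps a 300-day no-damage run glued to homeostasis), while the nonlinear
  reaction and chemotaxis terms enter through φ-function weights.  The
  scheme is unconditionally stable in the linear part; accuracy, not
  stability, sets the step.  Measured against `rk4` on a 1-day disease
  fixture the deviation is 1.9e-3 at `dt = 0.02` (the production default),
  falling to 1.0e-4 at `dt = 0.0025` — the observed order is ≈ 1.5, the
  usual stiff order reduction of ETD2RK.

For multi-hundred-day runs the integrator supports two-rate stepping: the
fine `dt` during the onset transient (up to `slow_after = 40` days) and in a
margin around each drug ramp, a coarser `dt_slow` in the slowly evolving
fibrotic phase.  A 120-day treated run at 8³ agrees with single-rate
stepping to 5e-6 relative.

Slight negative undershoots (the price of a non-positivity-preserving
two-stage scheme) are clamped to zero after each stage; they occur at
round-off amplitudes only.  A blow-up guard aborts a run when any domain
average exceeds `1e6 × max(baseline, 1e-3 × typical)` — generous headroom
is required because activated TGF-β legitimately rises four orders of
magnitude above its (tiny) healthy level once activated AECs appear.

**Problem sizes.**  The packaged studies use 20³ cells for the 30-day
baseline disease run, 16³ for the 300-day five-arm treatment comparison
(fine step 0.04 day, slow step 0.2) and 10³/20³/40³ for the grid-convergence
check, with the corrector problem solved at 56 voxels per edge.  These sizes
are the package's own choices; the original publication states neither its
grid nor its step size, which is why the simulation-level comparisons carry
tolerance bands.

## What the tests do and do not show

The property suite verifies conservation identities of the kinetics
(phenotype switching and fibroblast conversion are pure exchanges),
agreement of the rates with an independent literal transcription to 1e-12,
discrete conservation of both transport operators, exact collapse of the
PDE to the homogeneous ODE system under uniform damage, homeostasis
persistence (< 0.1% drift over 30 days), positivity over 300 days, monotone
untreated ECM growth, and grid convergence of the day-30 ECM.  The
comparative treatment outcomes (TNF-α blockade ineffective; TGF-β blockade
strictly beneficial; adding IL-13 blockade strictly improves on TGF-β
blockade alone) reproduce the published qualitative findings.

These are consistency checks of the model and its discretization, not
clinical validation: the model has no patient heterogeneity, no
pharmacokinetics, no mechanics or oxygen physiology, a single idealized
damage geometry, and several rate constants that are order-of-magnitude
estimates or calibration outputs.  Quantities that depend on absolute
cytokine levels far from their saturation constants (TGF-β above all, whose
promoting factors are nearly saturated in disease) should be read as
qualitative.  The day-30 TIMP increase (~12% on the default grid, against a
reported ~20%) and the small relative ECM differences between treatment
arms are grid- and step-size-dependent at the stated tolerances.
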