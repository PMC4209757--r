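---
title: "Models and methods: speciation, refinement and plasma mobilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: speciation, refinement and plasma mobilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqspec)
```

## The equilibrium model

A solution containing a metal ion M, a (poly)protic ligand L and protons H
is described by the set of species $\mathrm{M}_p\mathrm{L}_q\mathrm{H}_r$
with overall formation constants on the concentration scale,

$$\beta_{pqr} = \frac{[\mathrm{M}_p\mathrm{L}_q\mathrm{H}_r]}
                     {[\mathrm{M}]^p[\mathrm{L}]^q[\mathrm{H}]^r},$$

where negative $r$ denotes proton loss relative to the components — amide
deprotonation in a complex, or hydroxide, which the package represents as
the species $(0,0,-1)$ with $\log\beta = -\mathrm{p}K_w$ so that no
separate OH$^-$ bookkeeping ever appears. All constants are conditional at
25 °C and $I = 0.15$ mol dm$^{-3}$ (NaCl); no activity-coefficient
corrections are applied, and pH throughout means $-\log_{10}[\mathrm{H}^+]$
on the concentration scale, the convention appropriate to an electrode
calibrated in situ at fixed ionic strength. The water autoionization
exponent defaults to $\mathrm{p}K_w = 13.73$, the conditional value under
these conditions.

The bundled model files carry the protonation constants and Ni(II)
formation constants of three pentadentate poly(amino)amido /
pyridine-dicarboxamide ligands (L1–L3), including the two competing
speciation models (MLH vs ML) reported for L1 and L2. Stepwise ligand
acidity constants follow from the cumulative constants as
$\mathrm{p}K_{a1} = \log\beta_{011}$ and
$\mathrm{p}K_{ak} = \log\beta_{01k} - \log\beta_{01(k-1)}$
(`compute_pka()`).

## The mass-balance solver

`solve_state()` finds free concentrations satisfying

$$T_M = [\mathrm{M}] + \sum_i p_i C_i,\qquad
  T_L = [\mathrm{L}] + \sum_i q_i C_i,\qquad
  T_H = [\mathrm{H}] + \sum_i r_i C_i,$$

with $C_i = \beta_i[\mathrm{M}]^{p_i}[\mathrm{L}]^{q_i}[\mathrm{H}]^{r_i}$
(the hydroxide species supplies the familiar $-K_w/[\mathrm{H}]$ term, and
$T_H$ may be negative for excess strong base). Numerical choices:

* **Variables** are $\log_{10}$ free concentrations, which keeps every
  trial concentration positive and makes the Jacobian
  $J_{XY} = \ln 10\,(\delta_{XY} c_X + \sum_i \nu_{iX}\nu_{iY} C_i)$
  analytic and cheap.
* **Damping**: full Newton steps are capped at 2 log units and halved (up
  to 20 times) whenever the scaled residual norm fails to decrease.
* **Scaling and convergence**: residuals are scaled by
  $\max(|T_X|, \sum_i |\nu_{iX}| C_i + c_X)$, so near-cancelling proton
  balances (e.g. $T_H = 0$) are still resolved; iteration continues to a
  scaled tolerance of $10^{-12}$ plus two polishing steps, which in
  practice drives raw residuals to rounding level (the test suite checks
  $<10^{-10}\,|T|$, or $10^{-16}$ absolute for zero totals).
* **Initial guess**: free M and L start at $10^{-3}\times$ their totals
  (floored at $10^{-15}$ M); $[\mathrm{H}]$ starts from the sign of $T_H$
  ($T_H$, $K_w/|T_H|$, or $10^{-7}$). Failures restart from a ladder of
  alternative proton guesses before raising a classed error.
* **Zero totals** remove a component exactly rather than approximating it
  with a tiny concentration.

`solve_at_ph()` clamps $[\mathrm{H}]$ and solves the remaining balances,
reporting the implied $T_H$; `speciation_vs_ph()` sweeps a pH grid with
warm starts and expresses species as fractions of total metal (or of total
ligand in metal-free systems), the basis used by conventional distribution
diagrams. Solver correctness is tested against an independent nested
bisection solver (each balance is monotone in its own free concentration)
to six significant figures, and against a dimensional-rescaling symmetry
that the exact equations must satisfy.

## Simulated titrations

`simulate_titration()` emulates a glass-electrode experiment: initial
moles in $v_0$ cm³, NaOH titrant delivered in fixed increments,
dilution-corrected totals $T_X(v) = n_X(v)/(v_0+v)$, an equilibrium solve
per point, and $E = E^\circ - s\,\mathrm{pH}$. Defaults, chosen once to
represent routine potentiometry with modern instrumentation:
$v_0 = 25$ cm³, 0.1 M titrant, 0.05 cm³ steps giving roughly
80–120 points per curve, $E^\circ = 400$ mV, Nernstian slope
$s = 59.16$ mV/pH at 25 °C, and noise $\sigma_E = 0.1$ mV,
$\sigma_v = 0.005$ cm³ — typical electrode and piston-burette precision.
`generate_study_dataset()` assembles full study designs: total metal
$5\times10^{-4}$ mol dm$^{-3}$, metal:ligand ratios 1:1, 1:2, 1:3, enough
initial strong acid ($10^{-2}$ M + 3 $T_L$) that curves genuinely span
pH 2–11.

The noise model treats a volume error as a *delivery* error: the burette
delivers $v+\varepsilon$ while $v$ is recorded, so the simulated emf is
re-computed at the true delivered volume while recorded volumes and the
totals derived from them stay nominal. This reproduces the
heteroscedasticity of real titrations — a 0.005 cm³ error near an
equivalence jump is worth tens of mV, the same error in a buffer region
almost nothing — which matters for weighting (below). What the generator
does **not** emulate: junction-potential drift, electrode hysteresis,
CO$_2$ ingress during a run, or temperature fluctuations; passing tests
therefore validate the computational chain, not the behaviour of any
particular electrode.

`calibrate_electrode()` recovers $E^\circ$ and $s$ from the strong-acid
branch, and `gran_check()` implements the Gran linearization
$G(v) = (v_0+v)\,10^{-\mathrm{pH}}$ whose acid- and base-side endpoints
disagree when the titrant is contaminated with carbonate (the classical
quality check; a >1 % disagreement raises the flag, and the simulator can
inject a chosen carbonate fraction).

## Experimental-data functions

With measured pH and known totals, the proton excess bound to ligand is
$B = T_H - [\mathrm{H}] + K_w/[\mathrm{H}]$. Assuming complexes carry no
net protons, $B$ lives entirely on the free-ligand protonation ladder, so

$$[\mathrm{L}] = \frac{B}{\sum_r r\,\beta_{01r}[\mathrm{H}]^r},\qquad
  \bar Z_M = \frac{T_L - [\mathrm{L}]\sum_r \beta_{01r}[\mathrm{H}]^r}{T_M},
  \qquad
  \bar Q_M = \frac{\bar n(\mathrm{pH})\,T_L - B}{T_M},$$

the classical Irving–Rossotti formation and deprotonation functions in
the operational forms adopted here. The literature contains variant
conventions for how the protons of complexed ligand are counted, so the
absolute level a $\bar Q$ curve reaches is convention-dependent and should
be read qualitatively; the shapes and onsets are not. Points where the inversion yields $[\mathrm{L}]\le 0$ —
the strong-complexation regime where the no-net-protons assumption fails —
are masked rather than made errors, mirroring how practitioners read these
curves. `diagnose()` raises the three advisory flags used in model
building: inter-ratio curve splitting (protonated/polynuclear species),
plateau deviation from 1 (mononuclear ML is not alone), and fan-back of
the pL trajectory at high pH (hydroxo or metal-assisted-deprotonated
species).

## Refinement

`refine_constants()` adjusts flagged $\log\beta$ values by
Levenberg–Marquardt least squares on the electrode's native observable
(emf in mV by default; pH by flag). The parameter Jacobian is analytic via
implicit differentiation of the mass balances — at a solved point
$\partial x/\partial\theta_j = -J_x^{-1}\,\partial F/\partial\theta_j$ —
so a refinement costs one equilibrium sweep per iteration instead of one
per parameter. Standard deviations use the crystallographic convention
$\sigma^2 = \mathrm{diag}[(J^TJ)^{-1}]\,\chi^2_\nu$; a singular normal
matrix degrades gracefully (pseudo-inverse, infinite $\sigma$ on the
undetermined directions). Fit quality is summarised by the Hamilton
R-factor $R_H = \sqrt{\sum w(o-c)^2 / \sum w\,o^2}$ and its limit $R_{lim}$,
computed by substituting the first-order propagated experimental
uncertainty $\delta_i = \sqrt{\sigma_E^2 + (dE/dv)_i^2\sigma_v^2}$ for the
residuals.

Two weighting schemes are provided. Unit weights are the default (simple,
reproducible). For noisy data the error-propagated weights
$w_i = 1/\delta_i^2$ are the appropriate choice, because the volume-error
contribution makes $\delta_i$ span more than two orders of magnitude along
one curve. Two numerical details keep these weights calibrated: the local
slope $dE/dv$ is taken as the envelope of the one-sided differences (a
central stencil smooths across an equivalence jump and understates the
variance exactly where it dominates), and within `refine_constants()` it
is evaluated on the *model-calculated* curve at the starting values rather
than on the noisy data, since data-derived slopes correlate with the
measurement errors themselves and bias the fit. With these choices,
Monte-Carlo experiments in the test suite show calibrated uncertainties
(≥90 % coverage of $\pm2\sigma$) and mean biases below 0.02 log units at
the default noise. Note a convention effect: the
*weighted* $R_H$ of a propagated-weight fit is small by construction
(residuals are normalised), so comparisons with conventional experimental
R-factors should use unit weights in the $R_H$ formula.

The recommended workflow mirrors practice: refine protonation constants
from metal-free curves first, then hold them fixed while refining the
metal block (the bundled Ni model files encode exactly this via their
`refine` flags). Species whose refined constant implies less than 2 %
maximal abundance anywhere in the data are flagged "not supported by
data"; `compare_models()` tabulates R-factors and flags (a parameter
$\sigma > 0.2$ log units is called out) without declaring a winner, since
model choice also rests on chemical evidence such as low-pH curve
splitting.

## The plasma model

The blood-plasma stage follows the convention of large plasma-speciation
programs: free metal-ion concentrations are *fixed inputs* (protein pools
buffer the free ion), pH is fixed at 7.4, and only the low-molecular-mass
(lmm) ligand mass balances are solved — each one an independent monotone
equation because every complex involves a single ligand type. The plasma
mobilizing index of a drug ligand for metal M is

$$\mathrm{pmi}(M, c) = \frac{\text{total lmm complexed M at drug total } c}
                          {\text{total lmm complexed M in normal plasma}},$$

counting the drug's own complexes in the numerator. By construction
$\mathrm{pmi}(\cdot,0)=1$, and in this reduced model
$\mathrm{pmi}\ge 1$ always (free metal cannot be depleted); the full
competitive depletion effects of a complete plasma database are out of
scope. The bundled fixture is **synthetic** — about a dozen endogenous
ligands with order-of-magnitude plausible constants, free-metal ratios
Ca:Ni $=10^{15}$ and Zn:Ni $=10^{9}$, and synthetic Cu/Zn/Ca drug
constants ordered by the usual stability series with facile Cu amide
deprotonation. All plasma claims are therefore *qualitative orderings*;
absolute pmi values depend on the (unavailable) database and are not
reproduced. The default drug grid spans $10^{-6}$–$10^{-2.5}$ mol
dm$^{-3}$, bracketing the low-millimolar doses of interest.

One definitional point deserves note. `selectivity()` implements the pmi
ratio $\mathrm{pmi}(M_1,c)/\mathrm{pmi}(M_2,c)$. Under this definition a
drug that mobilizes in the order Cu > Ca > Zn > Ni necessarily has
Cu/Ca < Cu/Zn < Cu/Ni — a ratio ordering that *reverses* the
stability-series ordering (Cu/Ca largest) often quoted for selectivity
factors, which is a statement about complex stabilities rather than about
pmi ratios. Both quantities are computable here; they should not be
conflated.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
generated in code: three curves of ~80–90 points per metal system, one
metal-free curve per ligand, 20 Monte-Carlo replicates for the noisy
recovery experiment, and a 15-point drug grid for the plasma stage —
sizes chosen to represent a realistic study design faithfully while keeping a
full run to a few minutes on one core. Every stochastic step takes an
explicit seed, output files embed the package version, seed and input
hashes, and zero-noise round trips (simulate → refine) are the identity
to $10^{-6}$ log units from starts perturbed by ±0.5.

## Known limitations

* Mixed-metal (ternary) complexes and polynuclear species beyond what a
  user declares are not modelled; no automatic species search is
  performed.
* The Z/Q functions assume the complexes carry no net protons when
  inverting the proton balance; in strongly complexing regimes they are
  masked rather than corrected.
* The plasma model's fixed-free-metal reduction cannot show pmi < 1 or
  inter-metal displacement; only a full database model can.
* pH is concentration-scale throughout; comparing with activity-scale
  constants requires the user's own conversion.
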