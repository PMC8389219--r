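---
title: "Models and numerical methods in antioxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in antioxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antioxkin)
```

antioxkin is a downstream-analysis package for the computational chemistry of
phenolic antioxidants. It consumes *digest tables* — stationary-point Gibbs
free energies, two-state energy scans, pKa values, reaction free energies and
docking energy decompositions — and turns them into rate constants, crossing
point classifications, speciation profiles and inhibition constants. No
electronic-structure computation happens here; everything downstream of the
quantum-chemistry engine is reproducible from small text tables.

## Transition-state-theory kinetics

The central expression is the Eyring equation

$$k = \sigma \kappa \frac{k_B T}{h} e^{-\Delta G^{\ddagger}/RT},$$

with reaction-path degeneracy $\sigma$ (default 1: the tables this package
mirrors never state a degeneracy, and any path-specific value can be set per
pathway), tunneling coefficient $\kappa$, and the activation free energy
$\Delta G^{\ddagger}$ in kcal/mol. `eyring_rate()` evaluates the expression
verbatim; `pathway_rate()` assembles it from stationary-point records.

Two conventions matter and are explicit options:

* **Barrier reference.** $\Delta G^{\ddagger}$ is measured from the separated
  reactants by default, which is how branching tables for radical reactions
  are usually printed. A `reference = "reactant_complex"` mode measures from
  the pre-barrier complex instead. The Eckart heights always use the
  flanking complexes regardless of the rate reference.
* **Bimolecular standard state.** A bimolecular $\Delta G^{\ddagger}$ is
  assumed to be expressed at the 1 M standard state already; the equation is
  applied verbatim and the molecularity only sets the unit label
  (s⁻¹ vs. M⁻¹s⁻¹). Nothing in the printed tables this package was validated
  against indicates an extra standard-state conversion, so none is applied.

### Eckart tunneling

$\kappa$ is the thermal average of the transmission probability through an
asymmetric Eckart barrier,

$$\kappa = \frac{e^{V_1/RT}}{RT}\int_{E_0}^{\infty} p(E)\, e^{-E/RT}\, dE,
\qquad E_0 = \max(0, V_1 - V_2),$$

parameterized by the forward and reverse barrier heights $V_1 = G(TS)-G(RC)$,
$V_2 = G(TS)-G(PC)$ and the saddle-point imaginary frequency $\nu$. The
transmission probability is the standard closed form with
$\alpha_i = 2\pi V_i/h\nu$; `eckart_transmission()` evaluates it in log space
(via $\log\cosh$/$\log\sinh$ identities), so arbitrarily thick barriers and
deep-tunneling energies do not overflow. The thermal average is computed by
adaptive quadrature on the shifted variable $(E-V_1)/RT$, split at the
barrier top (below-threshold tunneling and above-barrier reflection have very
different scales), with relative tolerance 1e-8. $\kappa < 1$ is permitted
and not clipped: low, thin barriers are reflection-dominated.

When only Gibbs energies are available — the common case for published digest
tables — the Gibbs barriers serve as proxies for the ZPE-corrected heights
the transmission formula formally wants. The resulting $\kappa$ is therefore
approximate; for a hydride-transfer-like barrier (e.g. $V_1 \approx 73$,
$\nu \approx 1550\,\mathrm{cm^{-1}}$) it agrees with reported values to
within a few percent, but order-of-magnitude agreement is all that should be
expected in general. `wigner_kappa()` ($1 + u^2/24$) is kept as an
independent high-temperature cross-check; the test suite also checks the
adaptive quadrature against a million-node trapezoid rule.

### Branching and series reports

`overall_rate()` sums corrected rate constants of parallel pathways (same
temperature and molecularity enforced) and reports branching fractions;
`water_series_report()` orders a proton-relay series by the number of
bridging water molecules and flags strictly decreasing barriers, the
signature of hydrogen-bond-lattice catalysis. Bimolecular rates are
classified against the aqueous diffusion-limited window
$[10^7, 10^{10}]\ \mathrm{M^{-1}s^{-1}}$ with inclusive bounds.

## Spin crossings and MECP refinement

Radical–radical recombination between two open-shell fragments can proceed on
two spin surfaces. When the crossing between them is met *before* the
adiabatic transition state and lies below it, the minimum-energy crossing
point (MECP) takes over the role of the kinetic bottleneck; a crossing met
after the barrier is kinetically irrelevant. The package separates three
concerns:

1. **Scan-based prediction** (`find_profile_crossings()`): every sign change
   of the sampled gap $E_\mathrm{low}(r) - E_\mathrm{high}(r)$ yields one
   crossing, placed by linear interpolation between the bracketing nodes.
   Linear interpolation (not a spline) matches the pointwise
   single-point-energy scan procedure that produces such profiles; smoothing
   is deliberately left to the refinement stage.
2. **Classification** (`classify_crossing()`): before-TS-and-below-TS gives
   `rate_determining`, after-TS gives `post_barrier`; a profile without a TS
   annotation gives `indeterminate`. The reaction direction is the storage
   order of the scan, so mirroring the coordinate axis (together with the TS
   coordinate) does not change the answer.
3. **Refinement** (`mecp_optimize()`): minimizes the mean energy on the seam
   $E_A = E_B$ with the effective-gradient construction — difference-gradient
   direction $x = (g_A - g_B)/|g_A - g_B|$, seam-restoring force
   $(E_A - E_B)\,x$, and the mean gradient projected orthogonal to $x$ —
   using numerical central-difference gradients
   (step $10^{-5}\max(1, |x_i|)$).

The descent phase is steepest descent with a safeguarded Barzilai–Borwein
step and backtracking line search. On ill-conditioned surface pairs
(near-parallel curvatures pushing the seam minimum far from the starting
region) plain descent can stall short of the tolerances, so when the line
search stalls unconverged the optimizer switches to a Levenberg–Marquardt
polish on the residual vector [energy gap; effective gradient], which
vanishes exactly at the MECP. Convergence requires both
$|E_A - E_B| < 10^{-6}$ kcal/mol and a projected-gradient norm below
$10^{-5}$, within 500 total iterations; exceeding the cap returns the best
iterate flagged unconverged rather than an error. Two surfaces with
(numerically) identical gradients have no isolated seam and are rejected as
degenerate. No spin–orbit coupling or transition probability is computed:
the MECP is treated purely geometrically, as a transition-state surrogate.

`predict_then_refine()` chains the stages, seeding the optimizer at the
*lowest-energy* profile crossing (when a lower-energy path exists through an
intersection, that is the one the reaction takes), lifted into surface space
by a user-supplied embedding.

## Speciation

For a polyprotic acid with stepwise constants $pK_{a,1} < \dots < pK_{a,n}$,
the fraction of the $j$-times-deprotonated state at a given pH is

$$f_j = \frac{10^{\,j\,\mathrm{pH} - \sum_{i\le j} pK_{a,i}}}
{\sum_k 10^{\,k\,\mathrm{pH} - \sum_{i\le k} pK_{a,i}}}.$$

The sums are accumulated in log10 space with max-shift normalization, so a
pKa spread of 20+ units or pH far outside the physiological range cannot
overflow. Activity corrections are deliberately ignored (ideal
Henderson–Hasselbalch arithmetic, which is what published molar fractions
are computed with); report display rounds to 4 decimals. Ties in
`dominant_species()` resolve to the less-deprotonated state.

## Reaction energetics

`reaction_delta_g()` composes $\Delta_r G$ from component free energies that
must share one declared standard-state tag — the subtraction only makes
sense between absolute free energies on a common footing. Published
complexation tables often print only the reaction values; the
`delta_g_override` field carries those directly, and the water-displacement
bookkeeping (one released water per bound donor pair) is encoded in the
reaction specification, never inferred. `chelation_ranking()` sorts by
exergonicity (ties broken by label), groups by metal:ligand ratio and emits
uniform-dominance flags between ratio groups. The isoergonic dead band is
0.1 kcal/mol.

## Binding energetics

Docking post-processing only: `compose_binding()` recomposes
$\Delta G_\mathrm{bind} = \Delta G_\mathrm{inter} + \Delta G_\mathrm{total} +
\Delta G_\mathrm{tor} - \Delta G_\mathrm{unb}$, and `ki_from_binding()`
derives $K_i = e^{\Delta G_\mathrm{bind}/RT}$ on the 1 M reference state,
reported in µM. Docking programs do not always state the temperature behind
their printed constants; 298.15 K reproduces reference constants to within
1% and is the documented default. Consistency checks in `binding_report()`
use 0.02 kcal/mol (printed rounding) for energies and 1% for constants.

## Synthetic data and what passing tests show

Each pipeline stage has a generator with embedded ground truth:

* `gen_two_state_profile()` — Gaussian high-spin barrier, steep logistic
  low-spin curve pinned to cross it exactly once, before or after the TS on
  request. The crossing offset is kept at or beyond
  $w\sqrt{2\ln 2}$ of the TS, which bounds the crossing energy at half the
  barrier and guarantees a single sign change.
* `gen_quadratic_surface_pair()` — axis-aligned positive-definite quadratics
  (coefficients in $[0.5, 3]$, centres in $[-3, 3]$), offsets adjusted so the
  seam is non-empty; the exact seam minimum is solved from the Lagrange
  stationarity condition with a guarded 1-D root search in the multiplier,
  independent of the iterative optimizer.
* `gen_pathway_thermo()` — stationary-point records realizing requested
  barrier/reaction energies, with the rate constant evaluated analytically.
* `gen_polyprotic()` — ascending random pKa sets with fractions evaluated by
  the direct (non-normalized) closed form.

Generators are pure functions of their seed; optional Gaussian noise is off
by default, and truth always refers to the noiseless construction. These
surrogates are smooth, low-dimensional and noiseless-by-default: passing
tests demonstrate the correctness of the numerics (quadrature, root finding,
optimization, classification logic), not robustness to real scan artifacts
such as wavefunction-switching discontinuities, multi-reference regions, or
DFT error distributions, which the generators make no attempt to mimic.

## Problem sizes and tolerances used in the shipped checks

The test suite exercises: 20 random Eckart barriers against a $10^6$-node
trapezoid oracle (1e-5 relative), 50 randomized quadratic pairs for the MECP
optimizer (1e-4 recovery, with a brute-force grid seam search spot check),
20 seeds per crossing topology, 25 random acids against a numerical
equilibrium solver (1e-10), and exact (1e-12) checks for Hess-law linearity,
branching normalization and the $\kappa \times k$ product identity. These
sizes keep the whole suite under a minute on one core while giving each
stochastic property enough draws to be meaningful.

## Known limitations

* Tunneling coefficients computed from Gibbs-barrier proxies are approximate
  by construction; exact reproduction of published coefficients requires the
  ZPE-corrected heights the publications do not print.
* No variational TST, small/large-curvature tunneling, or diffusional
  (Collins–Kimball) correction.
* The MECP machinery works on user-supplied surface functions or scans; it
  has no notion of molecular geometry, Hessians, or an MECP "imaginary
  frequency" (where a digest table reports one, it is carried as input).
* Charge/element balance of reaction specifications is the caller's
  responsibility; only coefficient bookkeeping is validated.
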