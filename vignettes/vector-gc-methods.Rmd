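---
title: "Predicting PCP-SAFT parameters of dipolar molecules by vector group contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PCP-SAFT parameters of dipolar molecules by vector group contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The PCP-SAFT equation of state describes a nonassociating dipolar fluid
with four pure-component parameters: the segment number $m$, the segment
diameter $\sigma$ (Å), the dispersion energy $\varepsilon/k$ (K), and a
dipole parameter $\mu$ (Debye). Group-contribution (GC) methods predict
these parameters for unmeasured molecules by decomposing the molecular
graph into predefined groups with regressed, transferable contributions.
For $m$, $\sigma$, $\varepsilon$ the homosegmented sum rules work well:

$$m_i = \sum_\alpha n_{\alpha i}\, m_\alpha,\qquad
  m_i \sigma_i^3 = \sum_\alpha n_{\alpha i}\, m_\alpha \sigma_\alpha^3,\qquad
  m_i \varepsilon_i = \sum_\alpha n_{\alpha i}\, m_\alpha \varepsilon_\alpha,$$

with $n_{\alpha i}$ the occurrence count of group $\alpha$ in molecule
$i$. The dipole moment, however, is *not* additive: it is a vector
quantity, and symmetric arrangements of polar bonds cancel. A scalar GC
scheme must either ignore the dipole term or restrict itself to
molecules with a single polar group.

This package implements a vector sum rule instead. Each polar bond type
$\beta$ carries a transferable scalar contribution $\mu_\beta \ge 0$;
for a specific molecule, every occurrence of that bond contributes
$\mu_\beta \hat e_\beta$, where $\hat e_\beta$ is the bond's unit vector
in an embedded 3D conformer, pointing from the atom of higher Pauling
electronegativity to the lower. The molecular dipole parameter is the
magnitude of the vector sum:

$$\mu_i = \Bigl\lVert \sum_\beta \mu_\beta\, \hat e_{\beta} \Bigr\rVert .$$

Antiparallel bonds of the same type cancel exactly, so centrosymmetric
molecules come out nonpolar, and cis/trans isomers — identical in every
group count — receive different dipole parameters. That is the method's
point: it extends GC prediction to polyfunctional dipolar molecules and
resolves stereoisomerism, which scalar schemes cannot.

## Groups, bonds, and fragmentation

The shipped definition set (JSON in `inst/extdata/group_defs.json`, see
`vgc_group_defs()`) contains 16 first-order groups — seven carbon groups
(CH3, CH2, >CH, >C<, =CH2, =CH, =C<) whose contributions are adopted
from the established hydrocarbon calibration and stay frozen in all
regressions, five oxygen groups (aldehyde, ketone, ether, formate,
ester), and the four halogen atoms — plus nine second-order groups that
describe halogenated-carbon contexts (`CH2(X)`, `>CH(X)`, `CH(X2)`,
`>C<(X)`, `>C<(X2)`, `C(X3)`, `=CH(X)`, `=C<(X)`, `=C<(X2)`). Eight
bond types are defined; C–H and the sp²-/sp³-carbon bond are pinned to
zero dipole so hydrocarbons remain exactly nonpolar and consistent with
the adopted carbon table.

First-order groups must partition the heavy atoms. Overlaps are resolved
by explicit priorities (formate > ester > aldehyde > ketone > ether >
halogen atoms > carbon groups), which makes the partition deterministic;
multi-atom oxygen groups claim their atoms before the generic patterns
can. Second-order groups are additive corrections and claim nothing.
Matching runs on a purpose-built SMARTS-subset matcher over the
hydrogen-explicit molecular graph (element, connection-count `X` and
H-count primitives, element alternation, bond orders, branches): atom
maps are required for the partition and for locating bond vectors, and
no installed matcher exposes them.

Scope is enforced at parse time: single connected acyclic uncharged
molecules over C/H/O/F/Cl/Br/I, no hydroxyl groups (association is out
of scope). A double bond whose two ends each carry two distinct
substituents is geometrically ambiguous; such SMILES are rejected unless
E/Z-annotated, because silently picking an isomer would defeat the
method's selling point. Molecules outside the 3–8 carbon range used by
the regression datasets are predicted with a warning — the range is a
dataset filter, not a validity bound.

## Conformer embedding

Unit vectors need coordinates. `embed_conformer()` builds one conformer
per molecule deterministically from internal coordinates: reference bond
lengths, hybridization-ideal angles, anti/staggered torsions with the
largest heavy subtree taking the anti slot (so all-anti backbones stay
planar, and centrosymmetric conformers — e.g. the trans diester of
but-2-enedioic acid — actually cancel), double-bond torsions pinned to
the recorded cis/trans configuration, and one small seeded torsion
jitter per rotatable bond (sd 5°, capped at ±15°). The geometry is then
relaxed with the MMFF94 force field through OpenBabel's
conjugate-gradient minimizer, and validated (bonded distances 0.7–2.5 Å,
stereochemistry preserved; bounded retries with incremented seeds).

Two properties drive this design. First, reproducibility: the same
(molecule, seed) pair gives bitwise-identical coordinates on one
platform — stochastic embedders whose random state cannot be fixed from
the outside would break every downstream regression test. Second,
locality: different seeds probe the local conformational basin rather
than hopping between rotamers, so predicted dipoles are stable to about
±0.15 D across seeds. An optional mode (`n_candidates > 1`) samples
seeded rotamer states per rotatable bond and keeps the lowest-energy
refined candidate; it is off by default because MMFF94 energy
differences between neighbouring rotamer basins are small enough that
the winner is not stable across candidate sets, which would reintroduce
seed sensitivity.

The embedding is rule-based rather than distance-geometry based. For
acyclic molecules of this size the two approaches give equivalent local
geometry after force-field refinement, and the rule-based construction
is what makes determinism and symmetry preservation possible here.

## The regression framework

Calibrating a table means fitting the free group contributions
($m_\alpha$, $\sigma_\alpha$, $\varepsilon_\alpha$ per group) and bond
dipoles $\mu_\beta$ simultaneously to vapor-pressure and liquid-density
data. The objective is a weighted least-squares sum of logarithmic
deviations over substances $i$ and properties
$\xi \in \{p^{sat}, \rho^{liq,sat}, \rho^{liq}\}$:

$$L = \frac{1}{N_{tot}} \sum_i \sum_\xi
      \frac{\omega_\xi}{\sqrt{N_i^\xi}}
      \sum_j \bigl(\ln x^{pred}_{i,j} - \ln x^{exp}_{i,j}\bigr)^2,$$

with $\omega_{p^{sat}} = 3$ and $\omega_{\rho} = 2$ (the stated
vapor-pressure/saturated-density weighting; the compressed-liquid
density, added because saturated data is not available for every
substance, reuses the density weight). Each substance/property block's
total weight grows with $\sqrt{N_i^\xi}$, damping the dominance of
heavily measured substances. Saturation queries above a parameter set's
predicted critical temperature have no solution; such points are
skipped and logged, all $N$ count evaluable points only, and when two
method variants are compared their medians are recomputed over the
points both can evaluate (the lower predicted critical temperature sets
the shared cutoff).

Numerical choices that matter:

* **Coordinates.** Each free group is optimized in its additive
  coordinates $(m_\alpha,\; m_\alpha\sigma_\alpha^3,\;
  m_\alpha\varepsilon_\alpha)$ — exactly the quantities the sum rules
  add. This keeps the group part of the model linear in the parameters
  and removes the saddle at $m_\alpha = 0$ that the
  $(m, \sigma, \varepsilon)$ coordinates have for second-order
  corrections (where $\partial (m\sigma^3)/\partial\sigma = 0$).
  Bounds translate exactly: first-order groups and all bond dipoles are
  bounded below by zero; second-order corrections may go negative.
* **Optimizer.** Bound-constrained Levenberg–Marquardt on the weighted
  log-residual vector (`minpack.lm::nls.lm`, finite-difference
  Jacobian). The problem is a classical sloppy least-squares landscape;
  quasi-Newton descent on the scalar objective stalls in its shallow
  curved valleys, while LM reaches machine-precision recovery of
  noise-free synthetic data in seconds. For larger parameter sets the
  landscape is also multimodal — there are basins in which a bond
  dipole collapses to zero and the co-occurring group's dispersion
  energy absorbs its effect — so fits support seeded multi-start
  (`n_starts`): jittered copies of the initial values, best final
  deviance wins.
* **Initial values.** New first-order groups start from the methylene
  row, second-order corrections from zero, bond dipoles from 1 D
  (`vgc_default_initial_table()`); all overridable.

Validation uses substance-level leave-one-out cross-validation:
cis/trans partners share an `isomer_pair_id` and leave jointly, the free
contributions are refitted from the configured initial values on the
remainder, and the held-out substances are predicted with the refitted
table. Errors are reported as the mean absolute percentage deviation
per substance and property, aggregated by the median; a held-out
substance whose groups or bonds do not occur in the training remainder
is reported as unpredictable rather than dropped. The benchmark that
previous GC methods correspond to — no dipole term at all — is one
switch away (`mu_zero_variant()`), which freezes every bond
contribution at zero inside the same pipeline.

## The synthetic bench

The original calibration data (curated vapor pressures and liquid
densities for 158 oxygenated and 95 halogenated substances) is bound to
licensed databases and cannot ship. The package therefore carries a
self-contained simulation bench:

* **Fixtures** (`vgc_fixture_molecules()`): 45 molecules with 3–8
  carbons — ethers, esters, formates, ketones, aldehydes, and
  chloro-/fluoro-/bromo-/iodo-alkanes and -alkenes, including three
  cis/trans pairs. The set was designed for identifiability: every free
  group and bond occurs in at least two isomer-pair-disjoint fixtures,
  and each halogen occurs in a polysubstituted molecule. The latter is
  essential: a molecule with a *single* polar bond has a geometry
  factor of exactly one, making $\mu_\beta$ indistinguishable from an
  offset in the co-occurring group's $\varepsilon_\alpha$; two bonds of
  the same type at varying mutual angles break that confound.
* **Truth table** (`vgc_table_synthetic()`): the adopted carbon rows
  plus *synthetic* contributions for everything the original work
  regressed — bond dipoles taken from classical bond-dipole-moment
  magnitudes scaled to effective equation-of-state size, and plausible
  segment parameters for the oxygen/halogen groups. It is the ground
  truth of the simulation studies, not a reproduction of the published
  calibration.
* **Surrogate evaluator** (`surrogate_evaluator()`): an analytic
  property model with the qualitative structure of an equation of
  state — Clausius–Clapeyron vapor pressure
  $\ln p^{sat} = c_1 - c_2\, m^{0.35} \varepsilon_{eff}/T$ with
  $\varepsilon_{eff} = (\varepsilon/k)\,
  (1 + c_5\, \mu^2/(m\sigma^3))$ (a dipolar perturbation scaling with
  $\mu^2$ over molecular volume), a liquid density declining toward a
  pseudo-critical point at $T_c^{*} = c_2 \varepsilon_{eff}/10$, and a
  small linear pressure term for the compressed liquid. It is smooth,
  monotone, sensitive to all four parameters, and exposes the
  no-solution code path. A real PCP-SAFT backend plugs into the same
  evaluator contract (`pcp_saft_evaluator()`), which raises a typed
  configuration error when no backend is registered; the Helmholtz
  model itself is deliberately outside this package.
* **Noise** (`vgc_noise_model()`): multiplicative log-normal, 2 % for
  vapor pressures and 0.5 % for densities — typical reproducibility of
  curated data for these properties.
* **Grids**: eight temperatures per substance and property spanning
  0.55–0.80 of the predicted critical temperature. The cap stays
  clearly below the exclusion threshold because data points that drift
  across the predicted critical point *during* optimization put
  discontinuities into the objective.

Because the bench shares none of the licensed data, passing its tests
demonstrates that the machinery is correct — fragmentation, sum rules,
objective, fitting, cross-validation — and that the model family is
recoverable under realistic noise. It does not demonstrate the
published predictive accuracy on experimental data, which depends on
the real datasets and the originally regressed contributions.

## An identifiability result worth knowing

The nine second-order groups cover *every* halogenated-carbon context,
which has a structural consequence: for any in-scope halogenated
molecule, the total halogen count equals a fixed weighted sum of the
second-order counts (each halogen atom sits on exactly one context).
The group-count design matrix of the halogenated class is therefore
rank-deficient by one, and group contributions of that class are
identifiable only up to a one-dimensional gauge direction in each
additive quantity. Nothing observable depends on the gauge: bond
dipoles, and the molecular $(m, \sigma, \varepsilon, \mu)$ of every
substance — in or out of sample — are fully identified, and the
package's recovery tests check exactly that (plus the gauge-projected
group values). Reported group contributions for halogenated classes
should be read accordingly: they are one representative of an
equivalence class, as they are in any GC scheme whose correction groups
tile all contexts.

## Problem sizes and limitations

The shipped simulation studies use the 18-substance oxygenated bench
(432 points) for full-recovery and cross-validation runs and the
27-substance halogenated bench (648 points) for the large joint fit;
these sizes keep a complete run in minutes on a single core while
leaving every parameter identifiable.

Known limitations: single conformer per molecule (no Boltzmann
averaging over rotamers — predicted dipoles of flexible molecules are
conformer-specific to within the seed spread); tetrahedral (R/S)
stereocenters are accepted but not canonicalized (enantiomers share all
predictions; diastereomer geometry follows the embedding); no rings,
aromatics, association or quadrupoles, as scoped; and the surrogate is
a test double — scientific property predictions require a real
PCP-SAFT backend behind the evaluator contract.
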