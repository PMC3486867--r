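---
title: "Linking microscopic pKa values to an apparent pKa through a four-state cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking microscopic pKa values to an apparent pKa through a four-state cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phlinkage)
```

## The problem

Nitrophorin 4 (NP4) is a salivary heme protein of a blood-feeding insect
that binds nitric oxide tightly at the acidic pH of the salivary gland and
releases it at the neutral pH of the host's tissue. The release is driven
by a conformational change of two surface loops from a *closed* to an
*open* arrangement, and the trigger is the deprotonation of a single
buried aspartate (Asp30). Because the residue's environment differs
radically between the conformations — buried and hydrogen-bonded when
closed, solvent-exposed when open — its acid constant is
conformation-dependent: a *microscopic* pKa of 8.5 in the closed state and
4.3 in the open state. Neither value matches the single midpoint near 6.5
that a titration experiment reports. This package implements the
four-state thermodynamic linkage analysis that reconciles them: the
*apparent* pKa is the pH of the closed-to-open population transition, a
property of the coupled system rather than of either structure.

## The four-state model

The species are CH (closed, protonated), C⁻ (closed, deprotonated), OpH
(open, protonated) and Op⁻ (open, deprotonated), connected by two acid
dissociations (governed by `pk_closed` and `pk_open`) and two
conformational equilibria, `K_H = (OpH)/(CH)` and `K_D = (Op⁻)/(C⁻)`.
Activities are identified with concentrations and all constants are
dimensionless on the 1 M reference, so pH enters only as
`u = 10^(pH - pk_closed)`. Going around the cycle must conserve free
energy, which removes one degree of freedom:

    K_H = K_D * 10^(pk_open - pk_closed)

so the model has exactly three free parameters (`pk_closed`, `pk_open`,
`K_D`); `thermo_cycle()` derives `K_H` and never accepts it
independently. With the reference values (8.5, 4.3, `K_D` = 100) this
gives `K_H` = 6.31e-3: opening while protonated is strongly unfavourable,
opening once deprotonated strongly favourable — precisely the coupling
that makes the switch work.

Relative to CH, the equilibrium weights of the species are `1`, `u`,
`K_H` and `K_D u`, and `populations()` normalises them to mole fractions.
The weights are assembled in log space and rescaled by the largest
exponent before exponentiation, so populations remain exact at
arbitrarily extreme pH instead of overflowing — the asymptotic limits
(only CH:OpH in ratio `1:K_H` at acid pH, only C⁻:Op⁻ in ratio `1:K_D`
at basic pH) are part of the tested surface.

An ensemble observable that depends only on conformation takes the value
`alpha` in the closed and `beta` in the open state (`signal_model()`;
defaults 0.03 and 0.55, the plateaus of the NO dissociation constant
versus pH). The measured signal is the population-weighted mixture

    S(pH) = alpha * x_closed(pH) + beta * x_open(pH),

a sigmoid whose inflection defines the apparent pKa. Because the open
fraction is an exact logistic in pH, the inflection has the closed form

    pKa_app = pk_closed + log10((1 + K_H) / (1 + K_D)),

which is bounded by the two microscopic values whenever `K_H <= 1 <= K_D`
and collapses to the single microscopic pKa in the symmetric limit
`K_H = K_D`. We did not adopt this expression on faith: the package also
ships `apparent_pka_numeric()`, an independent numeric oracle that
brackets the root of the second derivative of `S(pH)` by bisection to
1e-6, and the test suite requires agreement within 1e-3 across 100
randomized cycles before anything else relies on the closed form.

```{r headline}
cyc <- thermo_cycle(8.5, 4.3, kd = 100)
cyc
populations(cyc, c(5.5, 7.0, 7.5))
```

Two numerical details of the oracle are worth recording. First, the
inflection is located from a bracket around the extremum of the first
derivative rather than from the first sign change of the second
derivative on a grid, because the sigmoid's flat tails produce spurious
finite-difference sign flips. Second, the central-difference step is
`h = 1e-2`: for plateau separations as small as 1e-5 a smaller step makes
the second difference cancellation-limited, while for a logistic the
location bias of the discretised inflection is O(h^4) (the fourth
derivative vanishes at the midpoint by symmetry), so the large step costs
nothing.

## Choosing K_D

`K_D` is the one genuinely unknown parameter. Three complementary
analyses constrain it (scripts `analysis/02_kd_scan.R`):

* `kd_scan()` tabulates the apparent pKa and the two "working"
  populations — closed-protonated at pH 5.5, open-deprotonated at
  pH 7.5 — against `K_D`; the apparent pKa falls monotonically from 7.5
  at `K_D` = 10 to 5.4 at `K_D` = 1500.
* `optimal_kd()` maximises `min(x_CH at pH 5.5, x_Op⁻ at pH 7.5)`, the
  natural efficiency criterion for a pH switch that must hold NO at low
  pH and release it at high pH. The first fraction decreases and the
  second increases strictly in `K_D`, so the maximiser is their unique
  crossing, found by `uniroot` on log10 `K_D` over [-2, 6] to 1e-4 log
  units; it sits near 100 (101.5 unrounded) with both fractions at 0.90.
* `valid_kd_range()` bounds the region where neither off-pathway species
  (C⁻ at high pH, OpH at low pH) exceeds a tolerated fraction. The
  default mode uses the asymptotic limits `x_C⁻ -> 1/(1+K_D)` and
  `x_OpH -> K_H/(1+K_H)` because the "extreme pH values" at which
  significance should be judged are otherwise a free choice; a fixed-pH
  mode evaluates the same fractions at two supplied pH values instead,
  reporting 0 or Inf when a constraint never binds. At a 10% threshold
  the asymptotic bounds are `K_D` in [9, ~1761].

## The coarse-grained simulator

Constant-pH molecular dynamics interleaves molecular dynamics with
periodic Monte Carlo sampling of the protonation state. The package's
`simulate_cphmd()` reproduces that scheme at the level of the four-state
model: a discrete-time Markov chain (one frame per step) with

* a protonation flip attempted every `mc_interval` steps (default 10,
  mirroring the every-10-MD-steps convention of the constant-pH
  protocol), accepted by the Metropolis rule with
  `dG/kT = ln(10) * (pK_conf - pH)` for deprotonation, where `pK_conf`
  is the microscopic pKa of the *current* conformation; and
* a conformational flip attempted with probability `p_conf_attempt` per
  step (default 0.01), accepted with `min(1, K)` for opening where
  `K = K_H` (protonated) or `K_D` (deprotonated).

Temperature never appears: all free energies are expressed in kT units.
The two kernels individually satisfy detailed balance with respect to
the four-state equilibrium (verified exactly, acceptance-ratio by
acceptance-ratio, in the tests), so the chain's stationary distribution
is the analytic `populations()` — the simulator's principal oracle test.
Kinetics, by contrast, are deliberately fictitious: the chain is not a
Gillespie simulation and no quantitative rate is claimed. The default
`p_conf_attempt` makes conformational moves roughly a hundredfold slower
than protonation exchange, which is enough to reproduce the qualitative
signature of the transition trajectories — deprotonation first, opening
after — without attempting to match the ~9 ns onset seen in the real
simulations. The inner loop is compiled (Rcpp) and draws from R's RNG,
so trajectories are bit-reproducible from `kinetic_params(seed=)` and
leave the caller's RNG state untouched.

Each frame also carries observables drawn from conformation-conditioned
Gaussians (`observable_model()`): the Asp30–Leu130 hydrogen-bond distance
(3.5±0.3 Å closed, 8±1 Å open), the Asp35–Asp129 escape-route distance
(5±1 / 14±3 Å) and the SASA of the carboxylate (9±4 / 40±2 Å²). The
closed-state SASA standard deviation is wide relative to its mean, so
SASA is truncated at zero by resampling offending frames; distances never
come near zero under these parameters and are left untruncated. Multi-pH
experiments (`titration_experiment()`) derive the run at index i from
`seed + i - 1`, so every per-pH trajectory is independently reproducible.

What the generator emulates — and what it does not: it reproduces the
stationary four-state statistics, Henderson–Hasselbalch titration within
each conformation, state-conditioned observable levels, and the
deprotonate-then-open ordering. It has no atoms, no forces, no
intermediate conformations, no correlation between successive observable
draws beyond that induced by the state sequence, and no kinetic realism.
Passing recovery tests on this generator therefore demonstrates the
correctness of the estimators under the model's own assumptions, not
their robustness to the artefacts of real trajectories (conformational
intermediates, non-Gaussian observables, slow solvent degrees of
freedom).

## Estimation

`pka_from_counts()` inverts Henderson–Hasselbalch at a single pH:
`pKa = pH + log10(f/(1-f))` for protonated fraction `f`, with a standard
error propagated from the binomial error of `f`. Fractions of exactly 0
or 1 only bound the pKa, so the estimate is returned *censored*
("pKa < pH" / "pKa > pH") rather than infinite — no estimator in the
package emits a non-finite number. `fit_titration()` maximises the
binomial likelihood of per-pH counts under
`f(pH) = 1/(1 + 10^(n(pH - pKa)))`; with the Hill coefficient fixed at 1
(the default, matching the single-ideal-site assumption of the analysis)
this is a binomial GLM with a logit link and `-ln(10) pH` offset, and the
free-`n` variant — a diagnostic, not the default — adds the slope with the
midpoint standard error obtained by the delta method.

Trajectory-based estimators share two conventions. A burn-in fraction
(default 0.1) is discarded before any equilibrium tally, since the chain
may be started far from equilibrium on purpose; the real analyses do not
state an equilibration cutoff, and 10% is a deliberately blunt,
configurable choice. And because frames are autocorrelated, the binomial
standard errors are labelled as i.i.d.-assumption values, with a
moving-block bootstrap (`bootstrap_ci()`, default block 100 frames)
available for honest intervals; block length is not estimated from the
data — autocorrelation-time estimation is out of scope.

`conditional_pka()` partitions frames by conformation and inverts each
partition — this is the estimator that recovers 8.5 and 4.3 from a single
mid-pH trajectory, the central "microscopic values are observable"
demonstration. `running_pka()` and `running_average()` provide the
trailing-window traces used to visualise transitions (window default 100
frames; the trailing convention delays features by up to one window, and
`detect_transition()` — first midpoint crossing that persists for at
least `persistence` frames, default 50 — inherits that documented lag).
`recover_cycle()` rebuilds the full cycle from a titration experiment:
the two microscopic pKa values from conformation-conditioned titration
fits, and `K_D` from the pooled ratio of open to closed frames among
deprotonated frames, which is unbiased at every pH individually because
`(Op⁻)/(C⁻) = K_D` pointwise; `K_H` then follows from cycle closure.

## Problem sizes and statistical design of the checks

Stationarity is verified at five pH values (4, 5.5, 6.5, 7.5, 9) with
1e6-step chains. Frames are strongly autocorrelated — at mid pH the
conformational correlation time is on the order of 3e3 steps under the
default kinetics — so a naive binomial standard error based on the frame
count would understate the Monte Carlo error by an order of magnitude.
The comparison therefore uses the batch-means standard error (25
post-burn-in batches), and requires agreement within three such standard
errors per species.

Recovery is checked on an 8-point pH grid (3..10). The microscopic pKa
values are recovered within 0.1 pK units from 2e5 frames per pH: their
effective sample size is the (large) number of protonation events. The
rebuilt cycle's apparent pKa, however, also needs `K_D`, whose effective
sample size is the far smaller number of *conformational* transitions
(tens per run at mid pH), so the rebuild check uses 1e6 frames per pH;
across seeds this determines the rebuilt apparent pKa to well within 0.1.
The same reasoning is stated in `analysis/04_titration_recovery.R`, which
runs the full loop end to end. Coverage checks (2-standard-error coverage
of the titration fit, bootstrap interval coverage) assert rates inside a
band around the nominal value rather than a one-sided cut, since a
perfectly calibrated estimator fails a sharp >= 95% cut with appreciable
probability over a few hundred replicates.

## Degenerate inputs and edge conventions

* `K_D <= 0`, thresholds outside (0, 0.5), unsorted pH grids, counts with
  `n_prot > n_total`, and windows longer than the series are rejected
  with specific errors.
* `signal_model()` rejects `alpha == beta`: a conformation-blind
  observable carries no information about the transition.
* `apparent_pka()` degrades gracefully to the single microscopic pKa
  when `K_H = K_D` (the closed form is exact there), while
  `apparent_pka_numeric()` raises "transition undefined" — with a flat
  open fraction there is no inflection to locate.
* Empty conformational partitions yield "empty"-censored estimates, not
  errors, so scans over trajectories never abort on a frozen chain.

## Known limitations

The model has exactly one titratable site and two conformations; no
tautomers, no multi-site coupling, no intermediate structures. The
simulator's kinetics are schematic, so nothing downstream should
interpret its time axis quantitatively beyond ordering. `alpha` and
`beta` are treated as fixed inputs, not refit to experimental NO-affinity
data. And the microscopic pKa values themselves are inputs: computing
them from structure is the province of constant-pH molecular dynamics,
not of this package.
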