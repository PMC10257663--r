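---
title: "A linear-chain model of cell-cycle phase-specific drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A linear-chain model of cell-cycle phase-specific drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lctcycle)
```

## The problem

A proliferating cell population under drug treatment is observed through
two population-level time series: the total cell count and the fraction of
cells in G1 (a two-color reporter distinguishes G1 from the combined S-G2
phases, not S from G2). Drugs that target different cell-cycle phases can
produce similar endpoint counts through entirely different mechanisms —
lengthening G1, stalling S-G2, or killing cells in one phase — and at
intermediate doses they partially synchronize the population, producing
oscillations in the G1 fraction with a period of roughly one cell cycle.
A model of drug response that hopes to disentangle cytostatic from
cytotoxic action, and to predict combinations, must reproduce this
transient synchronization. `lctcycle` implements such a model, a stochastic
single-cell counterpart that doubles as a synthetic-data generator, a
simultaneous multi-drug fitting procedure, and Bliss-independence
combination prediction on the fitted rates.

## The mean-field model

A two-compartment exponential model (one state per phase,
`dG1/dt = 2βG2 − (α+γ1)G1`, `dG2/dt = αG1 − (β+γ2)G2`) assumes
exponentially distributed phase durations. Its G1 fraction relaxes
monotonically and cannot oscillate, and single-cell tracking shows phase
durations are far less dispersed than exponential: they are well described
by gamma distributions. The linear chain trick replaces each phase with a
chain of exponential subphases so that transit time becomes Erlang
(gamma with integer shape) while the system stays linear.

Concretely, G1 is divided into 4 parts of 2 subphases each (8 states) and
S-G2 into 4 parts of 5 subphases each (20 states). All subphases of part
*j* share that part's progression rate (α_j in G1, β_j in S-G2) and death
rate (γ_{1,j}, γ_{2,j}), all in 1/hour. Part-level resolution lets a drug
act preferentially at the beginning, middle, or end of a phase while
keeping the parameter count manageable. The expected occupancy vector
follows `dx/dt = A x`; each subphase loses mass at its part's progression +
death rate, progression feeds the next subphase, and exit from the last
S-G2 subphase feeds the first G1 subphase multiplied by 2 (division into
two daughters). `build_generator()` assembles `A` (28×28 by default, 30×30
when two absorbing dead compartments per phase are appended), and
`simulate_mean_field()` propagates the state with a single matrix
exponential per step size, applied repeatedly over the uniform grid — exact
for a linear system, with no stiffness concerns at this dimension.

The subphase counts 8 and 20 are not free knobs: they are the integer
shapes of gamma distributions fitted to single-cell G1 and S-G2 durations
in the untreated condition, a procedure `estimate_gamma_shape()` reproduces
on simulated lineages (maximum-likelihood gamma fit, shape rounded half-up,
floored at 1). With part-homogeneous rates and no death, mean phase
durations are exactly

\[ \bar G_1 = \sum_{j=1}^4 \frac{2}{\alpha_j}, \qquad
   \overline{SG_2} = \sum_{j=1}^4 \frac{5}{\beta_j}, \]

implemented by `average_phase_durations()`; death rates do not enter
(these are durations of cells completing the phase).

### Dead-cell accounting

The exact expected cumulative death count comes from absorbing
compartments that integrate the per-phase death flux — this is the primary
accounting. A discrete alternative, `accumulate_dead()`, sums the
instantaneous flux `n(t) = Σ_ij G_ij(t) γ_ij` over the grid. The raw
unweighted running sum (`weight = "none"`) depends on the step size; the
default applies a trapezoidal `dt` weight, which converges to the
absorbing-compartment value as the grid refines (left-rectangle weighting
would already miss the 96-hour pure-death benchmark by ~2.5% at a
30-minute step, so the trapezoid is the sensible quadrature). Both modes
are retained because published analyses of this type report the discrete
sum.

### The exponential baseline

`simulate_exponential_baseline()` solves the two-state model with the same
machinery — equivalently, the chain model with one subphase per phase — so
model comparison is like-for-like. The S-G2 loss term uses γ₂; an
`sg2_loss_uses_gamma1` flag substitutes γ₁ there instead, reproducing a
variant form of the equations in circulation that we read as a
typographical slip (with it, the S-G2 death compartment drains at the G1
death rate, which has no biological reading).

## Dose response

Every rate responds to concentration *C* (nM) through a four-parameter
Hill curve `E_min + (E_max − E_min)/(1 + (EC50/C)^k)`; `C = 0` is handled
as the analytic limit `E_min` rather than through the power law. Within a
drug one EC50 and one steepness k are shared by all 16 rate slots, the
E_min values are the globally shared drug-free control rates, and E_max is
free per slot but maskable (a "G1-only" drug constrains β and γ₂ to be
unaffected). This sharing scheme is a documented choice: the exact
free/shared partition used in the original analyses is not printed, and
one EC50 + k per drug is the most parsimonious layout consistent with
sharing all non-drug-specific parameters. Death-rate E_min defaults to 0 —
untreated cultures show essentially no death on this timescale.

## The synthetic-data generator

`simulate_cells()` runs the exact stochastic counterpart of the mean-field
system: each cell draws an independent exponential dwell in every subphase
at the part's progression + death rate and dies there with probability
γ/(rate sum) — competing risks within each subphase — and division at the
final S-G2 exit spawns two G1 daughters. This makes the oracle relationship
a theorem rather than an approximation: ensemble means of the binned
lineage tables converge to `simulate_mean_field()` exactly, which the test
suite checks with standardized deviations. G1 and S-G2 durations of a cell
are independent by construction, mirroring the observation that the phases
are independently regulated.

`generate_dose_response_dataset()` emulates the assay design: an 8-point
dose series, 3 replicates, samples every 30 minutes for 96 hours, counts
normalized to the mean of the first three timepoints. The defaults
(`n0 = 500` starting cells per replicate, `noise_cv = 0.05`) are choices,
not measured properties: the imaging pipeline's counting-noise magnitude
is not published, so we use multiplicative lognormal noise on counts with
a 5% coefficient of variation — a typical figure for automated nuclear
counting — and binomial sampling noise on the G1 fraction, and record both
in the dataset metadata. A `method = "mean_field"` switch replaces the
stochastic simulation by the exact expectation (the noiseless,
infinite-population limit) for recovery studies. To bound runtime, newborn
generations beyond 50,000 cells are uniformly subsampled with compensating
statistical weights, keeping weighted counts unbiased.

The untreated condition is anchored at mean G1 and S-G2 durations of
22.3 h (per-part rates α = 8/22.3, β = 20/22.3 per hour) with 75% of
starting cells in G1, the reported control behavior of the AU565-like
setting this package emulates. The reference drug profiles in
`example_profiles()` are derived from the same anchors: the G1 blocker
saturates at a 98% reduction of α (cytostatic plateau at the highest
doses), the S-phase agent at 10 nM stretches S-G2 toward 38 h and yields
about one death per starting cell over 96 h.

What passing tests on these synthetic data do *not* show: robustness to
segmentation errors, misclassified phases, mother–daughter duration
correlations, drug decay over the assay, or heterogeneous subpopulations —
none of which the generator emulates.

## Preprocessing

The pipeline is fixed and recorded in provenance: normalize (mean of the
first three timepoints), smooth each replicate with a Savitzky–Golay
filter, average replicates, then split the total count into G1 and S-G2 by
the G1 fraction. Window 11 samples (~5 h at 30-minute cadence) and
polynomial order 3 are defaults chosen to preserve the ~24 h oscillation
while suppressing frame-to-frame counting noise; both are configurable,
and `window = 1` disables smoothing. Whether the original analyses
smoothed before or after averaging is unstated; smoothing each replicate
first is the default because it treats replicates symmetrically. Negative
smoothed counts are clamped to zero with a warning.

## Fitting

The cost is the plain sum of squared errors between model and data G1 and
S-G2 counts over all timepoints, doses and drugs, with the model prediction
normalized by the mean of its first three timepoints — the same convention
the data carry, so a perfect parameter set reaches (numerically) zero cost.
Control rates and the initial G1 fraction are shared across drugs; each
drug adds one EC50, one k, and masked E_max slots. Rates and EC50s are
searched on a log10 scale and fractions on a logit scale inside finite box
bounds (rates 1e-4–10/h; EC50 within a decade of the dose range; k
0.1–10). The optimizer is a seeded rand/1/bin differential evolution with
dithered mutation factor (F ~ U(0.5, 1)), a standard self-adaptive variant;
population size and generation count are set per problem and
convergence-checked (the fit is flagged converged when the best cost
improves by <1% over the final quarter of the run). Identifiability is
assessed as in the source analyses by local sensitivity: each fitted
parameter is scaled across 0.1–10× with the others held at the optimum,
and flagged identifiable when the cost rises by more than 1% at 0.5× and
2× — the 1% threshold is our choice, as the original reports the analysis
but no cutoff.

Problem sizes used in the shipped tests and acceptance script: recovery
fits use a single drug, 8 doses at 30-minute resolution (1,544 residuals),
a 5-parameter tied layout (one α, β, E_max per family), DE population 30
for 120 generations; this recovers generating durations to well under 1%
and EC50 to ~0.1% on noiseless data, comfortably inside the 10%/20%
tolerances we regard as practically meaningful. The model-comparison fits
use 4 doses and smaller budgets; the chain model beats the exponential
baseline on oscillatory G1-blocker data by a factor of ~50 in SSE, so the
comparison is insensitive to optimizer effort.

## Drug combinations

Bliss independence is applied on the rate scale, per part-rate slot.
Progression effects are saturable and are first scaled to fractions of
control, `Ê = (ctrl − rate)/ctrl ∈ [0, 1]`, combined as
`E_ab = E_a + E_b − E_a E_b`, and mapped back; death effects are absolute
added rates and simply add, because death is not saturable. Per-slot
combination (rather than combining aggregate phase durations) is the
finest granularity consistent with combining "rate effects", and reduces
exactly to the single drug when either dose is zero. The conventional
baseline — Bliss directly on endpoint cell numbers — is provided as
`bliss_combine_cell_numbers()` and computed per timepoint, with the
endpoint the usual summary (whether the original baseline used the
endpoint only is unstated; the full-trajectory version contains it).

The two references disagree in exactly the situation the rate-level method
is designed for: two saturating G1 blockers are jointly cytostatic (counts
plateau at/above the starting number, since blocked G1 progression cannot
be reduced below zero) while the count-level baseline multiplies the two
single-drug reductions into an apparent net kill. For a G1 blocker plus an
S-phase agent the rate-level prediction is antagonistic — cells held in G1
are not exposed to S-phase killing, so the combination's final count is at
least the S-drug's alone, and the early G1 fraction is strongly enriched
relative to the S-drug or untreated populations. One caveat found while
implementing: when the S-phase agent also slows S-G2 exit, the combination's
early G1 fraction sits marginally *below* the pure G1 blocker alone
(slower S-G2 drainage), so "enrichment" is meaningful against the S-drug
and control, not against the blocker itself.

## Numerical choices and degenerate inputs

- Time is in hours; the default grid is 0.5 h over [0, 96], matching the
  30-minute imaging cadence. Non-uniform grids are rejected (the
  propagator is precomputed per step size).
- How the initial unit mass spreads across subphases within a phase is not
  fixed by the data (only the G1 fraction is); `uniform` is the least
  committal default, with `first_subphase` and `stationary` (dominant
  eigenvector, renormalized per phase) as alternatives since the early
  oscillation phase depends on it.
- Zero progression rates are permitted in the ODE machinery (needed for
  pure-death closed-form checks) but rejected where they imply infinite
  durations; zero concentration bypasses the Hill power law.
- Matrix exponentials use Padé scaling-and-squaring (`Matrix::expm`);
  eigendecomposition would fail for the part-homogeneous chain, which is
  defective.
- The gamma MLE is started from moment estimates for stability at large
  shapes; samples smaller than 30 or degenerate (zero-variance) samples
  are rejected.
- Seeds: every stochastic entry point takes a seed and records it; equal
  seeds give byte-identical outputs.

## Known limitations

Phase durations of related cells are independent here, but real lineages
show mother–daughter correlations; drug concentration is treated as
constant (no pharmacokinetics, no media-refresh dynamics); subphases are
phenomenological, not mechanistic cell-cycle stages; right-truncation at
the assay horizon biases long-duration estimates downward in slow/arrested
conditions, which matters when estimating shapes from heavily drugged
lineages; and the fit quantifies identifiability only through local
sensitivity curves, not posterior uncertainty.
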