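---
title: "Models and methods behind seedkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seedkin quantifies how small molecules perturb seeded amyloid (tau)
aggregation, and couples that assay analysis to an iterative
machine-learning loop that optimizes inhibitor potency over a molecular
library. This vignette explains the models, the estimation choices, what
the synthetic-data generators emulate, and where the package's own design
decisions lie.

## The kinetic model

Aggregation is described by the standard two-moment equations of
filamentous self-assembly, with fibril number concentration $P$ and
fibril mass concentration $M$ (molar, monomer equivalents), free monomer
$m = m_\mathrm{tot} - M$:

$$\frac{dP}{dt} = k_n m^{n_c}
  + k_2 \frac{m^{n_2}}{1 + m^{n_2}/K_M^{n_2}}\, M
  + k_- M, \qquad
\frac{dM}{dt} = 2 k_+ m P .$$

The three production terms for $P$ are primary nucleation ($k_n$, order
$n_c$), secondary nucleation on the fibril surface ($k_2$, order $n_2$,
optionally saturating in monomer with constant $K_M$; $K_M = \infty$
gives the unsaturated model) and fragmentation ($k_-$). Mass grows only
by elongation at fibril ends ($k_+$). Seeded reactions start from
$M_0 > 0$ with $P_0 = M_0 / L_0$ for a mean seed length $L_0$ (default
500 monomers — fibril length is rarely known, so it is exposed as a
parameter rather than hidden).

The system is integrated with `deSolve::lsoda` (relative tolerance
1e-10). We integrate numerically rather than using the fixed-point
analytic solutions of the aggregation literature so that saturation,
fragmentation and per-dose rate perturbations are all handled uniformly;
the integrator is validated in the test suite against analytic
early-time limits and an independent fixed-step Runge-Kutta integrator
(half-times agree to < 0.5%).

Reaction orders default to $n_c = n_2 = 2$, the usual convention for
amyloid systems. The default rate constants
(`default_kinetics()`) are the package's own calibration, chosen so that
5 µM monomer with 1% seeds reaches its half-time in 14–19 h under
quiescent conditions — the time scale of seeded tau amplification
assays — while seed-end elongation alone would need ~70 h, so
self-replication (secondary nucleation or fragmentation) dominates. The
fragmentation variant deliberately uses a lower $k_+$ (300 /M/s) with a
correspondingly higher $k_-$: when the elongation feed
$2k_+ m P_0/\kappa$ rivals the seed mass $M_0$, the classic $-1/2$
half-time scaling is distorted (we measured $\gamma \approx -0.61$ in
that regime), whereas in the amplification-dominated regime the
dilution-series exponent converges to $-0.51$.

## Half-times, normalization and the scaling exponent

`extract_half_time()` fits a four-parameter logistic to the raw trace
and reports the midpoint as $t_{1/2}$. The logistic is only used to
*locate* the transition: its symmetric asymptotes are biased on
asymmetric aggregation curves, so the baseline and plateau are
re-estimated from the flat phases themselves (medians outside
$t_{50} \pm 4$ slope-widths). Traces whose amplitude is below 5× the
estimated noise SD are flagged `"no_aggregation"` and return `NA` rather
than a number; traces still rising at the last read return a flagged,
warned estimate.

Wells that never plateau (strong inhibition, low monomer, high-seed
designs) cannot be normalized per-trace. `normalize_plate()` therefore
estimates each well's baseline by extrapolating the pre-transition reads
to $t = 0$ (a quadratic fit, since seeded growth is quadratic in $t$ to
leading order) and fixes a single fluorescence gain (AU per molar of
converted mass) from the reference wells that have demonstrably
plateaued; every other well is scaled through that shared gain and its
own convertible mass $m_\mathrm{tot} - M_0$. This is the assumption
made implicitly whenever a plate shares one fluorophore and optic.

`scaling_exponent()` regresses $\log t_{1/2}$ on $\log m_0$; the slope
$\gamma$ diagnoses the dominant mechanism ($\approx -0.5$ for
fragmentation or saturated secondary nucleation,
$-(n_2+1)/2$ for unsaturated secondary nucleation — the packaged
secondary default measures $\gamma \approx -1.4$).

## Global fitting and mechanism deconvolution

`global_fit()` minimizes the summed squared residual between normalized
traces and $(M - M_0)/(m_\mathrm{tot} - M_0)$, sharing the chosen free
constants across traces while each trace keeps its own concentrations.
Optimization is multi-start Levenberg–Marquardt (`minpack.lm`) on
log-parameters: the first start is the user's parameter set, the rest
are log-uniform draws within the bounds under a recorded seed (default
20 starts; a parameter landing on a bound is warned about). Only
identifiable combinations are asserted in tests — for seeded
secondary-dominated data the growth rate constrains
$\kappa^2 \propto k_+ k_2 m^{n_2+1}$, so the product $k_+ k_2$ is
recovered to a fraction of a percent while the individual constants may
trade off along the ridge.

`fit_dose_mechanism()` pins the assay baseline on the vehicle control,
then refits each dose with only the compound-sensitive constants free:
$k_+$ against the high-seed (elongation-dominated) traces and $k_2$
against the low-seed traces. Because each refit conditions on the other
constant, the two are alternated until stable (≤ 4 passes, 0.5%
tolerance); on synthetic data a pure-$k_+$ perturbation leaks < 2
percentage points into $k_2$. Reductions are reported as
$1 - k(\mathrm{dose})/k(\mathrm{control})$ at the top dose. The
`elongation_slope()` view (OLS over the first 10 h of the high-seed
trace) is also reported; it is the traditional readout but understates a
planted reduction when the trace curves within the window, so the
kinetic refit is the quantitative route.

## Dose–response and binding

`kic50()` normalizes approximate rates $1/t_{1/2}$ so the vehicle is 100
and complete arrest is 0 (the natural anchoring; configurable), then
fits a descending log-dose logistic with the top fixed at 100 and the
bottom at 0, Hill slope free — four doses cannot support four free
parameters. If no dose brings the rate below 75 only the bound "> max
dose" is reported. KIC50 is the fitted 50-crossing.

`fit_one_site_binding()` fits $\Delta mP = B_\mathrm{max}[F]/(K_D+[F])$
with fibril concentration in monomer equivalents (site multiplicity
folds into $B_\mathrm{max}$). A quadratic ligand-depletion variant is
available behind a flag; the default is the plain hyperbola, matching
standard one-step binding analyses. The fit is flagged *poorly
determined* when the titration fails to bracket the affinity — no
saturation evidence, $K_D$ beyond the highest fibril concentration, the
95% interval extending past it, or SD ≥ half the estimate. This
reproduces the qualitative behaviour of a weak binder whose $K_D$ sits
at the edge of the tested range.

## The active-learning loop

Molecules are featurized as 1024-bit path-based binary fingerprints
(OpenBabel FP2 via ChemmineR) — a deterministic,
canonicalization-invariant graph property. The featurizer is a plain
function from SMILES to a matrix so learned embeddings can be swapped
in; similarity calculations always use the binary fingerprint, the
standard Tanimoto usage.

The surrogate is two-stage: a 500-tree random forest (ranger) regresses
the normalized half-time on the features, and an exact Gaussian process
(squared-exponential + noise kernel, hyperparameters by maximum marginal
likelihood from a small deterministic restart grid) is fitted to the
forest's in-sample residuals. Predictions add the GP residual mean to
the forest mean; predictive uncertainty is the GP SD. The GP is written
in-package because no installed library offers GP regression with
marginal-likelihood hyperparameter optimization.

Acquisition is an upper confidence bound, `mean + beta * sd`
(`beta = 1` by default): beta weighs exploration of uncertain chemistry
against exploitation of predicted potency. Batches are greedy top-k with
lexicographic tie-breaks (determinism) and an optional intra-batch
Tanimoto diversity filter. `run_campaign()` seeds with a supplied
docking-hit list or a uniform random draw, then iterates
train → score → select → measure, recording per-iteration hit rates
under the strict thresholds (ratio > 1.5 potent, > 2 highly potent,
both strict inequalities; below 1 by a 0.1 margin counts as induction).

`tanimoto_cluster()` is leader-style (Butina) sphere exclusion at
cutoff 0.78; every member has similarity ≥ cutoff to its centroid by
construction, verified in tests against the full pairwise matrix.
`cns_mpo()` computes the six-component desirability score (0–6; pass at
≥ 4 by default) from computed descriptors; since no logD or pKa
predictor is bundled, computed logP stands in for logD and the most
basic pKa comes from a SMARTS-based class proxy — both stand-ins are
declared in the output metadata.

## What the synthetic data emulate — and what they do not

The generators (`gen_dilution_series`, `gen_inhibitor_doses`,
`gen_fp_titration`, `gen_rate_response`, `gen_library`) reproduce the
study designs: 3.2–15 µM monomer dilution with 1% seeds; 5 µM monomer +
50 nM seeds dosed at molar equivalents 1×/2×/4× (5/10/20 µM); a
high-seed 2.5 µM seed / 5 µM monomer elongation design; 10 µM compound
titrated against fibrils up to 10 µM (monomer equivalents); 15-minute
read cycles; n = 3 replicates (replicate counts are not specified in
such screens; 3 is the bench norm). The ThT signal map is linear in
aggregate mass (offset 50 AU, gain 2 × 10⁸ AU/M → 1000 AU amplitude at
5 µM) with additive Gaussian noise of 10 AU (≈ 1% of amplitude,
moderate plate-reader noise); distinct gains per polymorph are the only
amplitude structure modelled. Planted dose effects follow a saturating
dose law that reaches the planted reduction exactly at the top dose —
the true dose law in such assays is unknown, so exactness at the
anchor dose keeps the ground truth unambiguous. FP titration noise is
3 mP per replicate, which makes the fitted $K_D$ SD for the strongest
binder ≈ 6%, comparable to the uncertainty scale of published one-site
fits.

The screening library is a five-scaffold combinatorial grammar (amide,
sulfonamide, urea, ester and a 1,3,4-oxadiazole family echoing the
recurring oxadiazole chemotype) over 20 substituents — 2,000 molecules,
all valid SMILES. Eight hidden actives sit inside the oxadiazole
family; the assay oracle returns
$1 + (r_\mathrm{max} - 1)\exp(-d^2/w^2)$ plus noise, where $d$ is the
Tanimoto distance to the nearest active, $r_\mathrm{max} = 3$ and
$w = 0.15$. The width was set so that ≈ 4–5% of the library clears the
hit threshold — the low-prevalence regime a real screen operates in.
Oracle noise (SD 0.1) is drawn from an RNG seeded by the fingerprint
itself, so the oracle is deterministic and invariant under SMILES
re-spelling.

What passing tests on these data do **not** show: real ThT kinetics have
well-to-well gain variation, evaporation drifts and non-Gaussian
artifacts; real SAR landscapes are not smooth single-kernel functions of
fingerprint distance and real libraries are vastly larger (the
desk-scale library tests *enrichment relative to random selection*, not
absolute hit rates, which in the laboratory depend on the wet assay);
and the binding model ignores ligand depletion unless asked not to.

## Numerical choices and degenerate inputs

Integrator tolerances rtol 1e-10 / scaled atol; negative-concentration
excursions abort. The dilution-series simulations run 60–80 h at
15-minute resolution so that mid-range wells plateau (the gain reference
needs at least one demonstrably flat tail; convergence = tail slope
< 2% of amplitude across the last 15% of reads). Fits run at 3–20
Levenberg–Marquardt starts depending on context; all multi-start seeds
are recorded in the output. Flat traces, empty free sets, unparseable
SMILES, constant targets, exhausted pools and missing plateaus each have
explicit, tested behaviours (sentinels, warnings or errors) rather than
silent numbers.

Problem sizes throughout (6-concentration series, 4-dose designs,
2,000-molecule library, 10-replicate enrichment comparisons) are the
package's chosen desk scale: large enough for the statistical claims the
tests make, small enough to run interactively.

## Known limitations

- Individual rate constants from a single seeded condition are not
  identifiable; only documented combinations are (the tests enforce
  honesty here).
- The scaling-exponent diagnostic assumes a shared mechanism across the
  dilution series.
- CNS MPO uses declared proxies for logD and pKa; scores for strongly
  basic or zwitterionic molecules are approximate.
- The GP uses an isotropic kernel on fingerprint bits; with very small
  training sets its uncertainty is a smooth proxy, not a calibrated
  posterior.
- Elongation slopes understate inhibition when high-seed traces curve
  within the regression window; use the kinetic refit for quantitative
  claims.
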