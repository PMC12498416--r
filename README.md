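# seedkin

Quantitative analysis of polymorph-specific tau aggregation inhibition:
seeded amyloid kinetics, inhibitor mechanism deconvolution, binding and
dose–response metrics, and an iterative machine-learning loop for
optimizing inhibitor potency over a molecular library.

## Who this is for

Groups running seeded ThT aggregation assays (e.g. brain-seed-amplified
tau) who want to go beyond "the curve shifted right": to attribute an
inhibitor's effect to specific microscopic steps (secondary nucleation
vs elongation), to put numbers with uncertainties on potency (KIC₅₀)
and fibril binding (K_D), and to drive compound selection with an
active-learning surrogate instead of one-shot screening.

## The models

**Kinetics.** Two-moment equations of filamentous assembly, for fibril
number P and mass M with free monomer m = m_tot − M:

    dP/dt = k_n m^(n_c) + k₂ m^(n₂)/(1 + m^(n₂)/K_M^(n₂)) · M + k₋ M
    dM/dt = 2 k₊ m P

covering primary nucleation, (saturating) secondary nucleation,
fragmentation and elongation. Seeded reactions start at M₀ with
P₀ = M₀/L₀. Half-times come from four-parameter logistic fits; the
scaling exponent γ (slope of log t₁/₂ vs log m₀) diagnoses the dominant
mechanism (γ ≈ −0.5 for fragmentation/saturated secondary nucleation).
Global fits share rate constants across dilution series; dose-series
refits recover per-dose k₂ and k₊ and report fractional reductions.

**Potency and binding.** KIC₅₀ is the 50-crossing of a descending
log-dose logistic on the normalized approximate rate 1/t₁/₂
(vehicle = 100, arrest = 0, top/bottom fixed); fibril binding is the
one-site fit ΔmP = B_max·[F]/(K_D + [F]) with honest
"poorly determined" flagging when the titration does not bracket K_D.

**Screening loop.** Molecules → 1024-bit fingerprints → two-stage
surrogate (random-forest mean + Gaussian-process residual model with
marginal-likelihood hyperparameters) → upper-confidence-bound
acquisition (mean + β·sd) → batch selection → assay → retrain. Butina
(Tanimoto 0.78) clustering and CNS MPO (0–6 desirability) filtering
support library design.

Every assay has a deterministic synthetic generator with planted ground
truth (`gen_dilution_series`, `gen_inhibitor_doses`, `gen_fp_titration`,
`gen_rate_response`, `gen_library`), so the whole pipeline is testable
without instrument data.

## Worked example

Recover an inhibitor's mechanism from a synthetic dose series planted
with a 97% secondary-nucleation knockdown and a 29% elongation slowdown
at the top dose (5 µM monomer, 50 nM seeds, doses 5/10/20 µM):

```r
library(seedkin)

cfg  <- generator_config(rng_seed = 103)
ds   <- gen_inhibitor_doses(cfg, "I1.21", k2_reduction = 0.97,
                            kplus_reduction = 0.29)
nds  <- normalize_dose_series(ds)
base <- update_params(default_kinetics("secondary"),
                      k_2 = 600, k_plus = 3e4)   # start off-truth
fit_dose_mechanism(nds, base, n_starts = 3, seed = 13)
#> <mechanism_report> I1.21: at top dose k2 reduced 97.2%, k+ reduced 27.5%
```

The report's per-dose constants table gives k₂ and k₊ at each dose;
the headline reductions are relative to the fitted vehicle control.
Binding and dose–response follow the same pattern:

```r
bt <- gen_fp_titration(generator_config(rng_seed = 201), K_D = 1.58e-6,
                       compound_id = "I1.21")
fit_one_site_binding(bt)[c("K_D", "K_D_sd", "poorly_determined")]
#> $K_D [1] 1.571e-06      # molar; 1.57 µM ± 0.10
#> $poorly_determined [1] FALSE
```

The numbered drivers under `analysis/` run the full study —
`01_kinetics_scaling.R` (dilution series, γ, global fit),
`02_mechanism_deconvolution.R` (three compounds),
`03_binding_and_kic50.R`, `04_screen_campaign.R` (CNS MPO filter,
clustering, 3-iteration active-learning campaign vs a random baseline)
— and write their tables under `results/`. On the packaged library the
campaign's final-iteration hit rate averages ~36% against ~4% for
budget-matched random selection (ahead in 9 of 10 seeded runs).

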