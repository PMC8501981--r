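# nascycle

Cell cycles are coordinated across generations: perturbing a mother
cell's cycle is compensated in its daughters. `nascycle` implements a
quantitative model of one molecular route for that coordination — a
natural antisense transcript (nAS25) of the notch-1 locus that the mother
synthesizes during G1 in proportion to her G1 length, transmits at
division, and that protects the daughter's notch-1 transcript from
C-to-U hyper-editing and nonsense-mediated decay (NMD) at G0, thereby
setting the daughter's G1 duration. The package is aimed at systems
biologists who want to interrogate the model's arithmetic, simulate
lineages under the perturbation scenarios, or reuse the companion
analysis computations.

## The model in brief

Per cycle, with titers as per-cell concentrations (control ≡ 1):

* **Mass balance.** Of the inherited antisense pool nAS25^F0, a fraction
  *s* = 0.5 survives G0 editing and G1 degradation; E2F1-driven
  intra-cycle synthesis (nAS25^F1) adds *k*·G1 with
  *k* = (1 − *s*)/460 min⁻¹, so a control cell restores its pre-G1 titer
  exactly (homeostasis). Perturbations act on individual terms:
  synthesis block → 50% of control; promoter block at efficiency 0.92 →
  54%; inherited-pool RNAi (0.54) plus synthesis block →
  0.5 × 0.46 = 23%; a 240-min G1–S delay raises the intra-cycle
  component by 240/460 ≈ 52%; G2 arrest changes nothing.

* **G1 coupling.** Available notch-1 is *n* = 0.68 · F0 (masking), and
  G1(*n*) = G1min + (G1max − G1min)·e^(−β·n), lognormal-noised
  (CV 0.15), with S+G2+M fixed at 440 min. Calibrated defaults (β = 3.2,
  G1min = 5 min, G1max from G1(0.68) = 460) give a 900-min control
  cycle, a 5.4-fold mitotic-slope reduction under antisense knockdown,
  and a ≈2.4-fold initial acceleration under an exogenous antisense
  bolus.

Around the core sit the analysis modules the study design needs:
sequence-level transcript fate (PTC scanning with the 50-nt
exon-junction rule, editing simulation, phase-gated pool mass balance),
ΔCt normalization of locus distribution across DNA supercoiling zones
(f_i = 2^ΔCt_i / Σ 2^ΔCt_j) with a permutation shift test, Nussinov
base-pairing propensity z-scores for tandem exon pairs, cumulative
mitotic-rate statistics (OLS slopes, fold changes,
deviation-from-linearity breakpoints), and a seeded synthetic-data
module that generates every input.

## Worked example

```r
library(nascycle)
p <- sim_params()

# closed-form mass balance: synthesis blocked leaves half the titer
nAS25_titer_at_G1_exit(1, p, scenario("roscovitine"))$total
#> [1] 0.5

# stochastic lineage simulation, 150 tracked founders over 1500 min
rec <- simulate_lineage(150, 1500, p, scenario("control"), rng_seed = 1)
summary(rec)
#> Lineage simulation (control)
#>   cells: 830   divisions: 340
#>   mean completed cycle: 894.4 min   mean G1: 468.8 min
#>   mean G1-exit titer: 1.007

# transgenerational compensation: long-G1 mothers make fast-G1 daughters
cs <- compensation_statistics(rec)
round(c(g1_correlation = cs$g1_correlation,
        period = cs$oscillation_period,
        interphase = cs$mean_interphase), 2)
#> g1_correlation         period     interphase
#>          -0.70         917.50         829.86

# mitotic-rate fold change, control over antisense knockdown
kd <- simulate_lineage(150, 1500, p,
                       scenario("rnai_nAS25", efficiency = 0.9),
                       rng_seed = 2)
fc <- rate_fold_change(
  linear_rate(cumulative_curve(division_events(rec$events$time), 10, 1500)),
  linear_rate(cumulative_curve(division_events(kd$events$time), 10, 1500)))
round(fc$ratio, 2)
#> [1] 4.97

# supercoiling-zone fractions from one replicate of delta-Ct values
normalize_zones(c(0, 0.4, 1.1, 1.9, 2.6))
#> Zone distribution (fractions):
#>   zone_I  zone_II zone_III  zone_IV   zone_V
#>   0.0701   0.0925   0.1503   0.2618   0.4252
```

The titer homeostasis (mean G1-exit titer ≈ 1), the ≈900-min cycle, the
negative mother–daughter G1 correlation with an oscillation period near
the interphase length, and the ≈5-fold slope reduction at one seed are
the model's headline behaviours; the knockdown fold change averages 5.4
over seeds.

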