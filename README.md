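# DomainCoupling

Quantitative analysis of **domain–domain coupling in multidomain membrane
transporters** (ABC transporters such as CFTR, MRP1 and ABCC6), for
structural biologists working with HDX-MS, equilibrium unfolding and MD
trajectories. The folding of these transporters is cooperative: interfaces
between the nucleotide-binding domains (NBD1/2), the transmembrane domains
and their coupling loops (CLs) stabilise each other, and mutations or
stabilising suppressor sets at one interface propagate allosterically to
distant sites. This package turns four raw data streams into coupling
energetics and network quantities:

1. **HDX uptake kinetics** — peptide-level deuterium uptake
   `D(t) = A0 + Σ Ai (1 − exp(−k_HXi t))` fit by bounded nonlinear least
   squares (mono-/biexponential, AICc order selection); differential maps
   Δ%D(state B − state A) with two-tailed Welch t-tests; opening
   free-energy differences `ΔΔG° = −R·T·ln(k_A/k_B)` from exchange-rate
   ratios (R = 1.986 cal/(K·mol)).
2. **EX1 kinetics** — bimodal isotope envelopes deconvoluted into a folded
   fraction F_f per labeling time (joint two-Gaussian mixture with profiled
   mixing fraction); `ln F_f = −k_u·t` fit through the origin; Eyring
   inversion `ΔG‡ = R·T·ln(k_B·T/(h·k_u))` and activation-energy
   differences.
3. **Equilibrium stability** — two-state urea titrations
   (`ΔG° = −R·T·ln K`, linear extrapolation to water), temperature
   extrapolation of ΔG° and of unfolding rates to 37 °C, Boltzmann T_m
   fits of thermal melts.
4. **Trajectory networks** — per-residue RMSF, fraction of native contacts
   Q, mutual-information generalized correlation
   `r_MI = sqrt(1 − exp(−2I/3))` (Kraskov k-NN estimator in C++), residue
   networks with `−log(C_ij)` edge distances, Girvan–Newman communities,
   betweenness centrality and inter-community coupling scores.

A first-class synthetic-data module generates every input type with
planted ground truth (exchange rates, folded-fraction decays, stability
parameters, correlation-block community structure, contact loss), so the
entire pipeline is testable end to end without any external download.

## Worked example

Simulate a wild-type-like and a stabilised state of one peptide, fit their
uptake kinetics, and convert the rate ratio to an opening free-energy
difference:

```r
library(DomainCoupling)

wt  <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60, rates = 0.01,
                                    noiseSd = 1, seed = 1),
                      PeptideRecord("WT", 1033, 1043))
mut <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60, rates = 0.002,
                                    noiseSd = 1, seed = 2),
                      PeptideRecord("6SS", 1033, 1043))
(fit_wt  <- fitUptake(wt,  order = 1))
#> UptakeFit (order 1): A0 = 10.22 %D
#>   A1 = 59.42 %D, k_HX = 0.0106 /s
(fit_mut <- fitUptake(mut, order = 1))
#> UptakeFit (order 1): A0 = 9.54 %D
#>   A1 = 62.22 %D, k_HX = 0.00195 /s
ddGFromRates(fit_wt, fit_mut, temperature = 310.15)
#> ddG_open(A-B) = -1.042 kcal/mol at 310.15 K (approximate (EX2 assumed; temperature-jump protocol))
```

The planted rates (0.01 vs 0.002 /s at the {10, 240, 1200 s} labeling
schedule, 3 replicates, 1 %D noise) are recovered within a few percent,
and the 5-fold rate ratio maps to about −1.0 kcal/mol: the slower-exchanging
state is more protected, i.e. its local opening costs ~1 kcal/mol more.

EX1 kinetics from bimodal envelopes, end to end:

```r
env <- simulateEx1Envelopes(ex1SimSpec(ku = 1e-3, noiseSd = 0.02, seed = 3),
                            PeptideRecord("WT", 487, 499))
(bf <- deconvoluteEnvelope(env))
#> BimodalFit: centroids 0.00 / 6.00 Da, widths 1.00 / 1.01 Da
#>   F_f: 1.000 0.942 0.786 0.548 0.301
fitUnfoldingRate(bf, temperature = 310.15)
#> k_u = 0.001001 /s; dG_act = 22.42 kcal/mol at 310.15 K (5 points)
```

The planted unfolding rate (1e-3 /s) is recovered within 0.2% and converts
to a 22.42 kcal/mol unfolding activation energy at 37 °C.

Whole analyses can also be driven from a YAML config via `runPipeline()`
(stages: `simulate`, `fit-uptake`, `diff-map`, `ex1`, `stability`,
`network`, `report`), or from a shell through the thin wrapper in
`inst/scripts/domaincoupling.R`. Outputs are written at fixed precision,
so a (config, seed) pair reproduces byte-identical files.

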