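# ch4box

Isotopic mass-balance attribution of decadal atmospheric methane change,
for atmospheric and biogeochemical scientists who want to test emission
hypotheses against the paired CH₄ / δ¹³C-CH₄ record.

Atmospheric methane plateaued around 2000–2006 and resumed growing after
2007 while its carbon-isotope ratio drifted lighter. Because source
categories carry distinct δ¹³C signatures (biogenic ≈ −60‰, fossil ≈ −45‰,
pyrogenic ≈ −24‰) and the OH sink fractionates (ε < 0 enriches the residual
atmosphere), the two observed records jointly constrain which mix of source
and sink changes is consistent with the data. `ch4box` implements the full
pipeline:

* a **two-hemisphere ¹²CH₄/¹³CH₄ box model** with annual explicit steps

  m<sup>N</sup>(t+1) = m<sup>N</sup>(t) + (S<sup>N</sup> − k·m<sup>N</sup> −
  (m<sup>N</sup> − m<sup>S</sup>)/2τ<sub>ex</sub>)·Δt,
  with k¹³ = (1 + ε/1000)·k¹² and
  δ¹³C = 1000·((m¹³/m¹²)/R<sub>std</sub> − 1), R<sub>std</sub> = 1.12372%
  (VPDB);

* **inverse mode**: an exact per-year algebraic solve for the OH removal
  rate reproducing the observed CH₄ record, bracketed root finding for the
  sink fractionation ε matching the observed δ¹³C at the study onset, and a
  per-year 2×2 linear solve for idealized wetland flux + OH reproducing
  both tracers at once;

* a **factorial emission-scenario ensemble** (default 4 IFF × 3 AGW × 2 WET
  × 2 BB × 2 GEO = 96 scenarios) with 1000 Monte Carlo draws of
  emission-weighted source-signature uncertainty per scenario;

* **scoring and selection**: Taylor statistics, RMSE and mean squared
  difference (MSD) of simulated vs observed δ¹³C, with the "most likely"
  subset defined as the first percentile lowest MSD;

* **attribution**: per-category mean-flux changes of the growth periods
  (1993–1999, 2007–2012, 2013–2017, 2007–2017) relative to the 2000–2006
  plateau, percent shares across IFF/AGW/WET, and ¹³CH₄-mass share changes;

* a **synthetic-data generator** producing gridded sector emissions,
  signature maps with Gaussian cell uncertainty, and pseudo-observations
  from a known truth, so the whole pipeline is testable without any
  external data.

## Worked example

```r
library(ch4box)

world <- generate_world(truth_config(seed = 42))   # synthetic truth + pseudo-obs
head(world$obs[, c("year", "ch4_ppb", "d13c_permil")], 3)
#>   year  ch4_ppb d13c_permil
#> 1 1993 1736.000   -47.30000
#> 2 1994 1737.790   -47.60469
#> 3 1995 1739.735   -47.91020

# fit the sink fractionation for the true sources (recovers the truth, -6.9)
fit_epsilon(world$truth$forcing, world$obs, world$truth$init)$epsilon
#> [1] -6.9

# 96 scenarios x 100 signature draws; each run refits epsilon, inverts OH,
# runs forward and is scored against the observed delta-13C
ens <- run_ensemble(world, n_draws = 100, seed = 42)
head(ens$scores[order(ens$scores$msd), c("run_id", "msd", "r", "epsilon")], 3)
#>                                    run_id          msd         r   epsilon
#> 440 S005_truth.truth.nostep.truth.low_d40 1.098899e-07 0.9999999 -6.857316
#> 1     S001_truth.truth.truth.truth.low_d1 1.192887e-07 0.9999999 -6.885403
#> 40   S001_truth.truth.truth.truth.low_d40 1.998585e-07 0.9999999 -6.857316

att <- attribute_ensemble(ens)        # over the 96 selected (1%) runs
att$shares$post2007$summary
#>   category delta_mean delta_sigma share_mean share_sigma
#> 1      IFF      12.12        1.75      34.73        4.35
#> 2      AGW      20.84        1.92      60.32        7.00
#> 3      WET       2.09        3.67       4.95       10.32
```

Reading the output: the lowest-MSD runs are the truth-scenario runs (and
near-truth variants), with fitted ε within 0.05‰ of the generating value;
the attribution over the selected subset recovers the synthetic world's
design — the post-2007 methane rise is dominated by agriculture/waste
(`AGW`, here ~60% of the IFF+AGW+WET change, Δ ≈ 21 Tg yr⁻¹), with
industrial fossil fuels (~35%) and wetlands (small, uncertain) behind it.

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ch4box.R", package = "ch4box"))') \
    ensemble --seed 1 --draws 1000 --out-dir out
```

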