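---
title: "Attributing the rise of atmospheric methane with a two-box isotope model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing the rise of atmospheric methane with a two-box isotope model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4box)
```

## The scientific problem

Atmospheric methane stopped growing around 2000–2006 and resumed growing
after 2007, while the global mean δ¹³C-CH₄ value — the per-mil deviation of
the ¹³C/¹²C ratio from the VPDB standard — drifted toward lighter
(more negative) values. Because the major source categories carry distinct
carbon-isotope signatures (biogenic sources near −60‰, fossil sources near
−45‰, pyrogenic sources near −24‰) and the OH sink preferentially removes
¹²CH₄, the pair (CH₄, δ¹³C-CH₄) constrains which mix of source changes and
sink variability can explain the observed record. `ch4box` implements this
isotopic mass-balance attribution as a reusable, fully testable pipeline:
a two-hemisphere ¹²CH₄/¹³CH₄ box model run in inverse and forward mode, a
factorial ensemble of emission scenarios with Monte Carlo signature
uncertainty, mean-squared-difference scenario selection, an idealized
wetland inversion, and period-based attribution.

## The box model

Each hemisphere is a perfectly mixed box holding the masses of the two
isotopologues, ¹²CH₄ and ¹³CH₄ (Tg). Annual explicit difference equations
update each box with its net source, first-order sink loss, and symmetric
interhemispheric exchange:

$$ m^N(t+1) = m^N(t) + \Big( S^N(t) - k(t)\,m^N(t)
   - \tfrac{1}{2\tau_{ex}} m^N(t) + \tfrac{1}{2\tau_{ex}} m^S(t) \Big)\,\Delta t $$

and symmetrically for the southern box. ¹³CH₄ uses the same equation with
its own sources and the fractionated rate $k^{13} = \alpha\,k$, where
$\alpha = 1 + \varepsilon/1000$ and $\varepsilon$ (‰, negative) is the
sink-weighted kinetic fractionation. δ values are reported via
$\delta = 1000\,( (m^{13}/m^{12}) / R_{std} - 1 )$ with the VPDB ratio
$R_{std} = 1.12372\%$; the global δ always comes from mass-summed
isotopologues, never from averaging hemispheric δ values.

Design choices worth stating explicitly:

* **Annual explicit stepping, not an ODE solver.** The budget is posed as
  difference equations on annual data; the inverse solvers below are exact
  for precisely this discretization, so forward and inverse modes are
  algebraically consistent by construction. A continuous solver would break
  that exactness without adding information at annual resolution.
* **Full two-isotopologue bookkeeping.** Sources are split exactly,
  $^{13}S/^{12}S = R_{std}(1+\delta/1000)$ with $^{12}S + {}^{13}S = S$,
  rather than the common linearization $^{13}S = R\,S$; this removes a ~1%
  bias at the source at no cost. δ appears only at reporting time.
* **Sinks.** The removal rate is OH-driven and year-varying; minor sinks
  (Cl, stratosphere) are absorbed into a constant `k_minor` (0 by default)
  with their fractionation folded into the single total ε. Soil uptake is
  treated as a flux subtraction in the net source (see below), not a rate.
* **Units.** ppb ↔ Tg conversion uses 2.767 Tg per ppb, the standard
  whole-atmosphere factor obtained from the dry-air mass
  ($\approx 5.13\times10^{21}$ g, mean molar mass 28.97 g mol⁻¹) and the
  CH₄ molar mass, with the conventional correction for incomplete
  stratospheric mixing. It is a configuration constant
  (`unit_convention()`), surfaced in all outputs, because the attribution
  results are insensitive to its exact value (it cancels in δ and acts as
  a common scale on masses). Hemispheric boxes hold equal air masses.
* **Exchange time** $\tau_{ex}$ = 1 yr, constant; global results are
  insensitive to it because exchange conserves global totals exactly.

## Inverse mode

**OH inversion.** Given an emission scenario and an observed CH₄ record,
`invert_oh()` solves, per year, the global mass balance for the OH rate so
that the simulated concentration equals the observation at year end. The
balance is linear in $k_{OH}$ given the start-of-year state, so the solve is
algebraic (no iteration) and the nested forward run reproduces the CH₄
record to machine precision — the tests require < 10⁻⁶ ppb. Years whose
implied rate is non-positive (observed growth exceeding the sources) are
flagged and the run marked infeasible rather than aborting the ensemble.

**Fractionation fitting.** ε is not well constrained a priori (the Cl sink
alone gives it a wide range), so `fit_epsilon()` chooses ε per run such
that the simulated δ¹³C matches the observed mean over the onset window of
the study period. The window is the first 3 observation years by default —
a single year would propagate observation noise straight into ε. The
residual is monotone in ε (a more negative ε leaves the atmosphere heavier),
so bracketed root finding on [−12, −1] ‰ is reliable; a missing sign change
is reported with the bracket residuals. ε is fitted with the OH inversion
nested inside (ε outer, OH inner). The alternative — joint estimation — is
not needed because the CH₄ balance is almost independent of ε (ε enters
only through the ~1% α-weighting of ¹³CH₄ mass).

**Idealized wetland inversion.** To ask how large wetland emissions would
have to be to reproduce *both* observed tracers, `invert_wetland()` solves,
per year, the 2×2 linear system in (wetland flux, $k_{OH}$) given by the
¹²CH₄ and ¹³CH₄ balances, marching forward year by year — this is what
linearizes the problem. The system becomes singular exactly when the
wetland isotopologue ratio equals the post-fractionation atmospheric
composition ($R_w = \alpha R_{atm}$): such years are flagged, solved
without the wetland increment, and reported. Negative wetland fluxes are
retained with a warning rather than clipped, because they are diagnostic of
an inconsistent scenario. The solved global flux is placed in the
hemispheres by a fixed fraction (`n_frac`), since a single global constraint
cannot determine the split.

## Emission scenarios and the factorial ensemble

A scenario picks one candidate per category — IFF (coal, oil, gas), AGW
(enteric fermentation, manure, rice, landfills, waste), WET, BB, GEO — and
shares a single OTH series and a constant climatological soil sink. The net
source is $S_{tot} = S_{IFF} + S_{AGW} + S_{WET} + S_{BB} + S_{GEO} +
S_{OTH} - S_{soil}$ per hemisphere and year. The default factorial is
4 × 3 × 2 × 2 × 2 = 96 scenarios, enumerated in a stable lexicographic
order. The soil sink defaults to 30 Tg yr⁻¹ split 2:1 north:south — a
documented placeholder, overridable, as process-model climatologies differ.
Subtracting a flux from an isotopologue budget requires a composition for
the removed methane; soil uptake removes near-atmospheric methane, so it is
assigned a fixed near-atmospheric signature (−47.3‰, configurable) with the
small soil fractionation folded into the fitted total ε.

## Signature uncertainty

Emission-weighted source signatures are computed per category and
hemisphere as $\sum F_c \delta_c / \sum F_c$ over grid cells (cell-center
latitude decides the hemisphere; cells are not split at the equator).
Uncertainty is propagated by Monte Carlo: 1000 perturbed maps per mapped
source, cell-wise independent Gaussian at the map's 1-σ layer, clipped to
[−120, 10] ‰ to guard unphysical tails; scalar sources are drawn the same
way. Cell-wise independence is the least-informative reading of a Gaussian
uncertainty map; a category-level offset mode would be the natural
sensitivity variant. Every draw uses a counter-based substream of one
master seed, so draw *i* of source *s* is reproducible in isolation and
ensembles are order-independent.

## Scoring, selection, attribution

Each run's simulated global δ¹³C series is scored against observations over
1993–2017 with MSD (= RMSE²), Pearson correlation, series standard
deviations and centered RMSE; standard deviations use the n-denominator so
the Taylor identity $crmse^2 = sd_{sim}^2 + sd_{obs}^2 - 2\,sd_{sim}\,
sd_{obs}\,r$ holds to rounding error. MSD is unweighted — the stated
observational δ uncertainty (0.04‰) is essentially flat in time, so
weighting would not reorder runs; a weighted option exists but is off by
default. The most likely subset is the lowest floor(p/100·n) runs by MSD
(first percentile by default; 96 000 runs → 960), ties broken by stable run
order.

Attribution compares period means against the 2000–2006 plateau: decreased
growth 1993–1999, renewed growth 2007–2012, accelerated growth 2013–2017,
and the post-2007 composite 2007–2017. Percent shares divide each
category's flux change by the summed change of the three headline
categories (IFF, AGW, WET); BB, GEO and OTH changes are reported separately
rather than in the denominator, since the share statement concerns the
growth attribution among the major movers. Shares are computed per run and
summarized as mean ± 1σ across the selected runs (not across scenario
means — the Monte Carlo draws contribute real spread). Runs with mixed-sign
changes keep their raw shares, which can leave [0, 100]%; runs whose summed
change is ~0 are excluded with a count. ¹³CH₄-mass shares are computed from
the exact isotopologue split per category and year, and reported as period
changes versus the plateau.

## The synthetic world

No real inventory or signature maps ship with the package; instead
`generate_world()` builds a self-consistent world from a known truth so
every stage is testable end to end:

* ~15 emitting sectors on a coarse 18 × 36 grid with stylized latitudinal
  placement (tropical + boreal wetlands, northern mid-latitude coal,
  tropical biomass burning, ...) — the masks only need to create
  hemispheric contrast, not realism.
* Sector totals follow base + trend + step + Gaussian interannual
  variability. The defaults encode the study conditions: an
  agriculture-dominated rise (AGW trend ≈ 2.3 Tg yr⁻¹ yr⁻¹), a slower
  fossil-fuel rise with coal accelerating after 2003, a +7.3 Tg yr⁻¹
  tropical-wetland step in 2007, declining biomass burning, geological
  15 Tg yr⁻¹.
* Signature means: coal −45.8, oil & gas −43.8, livestock −65.4, tropical
  wetlands −56.7, boreal wetlands −67.8, biomass burning −23.9 ‰, with
  cell-level σ of 1.5–3 ‰ for the mapped sources.
* True sinks: $k_{OH}$ = 0.109 yr⁻¹ with a ±1% sinusoidal anomaly
  (11-yr period), ε = −6.9‰, $\tau_{ex}$ = 1 yr. The implied lifetime
  (~9.2 yr) sits in the literature band.
* Pseudo-observations are the forward run of the truth, optionally with
  Gaussian noise (defaults: none on CH₄, none on δ; the *reported* δ
  uncertainty stays 0.04‰).

The scenario catalogue embeds the truth as candidate 1 of every category
and adds systematic variants (trend offsets emulating inventory spread, a
flat upward-revised fossil variant, a no-step wetland variant, a
non-declining biomass-burning variant, geological 15 vs 52 Tg yr⁻¹).

What the generator deliberately does **not** emulate: spatial patterns are
fixed in time (so a candidate's emission-weighted signature is constant
across years; in real data signature IAV comes from shifting flux
patterns), cell perturbations are uncorrelated, there is no seasonal cycle,
no interhemispheric observation gradient, and observation noise is white.
Passing tests therefore demonstrate the machinery — exact inversion,
unbiased weighting, correct selection under a known truth — not the
realism of any particular bottom-up inventory.

## Numerical choices

* ε bisection/root finding to 10⁻⁴ ‰ (tests require recovery within
  0.01 ‰); the ensemble engine uses 30 fixed bisection iterations
  (≈ 10⁻⁸ ‰), verified against the scalar `fit_epsilon()` path.
* The per-year OH solve is exact; feasibility requires $k_{OH} > 0$ every
  year.
* The wetland 2×2 solve is flagged near-singular when |det| falls below
  10⁻¹⁰ of the balance scale.
* Signature draws are clipped to [−120, 10] ‰; with the default σ ≤ 3‰ the
  clip never binds.
* Selection subset size uses floor(); 96 000 × 1% = 960 exactly.
* A constant series has OLS slope 0 with p = 1 by convention.

## Problem sizes

The package's standard experiment is the full 96-scenario × 1000-draw
ensemble over 25 annual steps (~30 s on one core, since the engine marches
all runs simultaneously as vectors with vectorized ε bisection). The test
suite exercises the same pipeline at reduced draw counts (8–50 per
scenario) plus the full-size run once, and uses 20 seeds for wetland-trend
recovery and 1000 replicates for the trend-test type-I rate.

## Known limitations

* Hemispheric δ¹³C observations are not assimilated; only the global value
  is scored (interhemispheric-transport uncertainty would otherwise leak
  into the scores).
* The OH inversion attributes *all* removal-rate variability to OH; if the
  minor sinks varied, their variability would be misattributed.
* The idealized wetland inversion needs a prescribed hemispheric split and
  a single (possibly year-varying) wetland signature; a two-hemisphere
  wetland unknown would make the yearly system underdetermined.
* Attribution shares are undefined for runs whose headline categories'
  changes cancel; such runs are excluded and counted rather than imputed.
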