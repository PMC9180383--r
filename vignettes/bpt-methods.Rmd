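---
title: "Methods: the benefit-per-ton chain for dioxin emission reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the benefit-per-ton chain for dioxin emission reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpthia)
```

## The model and its assumptions

`bpthia` monetizes the expected cancer mortality attributable to
emissions of dioxin-like compounds and expresses it per gram of TEQ, so
that emission-reduction plans can be compared against their costs. The
chain is the reduced-form impact-pathway approach:

1. **Dose to risk.** The lifetime average daily dose `LADD` (pg-TEQ/kg/day)
   times the cancer slope factor `CSF` gives the excess lifetime cancer
   risk. The CSF is age-invariant; age groups differ only through their
   doses (dietary and inhalation patterns) and populations.
2. **Risk to deaths.** Risk times the exposed population gives expected
   cancer cases; cases times the cancer mortality risk (one minus the
   all-cancer survival rate) gives expected deaths. Counts remain
   fractional throughout — the chain is continuous, and rounding is a
   formatting concern.
3. **Deaths to money.** Expected deaths times an age-specific value of a
   statistical life (VSL) gives the monetized mortality `mdc` in USD.
4. **Money to per-gram benefit.** Dividing by the emission mass `E`
   (grams TEQ) of the region and period yields the benefit per gram at
   the age-group, regional, or national level. The national aggregate is
   a first-class region with its own dose and risk, not a sum of
   sub-regions.

The per-gram framing assumes uniform mixing: a gram emitted (or abated)
anywhere in the domain has the same health consequence. This is the
standard reduced-form simplification; it cannot resolve siting questions.

The **net** benefit of a reduction plan compares two emission paths for
the same monetized burden: `netBPT = mdc × (1/E_policy − 1/E_baseline)`.
The published presentation of the Taiwan results does not state this
formula explicitly; it is the unique reading that reproduces the
published per-gram tables, and the package documents it as inferred. Note
its implication: because the baseline divisor stays at the base-year
emission level while the policy divisor shrinks, net benefit per gram
grows steeply as the policy path approaches zero — late, deep cuts
dominate the cumulative total.

## Key parameters

| Parameter | Default (Taiwan scenario) | Units | Notes |
|---|---|---|---|
| `csf` | 1.0e-4 | per pg-TEQ/kg/day | TCDD-based slope factor |
| `mortality_risk` | 0.2278 | probability | 1 − 0.7722 one-year all-cancer survival |
| VSL (children / working-age / older) | 2.19M / 12.33M / 25.75M | USD, 2020 | age-specific schedule bases |
| discount rate | 0.02 | per year | 20-year real government-bond rate |
| exchange rate | 31.807 | TWD/USD | 2001–2020 average; applied on ingest only |
| regional shares | 0.4448 / 0.2488 / 0.2770 / 0.0246 | fraction | northern/central/southern/eastern |

The VSL transfer applies an earnings elasticity (0.2476) to the percent
wage change between the study year and the analysis year, then deflates
by the CPI ratio; the two adjustments commute, and their composition is
a plain product of factors.

## Reporting conventions of the source tables

Three conventions were reverse-engineered from the published tables and
matter for cell-level reproduction; all are encoded in the packaged
scenario rather than guessed at run time.

* **Risk table over dose table.** The published dose and risk tables
  disagree in one cell (the national children's dose is printed two
  orders of magnitude below what the risk and slope factor imply). Every
  downstream number follows the risk table, so the scenario stores risks
  and back-derives doses as `risk / CSF`.
* **Four-decimal expected deaths.** The published monetized-mortality
  table was printed from expected deaths rounded to four decimal places.
  With that convention (`deaths_digits = 4` on the scenario) all 165
  cells reproduce to within about one dollar; without it, cells with
  tiny death counts — the sparsely populated eastern region above all —
  deviate by up to ~40%, including an apparent jump in one row that is
  exactly the rounding step from 0.0002 to 0.0003 deaths. Synthetic
  scenarios leave `deaths_digits` unset.
* **One illegible cell.** One northern-children cell of the published
  monetized table prints only its trailing digits; the four-decimal
  convention pins it at 42,378 (consistent with both the legible
  fragment and the published per-gram table), and the packaged copy
  flags it `reconstructed`.

Because published values are whole dollars, printed-table comparisons in
the tests use a relative tolerance plus a US$2 absolute slack per cell;
cumulative comparisons widen the absolute term by the number of summed
cells.

The published VSL schedule declines by roughly 0.76% per 5-year period,
which the stated 2%/year discounting does not reproduce (the published
schedule also averages over within-group ages, for which per-age values
are not printed). The packaged schedule is therefore the canonical
`fixture` convention, and a clean `geometric_annual` convention — the
period mean of annual factors `(1+r)^-(y-y0)` — is provided for
synthetic scenarios.

## The synthetic-data generator

`generate_scenario()` draws scenarios with the structure the analysis
assumes: K sub-regions plus a national aggregate, three age groups, a
base period plus 5-year intervals. Its defaults are fixed at the Taiwan
study conditions: doses log-uniform over the span of the published
regional values (8.37e-5 to 2.79e-2 pg-TEQ/kg/day), per-cell populations
uniform over the published regional range with a 2.83% per-period
decline (about a 25% fall over ten periods), VSL bases spanning the
published age-group values and discounted at 2%/year, regional base
emissions spanning 0.68–32 g, and a linear reduction to 50% of base by
the final period. Identical seeds give identical scenarios, and
generation never disturbs the caller's RNG stream.

What the generator does *not* emulate: cohort-component demographic
structure (drift is a uniform decline), correlation between dose and
population density, region-specific reduction schedules, and any
within-period dynamics. Tests passing on synthetic scenarios therefore
demonstrate the arithmetic and its invariants — linearity, homogeneity,
additivity, grid preservation — not demographic realism.

## Numerical choices

* Money is double-precision USD end to end; there is no internal
  rounding except the explicit `deaths_digits` reproduction convention.
* Aggregation computes real-valued group-level nets and sums them;
  published tables round per group before summing, which the absolute
  tolerance terms absorb.
* Per-gram division is guarded: zero or negative emissions raise a
  structured validation error rather than yielding infinities.
* Scenario bundles are written with shortest-round-trip decimal
  formatting and re-read with base R's correctly rounded parser, so a
  write/read cycle is bit-exact.
* Validation returns findings (severity, key path, message) instead of
  throwing; the pipeline refuses to run only on error-severity findings.
  Sub-region population shares may sum to slightly less than 1 (excluded
  offshore areas); more than 1% unallocated draws a warning, any excess
  over 1 an error.
* Uncertainty sweeps re-run the full pipeline per multiplier with all
  other parameters untouched; because the chain is multilinear, a
  uniform VSL multiplier moves every benefit value by exactly that
  multiplier, which the tests assert to machine precision.

## Problem sizes

The packaged scenario is 3 age groups × 5 regions × 11 periods; a full
pipeline run takes well under a second. Property tests run the generator
at 2–4 regions and 3–5 periods with fixed seeds, cross-checked against a
plain-loop oracle at relative error below 1e-12.

## Known limitations

* Uniform mixing: per-gram benefits carry no spatial gradient, so the
  framework ranks regions by burden, not by source location.
* A single all-cancer endpoint with a linear, threshold-free
  dose-response; no cancer-type or latency structure.
* Doses are held constant across periods (the published tables print a
  single dose table; only populations, VSLs and emissions vary in time).
* The cumulative phase totals published alongside the Taiwan tables
  contain two internal inconsistencies (one regional 2021–2050 total and
  one phase ratio) that cannot be reproduced from the per-period tables;
  the package follows the tables.
* Monte Carlo propagation of dose uncertainty is out of scope (the
  published dose simulation's input parameters are unavailable); the
  sweep module covers one-at-a-time perturbations only.
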