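---
title: "Methods: a six-state Markov cohort model for in situ breast cancer surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a six-state Markov cohort model for in situ breast cancer surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insituCEA)
```

## The decision problem

Carcinoma in situ of the breast (ICD-10 D05) can be managed by mastectomy,
by lumpectomy alone, or by lumpectomy followed by irradiation. All three
achieve similar survival; they differ in long-term recurrence risk, in
quality of life after surgery, and in cost. `insituCEA` implements a
cost-utility comparison of the three strategies for a Swedish cohort
entering at age 58, following each hypothetical patient for 30 one-year
cycles — effectively a lifetime horizon.

## Model structure and assumptions

The cohort moves between six health states: cancer-free after successful
primary surgery (A), loco-regional recurrence (B), remission after
recurrence (C), distant metastasis (D), remission after metastasis (E) and
death (F, absorbing). The permitted transitions are A→{A,B,D,F}, B→{B,C,F},
C→{C,D,F}, D→{D,E,F}, E→{E,F}: remission states never return to the
cancer-free state, and repeated recurrences are modelled as continued
occupancy of the disease state. Primary surgery is assumed successful, with
no complication sub-model; the strategies differ only in the A→B recurrence
probability, in the State A utility weight, and in costs. All of this is
fixed topology — the package deliberately supports no other state graph.

## Transition probabilities

Annual probabilities are derived from two kinds of published evidence:

* **Cumulative incidences.** An event proportion `CI` observed over `T`
  years implies a constant rate `r = -log(1 - CI)/T` and an annual
  probability `p = 1 - exp(-r)` (`prob_from_cumulative_incidence()`). The
  six disease transitions tpA2D, tpB2C, tpB2F, tpC2D, tpD2E, tpD2F are
  stored as their rounded published values (0.008, 0.165, 0.065, 0.230,
  0.375, 0.178) together with the source (CI, T) pairs, and the derivation
  is verified against the stored values in the test suite.
* **Incidence rates.** Loco-regional recurrence is strongly time-dependent,
  so A→B uses per-window incidences (per 1000 person-years) over the
  windows [0,5), [5,10), [10,30) years, converted by
  `p = 1 - exp(-rate/1000)` (`prob_from_rate()`). Window membership of
  cycle `t` (0-based) is half-open: cycles 0–4, 5–9, 10–29 — a boundary
  year belongs to the later window, which partitions the horizon
  unambiguously. No Swedish mastectomy incidence exists, so the mastectomy
  schedule divides the lumpectomy-without-irradiation incidences by the
  incidence rate ratio 1.27 observed between those arms in a US trial
  (71.70 → 56.46 per 1000 person-years in the first window, and so on).

Background mortality enters from a life table as the annual death
probability `mor_gp(age)` at integer attained age `entry_age + cycle` (no
interpolation; ages beyond the table's coverage reuse its oldest rate). It
is the sole death probability from A, C and E, and is *added* to the
disease-specific death probabilities from B and D, with the
stay-probability absorbing the deduction. Whether the underlying trial
estimates of tpB2F and tpD2F should be treated as disease-specific (and
background mortality added, risking mild double counting) or as all-cause
is genuinely open; the additive reading follows the stated construction of
the original model, and `options$bg_mortality_additive = FALSE` provides
the alternative (it shifts the healthcare ICER by about +4%). If an
infeasible row ever arises (death probability above 1, possible only under
extreme sampled parameters), death is capped at 1, the other exits are
zeroed and a warning is emitted.

## Costs, perspectives and valuation conventions

All costs are in SEK, price year 2020; the packaged 2005→2020 inflation
factor 10,003/8,350 ≈ 1.198 is the one implied by the informal-care cost
pair, which keeps the package self-contained and reproduces the metastasis
state cost of 499,343 SEK from its 2005 source value to within 0.01%.

Costs accrue only in states A, B and D; remission and death are costless.
State B costs 17,680 SEK/year after mastectomy (adjuvant radiotherapy plus
hospitalisation) and 87,670 SEK/year after either lumpectomy (a salvage
mastectomy episode); State D costs 499,343 SEK/year in every arm. State A
accrues the arm's baseline surgery cost — 87,670 / 27,655 / 50,352 SEK for
mastectomy, lumpectomy without and with irradiation — in *every cycle of
occupancy*, not only at entry. This per-cycle convention is deliberate: it
is the only cost scope under which the model reproduces the published
deterministic results for this decision problem (total healthcare costs
around 1.2 M / 0.63 M / 0.86 M SEK and mastectomy strongly dominated);
charging surgery once at entry yields totals of a few
hundred thousand SEK and reverses the cost ordering entirely. The
alternative remains available as `options$state_a_cost = "baseline_once"`
and is reported in the convention-sensitivity table of
`analysis/02_deterministic_cea.R`.

Valuation is start-of-cycle: occupancy rows `t = 0 .. 30` are valued with
discount factor `(1+r)^-t`, so the initial all-in-A row carries the
undiscounted surgery cost and one undiscounted year at the State A
utility. The cycle-0 term matters for one qualitative result: the QALY
ordering between mastectomy (utility 0.84, fewer recurrences) and
lumpectomy without irradiation (utility 0.87, most recurrences) is nearly
balanced, and valuing the entry year tips it to the published direction
(mastectomy lowest). End-of-cycle valuation (`options$count_cycle0 =
FALSE`, rows 1–30) is the usual textbook alternative and preserves every
qualitative conclusion. No half-cycle correction is applied anywhere
(`options$half_cycle_correction` exists as a documented placeholder and is
off; the original model shows no sign of one).

The societal perspective adds two components to healthcare costs:

* **Informal care** (transportation and care by family and friends):
  10,003 SEK/year for mastectomy and lumpectomy with irradiation, halved
  (5,002) for lumpectomy without irradiation, charged per expected
  *undiscounted* alive-year across all alive states. Both choices —
  all-alive scope rather than metastasis-only, and no discounting — were
  fixed by back-solving the published societal-minus-healthcare cost gaps,
  which decompose exactly as rate × undiscounted alive-years (≈19.6 years
  with a real national life table) minus the productivity term below.
  `options$informal_care_scope = "state_D"` and
  `options$informal_care_discounted = TRUE` expose the alternatives; the
  metastasis-only scope nearly equalises the two perspectives.
* **Productivity gain**: moving from mastectomy to lumpectomy increases
  productivity by 4,104 SEK/year for the first 10 years; it is deducted
  from the lumpectomy arms as a 10-year annuity discounted at the cost
  rate (Σ 1.03^-t, t = 1..10, i.e. 35,008 SEK), not weighted by survival —
  again the back-solved convention, with survival weighting available via
  `options$productivity_survival_weighted`.

## Utilities and discounting

State A is worth 0.84 after mastectomy and 0.87 after either lumpectomy;
B 0.78, C 0.81, D 0.69, E 0.76, death 0. The remission weights are
described at source as averages of the neighbouring states; the printed
scalars match that rule for the mastectomy State A weight only
((0.84+0.78)/2 = 0.81) and are used as printed for all arms rather than
re-derived per arm. Costs and QALYs are both discounted at 3%/year, the
Swedish reference rate; both rates are exposed and the tests check that
totals are monotone in them.

## Synthetic inputs: what they emulate and what they do not

Two inputs of the original analysis cannot be shipped: the WHO Swedish
all-cause mortality schedule and the patient-level cost registry extract
(derived from a confidential national cancer registry).

* `generate_lifetable()` substitutes a Gompertz–Makeham schedule
  `q(age) = 1 - exp(-(a + b·c^age))` with defaults `a = 2e-4`,
  `b = 5.3e-6`, `c = 1.12`, calibrated so q(58) ≈ 0.004 and q(85) ≈ 0.08 —
  the order of magnitude of contemporary Swedish female mortality. It is
  smooth by construction; real tables have infant mortality, accident humps
  and cohort effects that the stand-in ignores. Absolute QALY totals are
  therefore a few percent higher than with a real (heavier-mortality)
  national table, and the packaged checks assert the qualitative results —
  dominance pattern and ICER band — rather than absolute totals. Exact
  reproduction runs should supply the real table through
  `read_lifetable()`; whether an all-person or female table is used should
  be documented with the run, as the choice shifts QALY levels visibly.
* `generate_registry()` substitutes 96 mastectomy and 629 lumpectomy
  records with Gamma-distributed costs (right-skewed, positive), each
  component parameterised from the published arm mean and standard error
  (SD = SE·√n) at the published n (96/240/389). Lumpectomy records carry no
  irradiation label, mirroring the real registry;
  `estimate_baseline_costs()` recovers the arms by splitting at the DRG
  reference cost 36,439 SEK for lumpectomy without irradiation — records
  at or below the threshold are classified as the cheaper,
  without-irradiation arm, whose mean (27,655) sits below the reference
  while the with-irradiation mean (50,352) sits above. Because the two
  Gamma components overlap, roughly 10% of records fall on the wrong side,
  so recovered arm means carry a small classification bias (within 10% of
  their targets in the packaged checks) — exactly the distortion the real
  DRG split would produce.

Passing tests on these stand-ins demonstrate that the pipeline — input
validation, splitting, conversion, simulation, summarisation — behaves
correctly, not that the synthetic data equal the confidential sources.

## Probabilistic sensitivity analysis

`run_psa()` performs 1,000 Monte Carlo iterations by default (the packaged
analyses and checks use exactly 1,000; a full run takes a few seconds).
Per draw, every uncertain parameter is sampled jointly and all three
strategies are evaluated on the *same* draw (common random parameters), so
pairwise comparisons are within-simulation, which is what permits
statements such as "mastectomy is costlier in every simulated point".

* Probabilities and utilities: Beta(α, β) as published; the shape pairs
  sum to ≈999, i.e. they encode an effective sample size of about a
  thousand around each point estimate.
* Costs: Gamma(shape, scale). The published "(alpha, beta)" pairs are
  interpreted as shape and scale because shape×scale reproduces each
  deterministic mean (4,253.80 × 6.50 ≈ 27,655); a shape/rate reading does
  not.
* Entry age: Normal(58, 11.8), truncated to [18, 100] by inverse-CDF
  remapping (deterministic given the underlying draw) and rounded to whole
  years. Sampling age moves mean PSA QALYs visibly below the deterministic
  value — older entry interacts super-linearly with mortality — which the
  tests assert as a direction, not a magnitude.
* Recurrence uncertainty: a single Beta is published for the nine
  time-dependent A→B probabilities; its mean equals the first-window
  mastectomy annual probability (0.0549). The draw is converted to a
  multiplicative shift `p*/0.0549` applied to all nine window
  probabilities (clipped to [0,1]). This perfect-correlation scheme is a
  modelling construction of this package — the source specifies neither
  the anchor nor the co-variation — and is the main PSA assumption a
  reviewer should scrutinise.
* Parameters published without a distribution (discount rates, background
  mortality, informal care, productivity, DRG reference) are held fixed;
  complements are recomputed inside the transition matrix per draw. Draws
  with an infeasible complement (tpB2C+tpB2F > 1 or tpD2E+tpD2F > 1) are
  rejected and redrawn, with a hard stop after 1,000 consecutive
  rejections; under the published distributions rejections essentially
  never occur.

CEAC curves report, for each willingness-to-pay λ on a default grid of 0
to 2,000,000 SEK in 100,000-SEK steps, the fraction of draws with positive
incremental net monetary benefit λ·ΔQALY − ΔCost.

## Incremental analysis

Strategies are sorted by QALYs; a strategy is strongly dominated if some
alternative is no less effective and no more costly (with one strict —
equal-QALY ties resolve in favour of the cheaper option). Extended
dominance then removes any strategy whose incremental ICER strictly
exceeds the next ICER up the frontier, iteratively; equal successive ICERs
are kept. The remaining frontier ICERs are classified on the Swedish
scale: below 100,000 SEK/QALY low; 100,000 to just below 500,000 moderate;
500,000 up to and including 1,000,000 high ("exceeding one million" is
read strictly); above, very high. The test suite checks frontier
membership against an independent geometric oracle (single-alternative
weak dominance plus convex-mixture dominance) on random instances.

## Numerical choices

Row sums of every transition matrix are exact by construction
(complements), and the tests require 1e-12; occupancy conservation is
checked to 1e-10 over the full horizon; the matrix-power closed form must
agree with the iterated trace to 1e-10 on time-homogeneous subcases. The
moment-consistency check between each PSA specification and its
deterministic value uses an absolute tolerance of 0.0051 for Beta means
(the published metastasis-utility Beta has mean 0.68500 against a point
estimate of 0.69 — a rounding artefact of its printed shape parameters)
and 0.5% for Gamma means; drift beyond that (e.g. a user overrides a cost
but not its distribution) warns rather than errors.

## Known limitations

* The engine's cost/QALY conventions were fixed by calibration to the
  published deterministic totals rather than first principles; all
  alternatives are switchable, and `analysis/02_deterministic_cea.R`
  reports the sensitivity table.
* No tunnel states, no cause-of-death partition, no complication or
  budget-impact modelling, no currency conversion.
* The synthetic life table and registry reproduce summary structure, not
  the confidential micro-data; absolute cost/QALY totals shift by a few
  percent under a real national mortality table.
* The A→B uncertainty model (one Beta, perfect correlation across windows
  and arms) is a package construction, as is the Gompertz–Makeham
  mortality stand-in.
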