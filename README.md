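# insituCEA

Cost-effectiveness analysis of the three surgical strategies for carcinoma
in situ of the breast (ICD-10 D05) used in Sweden — mastectomy, lumpectomy
(breast-conserving surgery) without follow-up irradiation, and lumpectomy
with irradiation — using a six-state Markov cohort model over a 30-year
horizon. The package is aimed at health economists and HTA analysts who
want to inspect, re-run or perturb every step of the analysis: parameter
handling, transition-probability derivation, the cohort engine, incremental
cost-effectiveness analysis, and probabilistic sensitivity analysis (PSA).

## The model

A cohort of women (entry age 58) starts cancer-free after successful primary
surgery and moves annually between six states:

| State | Meaning | Utility |
|---|---|---|
| A | cancer-free | 0.84 (mastectomy) / 0.87 (lumpectomy arms) |
| B | loco-regional recurrence | 0.78 |
| C | remission after recurrence | 0.81 |
| D | distant metastasis | 0.69 |
| E | remission after metastasis | 0.76 |
| F | death (absorbing) | 0 |

Disease transition probabilities come from published cumulative incidences
via the exponential conversion `p = 1 − exp(−rt)` with
`r = −log(1 − CI)/T`; the recurrence transition A→B is time-dependent
(windows 0–5, 5–10, 10–30 years) and, for mastectomy, transferred from the
Swedish lumpectomy-without-irradiation incidences through an incidence rate
ratio of 1.27. Age-specific background mortality `mor_gp(age)` is the death
probability from states A, C, E and is added to the disease-specific death
probabilities from B and D. Costs (SEK, price year 2020) accrue in states
A (the arm's baseline surgery cost, per cycle of occupancy), B
(17,680 SEK after mastectomy; 87,670 SEK after either lumpectomy, a salvage
mastectomy episode) and D (499,343 SEK for all arms). The societal
perspective adds informal care (10,003 SEK/year; halved for lumpectomy
without irradiation) over expected alive-years and deducts a productivity
gain of 4,104 SEK/year for the first 10 years in the lumpectomy arms. Costs
and QALYs are discounted at 3% per year.

Strategies are compared by incremental cost-effectiveness ratios
(`ICER = ΔCost/ΔQALY`) after excluding strongly and extendedly dominated
options, and classified against the Swedish bands: < 100,000 SEK/QALY low,
100,000–499,999 moderate, 500,000–1,000,000 high, above that very high.
The PSA redraws every uncertain parameter from its published Beta/Gamma/
Normal distribution (1,000 iterations) and summarises the draws as
CE-plane clouds and cost-effectiveness acceptability curves (CEAC).

Two inputs are confidential or external and are replaced by synthetic
stand-ins generated in code: a Gompertz–Makeham life table
(`q(age) = 1 − exp(−(a + b·c^age))`, calibrated to q(58) ≈ 0.004,
q(85) ≈ 0.08) and a 725-patient surgical cost registry (96 mastectomy,
629 lumpectomy) whose lumpectomy costs form a two-component Gamma mixture
split downstream at the DRG reference cost of 36,439 SEK. A real national
life table can be supplied via `read_lifetable()` (CSV `age,q`).

## Worked example

```r
library(insituCEA)

params    <- default_parameters()     # published base case, 2020 SEK
lifetable <- generate_lifetable()     # synthetic background mortality

tab <- cea_table(params, lifetable)
print(tab$cea$healthcare)
```

```
Incremental cost-effectiveness analysis (healthcare perspective)
         strategy      cost   qaly   acer          dominance frontier    icer category
       mastectomy 1,245,865 12.833 97,085 strongly_dominated    FALSE       -     <NA>
 lumpectomy_no_rt   654,675 12.860 50,906               none     TRUE       -     <NA>
    lumpectomy_rt   904,853 13.524 66,906               none     TRUE 376,901 moderate
```

Mastectomy accrues the fewest discounted QALYs (12.83) at the highest cost
(1.25 M SEK) and is strongly dominated by both lumpectomy alternatives;
irradiation after lumpectomy buys 0.66 extra QALYs for about 250,000 SEK,
an ICER of ~377,000 SEK/QALY — "moderate" on the Swedish scale (the
societal-perspective ICER, ~553,000 SEK/QALY, is "high"). The
probabilistic analysis keeps the same ordering in every draw:

```r
psa <- run_psa(params, lifetable, n_iter = 1000, seed = 42)
ceac(psa, c("lumpectomy_rt", "lumpectomy_no_rt"))  # P(cost-effective) by WTP
```

## Analysis workflow

The full analysis is organised as numbered drivers over the package API,
each writing its tables under `results/`:

```sh
Rscript analysis/01_synthetic_inputs.R --seed 1   # life table, registry, DRG split
Rscript analysis/02_deterministic_cea.R           # deterministic CEA + convention sensitivity
Rscript analysis/03_psa.R --seed 1                # 1,000-draw PSA, CE planes, CEACs
```

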