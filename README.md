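# lcscreen

Cost-effectiveness modelling of AI support at the baseline low-dose CT
(LDCT) scan of lung cancer screening.

LDCT screening of high-risk smokers reduces lung cancer mortality but is
burdened by false positives (invasive, costly work-up of benign nodules) and
false negatives (cancers missed until they progress). Deep-learning readers
for the baseline scan report materially better sensitivity and specificity
than standalone radiologist reads. `lcscreen` is for health-economics and
HTA analysts who want that trade-off quantified: it implements a diagnostic
decision tree feeding an annual-cycle Markov cohort model and computes
discounted costs and QALYs per strategy, the incremental cost-effectiveness
ratio (ICER) with dominance classification, deterministic (tornado) and
probabilistic (Monte Carlo) sensitivity analyses, and a threshold analysis
on the admissible per-screen price of the AI system.

## The model in brief

A cohort of 60-year-old screenees with bronchial-cancer prevalence
*p* = 0.02635 is screened once by one of two arms (CT: sens 0.779 /
spec 0.877; CT+AI: sens 0.977 / spec 0.984; both USD 161 per scan). The
screen outcome fixes the entry state of a 20-year annual Markov model with
states {no BC; no BC, suspicious nodule; BC undetected (3-year tunnel); BC
after resection (first/later years); BC palliative; dead}, background
mortality from a life table, and per-state costs and utilities. With
discounted totals *(C, E)* per arm,

    ICER = (C_ai − C_ct) / (E_ai − E_ct),
    NMB  = λ·E − C,   λ = willingness-to-pay (USD 100,000/QALY),

and because the AI cost enters only cycle 0, the maximum AI cost at a target
ICER is affine: `c* = target·ΔE − ΔC₀`.

## Worked example

```r
library(lcscreen)

params <- parameter_set()              # base-case inputs
arms   <- default_strategies()         # ct and ct_ai
lt     <- default_life_table()         # bundled synthetic US-style table

bc <- run_base_case(params, arms, lt)
bc$results$ct
#> <lcs_ce_result> ct: 3910.35 USD, 12.3142 QALYs (discounted)
bc$results$ct_ai
#> <lcs_ce_result> ct_ai: 3630.82 USD, 12.3201 QALYs (discounted)
bc$comparison
#> <lcs_icer> ct_ai vs ct at WTP 1e+05 USD/QALY
#>   incremental cost -279.53 USD, incremental effectiveness 0.00591 QALY
#>   classification: dominant (raw ratio -47293.35)

threshold_ai_cost(0, params, arms, lt)       # AI price at which ICER = 0
#> [1] 279.5282
threshold_ai_cost(100000, params, arms, lt)  # ... at which ICER = WTP
#> [1] 870.5799
```

Reading: with AI priced at USD 0, the AI arm saves USD 279.53 and gains
0.0059 QALYs per screened person — it *dominates* conventional reading
(the negative ICER is reported as a classification, not a ratio). Charging
for the AI erodes the saving dollar-for-dollar: up to USD 279.53 per screen
the arm still saves money, and up to USD 870.58 it stays below the
willingness-to-pay of USD 100,000 per QALY. (Numbers depend on the bundled
synthetic life table and the package's default accrual convention;
`replication_convention()` reproduces the published per-arm totals instead.)

Sensitivity analysis and a command-line front end:

```r
tornado(params = params, strategies = arms, lt = lt)   # one-way DSA, ranked
p <- psa(n_iterations = 30000, seed = 1,
         params = params, strategies = arms, lt = lt)  # probabilistic SA
ceac(p)                                                # acceptability curve
```

```sh
Rscript inst/cli/lcscreen.R compare --out results/
Rscript inst/cli/lcscreen.R threshold --target-icer 100000 --out results/
Rscript inst/cli/lcscreen.R psa --n 30000 --seed 1 --out results/
```

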