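# cbtvalue

Value-based pricing of cognitive behavioural therapy (CBT) for depression
in primary care.

Health-technology-assessment bodies usually take a technology's price as
given and ask whether its incremental cost-effectiveness ratio (ICER)
clears a willingness-to-pay threshold. Value-based pricing inverts the
question: given the threshold, what is the highest price at which the
technology is still worth paying for? Applied to psychotherapy, the
"price" is the fee for a 50-minute session — so the inversion yields a
value-based salary for the therapist's time. `cbtvalue` implements this
analysis for CBT versus treatment as usual in adult primary-care patients
with moderate or severe depression, from the perspective of the German
statutory health insurance (SHI).

## The model

A two-arm decision tree over a 12-week horizon. Each arm resolves into
remission / no remission; remitters hold the remission utility
(EQ-5D 0.73) for the horizon, non-remitters the severity-weighted
baseline utility (0.68 × 0.51 + 0.32 × 0.37 = 0.4652) and the two-monthly
depression-care cost. CBT raises the control remission rate (35%) by the
absolute remission reduction 1/NNT = 1/10.08 ≈ 9.9%; the comparator arm
carries the treatment-as-usual mix (10% psychotherapy, 26%
antidepressants).

Value-based pricing rests on the threshold identity

```
c / h = (p + b) / h = λ
```

with `c` the incremental cost, `h` the incremental QALY gain, `p` the
price of the CBT course, `b` the induced (non-price) incremental costs —
negative when CBT saves money — and `λ` the willingness-to-pay threshold
(€88,000/QALY). Because `c` is affine in the per-session fee `f`, solving
`ICER(f) = λ` for `f` is a closed-form linear solve; under the package's
self-referential convention the psychotherapy consumed in the comparator
arm is billed at the same fee, giving
`f = (λh − b) / (n_sessions × (1 − prop_psychotherapy))`. The
per-time-unit rate of the identity is the fee per 50-minute
session-equivalent.

Two extensions: a back-of-the-envelope suicide-aversion QALY increment
(quality-adjusted life expectancy of an averted case spread over the NNT
to avert one suicide), and a 46-month sustained-remission scenario (28%
vs 18% remission, no additional savings). A one-way deterministic
sensitivity analysis sweeps every parameter with a published 95%
confidence interval and emits a tornado table; a seeded sampler draws
whole parameter sets from those intervals to stress the pipeline.

## Worked example

```r
library(cbtvalue)

p <- default_parameters()
inc <- incremental(arm_outcomes(p, "CBT", p$cost_per_session),
                   arm_outcomes(p, "standard_of_care", p$cost_per_session))
inc
#> incremental cost EUR 1371.84, incremental QALYs 0.006567
#> ICER: EUR 208885 per QALY

value_based_price(p, wtp = 88000)
#> value-based fee: EUR 45.06 per 50-minute session (EUR 45 rounded)
#>   course price EUR 675.93 over the treatment course
#>   induced costs EUR -97.99 (negative = net savings)
#>   QALY gain 0.006567 at threshold EUR 88000 per QALY

g <- suicide_qaly_gain(suicide_inputs())
g
#> NNT to avert one suicide: 16409
#> per-patient QALY increment: 0.000914
adjusted_fee(p, g$delta_qaly)
#> value-based fee: EUR 51.02 per 50-minute session (EUR 51 rounded)
#>   ...

head(one_way_sensitivity(p), 3)
#>                 parameter   low   high  fee_low  fee_high    spread note
#> 1  effect_duration_months 3.000 46.000 45.06204 663.92502 618.86297
#> 2 abs_remission_reduction 0.027  0.172 12.51276  77.87607  65.36331
#> 3       utility_remission 0.690  0.770 38.59526  51.52883  12.93357
```

Reading: at the current fee of €103.87 the course costs €1,372 more than
usual care for 0.0066 extra QALYs (ICER ≈ €208,885/QALY, far above the
threshold), so the value-based fee is €45 per session — less than half
the current rate. Crediting CBT with averted suicides adds ~0.001 QALYs
and lifts the fee to €51. The tornado shows the duration of the remission
effect dominating every parametric uncertainty: if the effect persists
for 46 months the ICER falls to ≈ €13,515/QALY and the value-based fee
rises far above the current rate.

A thin command-line wrapper over the same functions ships at
`inst/cli/cbtvalue` (subcommands `evaluate`, `price`, `curve`, `tornado`,
`scenario`, `suicide`, `sample`).

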