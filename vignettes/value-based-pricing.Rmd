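---
title: "Value-based pricing of CBT for depression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based pricing of CBT for depression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbtvalue)
```

## The question

The German statutory health insurance reimburses a 50-minute individual
behavioural-therapy session at €103.87. Is that what the session is
*worth*? Value-based pricing answers by inverting the usual
cost-effectiveness appraisal: instead of checking whether the incremental
cost-effectiveness ratio (ICER) of CBT at the current fee clears the
payer's willingness-to-pay threshold λ, it solves for the fee at which
the ICER *equals* λ. Everything in this package serves that inversion.

## The decision model

A two-arm decision tree — CBT versus treatment as usual — for adult
primary-care patients with moderate or severe depression, evaluated as
expected cost and expected QALYs per patient over the model horizon.

* **Remission pathway.** The control arm remits with probability 0.35;
  CBT adds the absolute remission reduction, stored as the reciprocal of
  the meta-analytic number needed to treat, 1/10.08 ≈ 0.0992 (the
  published "9.9%" is this value rounded; keeping the reciprocal makes
  the NNT arithmetic exact downstream). Remitters hold the remission
  utility (0.73) for the whole horizon from time zero — no ramp-in —
  and non-remitters the severity-weighted baseline utility. The severity
  mix uses the published 68%/32% moderate/severe split (not the verbal
  "twice as many" 2/3–1/3 gloss), giving a baseline utility of
  0.68·0.51 + 0.32·0.37 = 0.4652 and a utility gain of 0.2648.
* **Horizon and proration.** The 12-week horizon is represented as 0.25
  years. The two-monthly depression-care cost (€173.30, non-remitters
  only, both arms) scales by 0.25 × 6 = 1.5; the 12-month antidepressant
  cost (€70.96) by 0.25. This pair of conventions is what makes the
  QALY and fee arithmetic reproduce the headline results simultaneously;
  a 12/52-year convention does not.
* **Comparator utilisation.** Treatment as usual is 10% psychotherapy
  (a full 15-session course) plus 26% antidepressants; the CBT arm
  receives no background psychotherapy or antidepressants — the
  utilisation fractions fully describe the comparator.
* **Indirect costs** (productivity, €200.64 per two months) default to
  zero and enter exactly like depression-care costs when enabled: per
  two months, ×1.5, non-remitters only.
* **Discounting** applies continuously at the annual rate r through the
  factor (1 − e^(−rT))/(rT), multiplying QALYs and recurring costs
  (session fees, paid during treatment, are not discounted). With a
  sub-year base-case horizon r = 0 and the factor is 1.

With the base-case inputs the incremental QALY gain is
0.0992 × 0.2648 × 0.25 = 0.00657 and the incremental cost at the current
fee is €1,371.84, an ICER of ≈ €208,885/QALY. (The originally reported
pair — €1,308 and €207,995/QALY — is not exactly derivable from the
published inputs under any linear price structure we tested; the package
reports its own reconstruction, which agrees with the reported ICER to
well within 1%, and does not chase the reported pair.)

Every arm evaluation is shadowed by `enumerate_tree_oracle()`, a
brute-force enumeration of all terminal branches (remission status ×
utilisation states) that shares no algebraic shortcuts with
`arm_outcomes()`; the test suite holds the two equal to 1e-9 across
randomly generated parameter sets.

## The pricing inversion

The threshold identity c/h = (p + b)/h = λ, with p the course price and
b the induced non-price costs, is affine in the per-session fee f, so
`value_based_price()` solves it in closed form by evaluating the
incremental cost at f = 0 and f = 1 and inverting the resulting line.

Two genuinely open design choices were resolved as follows:

* **Self-referential comparator pricing (default).** The 10% of
  comparator patients receiving psychotherapy are billed at the same
  value-based fee being solved for, so the effective number of billed
  session-equivalents is 15 × (1 − 0.10) = 13.5 and
  f = (λh − b)/13.5. This is the convention under which the base case
  lands at €45.06 (≈ €45) at λ = €88,000/QALY, and it is conceptually
  coherent: a value-based fee applies to all psychotherapy in the
  system. `comparator_pricing = "current_price"` restores a comparator
  billed at €103.87 (yielding ≈ €50.9) for comparison.
* **Bookkeeping of the reported fields.** `total_price` is the full
  course price 15f, and `induced_costs` is defined as b = λh − 15f, so
  the identity (p + b)/h = λ holds on the reported fields exactly. Under
  self-referential pricing b therefore contains the comparator
  psychotherapy offset (1.5 sessions at f) alongside the antidepressant
  offset (€4.61) and the depression-care savings (€25.79). The identity
  is additionally verified end to end: re-evaluating the decision model
  at the solved fee returns an ICER equal to λ to 1e-9.

Negative fees, arithmetically possible when induced costs are positive
at low thresholds, are returned as-is with a warning — the fee–λ
relation is an unconstrained affine map with slope
h/(n_sessions × (1 − prop_psychotherapy)), and `fee_curve()` exposes the
whole line.

The follow-up-therapy invariance (`followup_invariance()`) records why
the horizon may stop at the end of the acute course: when subsequent
(maintenance) therapies are themselves priced at the threshold, their
incremental costs and benefits are proportional to the initial course's
(factor x = Σxᵢ, which can absorb discounting and probabilities of later
therapies), and (c(1+x))/(h(1+x)) = c/h for every x ≥ 0.

## Suicide aversion

A deliberately coarse sensitivity extension. The suicide incidence among
depressed adults over the horizon — annual suicides (10,076) × the
fraction attributable to major depression (0.50) / (prevalence 0.101 ×
adult population) × horizon — times the relative reduction of suicide
attempts under CBT gives the NNT to avert one suicide; the remaining
quality-adjusted life expectancy of an averted case spread over that NNT
is the per-patient QALY increment, which enters the pricing solve as an
additive term on h.

Two component inputs (adult population; the effect size on suicide
attempts) are not published alongside the headline result, so the
published NNT of 16,409 is carried as `nnt_override` and wins by
default; the component pathway (defaults 69 million adults, relative
risk reduction 0.34 — both labelled reconstructions) lands at ≈ 16,274
and exists for exploration. `qale_at_45 = 15` QALYs is
reverse-engineered as the value consistent with the published pair
(increment 0.001, fee €51); the underlying patient-level simulation
value is not published. With these defaults the increment is
15/16,409 ≈ 0.00091 and the fee moves from €45 to €51.

## Sensitivity machinery

`one_way_sensitivity()` moves each parameter with a published 95%
confidence interval to its lower and upper bound, one at a time,
re-solves the fee, and sorts by spread (tornado order). The duration of
the remission effect is included as one entry spanning the base-case 12
weeks to the 46-month scenario; it dominates every parametric bound
(spread ≈ €619 against ≈ €65 for the remission effect itself). An
excursion that invalidates the parameter set is flagged in the `note`
column, never silently dropped.

The long-term scenario holds the 46-month trial's remission difference
(28% − 18% = 0.10 — the trial's own arms, not the base-case 0.0992)
constant from time zero, consistent with the flat effect the trial
reported; no additional savings are modelled because long-term
health-care costs were reported as very similar between arms. The
scenario QALY gain is 0.10 × 0.2648 × 46/12 ≈ 0.1015, the ICER at the
current fee ≈ €13,515/QALY, and the value-based fee ≈ €664. The
originally reported scenario fee of €226 is not derivable from any
stated input combination (a plausible unstated assumption — additional
maintenance sessions spreading the total price — cannot be confirmed),
so the package reports its own convention and flags the discrepancy;
whether the scenario discounts QALYs is likewise unstated, so the
default is 0% with `discount_rate_annual` exposed.

Monte Carlo probabilistic sensitivity analysis is deliberately *not* an
analytic product: with one variable (effect duration) dominating, a PSA
adds little. The sampler below exists to exercise the pipeline.

## The parameter sampler

`sample_parameters()` emulates "new studies": each parameter with a
genuine 95% confidence interval is drawn independently from a normal
with the base-case mean and sd = (high − low)/3.92, resampled into its
legal domain (proportions and utilities into [0, 1], costs ≥ 0, total
remission probability ≤ 1). Normal-with-resampling was chosen over
beta/gamma forms because only symmetric intervals are published;
independence is assumed because no correlation structure is published.
Draws carry point estimates only — the intervals describe uncertainty
about the base case, not about a draw — and the indirect-cost entry, a
deterministic scenario range rather than a confidence interval, is never
sampled. The seed is mandatory.

What passing tests on sampled inputs do and do not show: they
demonstrate that every pipeline stage is total over the plausible input
region (prices are finite or fail with a declared error) and that the
sampler recovers the published means and interval endpoints; they say
nothing about real-world parameter correlation, heavier-tailed effect
uncertainty, or structural assumptions (no treatment discontinuation, a
universal treatment effect, remission as a binary endpoint).

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs: a zero QALY difference flags the ICER
undefined rather than erroring; h ≤ 0 makes pricing undefined (declared
error); `prop_psychotherapy` ≥ 1 is a declared degenerate-model error;
fees are computed and reported to full precision, with whole-euro
rounding left to presentation. The test suite checks the
oracle-equivalence property on 1,000 random parameter sets (tolerance
1e-9), the pricing round-trip on 200 random sets and 50 thresholds
(1e-9), the follow-up invariance on 1,000 random factors, and sampler
moment recovery at n = 10,000 — sizes chosen so the full suite completes
in well under a minute while leaving Monte Carlo error far below every
asserted tolerance.

## Known limitations

The model inherits the evidence base's limits: a 12-week horizon, a
single long-term trial (in treatment-resistant depression) behind the
46-month scenario, no treatment discontinuation, no Markov/state
transition structure, no patient-level simulation, and a payer
perspective that excludes direct non-medical costs. The suicide
extension is a back-of-the-envelope calculation resting partly on
reconstructed inputs. Costs are taken as already expressed in 2019
euros; no inflation machinery is provided.
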