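---
title: "Methods: decision-tree cost-effectiveness analysis of pediatric MRI sedation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness analysis of pediatric MRI sedation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcea)
```

## The decision problem and the model

A 3-year-old ASA-PS I/II child needs a 38-minute brain MRI under sedation.
Five strategies are compared from the Japanese public payer's perspective:
oral triclofos sodium, IV midazolam and IV dexmedetomidine (administered by
non-anesthesiologists), IV propofol (administered by anesthesiologists), and
general anesthesia (GA) with sevoflurane via supraglottic airway. The episode
is short — at most a failed attempt and a rescheduled rescue — so a decision
tree is the right formalism (no time-dependent state transitions) and a 0%
discount rate applies.

Each arm is a chance cascade. The first-line attempt succeeds with the
regimen's pooled success probability; on failure the episode accrues
opportunity costs and proceeds to the rescue stage:

* oral triclofos → IV dexmedetomidine → IV propofol → GA,
* midazolam / dexmedetomidine → IV propofol → GA,
* propofol → GA,
* GA → GA retry on a later day, which succeeds by assumption (this closes
  the tree; without it a GA failure would have no terminal).

Effectiveness is the averted sedation failure, aSF = 1 − sedation failure
rate. It is a *first-attempt* outcome: any rescue path means the scan was
cancelled and rescheduled, i.e. a sedation failure occurred, so every rescue
terminal carries effectiveness 0 and each arm's expected effectiveness equals
its first-line success probability. This convention reproduces the published
effectiveness cells for triclofos (0.940), midazolam (0.792) and
dexmedetomidine (0.933) exactly. The published propofol and GA cells (0.972,
0.980) do not equal the published success-rate inputs (0.983, 1.000) and the
mapping behind them is not derivable from the published material; we do not
guess at it. The success-rate inputs are ordinary registry parameters, so a
user who knows the intended mapping can configure it directly
(`base_values(registry, overrides = ...)`).

### Cost accrual

Costs attach to nodes and accumulate along root-to-terminal paths
(effectiveness never accumulates — it is a terminal payoff). Per stage:

* **Oral triclofos**: drug cost only (60 mg/kg of a 100 mg/mL syrup billed
  per mL).
* **Non-anesthesiologist IV stages** (midazolam, dexmedetomidine): sedation
  fee $39.00 + peripheral IV infusion fee $6.83 + IV fluid $1.378 + drug.
* **Propofol**: anesthesiologist sedation fee $71.50 + infusion fee + fluid
  + drug.
* **GA**: GA fee $390.00 + supraglottic airway device $4.004 + sevoflurane
  consumption + (by default) the IV infusion fee and fluid, since GA implies
  IV access. Sevoflurane liquid use follows the low-flow formula
  3.3 × concentration[%] × flow[L/min] mL/h (at the 2.5%, 3 L/min settings of
  the published worked example: 24.75 mL/h, $4.381/h at $0.177/mL).

Drug quantities are loading dose × weight + maintenance rate × weight ×
duration/60. Vials are billed **whole-pack** by default (`ceiling(dose /
pack size)` — Japanese claims do not split vials); a `proportional` mode is
exposed because the published tables do not state the convention, and
`calibration_report()` evaluates both.

Opportunity costs on failure, itemized by `opportunity_costs()`:

* the MRI fee ($105.30) always — the aborted scanner slot could have served
  another patient;
* when a **non-anesthesiologist's IV sedation** fails: the pediatrician's
  forgone outpatient throughput, consultation fee × visits/hour × involvement
  time = $46.80 × 2.5 × (38/60 h) = $74.10. The published inputs carry the
  visits-per-hour figure for exactly this purpose but never write the
  product; the formula and the choice of MRI duration as involvement time are
  our design decisions.
* when the **anesthesiologist's propofol sedation** fails: the GA fee
  ($390.00), the value of the OR anesthetic the physician could have given;
* a failed GA is retried later: the retry terminal re-accrues the full GA
  stage cost plus the forfeited MRI slot.

Rescue attempts happen on a rescheduled day but are costed within the episode
(0% discount over the few-week horizon).

### Calibration against the published base case

```{r calibration}
calibration_report()
```

The triclofos cost cell is matched within $1 under whole-pack billing; the
other arms carry residuals of roughly $6–17. The published per-branch cost
attribution lives in supplementary model diagrams we deliberately do not
reverse-engineer; the scenario arithmetic of the published tables implies,
for instance, that the anesthesiologist fee enters the propofol arm with
weight 1.10 (218.35/198.50), whereas first-line-once accrual gives weight
1.00. GA's published $415.18 exceeds our itemized $404.99 by a similar
unattributed ~$10. These residuals do not affect the qualitative results
(frontier membership, dominance pattern, CEAC ordering), all of which
reproduce.

## Parameter registry and distributions

The packaged registry (`table1_registry()`, shipped as
`inst/extdata/table1.yaml`) carries every model quantity with base value,
one-way range, 95% CI where published, and a fitted sampling distribution.
All money is 2024 USD at 1 JPY = 0.0065 USD; JPY-tagged entries are converted
on load, and rounding happens only at presentation (costs/ICERs 2 decimals,
effects 3).

* **Success probabilities — beta.** `fit_beta_mean_ci()` pins the mean
  exactly (α = m·s, β = (1−m)·s) and chooses the concentration s by 1-D least
  squares on the 2.5%/97.5% quantiles. With one free parameter against two
  targets, near-symmetric intervals fit to within 0.005 (triclofos,
  propofol, dexmedetomidine) while the very wide midazolam interval
  (0.206–0.982 around 0.792) retains a ≈0.018 residual on its upper end —
  an intrinsic limit of an exact-mean beta, reported in `fit_diagnostics()`.
* **Fees, prices, doses — gamma.** The sources print no variance. Where a
  one-way range exists we read it as an approximate 95% interval,
  σ = (high − low)/(2 × 1.96); otherwise a default CV of 0.2 applies
  (configurable in the registry settings). Shape (m/σ)² and scale σ²/m
  reproduce the mean exactly. Because these spreads are conventions rather
  than published values, interior PSA quantities are tolerance targets only.
* **MRI duration and body weight — truncated normal.** 38 ± 14 min and
  13.5 ± 1.53 kg, resampled below physical floors (5 min, 5 kg). Truncation
  shifts the duration mean up by ≈0.35 min; tests compare against the
  truncated mean.
* **Degenerate rows.** The all-success GA rate (1.000, no CI) cannot carry a
  beta and is held fixed. The published dexmedetomidine row prints a 95% CI
  (0.946–0.964) that does not bracket its printed mean (0.933, confirmed by
  the base-case table); the registry keeps the mean and the CI *width*,
  recentred (0.924–0.942). The published sevoflurane per-mL price conflicts
  with the source's own worked example (24.75 mL × 0.177 $/mL = 4.381 $); we
  follow the worked example, $0.177/mL.

## Cost-effectiveness analysis

`icer_table()` reports ΔC, ΔE and ICER = ΔC/ΔE against a reference for every
strategy, including dominated ones with their (possibly negative) sign —
matching the publication convention — and reports ICERs as undefined (`NA`,
never ±Inf) when |ΔE| < 1e-12. `dominance_classification()` removes
absolutely dominated strategies (another strategy costs no more and is at
least as effective, one inequality strict; exact ties dominate neither and
are flagged), then applies the standard lower-convex-hull sweep for extended
dominance; frontier ICERs are strictly increasing in effectiveness. The
sweep is verified against an O(n²) brute-force oracle on 1,000 random
strategy sets.

Run on the published $270-fee scenario pairs, the sweep classifies
dexmedetomidine ($90.60, 0.933) as absolutely dominated by triclofos
($12.29, 0.940) — supporting the scenario table's own label over the
accompanying frontier figure, which draws dexmedetomidine on the frontier;
the two published displays disagree and the arithmetic sides with the table.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves to its range ends with all others
at base; success rates, published with CIs instead of ranges, sweep over
their CIs; parameters with neither are skipped and listed. The default
metric is the ICER of a named comparison; NMB at fixed λ is provided as the
sign-stable alternative (ICERs are unstable when ΔE crosses 0). For propofol
vs dexmedetomidine, the anesthesiologist fee is by far the widest bar among
fee/price/dose inputs, with the two success rates next — matching the
published sensitivity ordering.

**Threshold.** `threshold_analysis()` bisects one parameter to a $0.01 width
on a user predicate. The fee at which propofol and GA become equally
cost-effective vs triclofos comes out at $265.44 in this model, close to the
published $270 scenario; the result is bracket-independent for monotone
metrics.

**Probabilistic.** `run_psa()` samples all parameters jointly and
independently (no correlation structure is published), resolves the tree on
every draw in one vectorized pass, and is bitwise reproducible from its seed;
draws are stored for audit. `ceac()` computes, per λ on a default grid of
$0–$3500 in $50 steps (the sources state the range, not the step), the
probability each strategy has maximal NMB — exact ties split equally, a
measure-zero event for continuous draws but needed for degenerate registries
— plus the acceptability frontier (highest mean NMB).

At 10,000 iterations the CEAC endpoints are: triclofos wins in ~100% of
iterations at λ = 0, falling as λ grows; propofol rises from 0 toward its
maximum at λ = $3,500; neither midazolam nor GA is ever the adopted frontier
strategy on the grid. Interior probabilities depend on the unprinted gamma
variances (our CV/range conventions above) and on midazolam's extremely wide
success CI, which gives midazolam substantial per-iteration win mass at high
λ even though its *expected* NMB never leads; we therefore reproduce the
published CEAC ordering qualitatively, not its interior percentages (51.6%,
38.9%), which is the appropriate claim given the unpublished spreads.

## Pooling success rates

`pool_proportions()` pools per-study success counts on the logit scale:
variance 1/e + 1/(n−e) per study, DerSimonian–Laird between-study variance,
inverse-variance pooled logit with a 95% Wald interval, back-transformed
(implementation delegated to `metafor`; continuity correction 0.5 for
zero/full-event studies). All-success inputs (the GA row) cannot be pooled on
the logit scale and return the crude proportion as a fixed value with a
warning. Tests verify the routine against a hand-rolled DerSimonian–Laird
computation and recover a known rate from 20 simulated studies.

## Synthetic generators and what the tests show

`random_tree()` builds seeded random trees (normalized chance probabilities,
costs on interior nodes, terminal effectiveness anywhere in [0, 1] — wider
than the binary episode outcome, deliberately stressing the engine) and
`random_registry()` builds registries with recorded true moments. They power
the oracle-equivalence sweep (rollback vs exhaustive path enumeration,
|Δ| < 1e-9 over 1,000 trees), the dominance brute-force comparison, and
sampler recovery tests. These generators emulate structure, not clinical
reality: passing tests demonstrate the algebra (rollback, dominance, fitting,
pooling, CEAC bookkeeping) is correct, not that the sedation parameters
generalize to other populations, ages, or payer systems.

Problem sizes used by the test suite — 1,000 random trees, 1,000 strategy
sets, 10,000-iteration PSAs, 20,000–200,000-draw sampling checks — keep the
whole suite under a minute while leaving Monte-Carlo error well below the
asserted tolerances.

## Numerical conventions and edge cases

* Chance-node probabilities must sum to 1 within 1e-9 after resolution;
  out-of-range probabilities or unresolved parameter names abort with the
  offending node/parameter named.
* Decision nodes exist only at the root (the strategy choice). Interior
  decision nodes are a validation violation: with two payoff dimensions
  there is no defensible interior optimization rule, and the sedation model
  never needs one.
* Bisection tolerance $0.01; probability-sum tolerance 1e-9; undefined ICERs
  are `NA`; internal arithmetic is never rounded.
* Same-seed runs (sampling, PSA, generators) are bitwise identical.

## Limitations

Adverse events, patient heterogeneity (age, ASA class, behavioral history),
rectal chloral hydrate, QALY-based outcomes and correlated parameter
uncertainty are out of scope, as in the source analysis. The per-branch cost
attribution of the published supplementary tree is approximated by the
conventions above, with residuals documented in `calibration_report()`
rather than tuned away.
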