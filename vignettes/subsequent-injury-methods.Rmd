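---
title: "Modelling subsequent injury risk with first-order Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subsequent injury risk with first-order Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurychain)
```

## The model and its assumptions

`injurychain` treats the time-loss injuries of one player within one
competitive season as a categorical sequence and estimates a
first-order Markov model over injury states. The assumptions this
buys, and their costs, are worth stating plainly:

* **First order.** The next injury's state depends only on the current
  injury's state, not on the deeper history. Each injury except the
  last of a season therefore contributes exactly one transition, to its
  first subsequent injury ("chain semantics"); the number of
  transitions equals the number of subsequent injuries.
* **Time homogeneity.** The transition law ignores both calendar time
  and the gap between injuries. The gap in days is recorded on every
  transition for audit, but never enters estimation — a semi-Markov
  model would be the natural extension.
* **Season independence.** Sequences are cut at season boundaries: the
  last injury of one season never pairs with the first of the next.
  This deliberately discards off-season carry-over effects.

An injury state is, at the default level, the side-qualified body part
crossed with tissue nature (`Thigh|L : muscle`): a left-thigh and a
right-thigh injury are different states. At the alternative
`categorization` level the state is a specific diagnosis label
(`Hamstring Muscle Injury`); records whose category is missing or in
the exclusion list (default `"Unsure"`, `"Others"`) have no state at
that level and drop out of that analysis only.

## Preprocessing rules and their order

The cleaning pipeline applies, in a fixed order: label normalisation
(exact-match map, never fuzzy), removal of records missing the player
id or body part, exclusion of contact-caused injuries, optional
exclusion of exacerbations, side-merging, season resolution, and
removal of single-injury player-seasons. Two ordering facts are load
bearing:

* The single-injury rule runs **last** and to a fixed point, because
  every earlier exclusion can reduce a player-season to one record,
  and a one-record season supports no transition.
* Each removed record is attributed to exactly the first rule that
  catches it, so per-rule removals sum exactly to `before − after` and
  the whole pipeline is idempotent (running it twice removes nothing
  new — asserted in the test suite).

Decisions the consensus-style coding leaves open were resolved as
follows, each behind an explicit switch:

* `contact = "unknown"` is **retained** by default: the exclusion rule
  targets injuries *caused by* contact, not injuries of unknown
  mechanism (`drop_unknown_contact = TRUE` for the strict reading).
* Bilateral injuries map to their own side token (`Knee|B`) rather
  than being duplicated into left and right — no duplication rule
  exists in the coding, and duplication would double-count
  transitions.
* Exacerbations (recurrence before return to play) are kept as
  ordinary records by default; `drop_exacerbations = TRUE` removes
  them. Neither choice is claimed to match any particular study's
  unstated convention.
* Same-day injuries keep their input row order (stable sort) and emit
  a warning: their true order is unobserved, and a stable artefact
  beats a silent one.
* Season labels, when absent, derive from the date with a configurable
  season start month (default July, matching leagues whose season
  spans the calendar-year boundary).

## Estimation: the denominator question

Published transition matrices in this literature are ambiguous about
the denominator. Text descriptions usually say "transitions from the
initial state" (the row convention), but printed confidence intervals
are often exactly the Wald half-width at the *overall* transition
count (the global convention). The package refuses to guess silently:
both conventions are implemented, the denominator is recorded on every
estimate, and the default is `global` because that is the convention
under which published interval arithmetic reproduces. Concretely, with
1,599 subsequent injuries, `wald_halfwidth(0.075, 1599)` is 1.29% and
`wald_halfwidth(0.095, 1599)` is 1.44% — the half-widths printed next
to 7.5% and 9.5% cells in published figures. Under the row convention
those cells would carry much wider intervals (their row totals are far
smaller than 1,599).

One published worked example — a 95% interval of (0.098, 0.102) around
p = 0.10 — would require n ≈ 86,000 and is inconsistent with every
other printed interval; the package does not attempt to reproduce it.

Confidence intervals default to Wald with z = 1.96 (the convention the
published half-widths follow); Wilson score intervals are available
via `attach_cis(method = "wilson")` and are preferable for cells with
a handful of counts, where the Wald interval collapses at p = 0 and
can overshoot the unit interval (the package clips to [0, 1] and
records the method used).

The reporting threshold removes estimates with p **strictly below**
0.002 (a cell at exactly 0.2% survives). It is presentation-only:
counts, totals and denominators are computed before filtering, so the
threshold can never change a retained number.

## The synthetic cohort generator

Because league surveillance datasets are private, all validation runs
on synthetic cohorts whose generating process is known. The defaults
are fixed once, to emulate the published scale of an eight-season
professional cohort:

| parameter | default | why |
|---|---|---|
| `n_players` | 1,250 | published cohort size |
| `seasons` | 8 labels, 2013-14 … 2020-21 | published observation window |
| chain injuries / player-season | NB(mu = 0.42, size = 0.45) | mean chosen so total ≈ 4,700 injuries; the overdispersion (size 0.45) is what yields a ~34% subsequent share — a Poisson at the same mean gives only ~20% |
| `contact_rate` | Poisson(0.05) overlay | exercised by the contact-exclusion rule |
| `missing_field_prob` | 0.02 | exercises the missing-core rule |
| `label_noise_prob` | 0.15 | case-mangled raw labels, undone by the returned normalisation map |
| state space | 34 side-qualified part × nature states | body-part margins: thigh 32.4%, knee 15.7%, ankle 14.3%, hip/groin 12.9%, lower leg 9.7%, remainder spread |
| kernel | 0.25·I + 0.10·same-part + 0.65·marginal | re-injury inertia dominating, as observed in this literature |

Two generator design choices matter for inference:

* **Contact injuries are an independent overlay, not chain members.**
  If contact injuries sat inside the latent chain, excluding them
  would splice two-step transitions into the data and bias kernel
  recovery. As an independent marked process they model the mostly
  exogenous nature of contact trauma and keep the post-exclusion
  process exactly first-order.
* **Missing-field blanking does hit chain members**, so the default
  cohort carries a small, realistic adjacency contamination (~2%).
  Estimator-recovery experiments therefore use a noise-free
  configuration; pipeline-equivalence tests use the noisy one.

What the generator does **not** emulate: roster turnover (every player
is present all eight seasons, so the count of *players* with a
subsequent injury runs higher than a real cohort's), severity-dependent
return-to-play gaps, within-season seasonality, exposure differences
between training and matches, and any real per-player heterogeneity
beyond the negative-binomial count. Passing tests therefore demonstrate
correctness of the estimator and pipeline semantics — not that real
injury data are first-order Markov.

A `second_order = TRUE` mode generates under a deliberate violation of
the model (extra inertia once a state repeats), as a demonstration
harness for misspecification studies; it is outside the default
conditions.

## Validation design and problem sizes

The test suite validates along three independent routes:

1. **Brute-force oracle.** An independent reimplementation of the
   analysis semantics (plain loops: group → sort → pair → tally →
   divide) must agree *exactly* with the pipeline on 50 noisy cohorts
   of ≤ 2,000 records, under both denominator conventions.
2. **Ground-truth tallies.** `reference_statistics()` recomputes
   transition counts from the latent states, bypassing the analysis
   path entirely; counts must match wherever the noise model permits.
3. **Parameter recovery.** 200 replicate cohorts of 5,000 players ×
   8 seasons, noise off: row-convention estimates must fall within 3
   standard errors of the true kernel in ≥ 95% of cells with expected
   count ≥ 25, and pooled 95% Wald coverage of the true cell must lie
   in [0.92, 0.97]. These sizes give roughly 6,500 transitions per
   replicate — large enough that a handful of rows pass the
   expected-count gate, small enough that the whole study runs in
   about a minute.

Degenerate inputs are defined rather than accidental: an empty
transition set is fatal under the global convention (no denominator)
and yields no rows under the row convention; a count-0 cell under Wald
gets the degenerate interval [0, 0]; unobserved (from, to) pairs are
simply absent from the estimates table rather than materialised as
zeros.

## Known limitations

* First-order and time-homogeneous by construction; recovery-time
  dynamics and injury-burden effects are invisible to the model.
* The state space at part × nature level grows quickly with coding
  granularity; sparse rows make row-convention estimates noisy, which
  is why the reporting threshold and the expected-count gate exist.
* Exact-match label normalisation is deliberate (auditability over
  convenience): a misspelled label passes through with a warning
  rather than being silently fuzzy-matched.
* The global/row denominator ambiguity is documented and configurable,
  but no amount of configuration resolves which convention any given
  published figure used; read the recorded `denominator` column before
  comparing numbers across studies.
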