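---
title: "Simulating and analyzing longitudinal name-generator network panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing longitudinal name-generator network panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpanel)
```

## The setting

`netpanel` analyzes longitudinal egocentric network panels of the kind
collected in respondent-driven sampling (RDS) cohort studies of hidden
populations — here, a cohort of young Black individuals assigned male at
birth who have sex with men, comprising transgender women (TGW) and men
who have sex with men (MSM). At each study wave a respondent (the *ego*)
answers two name generators: a confidant generator (up to five people
"with whom you discuss things that are important to you") and a
sexual-partner generator (up to five recent partners plus one current
primary partner). At follow-up waves the interviewer shows the
respondent their earlier lists and records which names refer to the same
person; at the third wave that confirmation list is cumulative over the
first two waves. These respondent-confirmed matches are the only
identity information the instrument provides.

Because studies of this design typically cannot deposit raw rosters, the
package is built around a cohort simulator that reproduces the design —
seeded coupon-based RDS recruitment, per-wave roster caps, confirmed
matches, differential attrition — with known ground truth, so that every
estimator in the package can be validated by parameter recovery rather
than by reference to confidential data.

## The quantities of interest

For every ego with two or more attended visits, and separately for the
confidant and sexual networks, ties are classified over the ordered
attended visits $v_1, \dots, v_k$:

* **original** ties: the distinct alters on the $v_1$ roster (count $O$);
* **retained** ties: original alters present at every subsequent
  attended visit (count $R$);
* **new** ties: alters first nominated after $v_1$, counted once
  (count $N$);
* **lost** ties: one loss for each disappearance of an *original* alter
  between consecutive attended visits (count $L$); a transient new tie
  (first nominated after $v_1$, later gone) affects turnover only
  through the cumulative size — counting its disappearance as a loss as
  well would push turnover above 1;
* the **cumulative network size** $C$: distinct alters over all attended
  visits, so $C = O + N$.

The two headline ratios are

$$\text{stability} = R / O, \qquad
  \text{turnover} = (N + L) / C.$$

For an ego with exactly two visits the identity
$\text{turnover} = 1 - R/C$ holds exactly, and the suite asserts it at
machine precision. A tie that is lost and later regained contributes one
loss and no new tie (the alter is already in $C$). With the
original-tie loss rule, $L \le O$ for panels of up to three visits (an
original tie can disappear at most once), so turnover stays in
$[0, 1]$. Group contrasts of the two
ratios use a two-sided independent t-test — Welch's unequal-variance
version by default, the pooled version by flag — and egos with fewer
than two visits, or with $O = 0$ (undefined stability), are excluded
with a logged reason rather than scored zero.

With more than two visits the instrument defines "retained" only
implicitly. The default rule is strict persistence (present at every
later attended visit), which matches the cumulative confirmation list's
reading of a tie that *lasts*; the alternative reading (re-nominated at
any later visit) is available as `retained_rule = "any_later"` and is
reported side by side by the pipeline when asked.

## The composite graph and its metrics

`assemble_graph()` builds one undirected simple graph whose nodes are
enrolled egos plus their resolved alters and whose typed edges come from
three layers: RDS recruitment (recruiter–recruit), confidant
nominations, and sexual-partner nominations. Nominations of the same
person merge into a single edge carrying a type set (e.g.
`confidant,sexual`, using the respondent's same-wave overlap
confirmations) and per-wave provenance.

A structural limitation mirrors the instrument: observed data cannot
reveal that two *different* egos named the same person, so each ego's
alters are distinct pendant nodes, which inflates path lengths. The
simulator's ground-truth identities can optionally be supplied to merge
such nodes, and the difference between the two graphs quantifies what
the instrument cannot see. Without the RDS layer the observed graph is a
disjoint union of ego stars (every ego's mean geodesic distance is
exactly 1); the RDS layer is what connects the cohort, so the default
edge-kind set includes it.

Per-node metrics are the field's standard four, normalized so they are
comparable across graphs:

* degree $k_i$;
* betweenness centrality divided by $(n-1)(n-2)/2$, so it lies in
  $[0, 1]$;
* closeness centrality with the component-size correction
  $c_i = \frac{r_i}{n-1}\cdot\frac{r_i}{\sum_{j \in \mathrm{reach}(i)} d_{ij}}$,
  where $r_i$ is the number of nodes reachable from $i$ — on a connected
  graph this is classical closeness, and on a disconnected graph a node
  never scores above its value in its own component alone;
* average shortest path length, the mean geodesic distance to reachable
  nodes (undefined and flagged for isolated nodes).

Shortest-path machinery is igraph's; the formulas above are asserted
against an exhaustive Floyd–Warshall plus geodesic-enumeration oracle on
hundreds of random graphs of up to eight nodes. Group comparisons of the
metrics average over enrolled egos only (alter nodes carry no group).

## Comparative statistics

`ego_composition()` turns each ego's resolved wave-1 rosters into the
composition covariates used in network-characteristic comparisons
(proportion of transgender confidants, number of HIV-positive
confidants, exchange-sex indicators, partner-preference counts, and so
on). Proportions are computed over alters with a non-missing value of
the attribute and the effective denominator is recorded; an empty
denominator yields an explicit `NA`, never a zero.

`unadjusted_or()` relates a covariate to group membership (MSM the
reference group). Binary ego-level covariates default to an
outcome-on-group logistic model, so the OR is the TGW-vs-MSM odds ratio
of the outcome; count and proportion covariates default to a
group-on-covariate model, so the OR is per unit of the covariate. Both
framings are available through the `direction` flag because the
published table layout does not disambiguate them. On a 2×2 table the
logistic maximum-likelihood OR equals the cross-product ratio (the
saturated-model identity, asserted to 1e-6 in the suite); complete
separation — a zero cell — falls back to the Haldane–Anscombe
0.5-corrected cross-product OR and is flagged rather than silently
reported.

`baseline_table()` summarizes the respondent covariates per group with
pairwise-complete denominators (each variable over its own non-missing
records — denominators visibly vary in tables of this kind, and
listwise deletion would misstate them), t-tests for continuous
variables, chi-square tests for categorical ones with Fisher's exact
fallback when an expected cell is below 5, and significance marked at
p ≤ 0.05 two-sided. No multiple-testing correction is applied by
default, mirroring the plain p ≤ 0.05 convention of the study design;
annual income is dichotomized strictly below \$20,000, with exactly
\$20,000 deterministically classified as not-below (the under/over
framing leaves the boundary unassigned, and a reproducible rule is
required).

## The simulator and its defaults

The generator's defaults are the study conditions of the cohort it
emulates: a target Wave-1 sample of 618 with 7.6% TGW, 62 seeds, three
waves, wave-to-wave study retention of 86.4% for MSM and 66.7% for TGW,
and the roster caps above. Initial ties come from a two-block
degree-homogeneous random-graph model: block edge probabilities are
$p_{gh} = s_g s_h W_{gh}$ with the mixing matrix $W$ setting the
relative within/between-group tie odds, and the per-group scales $s_g$
solved so every group's expected degree equals the configured mean
regardless of the group-size imbalance (without this, the 7.6% minority
would have systematically lower degree and be starved by degree-weighted
recruitment). Degree-corrected variants are deliberately out of scope.

Recruitment passes coupons over confidant ties only (coupons travel
through social, not sexual, contacts; the union is available by flag),
breadth-wise in coupon-issue order, at most three coupons per enrollee
by default, halting at the target sample or exhaustion. Seeds default to
degree-weighted draws, emulating highly socially connected initial
participants. The number of coupons per enrollee and the seed-selection
rule are not pinned down by the study design; both are documented
configuration knobs.

Between waves, each existing tie persists independently with a
per-kind, per-group retention probability, and new ties arrive per ego
as Poisson draws attached to eligible partners. Retention defaults are
the cohort's reported stability ratios (confidant 0.334 TGW / 0.408
MSM; sexual 0.175 TGW / 0.278 MSM) — chosen because, for two-visit egos
with no arrivals, expected stability equals the retention probability —
and the default arrival rates (confidant 0.65 TGW / 0.45 MSM; sexual
0.10 / 0.20 per interval) are solved once from the reported turnover
ratios at typical roster sizes. Attrition is Bernoulli per ego per
wave, group-specific and independent of network position (only marginal
retention is reported for the design being emulated), so an ego can
miss Wave 2 and return at Wave 3; analysis then uses the attended-visit
sequence without interpolation.

Sexual rosters in such cohorts include cis-women partners from outside
the AMAB hidden population, so the simulator carries an external
cis-women partner pool (sexual ties only; not recruitable; no confidant
ties), sized at 20% of the population by default with per-group
attachment rates. Partnership attributes (exchange sex, payment
received) are drawn once at tie creation and persist; alter attributes
(gender identity, HIV status with a 70% disclosure probability,
partner preference) come from the underlying member. One master seed
streams to named sub-generators (population, recruitment, dynamics,
emission), so each stage is independently reproducible and two runs
with the same seed are byte-identical.

What the simulator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: name-matching error by
respondents (confirmations are perfect unless `match_dropout` is set),
coupon expiry and incentive behavior, geographic structure, degree
heterogeneity beyond the Poisson-like block model, and any dependence of
attrition on network position.

## Numerical and design notes

* **Roster caps censor dynamics.** When an ego's true network exceeds
  the cap, the wave-2 roster is a subsample of surviving ties, so
  observed stability under-estimates the true retention probability —
  increasingly so at high retention. Parameter-recovery experiments
  therefore use a mean degree below the cap (3 by default in the
  acceptance runs); at the cohort defaults (mean confidant degree 8) the
  bias is a property of the instrument itself, not of the estimator.
* **Calibration requires exchangeable groups.** In null simulations the
  independent t-test on structural metrics holds its 5% level only when
  group labels are independent of network position (uniform mixing).
  With homophily, metrics cluster by community and the test is
  anticonservative — a caveat that applies equally to observed cohorts.
* **Conflicting match chains.** A chain of confirmations implying that
  two nominations from the same interview are one person is
  inconsistent (one roster lists distinct people). The resolver refuses
  the offending merge — matches are processed in wave order, so
  earlier-wave links win — and reports it; this reconciliation rule is
  an implementation choice the instrument leaves open.
* **Identity resolution** is per ego and per roster kind (the
  instrument never links alters across egos); confidant–sexual overlap
  confirmations are kept as a flag and used only when assembling the
  composite graph, so each kind's network remains separately
  analyzable. Resolution is idempotent and order-independent, and
  recovers simulator ground truth exactly under perfect confirmation.
* **Wave-1 recall windows differ** (past 6 months at Wave 1, since last
  interview later); the window is roster metadata and does not change
  any computation.
* **Problem sizes.** The shipped acceptance runs use a 1000-ego
  two-wave cohort for the ratio identities, 500 egos per group for
  parameter recovery, 200 replicates of a 160-ego cohort for type-I
  calibration, and 200 random graphs of up to 8 nodes against the
  exhaustive oracle — sizes at which Monte-Carlo error is small
  relative to the asserted tolerances while a full run stays in the
  minutes range on one core.
* **Logistic fits** use `stats::glm` with convergence tolerance 1e-10;
  GLM output is never reported when the fit has not converged or shows
  separation-scale standard errors.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 7)          # cohort defaults: 618 egos, 3 waves
sim <- simulate_cohort(cfg)
ds  <- validate_dataset(sim)

dyn <- cohort_dynamics(ds)               # stability/turnover + Welch tests
dyn$comparisons

g   <- assemble_graph(ds)                # RDS + confidant + sexual layers
cmp <- group_structure_comparison(node_metrics(g), ds$respondents)

bl  <- baseline_table(ds)                # Table-1-style summary
ors <- or_table(ego_composition(ds))     # unadjusted ORs, MSM reference

run_pipeline(list(simulate = list(), seed = 7), "results/")  # all of it
```

## Known limitations

Ratios are unweighted (no RDS inclusion-probability weighting, matching
the design being emulated, whose sampling weights were unusable); tie
duration is not modeled dyadically; the two-block model has no degree
correction; and the structural metrics inherit the instrument's
inability to merge alters across egos, which biases path-based metrics
upward in observed (non-simulated) data.
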