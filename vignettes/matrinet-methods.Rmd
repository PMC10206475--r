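---
title: "Methods: social network ontogeny in matrilineal primate troops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social network ontogeny in matrilineal primate troops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(matrinet)
```

## The scientific question

In female-philopatric primates such as chacma baboons, a mother and her
descendants form a matriline, and offspring are thought to "inherit" the
mother's social network much as they inherit her dominance rank, before
differentiating from it during development — increasingly associating with
age peers and same-sex partners. matrinet implements the observational
analysis pipeline used to test that idea in the wild: time-aggregated
proximity and grooming networks built from field records, ego-network
responses per immature per period, mixed-model fits, and permutation-based
null-model inference. Because the original field data are not required, the
package pairs the pipeline with a synthetic troop generator whose ground
truth is known, so every stage can be validated by parameter recovery and
null calibration rather than by eyeballing.

## From field records to networks

**Records.** Proximity comes from instantaneous scan sampling: a focal
individual is drawn from a randomized troop list and every troop member
within 10 m is recorded as a "subgroup" (an individual with no neighbour is
recorded alone); a focal is not re-sampled within an hour. Grooming is
recorded ad libitum with direction (giver to recipient), and a dyad is not
recorded twice within the same half-hour. Dominance interactions
(displacements, supplants, threats, chases, attacks) are recorded ad
libitum among adult females.

**Periods and filters.** Each (troop, field season) stream is cut into
consecutive 30-day windows anchored at the first day on which data were
collected in that season — separately for proximity and grooming, so the
two streams have different window boundaries and period counts. A trailing
partial window is generated like any other; the robustness filters then
remove periods with fewer than 95 observations and, per season,
individuals seen fewer than five times. Both thresholds are inclusive on
the retained side (95 stays, 94 goes; 5 stays, 4 goes).

**Networks.** Per troop-period, scans become a group-by-individual (GBI)
matrix (rows = subgroups, columns = individuals) from which the simple
ratio index is computed: `SRI(A, B) = x / (x + yA + yB)`, the proportion of
sampled subgroups involving either individual in which both occurred.
Joint absences are excluded from the denominator (the canonical
simple-ratio definition); "alone" rows still contribute the y-terms of
every dyad containing that individual, because they are sampled
observations of non-association. A dyad with an empty denominator —
possible only when a roster id was never observed — is stored as 0 and
flagged in a mask rather than dropped, keeping matrices dense for the
metric stage. Edge weights are never thresholded. Grooming becomes a
directed count matrix, viewed as given, received (the transpose), or total
(the symmetrized sum), with a row-proportion variant used wherever the
distribution of grooming across partners matters more than its volume.

## Dominance ranks

Adult-female ranks are computed per season with the I&SI criterion: find a
linear order minimizing first the number of inconsistencies I (dyads in
which the lower-ranked female won more interactions), then their summed
rank distances SI. Ties in win counts and unknown (0–0) dyads contribute to
neither objective. The optimizer does repeated pairwise-swap improvement
passes from a win-proportion seed plus random restarts (100 by default,
seed-controlled); exhaustive search pins the optimum in tests up to n = 6,
and steep simulated hierarchies are recovered with Kendall tau = 1 in over
95% of replicates. Ordinal ranks are standardized by group size with
`1 - (1 - r) / (1 - n)`, mapping rank 1 to 1 (highest) and rank n to 0.

## Node metrics, transforms, standardization

Strength, eigenvector centrality and betweenness are computed per
troop-period through igraph, the library the replicated analysis used.
Grooming strength is split into given/received/total; centrality and
betweenness use the symmetrized total because in/out components cannot be
separated for them. Two conventions deserve attention:

* **Betweenness weights.** The default treats edge weights as *costs*
  (larger SRI = longer path), replicating the graph library's default
  convention the original analysis evidently inherited. The biologically
  intuitive alternative — lengths = 1/weight, so strong associations are
  short paths — is available as `weight_handling = "inverse_weights"`.
  Replication first; the pitfall is documented rather than silently fixed.
* **Disconnected graphs.** Eigenvector centrality is computed on the full
  matrix; scores outside the dominant component fall to ~0, matching
  common library behaviour, and a message flags the situation.

Proximity betweenness and grooming strength given are log1p-transformed;
grooming centrality and betweenness square-root transformed; all metrics
are then z-scored within each sampling period (sample SD), making values
comparable across networks of different sizes. A zero-variance period
standardizes to zeros with a warning rather than NaN.

## Responses per immature per period

* **Time with mother**: for proximity, the proportion of records containing
  the immature whose subgroup also contains the mother (joint subgroup
  membership is the recorded unit, so "with the mother" is implemented as
  co-membership); for grooming, events with the mother in either direction
  over events involving the immature, on the total network only.
* **Ego-network similarity**: Pearson r and cosine similarity between the
  immature's and the mother's matrix rows. Both members' columns are
  dropped before aligning the vectors: the self column is structurally
  zero, and the mother–immature edge sits at different positions in the
  two rows and would distort the correlation. Proximity uses SRI; grooming
  uses the row-proportion matrix, which represents how grooming is
  distributed over partners independently of its volume.
* **Binary comparisons**: score 1 when the mother–immature r strictly
  exceeds (ties score 0) the r with one uniformly drawn non-mother
  individual (comparator recorded for reproducibility), or the mean r over
  all non-mother individuals. Eligibility is anyone in the period's network
  other than the immature and its mother; no age restriction is applied.
* **Partner-category proportions**: distinct partners with a nonzero edge
  (direction follows the network mode) in a category over the category's
  size in the troop-period excluding the focal. Categories: immature (age
  at most 60 months), peer (within 6 months of the focal's age, inclusive
  at exactly 6), same sex. Ages are evaluated at the period midpoint; an
  empty category yields a missing value, not zero.

## Mixed models and effect sizes

Every model regresses its response on age (months, uncentred, so slopes
are per month), sex (female reference; reported sex effects refer to
males), their interaction, the mother's offspring count, the mother's
relative rank and troop, with random intercepts for year and for immature
identity nested in mother identity. Node-metric models additionally
control for the mother's corresponding standardized metric. Gaussian
responses use REML (`lme4::lmer`); proportion responses use binomial
logit GLMMs on successes/trials (`lme4::glmer`, bobyqa optimizer). Models
are never simplified. Factors with a single level in the data at hand
(one troop, one year) are dropped from the formula automatically and the
drop is visible in the stored formula — lme4 cannot estimate single-level
grouping factors, and a one-troop simulation should not forfeit the rest
of the structure. Singular (boundary) variance estimates are flagged
separately from genuine optimizer non-convergence.

Binomial effect sizes are reported as percent changes in odds:
`(OR - 1) * 100` per unit predictor, `[(OR(t1) - OR(t0)) / OR(t0)] * 100`
between 12 and 48 months of age (weaning vs. social independence), and the
sex contrast at 30 months (the middle of the immature age range). Gaussian
slopes are expressed as percent of the observed response range covered
over the same age span. The package ships the published fixed effects of
the original field analysis as a plain-text table
(`reference_fixed_effects()`), and feeding them through these formulas
reproduces the published percentages to well within rounding error of the
4-decimal inputs.

## Permutation null models

Proximity models use datastream permutations: 2x2 checkerboard flips of
the GBI (`[[1,0],[0,1]] -> [[0,1],[1,0]]`), each preserving every subgroup
size and every individual's sighting count. One chain step performs 20
successful flips; chains run 300 steps per period, the first 200 states
are discarded, and the 100 retained GBIs are converted to SRI matrices.
Grooming models — and the proximity partner-category models, where the
question is a shift in partner phenotype rather than in association
counts — use node-label permutations: rows and columns relabelled jointly,
composed sequentially with the last 100 of 300 states kept (composition of
uniform permutations is itself uniform; the chain form mirrors the
replicated procedure). Chains run independently per troop-period, and
chain state k across all periods assembles whole-dataset replicate k; the
model is refit on each replicate with identical settings, and the
two-tailed p is `2 * min(#(null >= obs), #(null <= obs)) / K`, capped at
1, reported alongside the binary "0.05"/"NS" label of the replicated
analysis (with K = 100 the smallest attainable nonzero p under this rule
is 0.02). Time-with-mother models are not permutation-tested: their
response is not a network quantity. A run in which more than 20% of
permuted refits fail to converge is flagged unreliable.

Responses on permuted data are recomputed from the permuted matrices (not
the raw records); individual attributes (age, sex, category membership)
stay attached to the labels whose positions are shuffled, so node
permutations break exactly the phenotype-network association under test.

## The synthetic troop generator

The generator emulates the field protocol above with a known latent
structure. Defaults describe one troop of 60 — 40 adult females in 10
matrilines plus 20 immatures aged 3–57 months — observed for five 30-day
periods across two annual field seasons, 12 focal scans and about 15
grooming events per individual per month, all within the ranges reported
for wild troops (21–74 individuals, 4–20 scans, 5–52 grooming events).
Three channels define per-scan association propensities, re-evaluated at
each period midpoint as individuals age:

* adult females associate at a baseline 0.01 per scan, elevated by 0.08
  within a matriline;
* the probability that an immature's subgroup contains its mother is
  logit-linear: intercept 0.8, age slope -0.025/month, male offset 0.4,
  male-by-age -0.012/month — the declining time with the mother, with a
  faster male decline;
* an immature's remaining row is the inheritance mixture
  `w * mother's row + (1 - w) * homophily`, with
  `w = lambda0 * exp(-(decay + male_extra_decay * male) * age)`
  (defaults 0.9, 0.04/month, +0.01/month for males) and a homophily kernel
  combining a same-sex term growing at 0.0015/month of the focal's age and
  a Gaussian age-assortment kernel (bandwidth 12 months, height 0.06).
  Immature-immature cells average the two directed mixtures to keep the
  matrix symmetric; the newborn limit (row identical to the mother's at
  lambda0 = 1, age 0) is exact over adult columns.

Grooming propensity reuses the association matrix, so grooming
concentrates on the same dyads; directed events are drawn proportional to
it and deduplicated per half-hour. Dominance interactions draw dyads at
random among adult females; the higher-ranked female of the troop's latent
order wins with probability `plogis(steepness * relative-rank gap)`
(default steepness 6, about 4 interactions per dyad per season).

**What the generator does not emulate**: demography within a run (no
births, deaths, dispersal or fission), unmarked individuals (everyone is
identifiable, matching the assumption under which the simple ratio index
is valid), spatial structure, observer error, and within-day spatial
autocorrelation of subgroups (scans are conditionally independent given
the propensities). Passing tests therefore demonstrate that the pipeline
recovers the structure this model generates, not that real field data meet
its assumptions.

## Induced generating values, recovery and calibration

A point that shaped the design: the raw channel parameters are *not* the
estimands of the downstream models. The scan protocol mixes three record
types for an immature — its own focal scans, its mother's focal scans
(which contain both whenever the immature joins), and third-party scans —
so the marginal proportion of records containing the mother is an
attenuated, shifted version of the logit-linear channel. Rather than
pretending otherwise, the generator computes the *induced* fixed effects
in closed form from the realized propensity matrices (record-level
expectations, then a weighted binomial regression on age and sex):
`induced_mp1a_coefficients()` for time with mother and
`induced_mp2c3_coefficients()` for the same-sex partner proportion, whose
per-dyad edge probability over a period is
`1 - (1 - P[i,j])^(2m) * prod_f (1 - P[f,i] P[f,j])^m` for m focal scans
each. Parameter-recovery acceptance asks the fitted GLMM coefficients to
land within 3 standard errors of these induced values — a sharp check,
since the induced values are conditioned on the same realized propensities
the records were sampled from. The same protocol coupling produces an
emergent inheritance pathway worth knowing about: even with the mixture
weight at zero, an immature that spends much time in its mother's
subgroups meets the mother's associates there, which correlates their ego
networks. Isolating the direct-inheritance channel in tests therefore
requires flattening the mother-association and homophily channels too.

Null calibration zeroes every generator effect (no inheritance, no
homophily, age- and sex-constant mother association) and runs the full
pipeline 40 times on a reduced troop (24 individuals, two periods) with a
reduced permutation schedule of 60/30/30, counting how often the age term
of the mother-offspring similarity model earns the "0.05" label. The count
is required to fall inside the exact binomial 95% interval around the
nominal rate. With 30 kept permutations the label fires only when the
observed coefficient escapes the entire null range, so the attainable
false-positive rate is itself discrete (about 2/31 two-sided); the
binomial check absorbs that granularity.

## Problem sizes and numerical choices

Test and acceptance runs use one troop of 60 over 5 periods for recovery
(about 3,600 scans) and troops of 24 over 2 periods for the 40-replicate
calibration — sizes chosen so the full suite exercises every stage,
including 1,200 permutation-refits of a mixed model, at desk scale.
Further conventions: ages count 30-day months (aligning age arithmetic
with the aggregation windows); period midpoints date both ages and
category membership; comparator draws, rank restarts and permutation
chains all derive their seeds from one master seed, making every report
bit-reproducible; grooming proportion rows with no events stay all-zero
rather than NaN; Pearson similarity is flagged missing when an ego vector
has zero variance (the cosine is still computed unless the vector is
all-zero); and strict inequality decides the binary comparison scores, so
ties score 0.

## Known limitations

The I&SI optimizer is a heuristic beyond n ≈ 10 (oracle-checked only at
small n); the induced-value oracles exist for the two models whose
responses have closed-form record-level expectations, so recovery for the
similarity models is asserted by sign and significance rather than by
value; the betweenness weights-as-costs default replicates a convention
that is biologically questionable; and the generator's linear propensity
mixture is the simplest structure producing the qualitative patterns of
interest, not a fitted model of baboon behaviour.
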