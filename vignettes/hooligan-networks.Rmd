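---
title: "Benchmark-referenced relation tests and signed hooligan networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-referenced relation tests and signed hooligan networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoolinet)
```

## The problem and the model

Organized football fan bases (*torcidas organizadas*) publicly declare
friendships and rivalries with fan bases of other clubs. The transitive
reading of those declarations — friend of my friend is my friend, friend of
my enemy is my enemy, enemy of my friend is my enemy, enemy of my enemy is my
friend — is often called the *Bedouin syndrome*, and, if real, it would let
police anticipate which club pairings are at risk from declarations alone.

`hoolinet` implements a two-step statistical test of that hypothesis on
per-match police incident counts around a small set of focal ("head") clubs,
the design used for the Pernambuco data (three head clubs, Feb 2005 – Aug
2015, incidents aggregated at club level, restricted to aggression-based
offenses).

**Step 1 — underlying relations.** For each head pair $(a,b)$, the mean
incidents per match $\bar h_{ab}$ over their $n_{ab}$ mutual matches is
compared with a pooled benchmark $\bar h_i$ (the per-match mean over all
$n_i$ matches in the benchmark scope), assuming unequal variances:

$$U(a,b) \;=\; \frac{\bar h_{ab} - \bar h_i}
  {\sqrt{s_{ab}^2/n_{ab} + s_i^2/n_i}}.$$

A significantly *higher* pair mean is read as an underlying **rivalry**, a
significantly *lower* one as an **alliance**, anything else is
**undefined**. Two significance tiers are used: strong ($p < 0.05$) and weak
($0.05 \le p < 0.1$).

**Step 2 — affinities.** For a third club $k$, the same statistic is
computed for $(a,k)$ and $(b,k)$. The triple is classified by the taxonomy

| heads    | both components | affinity |
|----------|-----------------|----------|
| alliance | rivalry         | coup     |
| alliance | alliance        | peer     |
| rivalry  | rivalry         | clash    |
| rivalry  | alliance        | split    |

and the observed relation of each (head, declared partner) pair is compared
with the relation the transitive premises predict from the declaration
registry, yielding a verdict of *supports*, *contradicts* or *inconclusive*.

## Numerical conventions

* **Degrees of freedom.** The package defaults to the Welch–Satterthwaite
  approximation with fractional df. An additive rule
  $(n_{ab}-1)+(n_i-1)$ is available via `df_rule = "additive"`. The
  fractional rule is the default because it is the only convention that
  reproduces the published per-pair p-values from their own summary
  statistics (e.g. $p = 0.076807$ at $n = 2$ requires df $\approx 1.095$).
* **Sidedness.** One-tailed in the direction of the observed difference by
  default (again the convention the published values require); two-tailed by
  option.
* **Undefined p-values.** A pair with fewer than two matches, or with zero
  sample variance, gets an undefined p (`NA`), mirroring the dashes the
  published tables print for all-zero pairs. Note that a literal
  plug-in of $s_{ab} = 0$ would instead produce an extreme t statistic and a
  spuriously "significant alliance" for every quiet pair; the undefined
  convention is the substantively faithful one.
* **Benchmark scope.** The benchmark group is configurable
  (`pooled_benchmark(records, scope = ...)`) because the published first-
  and second-step analyses use different, partly underdetermined benchmark
  groups. The second-step group is fully printed (n = 330, mean 2.28181800,
  SD 3.91970700) and is bundled as `pernambuco_benchmark()`. The first-step
  group is *not* recoverable (its stated aggregate mean of 8.064
  incidents/match cannot be reconciled with the overall totals), so the
  first-step rows are treated as label inputs only and no first-step p-value
  is claimed as reproducible.
* **Multiple testing.** No correction by default (matching the original
  procedure, which tests 30 interactions uncorrected); a `p_adjust`
  argument reports a corrected column separately without altering verdicts.

## Reconstructing counts from printed statistics

Published tables give only (mean, SD) per pair, printed to fixed precision.
For small non-negative integer count samples those two numbers often pin the
sample down exactly, so `reconstruct_counts()` searches exhaustively over
sample sizes $n = 2..n_{\max}$ and non-decreasing integer vectors (entries
$\le$ `count_max`, defaults 40/40 — far above any bundled row) for the
smallest $n$ whose exact statistics *print* as the given values.

Matching conventions: printed values with decimals are matched by
round-half-away-from-zero at the printed decimal count; values printed
without decimals are taken as exact (a table that prints SDs to six decimals
prints "2" only when the value is 2). One bundled mean ("1.66") is a
truncation of $5/3 \cdot 2 = 1.6\overline{6}$ rather than a rounding; the
`"auto"` convention tries rounding first and falls back to truncation, which
makes every bundled row reconstructable. When several vectors exist at the
minimal $n$, the lexicographically smallest is canonical; all solutions at
that $n$ share the printed statistics to printed precision, and the test
p-value depends only on (n, mean, SD), so the choice is inert downstream.

Two bundled rows (Remocada and Faccao Brasiliense under Santa Cruz — the
only p-values printed to six decimals) are *not* reproducible from any
admissible minimal reconstruction under any df/sidedness convention; their
true sample sizes most likely exceed the minimal reconstruction's $n$.
Both are insignificant under either reading ($p > 0.1$ printed and
recomputed), so no classification changes. They are excluded from the
reproduction claims, which cover the six uniquely pinned rows asserted in
`tests/testthat/test-acceptance.R`.

## The bundled reference fixture

`pernambuco_fixture()` rebuilds a complete incident dataset from printed
numbers alone: each per-pair row is expanded to per-match records via the
reconstruction oracle, and a synthetic benchmark population of 330 integer
counts (sum 753, sum of squares 6773 — matching the printed benchmark mean
and SD at printed precision; clearly labelled synthetic, the true counts
are unpublished) is attached as a separate benchmark scope.

The declaration registry is likewise a synthetic stand-in, because the
published declaration appendix is not reproduced in the available text. It
is the *minimal* consistent set: every partner club is declared friend of
exactly one head, chosen so that composing the declarations through the
transitive premises reproduces every published concordance statement —
including the circumstantial Santa Cruz–Nautico alliance, which is supplied
as an explicit `assumed_relations` override (provenance `"assumed"`), never
inferred. On this fixture the full second step yields 30 interactions over
15 clubs: 3 contradictions (all significant *alliances* where the
declarations predict rivalry — two weak, one strong), 2 supports, and 13 of
15 clubs with no support for the syndrome.

## The synthetic-data generator

`generate_dataset()` emulates the study regime: 3 head clubs, a body of
opponents, and per-match counts from a negative-binomial law. Defaults are
the published conditions: baseline rate $753/330 = 2.2818$ incidents/match
and dispersion $\hat\theta = \bar h^2/(s^2-\bar h) = 0.398$, the
gamma–Poisson size that matches the published benchmark mean/SD pair (the
source gives no dispersion estimate; this moment match is an emulation
choice). The default 30 matches per pair sits at the top of the published
per-pair range ("2 to dozens") and is the design point used for the power
analyses. Planted effects multiply a pair's rate (ratio > 1 rivalry, < 1
alliance) and are recorded in a planted-truth sidecar. A Poisson option
exists for limit checks. A single seed makes output byte-identical;
calibration derives one seed per replicate from a master seed.

What the generator does *not* emulate: seasonal/temporal structure, heaped
or censored police counts, correlation between matches of the same pair,
and schedule imbalance beyond a per-pair match count. Passing tests
therefore validate the statistical machinery under the stated count law,
not the full texture of real police data.

## Calibration findings and limitations

`run_calibration()` regenerates data, classifies every planted-neutral pair,
and reports the empirical rejection rate and recovery accuracy. Rejection is
evaluated through the level-$\alpha$ two-direction procedure (the union of
the two directional tests at $\alpha/2$), whose nominal null rejection
probability is exactly $\alpha$; the benchmark is either the full pool (the
published convention — the tested pair contaminates its own reference) or
leave-one-pair-out, which isolates the count-law behaviour.

The acceptance-grade calibration in the test suite (all-neutral planting at
the default study regime, 2000 replicates, leave-one-pair-out benchmark)
measures an empirical size of roughly 0.10 at nominal $\alpha = 0.05$ — the
t-approximation is markedly anticonservative on counts this overdispersed at
study-like per-pair sample sizes. The mechanism is the strong positive skew
of the count law: samples that happen to land low also exhibit collapsed
sample SDs, inflating the left tail — i.e. precisely the *alliance* side of
the procedure, which is where all of the published significant findings lie.
The corresponding test is deliberately left failing rather than retuned,
since it documents a real property of the method under the study conditions;
the uniformity property test uses a documented Kolmogorov–Smirnov tolerance
of 0.07 chosen to accommodate this known drift while still catching gross
errors (wrong tail, sidedness or df rule). Recovery of strong planted
effects is unaffected (accuracy $\ge 0.9$ at rate ratio 5 with 30
matches/pair).

Problem sizes in the test suite are the package's own choices: 12 opponent
clubs and 30 matches/pair for calibration (the benchmark side then pools
over a thousand matches, dominating no single pair), 100–340 replicates for
property checks, 2000 for the acceptance-grade null calibration.

## Network semantics

`build_network()` renders the broader landscape view: every club with at
least one incident against a head becomes a node (sized by an affine map of
$\log(1+\text{total incidents})$, stable under the heavy-tailed counts), and
every (head, club) pair with at least one incident becomes an edge whose
rendered length is $1/(1+\text{incidents})$ — only the ordering is
contractual. The per-edge **relevance score** is defined here as the
head-conditional incident share (edge incidents / head total, summing to 1
per head); the original source cites a relevance statistic without printing
its formula, so this definition is an interpretation, labelled as such in
output. Cluster membership (direct vs indirect enemies) is the dominant-head
partition attribute, not geometry.

Affinity subnetworks can be extracted under two relation modes:
`"statistical"` (step-2 labels) or `"incident"` (any co-occurring violence
counts as hostility — the reading under which the published coup/clash
instances enumerate 16, 23 and 31 member clubs). Requesting a coup between
heads inferred as rivals requires an explicit assumed-relation override.
The circular layout is deterministic: heads on an inner circle separated
inversely with their rivalry grade, opponents on `layers` outer rings at the
weighted mean of head directions, so a club sits nearer the head with the
larger affinity statistic and exactly between tied heads.

Exports: a documented Pajek dialect (`.net` vertices with label/x/y/size and
weighted edges, `.clu` 1-based partitions; byte-identical round trips),
GraphML with full attributes, and node/edge CSVs.

## Known limitations

* The first-step (head-pair) p-values are not reproducible from published
  numbers; the package treats their labels as inputs.
* The declaration registry bundled with the fixture is a synthetic minimal
  reconstruction, not the original appendix.
* The benchmark test inherits the anticonservatism described above;
  alliance findings at study-scale sample sizes should be read with that
  bias in mind, or checked against the calibration report for the design at
  hand.
* Relations are treated as static over the data window; temporal dynamics
  of fan-base alignments are out of scope.
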