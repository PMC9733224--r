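---
title: "Methods: signed co-occurrence networks and temporal persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-occurrence networks and temporal persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpersist)
```

## The problem

Longitudinal amplicon studies — here, the faecal microbiome of weaner pigs
sampled on days 0, 8, 22, 36, 57 and 87 post-weaning under two dietary
arms (a control arm, CL, and a yeast-fed arm, YL) — ask not only *which*
taxa respond to a treatment but whether the *associations among taxa*
persist as the community develops.  `netpersist` answers this in two
stages: it infers one signed co-occurrence network per (time point,
condition) stratum from the count table, and then classifies the nodes
and signed edges of each per-condition network series as stable or
transient across consecutive sampling occasions.

## Per-stratum network inference

16S count data are compositional: only relative abundances are
identified, and the unit-sum constraint induces spurious negative
correlation.  We therefore work on the centered log-ratio (CLR) scale,

$$z_{si} = \log(x_{si} + c) - \frac{1}{p}\sum_{j=1}^p \log(x_{sj} + c),$$

with pseudocount $c = 1$ by default (counts are integers, so $+1$ is the
smallest offset that leaves zeros meaningful; it is configurable).  On
the CLR scale, conditional dependence is estimated by
Meinshausen–Bühlmann neighborhood selection: each taxon's CLR column is
regressed on all others with an $\ell_1$ penalty,

$$\hat\beta^{(i)} = \arg\min_\beta \tfrac{1}{2n}\lVert z_i - Z_{-i}\beta
\rVert^2 + \lambda \lVert\beta\rVert_1,$$

columns standardized internally to zero mean and unit (population)
variance.  An edge $\{i, j\}$ is kept when either regression selects the
partner (the `"or"` rule; `"and"` is available), its weight is the
coefficient of larger magnitude, and its sign — proportional versus
inverse-proportional association — is the sign of that coefficient.

The penalty is chosen by StARS: `n_subsamples = 50` subsamples of size
$b = \min(\lfloor 10\sqrt n\rfloor, \lfloor 0.8 n\rfloor)$ are drawn
without replacement, the neighborhood graphs are fitted over a 20-point
log-spaced penalty path from $\lambda_{max}$ (the largest absolute
off-diagonal CLR correlation — the smallest penalty at which every
neighborhood is empty) down to $\lambda_{max}/100$, and the total
instability $D(\lambda) = \bar{2\xi_e(1-\xi_e)}$ over all node pairs is
monotonized from the sparse end.  The selected $\lambda^\*$ is the
smallest penalty (densest graph) whose monotonized instability stays at
or below $\beta = 0.05$, the conventional StARS cut.  If no penalty
qualifies, the empty graph at $\lambda_{max}$ is returned with a
warning.  The final network is refitted on the complete stratum data at
$\lambda^\*$; every taxon that passed the abundance filter remains a
node, so isolated nodes are meaningful (sparse strata routinely leave
most nodes disconnected).

With eight samples per stratum, as in the study design emulated here,
$b = 6$: stability estimates at such $n$ are necessarily coarse, which
the package signals with a message.  This is a property of the design,
not of the estimator.

## The abundance filter

Before inference, counts are collapsed to genus (agglomeration keyed on
the full lineage prefix, so homonymous genera in different families stay
separate, and taxa unclassified at genus are grouped by their deepest
classified prefix plus an explicit `unclassified` marker).  A taxon
enters a stratum's network when it has at least `min_count = 3` reads in
at least 20% of *all* samples **and** in at least 50% of the *stratum's*
samples.  We read the one-sentence filter rule as this conjunction — the
global clause evaluated once, the 50% clause per stratum — because
networks are built per stratum and a purely global 50% rule would
contradict per-stratum filtering; the "in its own stratum" reading is
implemented (not "in every stratum" or "in at least one").  Both
prevalence comparisons are inclusive (`>=`), with an epsilon guard so
decimal thresholds that are not binary-exact never flip a true boundary.
Sample-depth discards (e.g. the strict `< 40,000` rule used for
diversity summaries) are available separately and are *not* applied
before network inference by default, since the original depth rule is
stated for the diversity analyses; `min_depth` in the pipeline
configuration turns it on.

## Persistence classification

For one condition, the time-ordered networks form a series.  A node is
*present* at a time point when it has degree ≥ 1 there — a taxon that
passes the abundance filter but joins no association is not "in" the
network for persistence purposes (configurable via
`presence_rule = "in_node_set"`).  Then:

* a node is **stable** when present at two or more consecutive time
  points (`n_transitions` counts the consecutive present–present pairs;
  a node present at all five post-baseline occasions has exactly 4);
* a node is **transient** when present somewhere but never consecutively;
* a node **transits the whole experiment** when present at every time
  point, the baseline excluded by default (`exclude_baseline = TRUE`),
  mirroring the d0-excluded convention of the study design — the
  alternative strict reading is a flag away;
* an edge occurrence at time $t$ is **stable** when the same pair is
  present at $t+1$ *with the same sign*, otherwise **transient**; a sign
  flip breaks stability because "the same microbe–microbe relationship"
  implies the same direction of association (`sign_strict = FALSE`
  relaxes this).  Final-time-point occurrences have no following network,
  are classified transient, and are flagged `terminal` so summaries can
  exclude them.

Transitions are counted over consecutive sampling occasions; the uneven
calendar spacing (8 → 22 → 36 …) is deliberately ignored.  Pairs that
maintain a same-sign connection across two or more consecutive networks
are additionally reported with the maximal run they span.

## The synthetic generator

Ground truth for every downstream stage comes from a
logistic-normal-multinomial generator — the model class under which CLR
plus sparse precision estimation is consistent.  Latent abundances are
multivariate normal with a planted sparse precision matrix $\Omega$;
each sample's composition is the softmax of its latent vector;
sequencing depth is log-normal (median 60,000, $\sigma_{\log} = 0.3$,
matching the order of magnitude of typical MiSeq runs of this design);
counts are multinomial.  The planted truth graph has an edge wherever
$\Omega_{ij} \neq 0$ with sign $-\operatorname{sign}(\Omega_{ij})$, the
partial-correlation sign that inference should recover.

Support structures are `chain`, `band` (half-width 2 by default) and
`random`; off-diagonal magnitudes default to 0.3 — a moderate partial
correlation typical of published co-occurrence benchmarks — with random
signs, positive definiteness enforced by diagonal loading to minimum
eigenvalue 0.05 followed by rescaling to unit diagonal (support and
signs are preserved; magnitudes shrink accordingly).  Between
consecutive time points `evolve_truth` removes a recorded fraction of
edges (default 0.2), plants an equal number of new ones on empty pairs,
and isolates a recorded fraction of nodes (default 0.1) by deleting
their incident edges; the returned record lists exactly which edges and
nodes changed, and is derived from the actual before/after support so it
is consistent with the truth graphs by construction.  The default
design — two conditions, six time points, eight subjects per arm —
reproduces the study shape (96 samples, 12 strata).

What the generator does **not** emulate: subject-level random effects
(the network stage pools samples per stratum, so longitudinal
within-pig correlation is ignored), zero inflation beyond what the
multinomial induces, phylogenetic signal in the synthetic lineages, and
taxonomic misclassification.  Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every failure mode of real amplicon data.

## Numerical choices

* The lasso is solved by cyclic coordinate descent on the Gram matrix
  with fixed coordinate ordering, convergence tolerance $10^{-6}$ on the
  maximum coefficient change, at most $10^4$ sweeps, and a glmnet-style
  active-set strategy; together with warm starts along the path this
  makes the entire fit deterministic given its inputs.
* Constant CLR columns (taxa identical in every sample of a subsample)
  are dropped from the regressions — their correlations are treated as
  zero — with a warning.
* One master seed drives everything; per-stratum seeds are derived as
  `master XOR hash(stratum label)` modulo $2^{31}-1$ and recorded in the
  per-stratum JSON sidecars, so strata are independent yet the whole run
  is byte-reproducible.
* Edges are stored with the lexicographically smaller taxon first, which
  makes edge-set comparisons across networks well-defined.
* Test and benchmark problem sizes (e.g. recovery at $p = 30$,
  $n = 200$, ten replicates; closure checks at $p = 15$–20) were chosen
  as the smallest sizes at which the statistical claims are meaningful.

## Design decisions that were genuinely open

* **MB versus glasso.** Only neighborhood selection is implemented; the
  reference SPIEC-EASI implementation defaults to MB and the original
  analysis does not state a mode.
* **Presence = connected.** The degree ≥ 1 rule (rather than
  filter-passing membership) reflects that persistence questions concern
  taxa *participating* in associations; the alternative is one flag away
  and both are exercised in the tests.
* **Whole-experiment transit.** Read as "present at every time point
  from the second onward"; the stricter every-point reading is the
  `exclude_baseline = FALSE` branch.
* **Post-collapse units are the node identity.**  Networks are built on
  genus-collapsed units, and persistence is reported on those same
  units.

## Limitations

Stability selection at $n = 8$ per stratum is coarse, and inferred
per-stratum networks at that depth should be read as conservative
sketches; the recovery guarantees quoted in the test suite hold at
$n = 200$.  The persistence classification itself is purely
combinatorial and exact — its correctness is established against
brute-force enumeration independent of sample size.  No statistical
test is attached to condition differences in persistence counts; the
package reports the counts and set differences only.
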