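---
title: "Multimorbidity networks with Ising graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity networks with Ising graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbnet)
```

## The problem

In an elderly population, chronic conditions co-occur far more often than
chance would predict. Pairwise co-occurrence statistics, however, conflate
two very different things: a *direct* association between two diseases,
and a *spurious* one induced by their joint connection to third
conditions. morbnet treats a set of binary disease-group indicators as an
interconnected system and estimates an undirected graphical model in
which a missing edge means conditional independence given all other
variables — the association that remains after the rest of the system has
been accounted for.

## The model

For binary indicators $X_1,\dots,X_p \in \{0,1\}$ we use the Ising model,
the pairwise subfamily of the log-linear model:

$$
P(x) \;\propto\; \exp\Big(\sum_i \lambda_i x_i
  \;+\; \sum_{i<j} \lambda_{ij} x_i x_j\Big).
$$

Two properties drive everything in the package:

* with the $\{0,1\}$ coding, $e^{\lambda_{ij}}$ is **exactly** the
  conditional odds ratio of $X_i$ and $X_j$ at any fixed configuration of
  the remaining variables, so an edge weight has a direct epidemiological
  reading (we deliberately do not use the $\{-1,+1\}$ spin coding, under
  which this identity fails);
* $\lambda_{ij} = 0$ if and only if $X_i \perp X_j \mid$ rest, so the
  graph structure is the zero pattern of the interaction matrix.

Restricting to pairwise interactions matters in practice: with 12+
variables the full contingency table is sparse even at registry scale
(most cells empty), and higher-order log-linear terms are not estimable.

Because the odds ratio is asymmetric around 1, reporting uses Yule's
$Q = (\mathrm{OR}-1)/(\mathrm{OR}+1) \in [-1, 1]$, a symmetric transform
with $Q(1) = 0$.

## Marginal versus conditional screening

`marginal_or_matrix()` computes all $p(p-1)/2$ collapsed 2×2 odds ratios
with Wald tests on the log scale and Holm step-down adjustment
(`holm_adjust()`, which wraps `stats::p.adjust`). The Holm method is used
because it controls the family-wise error rate under arbitrary dependence
of the p-values — pairwise tests on the same cohort are anything but
independent. The paper-style contrast is reproduced analytically in the
test suite: for a three-variable chain
($\lambda_{12}=\lambda_{23}=\log 2$, $\lambda_{13}=0$) the two
conditional odds ratios of the end variables equal 1 exactly while the
collapsed marginal odds ratio exceeds 1 — a spurious association carried
entirely by the middle node. `conditional_strata_tables()` makes the
conditioning concrete: for a pair among 12 variables it enumerates all
$2^{10} = 1024$ strata of the remaining indicators and computes the
per-stratum odds ratio wherever the four cells are positive. These
stratum tables are descriptive only; no pooling (e.g. Mantel–Haenszel) is
applied, because their role is to *define* conditional independence, not
to estimate a common effect.

Inference choices the data cannot decide for us: the marginal screen uses
a Wald test with $SE = \sqrt{1/a+1/b+1/c+1/d}$ (fast, standard, and
accurate at registry-scale counts), 95% intervals, default
$\alpha = 0.05$. Zero cells are an error unless the Haldane–Anscombe
correction is switched on (`continuity = TRUE` adds 0.5 to every cell of
an affected table); the correction is off by default so that sparse data
problems surface rather than being silently smoothed.

## Two-step estimation

**Step 1 — structure.** `learn_structure()` runs one logistic regression
per node against all remaining nodes (sex and age band included as
ordinary nodes when present) and eliminates predictors backwards under
the extended BIC,
$\mathrm{EBIC} = -2\ell + k\log n + 2\gamma k \log m$, with $m$ the
number of candidate predictors. Backward-only elimination (no re-entry)
mirrors the selection the method prescribes. The default $\gamma = 0.25$
is a middle value of the range used in the EBIC literature for node-wise
binary model selection; $\gamma = 0$ recovers the BIC and larger values
are more conservative. Neighborhoods are combined with the **AND** rule
by default (an edge requires each endpoint to select the other), limiting
false edges before the joint refit; **OR** is available by flag.

Determinism and degeneracies are handled explicitly: among removals whose
EBIC ties within $10^{-9}$, the predictor with the smallest absolute Wald
z in the current model is removed first, then ties break by variable
order. A separated or non-convergent node-wise fit is replaced, for
selection only, by a ridge-penalized logistic fit (fixed ridge $10^{-4}$
on the slopes, intercept unpenalized) and a warning names the node.

Each node-wise likelihood is computed on the cohort aggregated to unique
0/1 row patterns with frequency weights. The weighted binomial
log-likelihood is identical to the row-wise Bernoulli one, so selections
are unchanged, but the cost per fit scales with the number of distinct
disease profiles (hundreds to a few thousand) rather than with $n$ —
which is what makes repeated selection at $n = 10^5$ routine.

**Step 2 — parameters.** `fit_ising_mle()` maximizes the exact likelihood
jointly over the free parameters (all main effects, plus one interaction
per learned edge) by Newton iterations in the exponential-family
parameterization: the gradient is observed minus expected sufficient
statistics and the Hessian is their model covariance, both obtained by
enumerating the $2^p$ states. Initialization is deterministic at zero;
convergence requires a per-individual gradient max-norm below $10^{-9}$
(a thousand-fold stricter than the $10^{-6}$ moment-match the package
promises), with step halving as a safeguard. Enumeration is capped at $p \le 20$;
the intended applications have $p \approx 14$. At the optimum the fitted
one-node and edge moments equal the sample means — the classical
moment-matching property — and this is checked directly in the tests,
together with agreement (to $10^{-4}$) with an iterative-proportional-
fitting oracle for the equivalent hierarchical log-linear model. Standard
errors come from the inverse observed information and feed the per-edge
Wald tests (`edge_wald()`).

If an observed margin involved in moment matching is exactly 0 or 1 the
MLE is infinite; the empirical moment vector is then shrunk toward the
uniform-distribution moments with weight $1/(2n)$ — the scale of half an
extra observation — and a warning is raised. No second significance
pruning is applied after the joint fit: blank cells of the conditional
odds-ratio matrix are exactly the edges excluded by structure learning.

## Topology

`centrality_table()` reports closeness (inverse of the summed shortest-
path distances to all other nodes) and betweenness (share of shortest
paths passing through a node), both computed on the *unweighted* learned
graph — edge strengths are reported alongside, but the centrality
measures answer a structural question and the normalized values we mirror
are consistent with unweighted computation. Each measure is min–max
normalized to $[0,1]$, the only normalization under which the most
central node takes value 1 and the most peripheral 0 on both scales
simultaneously; rows are ordered by descending normalized closeness.
Distances and betweenness are computed via igraph and verified against
brute-force path-enumeration oracles on randomized small graphs. For
disconnected graphs, unreachable pairs are assigned distance $p$: this
keeps closeness finite, ranks isolated nodes last, and is flagged with a
message. Density is $|E| / \binom{p}{2}$.

## Subgroups

Adding sex and age band as nodes adjusts every disease–disease edge for
them but forces a single interaction per pair across all subgroups.
`stratified_networks()` instead re-learns and refits the model
independently within the four sex × age-band strata (diseases only — the
covariates are constant within a stratum), using the same $\gamma$ and
combination rule as the pooled fit so that densities are comparable.
Because women are on average older than men, `age_balance()` first
retains an equal number of men and women within each five-year age band
(closed-open intervals from 65, the last band open-ended at 85+), by
seeded subsampling of the larger sex without replacement.

Edge sets are compared as three disjoint sets (only-in-A, only-in-B,
shared); on shared edges `compare_edge_logor()` performs the two-sample z
test $(\hat\lambda_A - \hat\lambda_B)/\sqrt{SE_A^2 + SE_B^2}$, valid
because strata are disjoint and fits independent. An edge absent in one
stratum yields an explicit *not comparable* result rather than a test —
the qualitative statement "present in women, absent in men" is the
finding itself. Holm adjustment across the shared edges is available but
off by default; when many comparisons are read at once it should be
switched on.

## The synthetic cohort generator

The study conditions the package validates against come from a
registry-style elderly cohort that is not publicly available, so the
generator is a first-class module rather than a test fixture.
`make_multimorbidity_preset()` defines a 14-node ground truth — the 12
major ICD-9-CM disease groups plus sex and age band — with:

* marginal prevalences calibrated by a deterministic fixed point against
  the exact enumerated joint to registry-scale values (cardio-circulatory
  9.66% down to psychiatric 0.66%; sex 45%, older band 50%);
* a cardio-circulatory hub carrying positive interactions to 10 of the
  11 other disease groups, plus a few off-hub links (endocrine–neoplasm,
  blood–neoplasm, sensory–psychiatric) and covariate effects (age raising
  cardio-circulatory and neurological risk, sex effects on
  cardio-circulatory and musculoskeletal disease, the latter negative);
* interaction magnitudes fixed between $\log 1.2$ and $\log 3$, the odds-
  ratio range discussed for real multimorbidity edges, with stronger
  values assigned to rarer partners so every edge carries comparable
  information. These are documented constants, not fitted quantities.

Exact sampling draws i.i.d. rows from the enumerated joint ($p \le 20$).
The Gibbs sampler runs one independent chain per simulated individual —
1000 full update sweeps of the logistic full conditionals from random
starts — rather than thinning a single long chain: draws from distinct
chains are exchangeable by construction, the scheme vectorizes across
individuals, and its output is validated against the exact sampler with a
goodness-of-fit test on all $2^p$ state frequencies. Integer ages
consistent with the age band (uniform 65–75; geometrically tapered 76–95)
support the age-balancing path.

What the preset does *not* emulate: higher-order interactions,
negative disease–disease dependence, diagnostic misclassification,
within-person correlation over time, or the real cohort's joint
distribution in any quantitative sense. Passing recovery tests on these
cohorts therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to their violation.

## Validation problem sizes

The test-suite simulations use sizes chosen to make their success
criteria sharp rather than marginal: structure recovery on a 5-node
chain ($\lambda = \log 3$, $n = 50{,}000$, 20 replicates) and on the
14-node preset ($n = 100{,}000$, 5 replicates, median edge sensitivity
and specificity), parameter recovery at the 3-SE level on a 6-node chain
($n = 100{,}000$), subgroup edge-detection and strength-comparison power
at the OR 3.14 vs 1.3 contrast ($n = 50{,}000$ per stratum), and null
calibration of the comparison test on identical truths. Oracle checks
(IPF, Floyd–Warshall, path enumeration, Holm step-down, bootstrap SEs)
run at small $p$ where brute force is exact.

## Known limitations

* The exact likelihood and sampler enumerate $2^p$ states; beyond
  $p = 20$ the package refuses rather than silently approximating
  (pseudo-likelihood fitting is the natural extension).
* Backward-only selection cannot re-admit a predictor dropped early;
  with strongly correlated hubs this can occasionally cost an edge.
* The two-step procedure conditions the joint fit on the learned
  structure; reported standard errors do not account for selection.
* Undirected edges are associations, not causal effects; a marginal
  independence with conditional dependence (collider structure) will be
  rendered as an edge, as in any undirected model.
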