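# morbnet

Multimorbidity network analysis with Ising graphical models.

In elderly populations, chronic diseases co-occur in patterns that
pairwise co-occurrence statistics cannot disentangle: two conditions may
look strongly associated merely because both are linked to a third.
morbnet estimates an undirected graphical model on binary disease-group
indicators in which a missing edge means *conditional independence given
all other variables*, separating direct disease–disease associations
from spurious ones carried by the rest of the system.

The model is the Ising distribution on indicators
$X_1,\dots,X_p \in \{0,1\}$:

$$P(x) \propto \exp\Big(\textstyle\sum_i \lambda_i x_i + \sum_{i<j} \lambda_{ij} x_i x_j\Big),$$

where $e^{\lambda_{ij}}$ is exactly the conditional odds ratio of the
pair given the remaining variables and $\lambda_{ij}=0$ encodes a missing
edge. Estimation is two-step: (1) structure learning by node-wise
logistic regressions with backward elimination under the extended BIC
($-2\ell + k\log n + 2\gamma k\log m$), combining neighborhoods with an
AND rule; (2) joint maximum likelihood of all main effects and the
retained interactions by Newton iterations on the exact likelihood, with
standard errors from the observed information. Around the core model the
package provides the marginal odds-ratio screen with Holm correction,
conditional-stratum enumeration, Yule's $Q$ reporting, network topology
(density, min–max-normalized closeness/betweenness), sex×age stratified
networks with five-year age-band balancing and formal edge-strength
comparison, ICD-9-CM major-group mapping, and a seeded synthetic Ising
cohort generator used as ground truth for validation.

## Worked example

```r
library(morbnet)

## a registry-style synthetic cohort: 12 disease groups + sex + age band
spec   <- make_multimorbidity_preset(n = 50000, seed = 1)
cohort <- sample_cohort(spec)

## marginal screen on the 12 disease indicators
mm <- marginal_or_matrix(cohort, continuity = TRUE,
                         nodes = setdiff(spec$truth$labels,
                                         c("sex", "age_band")))
mm$n_tests
#> [1] 66

## conditional strata for one pair among the 12 diseases
conditional_strata_tables(cohort, "SEN", "GEN",
                          nodes = setdiff(spec$truth$labels,
                                          c("sex", "age_band")))
#> Conditional 2x2 tables of (SEN, GEN) over 1024 strata of 10 variables
#> (8 non-degenerate)

## two-step estimation: EBIC structure learning, then joint Ising MLE
g   <- learn_structure(cohort)
g
#> Undirected graph: 14 nodes, 16 edges, density 0.176
fit <- fit_ising_mle(cohort, g)
conditional_or_matrix(fit)$or["CCD", "BLO"]
#> [1] 1.96

## topology: the cardio-circulatory hub is the most central node
centrality_table(g)
#> Centrality table (density 0.176):
#>      node closeness_raw betweenness_raw closeness betweenness
#>       CCD         0.038            61.5     1.000       1.000
#>       NEO         0.029             0.5     0.700       0.008
#>       BLO         0.028             0.0     0.676       0.000
#>       ...
#>       SEN         0.005             0.0     0.000       0.000
```

The 66 is the number of distinct pairs $p(p-1)/2$ tested by the marginal
screen; the 1024 strata are the $2^{10}$ level combinations of the other
ten indicators that define the pair's conditional odds ratios. After
structure learning, `CCD–BLO` carries a conditional odds ratio of about
2 (its ground-truth value), while pairs without an edge — e.g. SEN–GEN —
are conditionally independent and rendered blank. In the centrality
table each measure is min–max normalized, so the hub takes 1 on both
scales and the most peripheral node (SEN) takes 0.

The spurious-association mechanism itself is easiest to see exactly: for
a three-variable chain with $\lambda_{12}=\lambda_{23}=\log 2$ and
$\lambda_{13}=0$, the conditional odds ratios of the two end variables
equal 1 in both strata of the middle variable, while their collapsed 2×2
table has an odds ratio of $10/9 \approx 1.11$ — association without a
direct link.

A command-line wrapper over the same pipeline is installed at
`inst/cli/morbnet.R` (subcommands `simulate`, `marginal`, `fit`,
`topology`, `stratify`, `all`).

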