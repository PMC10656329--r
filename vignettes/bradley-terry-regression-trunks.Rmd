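---
title: "Bradley-Terry regression trunks: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bradley-Terry regression trunks: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(btrtrunk)
```

## The model

A panel of $H$ judges states complete rankings (no ties) of $n_o$ objects,
or equivalently the $n_o(n_o-1)/2$ binary paired comparisons each ranking
implies. The Bradley-Terry model places each object at a worth
$\lambda_i$ on a latent preference scale and sets, on the half-log-worth
parameterization $\lambda_i = \tfrac12\ln\pi_i$,

$$
P(i \succ j) \;=\; \frac{\exp\{2(\lambda_i-\lambda_j)\}}
                        {1+\exp\{2(\lambda_i-\lambda_j)\}} ,
$$

so that equal worths give probability one half. The factor 2 is a
parameterization choice, not a substantive one; we adopt it throughout
(estimation, prediction, simulation) so that worths, generating values and
estimates all live on the same scale. Identifiability pins the last object
in label order at $\lambda_{n_o}=0$.

Judge heterogeneity enters through $P$ numeric subject covariates
(dichotomous ones coded 0/1). The judge-specific worth of object $i$ is

$$
\lambda_{i,h} \;=\; \lambda_i \;+\; \sum_{p=1}^{P}\beta_{i,p}\,x_{p,h}
 \;+\; \sum_{t=1}^{T-1}\beta_{i,P+t}\,
       I\{(x_{1,h},\dots,x_{P,h})\in t\} ,
$$

a linear main-effects part plus a small set of *threshold interactions*:
indicator terms for the terminal regions $t$ of a shallow binary tree (the
"trunk") over the covariates. One terminal region is the reference and
carries no indicator. The full model therefore has
$(n_o-1)(1+P+T-1)$ structural parameters (`count_parameters()`).

### Log-linear representation and profiled fitting

The classical log-linear (Poisson) representation places each comparison
into two cells — "$i$ preferred" and "$j$ preferred" — whose means share a
nuisance parameter that fixes the pair total at its observed value of 1.
`build_design()` materializes exactly this design ($n = n_o(n_o-1)H$ rows)
for audit and for the test oracles. For fitting, the nuisance parameters
are profiled out analytically: conditioning each pair on its total turns
the Poisson model into a binomial logit on the binary outcomes with linear
predictor $2(\lambda_{i,h}-\lambda_{j,h})$, with identical structural
estimates and identical deviance

$$
D \;=\; 2\sum y \,\log\!\big(y/\hat m(y)\big)
$$

over the cells (the $y\log y$ convention $0\log 0=0$ applies). The test
suite verifies the equivalence coefficient-by-coefficient against an
explicit Poisson fit with nuisance dummies on small random instances.

Standard errors come from the observed information of the profiled fit. An
overdispersion factor $\hat\varphi$ = Pearson $X^2$ / residual df (residual
df $= n_o(n_o-1)H/2 - k$ for $k$ structural parameters) scales the
corrected standard errors, $\mathrm{SE}_{\mathrm{corr}} =
\mathrm{SE}\cdot\sqrt{\hat\varphi}$. The Pearson form was chosen because it
is the standard moment estimator; nothing downstream depends on this
choice.

## Growing the trunk

`grow_trunk()` starts from the main-effects fit in the root. Each step
considers, over **all** current terminal nodes jointly, every eligible
covariate and every distinct observed value within the node except its
maximum as a candidate threshold $v$, forming the dichotomizer
$I(x_p \le v)$ ("left" is always $\le$). For every candidate the *full*
model — all existing terms plus the refreshed region indicators — is
refitted and the candidate maximizing the decrease in $D$ wins; ties go to
the lowest covariate index, then the lowest threshold, then the lowest
node id. Children with fewer than `min_bucket` judges (default 5, counted
in judges, not design rows) are inadmissible, and a node needs at least
`2 * min_bucket` judges to be split at all. Growth stops at
`max_terminals` or when no admissible candidate remains.

Two search modes are provided: *multiple splitting* (`"ms"`, any covariate
can split any node) and *one split only* (`"oso"`, a covariate used once is
excluded from later splits). OSO guarantees that the retained interactions
involve distinct covariates; MS attains at least as large a deviance
reduction per step while the two trees coincide, which the tests check.

The reference region is the terminal reached from the root by always
taking the ">" branch; if it is split, reference status passes to its
right child. Raw observed values (not midpoints) are used as thresholds,
so a 0/1 covariate has the single threshold 0.

Candidate refits are warm-started along the threshold sweep of each
(node, covariate) chain — identical column layout, slowly varying
memberships — which makes the exhaustive scan cheap; any irregular
candidate falls back to a cold generalized-linear-model fit, and a
candidate that still fails is skipped with a warning rather than aborting
the search.

## Pruning by cross-validated deviance

`cv_profile()` cross-validates at the **judge** level: all rows of a judge
share a fold (V = 10 by default), fold sizes differ by at most one. For
each fold, a trunk of the same maximum size is **regrown from scratch** on
the V−1 training folds, and for each size $t$ its model predicts the
held-out judges' cells, routing them into regions through the fold-trunk's
threshold predicates. The pooled case-wise cross-validation deviance and
its standard error are

$$
D^{cv} = \frac1n \sum_i d_i , \qquad
SE^{cv} = \frac1n \sqrt{\frac1n \sum_i \big(d_i - D^{cv}\big)^2},
\qquad d_i = 2\,y_i\log(y_i/\hat y_i),
$$

with held-out probabilities clipped to $[10^{-10}, 1-10^{-10}]$ before the
log. `prune_select()` then applies the $c\cdot SE$ rule: with
$t^{*}$ the size minimizing $D^{cv}$, the selected size $t^{**}$ is the
smallest $t$ with $D^{cv}_t \le D^{cv}_{t^*} + c\cdot SE^{cv}_{t^*}$; it
is nonincreasing in $c$, and $c=0$ returns the minimizer itself.

Two design decisions here were genuinely open and deserve a record:

* **Why regrow the structure per fold?** The alternative — keep the
  full-data tree and refit only coefficients per fold — leaks information:
  the thresholds were selected using the held-out judges, so spurious
  splits *reduce* the cross-validated deviance. Measured under a null
  generating process, that variant retains at least one spurious split in
  about two thirds of replicates even at $c=0.9$, while the regrown
  variant correctly drives the type I error to zero and reproduces the
  qualitative shape — $D^{cv}$ falling to the true size and rising beyond
  it — that motivates the rule in the first place. Regrowth makes the
  per-size profile well defined by indexing fold models by size; a fold
  that admits fewer splits carries its largest model forward.
* **The scale of $SE^{cv}$.** The per-row contributions $d_i$ are heavily
  skewed (half of them are structural zeros), and several conventions for
  their standard error circulate. We use the root-mean-square deviation of
  the contributions about $D^{cv}$, divided by $n$ — the scale on which
  published model-selection tables for this class of models report their
  standard errors, a few times $10^{-4}$ for $n$ in the low thousands. The
  hand-worked two-cell example in the test suite freezes this definition.

## The synthetic-data generator

`scenario_config()` + `simulate_preferences()` implement three generating
processes over four iid standard-normal covariates: (1) one active
covariate, (2) four active covariates, (3) four active covariates plus a
threshold interaction $I(x_1>0 \wedge x_2>0.5)$ with its own object
effects. Consensus worths are $(0.9,0.4,0.3,0)$ for four objects and
$(0.8,0.4,0.2,0.1,0)$ for five; each scenario has a low and a high
effect-size table, with the last object's effects always zero. All four
covariates are always generated and supplied to the fitted model —
inactive ones have zero coefficients — so that the null scenarios expose
the split search to genuine noise covariates and the one-split-only mode
has material to overfit; with a single observed covariate the search could
never grow past one split and the null rejection rates would be
structurally understated.

Outcomes are Bernoulli draws with the preference probability above. A
judge's binary pattern need not be transitive ($2^{n_o(n_o-1)/2}$ patterns
vs $n_o!$ rankings; 64 vs 24 for four objects); intransitive patterns are
replaced by the closest permutation pattern in Hamming distance — which on
comparison vectors equals the Kendall distance of the implied orders —
with ties broken uniformly at random. The generator can also return raw
patterns (`project = FALSE`) for calibration checks; the tests verify the
pre-projection win frequencies against the generating probabilities.

What the generator does *not* emulate about real panels: correlated or
non-normal covariates, judge-specific response styles, partial rankings,
and any dependence between comparisons beyond the common worth vector.
Passing the simulation tests therefore says the machinery is correct under
the stated process, not that real survey data satisfies it.

`run_study()` chains simulate → grow (one-split-only by default, to
`max_terminals = 5`) → cross-validate → prune for a grid of $c$ values and
reports, for the null scenarios, the proportion of replicates whose pruned
trunk retains any split (type I error), and for scenario 3 the proportion
whose pruned trunk splits on exactly $\{x_1, x_2\}$ (power). At the study
conditions (100 judges, low effect, four objects) the deviance gain of
even the *oracle* interaction region is a fraction of the maximum gain
available to noise candidates, so the power of the search under this
process is intrinsically low at small samples; the type I error of the
honest cross-validation stays small at every $c$ (a few percent to ~0.25
at $c=0$, zero from $c\approx0.9$). The replicate scale
used by the automated checks is 25 per cell, with tolerances widened
accordingly.

## Consensus summaries

`consensus_by_node()` annotates each terminal region with its number of
judges, the exact median ranking, and the mean Emond-Mason $\tau_x$
between consensus and members. $\tau_x$ scores ties as agreement and
coincides with Kendall's $\tau$ on untied rankings. The median ranking
maximizes the average $\tau_x$ over **weak orders** (ties allowed in the
consensus only) by exhaustive enumeration of all ordered set partitions —
13, 75, 541, 4683 for 3-6 objects. Exhaustive search was a deliberate
substitution for stochastic heuristics: it is exact, deterministic, and
trivial at the panel sizes this model targets ($n_o \le 6$); it simply
does not scale beyond that, which is a documented limitation rather than a
missing feature. The objective factorizes through the summed member score
matrix, so the scan cost is independent of the number of judges.

## Numerical choices

* Convergence: iteratively reweighted least squares stops when the
  relative deviance change falls below $10^{-8}$, with a cap of 100
  iterations; non-convergence flags the fit instead of raising.
* Complete separation caps the working coefficients through the bounded
  step-halving of the solver; affected fits are flagged as boundary cases.
* Fitted and held-out probabilities are clipped to
  $[10^{-10}, 1-10^{-10}]$ before logs.
* Deviance ties in the split search are resolved within an absolute
  $10^{-6}$ band by the deterministic covariate/threshold/node order, so a
  duplicated covariate reproducibly loses to the lower index.
* All randomness (fold assignment, simulation, projection tie-breaks) is
  routed through explicit seeds; helper `with_seed()` restores the RNG
  state so library calls do not perturb user code.

## Problem sizes in the automated checks

The test suite exercises the full pipeline at 40-100 judges with 3-5
objects, cross-validation at 5-10 folds, and the simulation study at 25
replicates per cell; the parameter-recovery check fits root models at 300
judges over 20 replicates. These sizes keep the whole suite in the
minutes range on a single core while leaving every behavioural claim
testable at the stated tolerances.

## A worked run

```{r, eval = FALSE}
sim <- simulate_preferences(scenario_config(3, judges = 100, effect = "high"),
                            seed = 7)
m <- btrt(sim$pairs, sim$covariates, mode = "oso", max_terminals = 5,
          folds = 10, c = 0.5, seed = 1)
summary(m)
plot(m, what = "cv")
```

## Known limitations

* Complete rankings only: partial or tied input rankings are rejected.
* Nominal covariates with more than two levels are not supported; encode
  them as 0/1 indicators.
* No ties/undecidedness parameters in the comparison model.
* Exact median rankings are limited to six objects.
* The study grid at its largest published extent (five objects, 300
  judges, 100 replicates per cell) is computationally heavy; the package
  exposes the replicate count so users can scale it to their budget.
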