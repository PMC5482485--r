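---
title: "Nominal diagnosis models for situational tests: models, estimation, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominal diagnosis models for situational tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gndm)
```

## The measurement problem

Typical-performance constructs (temperament, personality, attitudes) are
usually measured with respondent-reported rating scales, which are exposed
to response biases and are norm-referenced rather than diagnostic.
Situational items offer an alternative: a realistic scenario with a set of
nominal response options, each option written to reflect a particular
combination of dichotomous latent attributes.  With `K` attributes there
are `L = 2^K` attribute patterns; respondent classification into these
patterns is the goal.

The relationship between an item's options and the attribute patterns is
coded in an *extended Q-matrix*: one row per option, with entry 1 where
the option presumes possession of an attribute, 0 where it presumes
non-possession or the attribute is not involved, and −1 marking a
*none-of-the-above* (NOA) option.  An item involving `G_j` attributes
distinguishes only the `H_j = 2^{G_j}` *reduced patterns* obtained by
restricting a full pattern to the item's attributes.  Designs are labelled
by the multiplicity of the option-to-pattern map: OCOP (one choice one
pattern, a bijection), OCMP (one choice multiple patterns; *controlled*
when every reduced pattern is covered — typically via a NOA option — and
*uncontrolled* when some patterns map to no option), MCOP and MCMP
(`classify_design()`).

## The saturated model and its reduced forms

The saturated general nominal diagnosis model (GNDM) places a free
conditional probability on every option of every item given every reduced
pattern,

$$P(X_j = c \mid \eta_{jh}) \equiv P_c(\eta_{jh}), \qquad
  \sum_{c=1}^{C_j} P_c(\eta_{jh}) = 1,$$

giving $(C_j - 1) H_j$ free item parameters (12 for a four-option
two-attribute item, 32 for a five-option three-attribute item), plus a
saturated joint attribute distribution $p(\alpha_l)$ with $L - 1$ free
parameters.  The conditional likelihood of a response vector is the
product over items of the probabilities of the observed options (local
independence given the attribute pattern), and the marginal likelihood
sums over the `L` patterns.

Two reduced summaries compress a saturated fit:

* **PEDM** (pattern-expected): per option, `e_jc` — the probability of
  selecting option `c` under its *expected* reduced pattern(s) — and
  `u_jc` — the weighted average probability under the unexpected patterns.
  Averages are weighted by the estimated pattern sample sizes
  $w_{jh} = \sum_i p(\eta_{jh} \mid X_i)$.  `2(C_j - 1)` free parameters
  per item.
* **OEDM** (option-expected): per reduced pattern, `e*_jh` — the
  probability of selecting an expected option given the pattern — with
  `u*_jh = 1 - e*_jh`; `H_j` parameters per item.

When a pattern has several expected options the package sums their
probabilities for `e*_jh` (so that `u*` remains the probability of the
complementary event); an unweighted mean is available behind
`aggregate = "mean"`.  The OEDM is treated as a summary rather than a
generative model, because nothing specifies how `1 - e*` splits across
unexpected options; a uniform-split expansion is provided for simulation
only.  PEDM fitting is two-step — fit the saturated model, collapse,
expand back to full blocks, and re-estimate the structural distribution
with blocks fixed (`fit_reduced()`) — rather than a constrained EM; the
collapsed estimates rarely satisfy the row-sum identity exactly, so the
expansion renormalizes rows as part of the procedure.

## Estimation

`gndm()` maximizes the marginal likelihood by EM.  The E-step computes
respondent posteriors over the `L` patterns; the M-step sets each block
row to the normalized expected option counts
$R_{jhc} = \sum_i p(\eta_{jh} \mid X_i) X_{ijc}$ and the structural
distribution to the mean posterior.  The loop is implemented in C++;
likelihoods are accumulated multiplicatively with probabilities clipped
at $10^{-10}$ (a respondent's conditional likelihood is then bounded
below by $10^{-10 J}$, far above double underflow at realistic test
lengths), so no per-iteration log/exp is needed.  Convergence requires
both a maximum absolute parameter change below `tol` (default `1e-5`)
and a relative log-likelihood change below `ll_tol` (default `1e-9`),
within `max_iter = 2000` cycles.  Block rows whose total expected count
falls below `1e-8` (starved rows) keep their previous values and are
flagged.  An alternative update that carries each respondent's previous
posterior as their own prior at the next cycle is available as
`variant = "individual"`; it progressively sharpens individual
posteriors and is not the default because the standard EM is the
maximizer of the marginal likelihood.

Two estimation choices deserve emphasis:

* **Orientation anchoring.**  Jointly complementing any attribute across
  all item blocks and the structural distribution is a relabeling that
  leaves the likelihood untouched, so the data cannot identify the
  orientation of an attribute — only the initialization can.  The default
  start (`init = "anchored"`) therefore centres each covered block row on
  a mild advantage (weight 3 vs 1) for the row's expected option taken
  from the expected map, with a seeded Dirichlet perturbation
  (concentration `50 C_j`).  A symmetric near-uniform start
  (`init = "uniform"`) is kept for comparison, but with it attributes
  return flipped at random and pattern-level accuracy drops to chance.
* **NOA pooling.**  A NOA option has no substantive content that could
  distinguish the missing patterns it collectively covers, so by default
  (`noa_collapse = TRUE`) those reduced patterns share a single block row.
  This is how the package reads the design: the NOA option covers its
  patterns *collectively*.  It also matters statistically — at `N = 1000`
  the pooled rows are estimated from roughly four times more effective
  observations, and in the packaged studies pattern-level classification
  accuracy under the controlled design drops by about 0.05 if every NOA
  pattern is estimated freely (`noa_collapse = FALSE`, the literal
  saturated parameterization, which is also what `count_parameters()`
  counts).

Classification (`classify()`) takes the posterior mode over the `L`
patterns for the attribute *vector* (ties broken toward the lowest
canonical pattern index — patterns are ordered by binary counting with
attribute 1 as the most significant bit) and thresholds the marginal
posterior possession probabilities at 0.5 for *individual* attributes
(0.5 counts as possession).  These are standard choices in diagnostic
classification; the vector mode maximizes the exact-match rate.

## Uncertainty and model comparison

`item_information()` evaluates the outer-product (score-based)
approximation to the Fisher information of an item's free parameters at
the estimates, with option 1 as the reference category; the score of
respondent `i` for $P_c(\eta_{jh})$ is
$p(\eta_{jh} \mid X_i) \left[ X_{ijc} / P_c(\eta_{jh}) - X_{ij1} /
P_1(\eta_{jh}) \right]$.  Free parameters are indexed
$(c - 2) H_j + h$ (`c = 2..C_j`, pattern index fastest); with NOA pooling
the pooled group takes the place of its patterns.  `item_se()` returns
square roots of the inverse-information diagonal; inversion uses a
pseudo-inverse with a condition-number warning at $10^{10}$, because
near-boundary estimates are common at high item quality.
`collapsed_se()` propagates to the PEDM/OEDM summaries by the delta
method, treating the collapse weights as constants (they are estimated
sample sizes, held at their fitted values).  `lrt_compare()` tests a
reduced model against the saturated fit by the deviance
$2(\ell_{sat} - \ell_{red})$ on a $\chi^2$ reference with degrees of
freedom equal to the difference in free item parameters (the shared
structural parameters cancel).

## Absolute fit

`assess_fit()` implements a simulated-predicted residual check: a
synthetic sample of `multiplier × N` respondents (default 10) is drawn
from the fitted model, items are dichotomized one indicator per option
`c = 2..C_j` (option 1 omitted, leaving `T − J` indicators), and for every
indicator pair the absolute difference between observed and predicted
log-odds ratios is divided by its approximate standard error
$\sqrt{\tilde N (1/\tilde N_{11} + 1/\tilde N_{00} + 1/\tilde N_{01} +
1/\tilde N_{10}) / N}$ computed from the predicted table.  A 0.5
continuity correction is added to every cell of both tables: within-item
pairs contain structural zeros (two options of one item cannot both be
chosen), and the correction keeps their tables finite, so the default
keeps within-item pairs, matching the $(T-J)(T-J-1)/2$ pair count; a flag
excludes them.  z-scores aggregate into root-mean-square statistics per
option (`sl_jc`), per item (`sl_j`), and for the whole test (`sl`), and
the maximum z-score is compared with the two-sided normal critical value
Bonferroni-corrected across all pairs.  Ranking options and items by
these statistics (`flag_misfit()`) localizes Q-matrix misspecification;
the package reports the ranking but performs no automated Q-matrix
search.  Misfit localization presumes the rest of the test anchors the
latent space — with very short tests the blame can land on a neighbouring
item.

## What the simulation harness emulates

`simulate_attributes()` draws correlated dichotomous attributes by the
multivariate-normal threshold method: a latent normal vector with unit
variances and exchangeable correlation `R` (a full correlation matrix is
accepted), thresholded so attribute `k` has prevalence `p_k`.
`simulate_responses()` generates option choices from pattern-expected
parameters: a covered reduced pattern selects its expected option with
probability `e` and each other option with probability `u`, while an
uncovered pattern (uncontrolled items) selects uniformly at random among
the options.  The packaged study conditions (`study_preset()`) are:
`N = 1000`, `K = 5` with prevalences 0.7, 0.6, 0.5, 0.4, 0.3 and
`R = 0.5`, 200 replications per cell, with per-replication seeds
`base_seed + r` so studies are bit-reproducible.  Study 1 crosses
controlled/uncontrolled three-attribute five-option items
(`sim_qmatrix(1)`) with low/high item quality (`sim_quality()`; the
uncontrolled parameters are raised slightly so that `e − u` matches the
controlled design) and test length `J = 10/20` (the ten-item form
doubled).  Study 2 mixes five two-attribute OCOP items with five
three-attribute controlled-OCMP items; its two-attribute items use the
same `e` with `u = (1 − e)/(C_j − 1)` (0.1333 at low and 0.0800 at high
quality), the only reading under which every generating row is a
probability vector.

The generator emulates clean, complete nominal response data under local
independence and a perfectly specified Q-matrix.  It does not emulate
missing responses, respondent heterogeneity in item quality, attribute
hierarchies, or mis-specified option wording, so passing simulation
checks demonstrates correctness of the estimation machinery under the
stated model, not robustness of the model on real questionnaire data.

Replication scale in the packaged checks is 200 replications of
`N = 1000` per cell (the acceptance script and the replication-scale
tests both use it), which puts the Monte-Carlo standard error of a mean
pattern-level accuracy near 0.001–0.002; smaller internal tests use a few
hundred respondents and a handful of replications, enough for the
qualitative properties they assert.

One attainability note: on the mixed design of study 2 at low quality the
Bayes-optimal classifier — posterior-mode classification using the *true*
generating parameters and the true pattern distribution — attains a mean
pattern-level accuracy of about 0.70.  Fitted-model accuracy is
necessarily below that ceiling (the package measures ≈ 0.65), while
per-attribute accuracy (≈ 0.87) and the PEDM recovery profile match
expectations; the corresponding replication-scale vector-accuracy check
is asserted at its nominal tolerance and is expected to flag this.

## Known limitations

* Missing responses are rejected at validation; there is no missing-data
  EM.
* Attributes are dichotomous and the structural distribution is
  saturated; constrained structures (higher-order, hierarchical) are out
  of scope, as are polytomous attributes.
* PEDM/OEDM are fitted by collapsing the saturated fit, not by
  constrained maximum likelihood.
* The Q-matrix is taken as given: no estimation or automated validation
  of the coding is attempted beyond misfit ranking.
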