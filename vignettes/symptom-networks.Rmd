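---
title: "Symptom networks, from item responses to simulated interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks, from item responses to simulated interventions}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses comorbid depression and anxiety symptoms as a binary
Markov random field. A respondent's state is a vector
$x \in \{0,1\}^p$ of absent/present symptoms with probability

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\Big).$$

The thresholds $\tau_i$ (log-odds scale) encode each symptom's disposition to
be active when all others are absent — negative values mean the symptom tends
to stay off. The edge weights $\omega_{ij}$ encode pairwise symptom
interactions. We work on the $\{0,1\}$ domain throughout, because the
binarization rule applied to questionnaire items (0 = absent, score $\ge 1$ =
present) defines those semantics; the common $\{-1,+1\}$ parametrisation of
the same family would change the numeric values of both $\tau$ and $\omega$.

## Estimation: eLasso

`fit_elasso()` estimates the network by node-wise L1-penalized logistic
regression. Each binary symptom is regressed on all the others along a
100-point log-spaced penalty path running from the smallest penalty that
zeroes every slope down to 1% of it (`lambda_min_ratio = 0.01`), with the
intercept never penalized. Per node, the penalty minimizing

$$\mathrm{EBIC} = -2\,\ell + k \log n + 2\gamma\, k \log(p-1)$$

is selected, where $k$ counts nonzero slopes. The defaults $\gamma = 0.25$
and the AND symmetrization rule (an edge survives only if both directed
coefficients are nonzero; its weight is their mean) are the canonical eLasso
settings; $\gamma = 0$ recovers plain BIC and denser networks, and the
selected edge count is non-increasing in $\gamma$ (a property the test suite
checks). Thresholds are the selected unpenalized intercepts.

Two deliberate edge cases: a column that is constant after binarization
aborts estimation with the column named, rather than being dropped silently
— silent dropping would corrupt node indexing for everything downstream,
interventions included. And coefficients beyond ±15 on the log-odds scale
are treated as symptoms of quasi-separation: the fit warns and caps them.

As a sensitivity companion, `partial_correlation_network()` computes the
unregularized partial correlations $-K_{ij}/\sqrt{K_{ii}K_{jj}}$ from the
inverse correlation matrix of the raw ordinal scores, and `mantel_test()`
correlates the two weight matrices (strict lower triangles) with a
permutation p-value from simultaneous row/column relabelling. The p-value is
two-sided, $(1 + \#\{|r^*| \ge |r|\})/(1 + n_{perm})$, and the seed is a
mandatory argument, as for every stochastic routine in the package. A large
Mantel $r$ indicates that binarizing the items did not distort the pattern
of symptom relationships; on data generated from the reference network at
$n = 708$ we observe $r \approx 0.8$.

## Centrality

`expected_influence()` is the one-step signed sum $\sum_{i \ne j}
\omega_{ij}$; `bridge_expected_influence()` restricts the sum to edges that
cross community boundaries (depression vs anxiety). One-step variants are
used because they are the default of the tooling this workflow standardizes;
the variant is recorded in the output's metadata. The two indices satisfy an
exact decomposition — EI equals bridge EI plus within-community influence —
which the tests assert node by node.

Standardization (`standardize_centrality()`) is a z-score across all p nodes
jointly, with the n−1 sample SD, and the conventional z > 1 rule flags
notable central/bridge symptoms. Joint (not per-scale) standardization is
used because published tables that mix both scales in one standardized
column are consistent with it.

## Accuracy and stability

`edge_ci_bootstrap()` resamples respondents with replacement and refits the
full eLasso per replicate; per-edge 95% intervals are percentile (2.5/97.5),
the default of the standard workflow, recorded as such. `difference_tests()`
bootstraps pairwise differences of edges and of node centralities on the
*same* replicate cache (`bootstrap_networks()`), halving compute; a
difference is significant when its percentile CI excludes 0.

`cs_coefficient()` uses the second, distinct resampling scheme:
case-dropping subsamples *without* replacement. For each drop proportion q
it correlates subsample and full-sample node statistics and returns the
largest q at which at least 95% of correlations stay at or above 0.7; 0.25
is conventionally acceptable, 0.5 preferred. Correlations are computed on
raw (unstandardized) statistics: standardization is an affine map per
replicate and would distort comparability across subsamples. Replicates
whose refit fails are dropped and counted; more than 10% failures abort.

## Simulated interventions

`nira_run()` simulates symptom-specific interventions by threshold
perturbation. For each node in turn, independently of the others, the
threshold is shifted by $\delta$ — alleviating subtracts, aggravating adds —
and the network's expected sum score $E[\sum_i x_i]$ (the expected number of
simultaneously active symptoms, the severity outcome) is recomputed. The
NIRA outcome is $|$baseline − post$|$; nodes are ranked by descending
outcome with ties broken by node index. $\delta$ defaults to twice the
sample SD (n−1) of the model's own threshold vector, the source algorithm's
convention for "two standard deviations".

For $p \le 20$ the sum score is computed exactly by enumerating all $2^p$
states ($2^{16} = 65{,}536$ for the full instrument pair), which makes
intervention tables fully deterministic. The Monte-Carlo mode (single-chain
Gibbs sampler, 1000 burn-in sweeps, thinning 1) exists for larger networks
and for attaching 95% CIs, computed as percentile intervals over at least
100 batch means. The tests require MC and exact modes to agree within three
batch-mean standard errors.

`correlate_outcomes()` closes the loop: Pearson correlations of the per-node
outcomes with thresholds or EI values show what drives intervention
efficiency (aggravation outcomes track low thresholds and high EI). Applied
to the bundled published tables (`study_tables()`), the standardized EI
column against the aggravating outcomes reproduces r = 0.61.

## The synthetic-data generator

Real item-level data for this design are rarely deposited, so
`reference_network()` fixes a 16-node ground truth: 9 depression and 7
anxiety nodes, 22 within-community edges and 6 bridges, the strongest bridge
(weight 1.12) joining the guilt node to the excessive-worry node. Thresholds
are all negative and were calibrated once, by an exact-marginal fixed point,
so node activation rates span 0.19–0.69 with the familiar gradient:
anhedonia and sad mood most prevalent, guilt and suicidal ideation rarest
(hence guilt's most-negative threshold). The calibrated values are frozen in
code; the generator takes no tuning arguments.

`make_questionnaire_data()` layers ordinal severities on top: present
symptoms draw a score from {1,2,3} with default probabilities (0.7, 0.2,
0.1), producing the right skew typical of community samples; absent symptoms
score 0. Binarization therefore recovers the latent binary sample *exactly*,
a round-trip the tests assert elementwise.

What the generator does **not** emulate: the severity draws are independent
across items given the binary layer, so ordinal inter-item correlations are
attenuated relative to real data — Cronbach's alpha on synthetic items comes
out near 0.5 rather than the ~0.9 typical of the real instruments — and
there are no demographic covariates, response styles, or missingness. The
ordinal layer is a stand-in for testing, not an estimate of any study's
data-generating process. Consequently, passing tests demonstrate that the
estimation and intervention machinery recovers a known truth under
realistic prevalence and network structure; they do not certify
distributional fidelity to any particular clinical sample.

## Numerical choices and problem sizes

* Seeds are explicit arguments everywhere; `run_pipeline()` derives
  per-stage seeds from the master seed by a fixed counter scheme so stages
  can be rerun in isolation, and reruns are byte-identical.
* Exact sampling draws i.i.d. states from the normalized Boltzmann
  distribution via full enumeration (capacity-limited at p = 20); the Gibbs
  chain is the fallback beyond that.
* The partial-correlation network is unregularized by default; a singular
  correlation matrix produces an error suggesting the `ridge` flag rather
  than a silent fix.
* Test and example sizes were chosen for quick iteration: parameter-recovery
  checks run ten replicates at n = 708, the pipeline smoke test uses n = 160
  with 100 bootstrap replicates, and the case-dropping grids in tests are
  coarse. Production analyses should use the defaults (B = 1000, drop grid
  0.10–0.75 by 0.05).

## Known limitations

Cross-sectional Ising networks describe conditional associations, not causal
effects, and simulated interventions inherit that caveat: they answer "what
would this fitted distribution look like with a shifted threshold", not
"what would happen to patients". Bridge definitions depend on the assumed
two-community partition. The AND rule can drop genuinely weak edges at
moderate n, which is visible in the recovery tests as shrinkage of small
true weights toward zero.
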