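# symptomnet

Network psychometrics for comorbid depression and anxiety symptoms, from raw
PHQ-9/GAD-7 item responses to simulated symptom-specific interventions.

Clinicians and epidemiologists who screen with the PHQ-9 (9 depression
items) and GAD-7 (7 anxiety items) increasingly analyse the two disorders as
one *symptom network*: symptoms are nodes, their conditional associations
are edges, and comorbidity is carried by *bridge* symptoms that connect the
two clusters. `symptomnet` implements that workflow end to end:

* **Descriptives & screening** — totals, the cutoff-5 screen, prevalence of
  the four categories (neither / depression only / anxiety only / comorbid),
  per-symptom prevalence, Cronbach's alpha, item moments.
* **Ising network estimation (eLasso)** — items are binarized
  (absent = 0, score ≥ 1 = present) and the binary Ising model

  $$P(x) \propto \exp\Big(\textstyle\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\Big)$$

  is estimated by node-wise L1-penalized logistic regression with EBIC
  selection ($\gamma = 0.25$, AND rule). Thresholds $\tau$ come from the
  intercepts, edge weights $\omega$ from the symmetrized coefficients. A
  partial-correlation network on the raw scores plus a Mantel permutation
  test checks that binarization preserved the association pattern.
* **Centrality** — one-step expected influence (EI) and bridge EI, raw and
  standardized, with the z > 1 rule for notable symptoms.
* **Stability** — bootstrapped 95% edge CIs, bootstrapped difference tests,
  and the correlation-stability (CS) coefficient from case-dropping
  subsampling (≥ 0.25 acceptable, ≥ 0.5 preferred).
* **Simulated interventions (NIRA)** — each node's threshold is shifted by
  2 SD of the threshold vector (alleviating −, aggravating +) and the
  network's expected sum score (expected number of active symptoms) is
  recomputed — exactly, by enumerating all 2^16 states. The absolute change
  is the intervention outcome; the top alleviating node is the treatment
  target, the top aggravating node the prevention target.
* **Synthetic data** — an exact Boltzmann sampler, a Gibbs sampler, a fixed
  16-node reference network with realistic prevalence structure, and an
  ordinal questionnaire generator whose binarization round-trips exactly,
  so the whole pipeline is testable without clinical data.

## Worked example

```r
library(symptomnet)

net   <- reference_network()                      # known ground truth
items <- make_questionnaire_data(net, n = 708, seed = 1)

classify_comorbidity(items)
#> Screening at cutoff 5 on n = 708 respondents:
#>   neither            190 (26.8%)
#>   depression_only    207 (29.2%)
#>   anxiety_only       130 (18.4%)
#>   comorbid           181 (25.6%)

fit <- fit_elasso(binarize(items), communities = net$communities)
ct  <- centrality_table(fit)
head(ct[order(-ct$bridge_ei_std), c("label", "community", "ei_std", "bridge_ei_std")], 3)
#>    label  community ei_std bridge_ei_std
#> 12  GAD3    anxiety  0.951          2.88
#> 6   PHQ6 depression  0.987          2.10
#> 3   PHQ3 depression  0.217          0.37

nira_run(net, "aggravating")
#> Simulated aggravating interventions (delta = 1.650 )
#> baseline expected sum score: 6.560
#>  label     post nira_outcome rank
#>   PHQ6 7.691991    1.1319775    1
#>   GAD3 7.453077    0.8930636    2
#>   PHQ3 7.443780    0.8837661    3
#>   ...
```

The guilt node (PHQ6) and the excessive-worry node (GAD3) surface as the
dominant bridge symptoms, and aggravating guilt raises overall network
severity the most — it is the prevention target in this network. The package
also bundles the symptom-level summary and intervention tables of a
published 708-respondent healthcare-worker study (`study_tables()`);
correlating its standardized EI column with its aggravating intervention
outcomes gives r = 0.61 (p = 0.011):

```r
tabs <- study_tables()
correlate_outcomes(tabs$nira_outcomes$nira_aggravating, tabs$item_summary$ei_std)
#> $r [1] 0.6137736    $p [1] 0.01143889
```

The full pipeline (descriptives → network → centrality → stability → NIRA →
correlations, with all artifacts and a manifest on disk) runs via
`run_pipeline(pipeline_config(...))`, or from a shell through the thin
wrapper `inst/scripts/symptomnet-cli.R` (`simulate` and `run-all`
subcommands).

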