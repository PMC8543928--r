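# bae — Bayesian Additional Evidence tipping-point analysis

`bae` answers a question p-values cannot: **how much additional evidence
would change the conclusion of a single study?** It is aimed at
biostatisticians and epidemiologists working with underpowered analyses —
small biomarker-defined cohorts, rare-disease registries, early
comparative-effectiveness studies — where an estimate can be clinically
striking yet non-significant, or significant yet fragile.

## The method

Analysis happens on the additive (log) scale, where a ratio effect measure
has null value 0 and the estimator is approximately normal,
β̂ ~ N(β, se²). Combined with a conjugate normal prior β ~ N(μ, s²), the
posterior is normal with

    s_p² = (1/se² + 1/s²)⁻¹
    μ_p  = s_p² (μ/s² + β̂/se²)

and central credible interval μ_p ± z·s_p. Because prior and data enter
symmetrically, the "prior" can encode a *hypothetical replication study*
with standard error s. Holding s fixed and solving for the prior mean μ\*
whose posterior credible interval just touches the null gives the
**tipping point**:

* non-significant initial result (*supportive* scenario): replication
  estimates more extreme than μ\* would make the combined evidence
  posterior-credible;
* significant initial result (*opposing* scenario): contrary estimates
  larger in magnitude than μ\* would destroy credibility.

The tipping point is located by bracketed root finding (the mechanism that
generalises beyond the conjugate case); the linear closed form available
in the normal-normal setting, μ\* = s²(∓z/s_p − β̂/se²), is exposed as
`closed_form_tipping()` and used as an independent cross-check. Whether
effects beyond μ\* are *plausible* is a domain-knowledge judgment the user
supplies; the package never computes it.

## Worked example

A comparative-effectiveness analysis in a 37-patient
microsatellite-instability-high colorectal-cancer cohort estimates a
hazard ratio of 0.42 (95% CI 0.14–1.23) for one first-line regimen versus
another — suggestive, but not significant.

```r
library(bae)
est <- effect_estimate(0.42, ci = c(0.14, 1.23), scale = "hazard_ratio")
obs <- to_additive(est)
tipping_point(obs, direction = "less_than_null", scenario = "supportive")
```

```
Bayesian Additional Evidence tipping point
  scenario: supportive; direction of interest: less than null
  prior SD (additive scale): 0.554379; credible level: 95%
  tipping point (additive scale): -0.669132
  tipping point (hazard ratio): 0.51
```

Reading: in a replication with the same precision, an observed hazard
ratio at or below ~0.5 would make the combined evidence 95%
posterior-credible. Hazard ratios in that range are not extreme for this
setting, so the question is worth a follow-up study. An earlier external
study of the same contrast (HR 0.13, 95% CI 0.06–0.30) is well beyond the
tipping point; using it as the prior:

```r
prior <- normal_prior(log(0.13), ci_to_se(0.06, 0.30, scale = "hazard_ratio"))
posterior_update(obs, prior)
```

```
Posterior (additive scale): mean -1.62483, SD 0.329944
  95% credible interval: (-2.2715, -0.978148)
  on the hazard ratio scale: 0.1969 (0.1032, 0.376)
  excludes the null value: credible evidence
```

The same analysis is available from a shell:

```sh
Rscript inst/cli/bae.R tip --point 0.42 --ci 0.14 1.23 \
  --scale hazard-ratio --direction less --scenario supportive \
  --reference-prior 0.13 0.06 0.30 --out report.json
```

`run_cli()` also provides `posterior` (forward update) and `simulate`
(summary-level replicate generation) subcommands.

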