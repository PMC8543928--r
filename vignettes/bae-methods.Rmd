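---
title: "Bayesian Additional Evidence: model, tipping-point search, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian Additional Evidence: model, tipping-point search, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bae)
```

## The problem

Small biomarker-defined cohorts routinely produce effect estimates that are
clinically striking but not statistically significant — a hazard ratio of
0.42 with a 95% CI of (0.14, 1.23), say. A p-value alone cannot distinguish
"no effect" from "promising but underpowered". Conversely, a significant
result from a small sample may be fragile. This package quantifies both
situations by asking a reverse-Bayes question: *what additional evidence
would change the conclusion?*

## The model

All computation happens on the additive scale: ratio measures (hazard,
odds, risk ratios) are log-transformed, so the null value is always 0. The
observed estimator is modelled as normal,

$$\hat\beta \mid \beta \sim N(\beta,\; \mathrm{se}^2),$$

with the standard error treated as known (the usual plug-in convention;
a fully Bayesian treatment would put a prior on the sampling SD, which we
deliberately do not do). With a conjugate normal prior
$\beta \sim N(\mu, s^2)$ the posterior is normal with

$$s_p^2 = \left(\frac{1}{\mathrm{se}^2} + \frac{1}{s^2}\right)^{-1},
\qquad
\mu_p = s_p^2\left(\frac{\mu}{s^2} + \frac{\hat\beta}{\mathrm{se}^2}\right),$$

i.e. posterior precision is the sum of the prior and data precisions, and
the posterior mean is the precision-weighted average. The central
credible interval is $\mu_p \pm z\, s_p$; "credible evidence" means it
excludes the null.

## The tipping point

Fix the prior SD $s$ and vary the prior mean $\mu$. Because prior and data
enter the update symmetrically, a "prior" here is best read as a
*hypothetical replication study* with standard error $s$. The **tipping
point** $\mu^*$ is the least extreme replication estimate whose combined
posterior credible interval just touches the null:

* **Supportive scenario** (initial result non-significant): any replication
  estimate *more* extreme than $\mu^*$ yields posterior credibility. If
  effects beyond $\mu^*$ are scientifically plausible, the question merits
  follow-up.
* **Opposing scenario** (initial result significant): any contrary estimate
  larger in magnitude than $\mu^*$ renders the combined evidence
  non-credible (or credible in the opposite direction). If such effects are
  plausible, the current evidence is fragile.

Plausibility is a domain-knowledge judgment; the package records it as a
user-supplied flag (`plausible`) and never computes it.

The direction of interest (`less_than_null` for benefit on a hazard-ratio
scale, `greater_than_null` for harm/positive effects) selects which
credible limit must touch the null: the upper limit for
`less_than_null`, the lower limit for its mirror. It is an analyst input
with no default — the hypothesis, not the data, decides it.

## Numerical choices

`tipping_point()` locates $\mu^*$ by bracketed scalar root finding
(`stats::uniroot`, tolerance `1e-10`) on the map from prior mean to the
touching credible limit. Root finding is the load-bearing mechanism
because it generalises to any posterior that can be evaluated numerically;
in the conjugate setting used here the touching-limit condition is linear
in $\mu$, giving the closed form

$$\mu^* = s^2\left(\mp\frac{z}{s_p} - \frac{\hat\beta}{\mathrm{se}^2}\right),$$

which `closed_form_tipping()` exposes and the test suite uses as an
independent oracle (agreement to $10^{-8}$ over a randomized grid). With
$s = \mathrm{se}$ this collapses to
$\mu^* = -\hat\beta \mp z\sqrt{2}\,\mathrm{se}$.

The initial bracket is $\pm(|\hat\beta| + 20\max(\mathrm{se}, s))$ and is
doubled until it straddles the root: when the prior is much wider than the
data are precise, $\mu^*$ scales like $s^2\hat\beta/\mathrm{se}^2$ and can
sit far outside any fixed bracket, so geometric expansion is required for
correctness rather than speed.

A credible interval whose limit equals the null *exactly* is classified
**not** credible. This makes the tipping point itself the first
non-credible point, so "strictly more extreme than $\mu^*$" is exactly the
credible region — the boundary convention the two scenarios' statements
require.

Quantiles use the exact normal inverse CDF rather than the literal 1.96,
so non-0.95 levels work; reproduction of published two-decimal examples is
checked to ±0.015 because the printed inputs are themselves rounded to two
significant figures and the SE can be derived either by CI inversion or
from the printed p-value (both paths are implemented; they differ in the
third decimal for the worked example, 0.554 vs 0.543).

## Parameters that matter

* `prior_s` (additive scale) — the assumed precision of the hypothetical
  replication. Default: the observed SE, i.e. "a future study with the
  same precision". `scale_prior_se(se, X)` encodes a study with $X$ times
  the subjects via $se/\sqrt{X}$; in survival models the per-subject
  variability depends on the true effect, so this is an approximate
  heuristic and is flagged as such.
* `cred_level` — posterior credible level, default 0.95, also used as the
  frequentist level in the scenario precondition so the two notions of
  "significant" stay aligned.
* `conf_level` on input — the level of the supplied CI, default 0.95;
  SE recovery assumes a symmetric Wald interval on the additive scale
  (profile-likelihood or bootstrap intervals are out of scope).

## What the simulator emulates

`simulate_estimates()` draws replicate estimates directly from the
summary-level sampling model $N(\beta_{\mathrm{true}}, \mathrm{se}^2)$ —
the level at which the method itself operates. It deliberately does not
simulate survival cohorts, censoring, delayed entry, or covariate
adjustment: passing tests therefore validate the Bayesian machinery and
its invariants, not the adequacy of a Cox model's normal approximation on
any particular dataset.
`replication_credibility_rate()` is the Monte-Carlo bridge between the two
views: when the replication truth sits exactly at $\mu^*$, the simulated
estimate is more extreme than $\mu^*$ with probability 1/2, so the
empirical posterior-credibility rate crosses 0.5 there — a property the
tests check with 20,000 draws (±0.02). Problem sizes in the suite (grids
of 200–1,000 configurations, 5,000–20,000 Monte-Carlo draws) were chosen
as the smallest that make the checked tolerances statistically meaningful.

## Design choices

* The null is hard-coded per scale (1 on ratio scales, 0 additive), not
  user-supplied; a configurable null would silently change what
  "credible" means.
* When both a CI and a p-value are supplied, the CI wins (it determines
  both width and asymmetry diagnostics) and a warning is issued.
* One global RNG seed per simulation config, and the simulator restores
  the caller's RNG state — no hidden global state.
* The CLI (`run_cli()`, or `Rscript inst/cli/bae.R`) exposes three
  subcommands (`tip`, `posterior`, `simulate`), echoes every input, labels
  ratio-scale output with its scale name, and writes a flat key/value JSON
  report in which every number regenerates from the echoed inputs.

## Known limitations

* Wald-interval SE recovery only; exact small-sample intervals are not
  supported.
* The plug-in SE understates uncertainty when the SE is itself poorly
  estimated (tiny cohorts); the method inherits this from the frequentist
  summary it consumes.
* Normal likelihood and prior only. The root-finding interface is the
  extension point for non-conjugate settings, but none are implemented.
* No meta-analytic pooling across more than one observed study; reference
  priors are checked one at a time.

## Worked example

```{r example}
est <- effect_estimate(0.42, ci = c(0.14, 1.23), scale = "hazard_ratio")
obs <- to_additive(est)
tip <- tipping_point(obs, direction = "less_than_null",
                     scenario = "supportive")
tip

# forward check against a published external study used as the prior
prior <- normal_prior(log(0.13), ci_to_se(0.06, 0.30, scale = "hazard_ratio"))
posterior_update(obs, prior)
```
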