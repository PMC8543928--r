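# Worked-example fixtures: two published-style hazard-ratio estimates from a
# small cohort, and a more precise external study usable as a reference prior.
hr_cohort <- function() {
  effect_estimate(0.42, ci = c(0.14, 1.23), scale = "hazard_ratio")
}
hr_abstract <- function() {
  effect_estimate(0.31, ci = c(0.09, 1.1), scale = "hazard_ratio")
}
prior_external <- function() {
  normal_prior(log(0.13), ci_to_se(0.06, 0.30, scale = "hazard_ratio"))
}

# random valid parameter configurations for property tests; scenario is
# dictated by the significance of the drawn (beta, se) pair
random_configs <- function(n, seed) {
  set.seed(seed)
  z <- qnorm(0.975)
  data.frame(
    beta = runif(n, -3, 3),
    se = runif(n, 0.05, 2),
    prior_s = runif(n, 0.05, 2),
    direction = sample(c("less_than_null", "greater_than_null"), n,
                       replace = TRUE)
  ) |> transform(scenario = ifelse(abs(beta) > z * se, "opposing",
                                   "supportive"))
}
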