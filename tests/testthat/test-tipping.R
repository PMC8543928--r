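test_that("tipping point reproduces the hazard-ratio worked examples", {
  tip42 <- tipping_point(to_additive(hr_cohort()),
                         direction = "less_than_null",
                         scenario = "supportive")
  expect_equal(tip42$mu_star_reported, 0.52, tolerance = 0.015 / 0.52)

  tip31 <- tipping_point(to_additive(hr_abstract()),
                         direction = "less_than_null",
                         scenario = "supportive")
  expect_equal(tip31$mu_star_reported, 0.54, tolerance = 0.015 / 0.54)
})

test_that("null-centered observation yields the symmetric closed form", {
  for (se in c(0.3, 1, 2)) {
    obs <- normal_summary(0, se)
    tip <- tipping_point(obs, direction = "less_than_null",
                         scenario = "supportive")
    expect_equal(tip$mu_star_additive, -qnorm(0.975) * sqrt(2) * se,
                 tolerance = 1e-9)
  }
})

test_that("root-finding and closed-form tipping points agree on a random grid", {
  cfgs <- random_configs(200, seed = 11)
  for (i in seq_len(nrow(cfgs))) {
    obs <- normal_summary(cfgs$beta[i], cfgs$se[i])
    root <- tipping_point(obs, prior_s = cfgs$prior_s[i],
                          direction = cfgs$direction[i],
                          scenario = cfgs$scenario[i])$mu_star_additive
    cf <- closed_form_tipping(obs, prior_s = cfgs$prior_s[i],
                              direction = cfgs$direction[i],
                              scenario = cfgs$scenario[i])
    expect_equal(root, cf, tolerance = 1e-8)
  }
})

test_that("the posterior at the tipping point touches the null and flips", {
  obs <- to_additive(hr_cohort())
  tip <- tipping_point(obs, direction = "less_than_null",
                       scenario = "supportive")
  at <- posterior_update(obs, normal_prior(tip$mu_star_additive, tip$prior_s))
  expect_lt(abs(at$credible_upper), 1e-8)
  # one small step more extreme (more negative) -> credible
  more <- posterior_update(obs, normal_prior(tip$mu_star_additive - 1e-6,
                                             tip$prior_s))
  expect_true(as.logical(is_credible(more)))
  # one small step less extreme -> not credible
  less <- posterior_update(obs, normal_prior(tip$mu_star_additive + 1e-6,
                                             tip$prior_s))
  expect_false(as.logical(is_credible(less)))
})

test_that("the touching limit is monotone in the prior mean (unique root)", {
  obs <- normal_summary(-0.5, 0.7)
  mus <- seq(-4, 2, length.out = 40)
  limits <- vapply(mus, function(m) {
    posterior_update(obs, normal_prior(m, 0.7))$credible_upper
  }, numeric(1))
  expect_true(all(diff(limits) > 0))
})

test_that("a more precise hypothetical replication needs less extreme evidence", {
  obs <- to_additive(hr_cohort())
  tips <- vapply(c(1, 2, 4, 9), function(x) {
    tipping_point(obs, prior_s = scale_prior_se(obs$se, x),
                  direction = "less_than_null",
                  scenario = "supportive")$mu_star_additive
  }, numeric(1))
  expect_true(all(diff(tips) > 0))   # strictly toward the null (0) from below
  expect_true(all(tips < 0))
})

test_that("negating the estimate and flipping direction negates the tipping point", {
  set.seed(3)
  for (i in 1:25) {
    beta <- runif(1, -1, 1); se <- runif(1, 0.6, 2); s <- runif(1, 0.1, 2)
    obs <- normal_summary(beta, se)
    scen <- if (abs(beta) > qnorm(0.975) * se) "opposing" else "supportive"
    a <- tipping_point(obs, prior_s = s, direction = "less_than_null",
                       scenario = scen)$mu_star_additive
    b <- tipping_point(normal_summary(-beta, se), prior_s = s,
                       direction = "greater_than_null",
                       scenario = scen)$mu_star_additive
    expect_equal(a, -b, tolerance = 1e-9)
  }
})

test_that("scenario preconditions mirror the significance of the input", {
  sig <- normal_summary(log(0.13), ci_to_se(0.06, 0.30,
                                            scale = "hazard_ratio"),
                        "hazard_ratio")
  expect_error(tipping_point(sig, direction = "less_than_null",
                             scenario = "supportive"), "significant")
  nonsig <- to_additive(hr_cohort())
  expect_error(tipping_point(nonsig, direction = "less_than_null",
                             scenario = "opposing"), "not statistically")
  # opposing scenario on a significant input runs and returns a less
  # extreme prior mean than the estimate itself
  tip <- tipping_point(sig, direction = "less_than_null",
                       scenario = "opposing")
  expect_gt(tip$mu_star_additive, sig$beta_hat)
})

test_that("scale_prior_se applies the square-root sample-size heuristic", {
  expect_equal(as.numeric(scale_prior_se(0.5544, 1)), 0.5544)
  expect_equal(as.numeric(scale_prior_se(0.5544, 4)), 0.2772)
  expect_equal(as.numeric(scale_prior_se(1, 2)), 1 / sqrt(2), tolerance = 1e-12)
  expect_true(attr(scale_prior_se(1, 2), "heuristic"))
  expect_error(scale_prior_se(-1, 2), "positive")
  expect_error(scale_prior_se(1, 0), "positive")
})

test_that("evidence_gap_report classifies reference priors", {
  obs <- to_additive(hr_cohort())
  tip <- tipping_point(obs, direction = "less_than_null",
                       scenario = "supportive")
  rep <- evidence_gap_report(obs, tip, list(prior_external()))
  expect_equal(nrow(rep$reference), 1)
  expect_true(rep$reference$credible[1])
  expect_true(rep$reference$beyond_tipping_point[1])
  expect_lt(rep$reference$posterior_upper[1], 0)

  # null-centered everything: not credible
  obs0 <- normal_summary(0, 1)
  tip0 <- tipping_point(obs0, direction = "less_than_null",
                        scenario = "supportive")
  rep0 <- evidence_gap_report(obs0, tip0, list(normal_prior(0, 1)))
  expect_false(rep0$reference$credible[1])

  # degenerate empty reference list still carries the tipping point
  rep_empty <- evidence_gap_report(obs, tip)
  expect_equal(nrow(rep_empty$reference), 0)
  expect_s3_class(rep_empty$tipping, "tipping_result")
})
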