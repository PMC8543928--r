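#' Full BAE analysis report
#'
#' Runs the whole pipeline — reporting-scale conversion, tipping-point
#' search, forward posterior check at the tipping point, and optional
#' reference-prior comparisons — and assembles a report whose every number
#' regenerates from the echoed inputs. Includes plot-ready interval triplets
#' (point, lower, upper) for the observed result, the tipping-point
#' hypothetical replication, and the resulting posterior, on both the
#' additive and reporting scales.
#'
#' @param est An [effect_estimate()].
#' @param direction,scenario,cred_level See [tipping_point()].
#' @param prior_s Prior SD on the additive scale; default the observed SE.
#' @param size_multiplier Alternative to `prior_s`: hypothetical replication
#'   with this many times the subjects (see [scale_prior_se()]).
#' @param reference_priors List of [normal_prior()] objects to check for
#'   posterior credibility.
#' @param plausible Optional user-supplied judgment (`TRUE`/`FALSE`/`NA`):
#'   are effects beyond the tipping point scientifically plausible? Never
#'   computed — this is a domain-knowledge input that selects the
#'   conclusion sentence.
#' @return An object of class `"bae_report"`.
#' @examples
#' est <- effect_estimate(0.42, ci = c(0.14, 1.23), scale = "hazard_ratio")
#' bae_report(est, direction = "less_than_null", scenario = "supportive")
#' @export
bae_report <- function(est, direction, scenario,
                       prior_s = NULL, size_multiplier = NULL,
                       cred_level = 0.95, reference_priors = list(),
                       plausible = NA) {
  stopifnot(inherits(est, "effect_estimate"))
  if (!is.null(prior_s) && !is.null(size_multiplier)) {
    stop("supply at most one of `prior_s` and `size_multiplier`",
         call. = FALSE)
  }
  obs <- to_additive(est)
  prior_s_used <- if (!is.null(prior_s)) prior_s
    else if (!is.null(size_multiplier)) scale_prior_se(obs$se, size_multiplier)
    else obs$se
  tip <- tipping_point(obs, prior_s = prior_s_used, direction = direction,
                       scenario = scenario, cred_level = cred_level)
  gap <- evidence_gap_report(obs, tip, reference_priors)
  post_at_tip <- posterior_update(
    obs, normal_prior(tip$mu_star_additive, as.numeric(prior_s_used)),
    cred_level)

  z <- stats::qnorm(1 - (1 - cred_level) / 2)
  plot_add <- data.frame(
    what = c("observed", "tipping_hypothetical", "posterior_at_tipping"),
    point = c(obs$beta_hat, tip$mu_star_additive, post_at_tip$mu_p),
    lower = c(obs$beta_hat - z * obs$se,
              tip$mu_star_additive - z * prior_s_used,
              post_at_tip$credible_lower),
    upper = c(obs$beta_hat + z * obs$se,
              tip$mu_star_additive + z * prior_s_used,
              post_at_tip$credible_upper))
  plot_rep <- plot_add
  plot_rep[c("point", "lower", "upper")] <-
    lapply(plot_add[c("point", "lower", "upper")], from_additive,
           scale = est$scale)

  conclusion <- if (is.na(plausible)) {
    paste0("Whether effects beyond the tipping point are plausible is a ",
           "domain-knowledge judgment; supply `plausible` to record it.")
  } else if (scenario == "supportive") {
    if (plausible) {
      paste0("Effects beyond the tipping point are judged plausible: the ",
             "observed data are useful and a follow-up study is warranted.")
    } else {
      paste0("Effects beyond the tipping point are judged implausible: the ",
             "current analysis offers little evidence worth following up.")
    }
  } else {
    if (plausible) {
      paste0("Effects beyond the tipping point are judged plausible: the ",
             "current evidence is not strong enough on its own.")
    } else {
      paste0("Effects beyond the tipping point are judged implausible: the ",
             "current evidence is robust to realistic contrary data.")
    }
  }

  structure(
    list(estimate = est, obs = obs, tipping = tip,
         reference = gap$reference,
         posterior_at_tipping = post_at_tip,
         frequentist_interval = c(lower = plot_add$lower[1],
                                  upper = plot_add$upper[1]),
         plot_data_additive = plot_add,
         plot_data_reported = plot_rep,
         plausible = plausible,
         conclusion = conclusion,
         cred_level = cred_level),
    class = "bae_report"
  )
}

#' Flatten a report to a named list of scalars
#'
#' Additive-scale values keep full precision; reporting-scale values are
#' also given rounded to 2 decimals, matching how ratio effect measures are
#' conventionally printed. Suitable for serialisation to JSON or key=value
#' text.
#'
#' @param report A [bae_report()].
#' @return A named list of length-1 values.
#' @export
flatten_report <- function(report) {
  stopifnot(inherits(report, "bae_report"))
  est <- report$estimate
  tip <- report$tipping
  out <- list(
    scale = est$scale,
    point = est$point,
    ci_lower = est$ci_lower,
    ci_upper = est$ci_upper,
    p_value = est$p_value,
    se_input = est$se,
    conf_level = est$conf_level,
    scenario = tip$scenario,
    direction = tip$direction,
    cred_level = report$cred_level,
    beta_hat = report$obs$beta_hat,
    se = report$obs$se,
    prior_s = as.numeric(tip$prior_s),
    tipping_additive = tip$mu_star_additive,
    tipping_reported = tip$mu_star_reported,
    tipping_reported_2dp = round(tip$mu_star_reported, 2),
    posterior_at_tipping_mean = report$posterior_at_tipping$mu_p,
    posterior_at_tipping_sd = report$posterior_at_tipping$s_p,
    posterior_at_tipping_lower = report$posterior_at_tipping$credible_lower,
    posterior_at_tipping_upper = report$posterior_at_tipping$credible_upper,
    frequentist_lower = unname(report$frequentist_interval["lower"]),
    frequentist_upper = unname(report$frequentist_interval["upper"]),
    plausible = report$plausible,
    interpretation = tip$interpretation,
    conclusion = report$conclusion
  )
  ref <- report$reference
  if (nrow(ref)) {
    for (i in seq_len(nrow(ref))) {
      pre <- sprintf("reference_%d_", i)
      out[[paste0(pre, "mu")]] <- ref$mu[i]
      out[[paste0(pre, "s")]] <- ref$s[i]
      out[[paste0(pre, "posterior_lower")]] <- ref$posterior_lower[i]
      out[[paste0(pre, "posterior_upper")]] <- ref$posterior_upper[i]
      out[[paste0(pre, "credible")]] <- ref$credible[i]
      out[[paste0(pre, "beyond_tipping_point")]] <- ref$beyond_tipping_point[i]
    }
  }
  out
}

#' @export
print.bae_report <- function(x, ...) {
  cat("=== Bayesian Additional Evidence report ===\n\nInput:\n")
  print(x$estimate)
  cat(sprintf("  additive scale: estimate %.6g, SE %.6g\n",
              x$obs$beta_hat, x$obs$se))
  cat(sprintf("  frequentist %d%% interval (additive): (%.6g, %.6g)\n\n",
              round(100 * x$cred_level),
              x$frequentist_interval["lower"], x$frequentist_interval["upper"]))
  print(x$tipping)
  cat(sprintf(
    "\nPosterior at the tipping point: mean %.6g, %d%% interval (%.6g, %.6g)\n",
    x$posterior_at_tipping$mu_p, round(100 * x$cred_level),
    x$posterior_at_tipping$credible_lower,
    x$posterior_at_tipping$credible_upper))
  if (nrow(x$reference)) {
    cat("\nReference priors (additive scale):\n")
    print(x$reference, row.names = FALSE)
  }
  cat("\nInterval data (", scale_label(x$estimate$scale), "):\n", sep = "")
  pd <- x$plot_data_reported
  pd[c("point", "lower", "upper")] <-
    lapply(pd[c("point", "lower", "upper")], round, 4)
  print(pd, row.names = FALSE)
  cat("\n", strwrap(x$conclusion, width = 74, prefix = "  "), sep = "\n")
  invisible(x)
}
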