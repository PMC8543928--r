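#' @name bae-tipping
#' @title Bayesian Additional Evidence tipping point
#'
#' @description
#' The reverse-Bayes core of the package. For a fixed prior standard
#' deviation, the tipping point is the least extreme prior mean `mu*` whose
#' normal-normal posterior credible interval just touches the null value
#' (0 on the additive scale). Because prior and data enter the conjugate
#' update symmetrically, the "prior" is read as a hypothetical replication
#' study: `mu*` is the least extreme replication estimate that, combined
#' with the observed result, yields posterior credibility (supportive
#' scenario, non-significant initial result) or destroys it (opposing
#' scenario, significant initial result).
#'
#' Sign conventions: `direction = "less_than_null"` declares effects below
#' the null (e.g. hazard ratio < 1) as the direction of interest; the
#' credible limit that touches the null is then the upper limit.
#' `"greater_than_null"` mirrors this with the lower limit.
NULL

.directions <- c("less_than_null", "greater_than_null")
.scenarios <- c("supportive", "opposing")

# credible-interval limit nearer the null, as a function of the prior mean
touching_limit <- function(mu, obs, prior_s, direction, cred_level) {
  post <- posterior_update(obs, normal_prior(mu, prior_s), cred_level)
  if (direction == "less_than_null") post$credible_upper else post$credible_lower
}

check_scenario <- function(obs, scenario, cred_level) {
  z <- stats::qnorm(1 - (1 - cred_level) / 2)
  significant <- abs(obs$beta_hat) > z * obs$se
  if (scenario == "supportive" && significant) {
    stop("the observed result is statistically significant at this level; ",
         "the supportive scenario applies to non-significant results ",
         "(use scenario = \"opposing\" to ask how much contrary evidence ",
         "would make it non-credible)", call. = FALSE)
  }
  if (scenario == "opposing" && !significant) {
    stop("the observed result is not statistically significant at this ",
         "level; the opposing scenario applies to significant results ",
         "(use scenario = \"supportive\" to ask how much additional ",
         "evidence would make it credible)", call. = FALSE)
  }
  invisible(significant)
}

#' Find the tipping-point prior mean by root finding
#'
#' Searches over prior means for the value `mu*` at which the posterior
#' credible limit nearer the null (chosen by `direction`) equals the null
#' value exactly. The root is located with bracketed scalar root finding
#' (tolerance 1e-10); the bracket starts at
#' `|beta_hat| + 20 max(se, prior_s)` and widens geometrically until it
#' straddles the root. The result is cross-checked against the linear
#' closed form available in the conjugate normal-normal setting
#' ([closed_form_tipping()]).
#'
#' @param obs A [normal_summary()] for the observed result.
#' @param prior_s Prior standard deviation on the additive scale. Defaults
#'   to the observed standard error, i.e. a hypothetical replication with
#'   the same precision as the original study. See [scale_prior_se()] for
#'   encoding larger or smaller studies.
#' @param direction `"less_than_null"` if effects below the null (hazard
#'   ratio < 1) are of interest, `"greater_than_null"` otherwise. Must be
#'   supplied explicitly; the analyst's hypothesis decides it.
#' @param scenario `"supportive"` (initial result non-significant; how much
#'   additional evidence would reach credibility?) or `"opposing"` (initial
#'   result significant; how much contrary evidence would destroy it?).
#' @param cred_level Posterior credible level, default 0.95; the frequentist
#'   significance check uses the same level.
#' @return An object of class `"tipping_result"` with the tipping point on
#'   the additive and reporting scales, scenario metadata, and the
#'   interpretation guidance for the matching scenario.
#' @examples
#' obs <- to_additive(effect_estimate(0.42, ci = c(0.14, 1.23),
#'                                    scale = "hazard_ratio"))
#' tipping_point(obs, direction = "less_than_null", scenario = "supportive")
#' @export
tipping_point <- function(obs, prior_s = obs$se,
                          direction = c("less_than_null", "greater_than_null"),
                          scenario = c("supportive", "opposing"),
                          cred_level = 0.95) {
  stopifnot(inherits(obs, "normal_summary"))
  direction <- match.arg(direction)
  scenario <- match.arg(scenario)
  check_level(cred_level, "cred_level")
  if (!is.numeric(prior_s) || prior_s <= 0) {
    stop("`prior_s` must be a positive number", call. = FALSE)
  }
  check_scenario(obs, scenario, cred_level)

  g <- function(mu) touching_limit(mu, obs, prior_s, direction, cred_level)
  b <- abs(obs$beta_hat) + 20 * max(obs$se, prior_s)
  lo <- -b; hi <- b
  tries <- 0L
  while (sign(g(lo)) == sign(g(hi))) {
    lo <- 2 * lo; hi <- 2 * hi
    tries <- tries + 1L
    if (tries > 60L) {
      stop("failed to bracket the tipping point; inputs may be degenerate",
           call. = FALSE)
    }
  }
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-10)$root

  cf <- closed_form_tipping(obs, prior_s, direction, scenario, cred_level)
  if (abs(root - cf) > 1e-6 * max(1, abs(cf))) {
    warning("root-finding and closed-form tipping points disagree by ",
            format(abs(root - cf)), "; reporting the root-finding value",
            call. = FALSE)
  }

  structure(
    list(mu_star_additive = root,
         mu_star_reported = from_additive(root, obs$scale_tag),
         scenario = scenario,
         direction = direction,
         prior_s = prior_s,
         cred_level = cred_level,
         scale_tag = obs$scale_tag,
         obs = obs,
         interpretation = interpretation_text(scenario)),
    class = "tipping_result"
  )
}

#' Closed-form tipping point (independent linear solution)
#'
#' In the conjugate normal-normal model with a plug-in standard error the
#' touching-limit condition is linear in the prior mean, so the tipping
#' point has an explicit solution:
#' \deqn{\mu^* = s^2\left(\mp z / s_p - \hat\beta / se^2\right)}
#' with the minus sign for `direction = "less_than_null"` (upper limit
#' touches the null) and the plus sign for `"greater_than_null"`. With
#' `prior_s = se` this reduces to
#' `mu* = -beta_hat -/+ z * sqrt(2) * se`. Serves as an independent oracle
#' for the root-finding search in [tipping_point()], which remains the
#' extension point for non-conjugate settings.
#'
#' @inheritParams tipping_point
#' @return The tipping point on the additive scale (numeric scalar).
#' @export
closed_form_tipping <- function(obs, prior_s = obs$se,
                                direction = c("less_than_null",
                                              "greater_than_null"),
                                scenario = c("supportive", "opposing"),
                                cred_level = 0.95) {
  stopifnot(inherits(obs, "normal_summary"))
  direction <- match.arg(direction)
  scenario <- match.arg(scenario)
  check_level(cred_level, "cred_level")
  if (!is.numeric(prior_s) || prior_s <= 0) {
    stop("`prior_s` must be a positive number", call. = FALSE)
  }
  check_scenario(obs, scenario, cred_level)
  z <- stats::qnorm(1 - (1 - cred_level) / 2)
  s_p <- sqrt(1 / (1 / obs$se^2 + 1 / prior_s^2))
  sgn <- if (direction == "less_than_null") -1 else 1
  prior_s^2 * (sgn * z / s_p - obs$beta_hat / obs$se^2)
}

#' Scale a standard error to a hypothetically larger or smaller study
#'
#' Dividing an observed standard error by `sqrt(X)` approximates the
#' standard error of a study with `X` times more subjects (holding the
#' underlying per-subject variability fixed). In survival models the
#' variability itself depends on the true effect, so this is an approximate
#' heuristic, not an exact relation.
#'
#' @param se Observed standard error (positive).
#' @param size_multiplier `X > 0`: the hypothetical study has `X` times the
#'   subjects of the original.
#' @return `se / sqrt(size_multiplier)`, with attribute `"heuristic" = TRUE`.
#' @examples
#' scale_prior_se(0.5544, 4) # a study four times the size
#' @export
scale_prior_se <- function(se, size_multiplier) {
  if (!is.numeric(se) || any(se <= 0)) {
    stop("`se` must be positive", call. = FALSE)
  }
  if (!is.numeric(size_multiplier) || any(size_multiplier <= 0)) {
    stop("`size_multiplier` must be positive", call. = FALSE)
  }
  structure(se / sqrt(size_multiplier), heuristic = TRUE)
}

#' Compare reference priors against a tipping point
#'
#' For each reference prior (typically a published study's estimate and
#' uncertainty), reports whether combining it with the observed result
#' yields posterior credibility, and whether its mean lies beyond the
#' tipping point in the direction of interest.
#'
#' @param obs The [normal_summary()] the tipping point was computed from.
#' @param tipping A [tipping_point()] result computed from `obs`.
#' @param reference_priors A list of [normal_prior()] objects (possibly
#'   empty).
#' @return An object of class `"evidence_gap_report"`: the tipping result
#'   plus one row per reference prior with columns `mu`, `s`,
#'   `posterior_lower`, `posterior_upper`, `credible`,
#'   `beyond_tipping_point`.
#' @examples
#' obs <- normal_summary(log(0.42), 0.5544, "hazard_ratio")
#' tip <- tipping_point(obs, direction = "less_than_null",
#'                      scenario = "supportive")
#' evidence_gap_report(obs, tip,
#'                     list(normal_prior(log(0.13), 0.4106)))
#' @export
evidence_gap_report <- function(obs, tipping, reference_priors = list()) {
  stopifnot(inherits(obs, "normal_summary"),
            inherits(tipping, "tipping_result"))
  if (inherits(reference_priors, "normal_prior")) {
    reference_priors <- list(reference_priors)
  }
  rows <- lapply(reference_priors, function(pr) {
    stopifnot(inherits(pr, "normal_prior"))
    post <- posterior_update(obs, pr, tipping$cred_level)
    beyond <- if (tipping$direction == "less_than_null") {
      pr$mu < tipping$mu_star_additive
    } else {
      pr$mu > tipping$mu_star_additive
    }
    data.frame(mu = pr$mu, s = pr$s,
               posterior_lower = post$credible_lower,
               posterior_upper = post$credible_upper,
               credible = as.logical(is_credible(post)),
               beyond_tipping_point = beyond)
  })
  structure(
    list(tipping = tipping,
         reference = if (length(rows)) do.call(rbind, rows) else
           data.frame(mu = numeric(), s = numeric(),
                      posterior_lower = numeric(), posterior_upper = numeric(),
                      credible = logical(), beyond_tipping_point = logical())),
    class = "evidence_gap_report"
  )
}

interpretation_text <- function(scenario) {
  if (scenario == "supportive") {
    paste0(
      "The initial result is not statistically significant. The tipping ",
      "point is the least extreme estimate a follow-up study (at the ",
      "stated precision) would need to observe for the combined evidence ",
      "to reach posterior credibility. A tipping point close to the null ",
      "means the current evidence is already strong; if effects beyond the ",
      "tipping point are scientifically plausible, the question is worth ",
      "a follow-up study."
    )
  } else {
    paste0(
      "The initial result is statistically significant. The tipping point ",
      "is the least extreme contrary estimate a follow-up study would need ",
      "to observe for the combined evidence to lose posterior credibility ",
      "(prior means larger in magnitude than the tipping point yield ",
      "non-credibility, or credible evidence in the opposite direction). ",
      "A tipping point close to the null means the current evidence is ",
      "strong; if effects beyond the tipping point are plausible, the ",
      "current evidence is not strong enough on its own."
    )
  }
}

#' @export
print.tipping_result <- function(x, ...) {
  cat("Bayesian Additional Evidence tipping point\n")
  cat(sprintf("  scenario: %s; direction of interest: %s\n",
              x$scenario, gsub("_", " ", x$direction)))
  cat(sprintf("  prior SD (additive scale): %.6g; credible level: %d%%\n",
              x$prior_s, round(100 * x$cred_level)))
  cat(sprintf("  tipping point (additive scale): %.6g\n", x$mu_star_additive))
  if (is_ratio_scale(x$scale_tag)) {
    cat(sprintf("  tipping point (%s): %.2f\n", scale_label(x$scale_tag),
                x$mu_star_reported))
  }
  cat("\n", strwrap(x$interpretation, width = 74, prefix = "  "), sep = "\n")
  invisible(x)
}

#' @export
print.evidence_gap_report <- function(x, ...) {
  print(x$tipping)
  if (nrow(x$reference)) {
    cat("\nReference priors (additive scale):\n")
    print(x$reference, row.names = FALSE)
  }
  invisible(x)
}
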