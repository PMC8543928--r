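#' Configuration for summary-level simulation
#'
#' The method consumes (estimate, standard error) summaries, so the test bed
#' simulates at the summary level: replicate estimates are drawn from the
#' sampling model `beta_hat ~ N(true_beta, se)` with `se` treated as known
#' (the plug-in convention).
#'
#' @param true_beta True effect on the additive scale.
#' @param se Standard error of each simulated estimate (positive).
#' @param n_replicates Number of replicate estimates (>= 1).
#' @param seed Integer seed; identical configurations reproduce identical
#'   draws.
#' @return An object of class `"synthetic_study_config"`.
#' @export
synthetic_study_config <- function(true_beta, se, n_replicates, seed) {
  if (!is.numeric(se) || se <= 0) stop("`se` must be positive", call. = FALSE)
  if (!is.numeric(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  structure(list(true_beta = true_beta, se = se,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

#' Simulate replicate estimates from the sampling model
#'
#' @param cfg A [synthetic_study_config()].
#' @param scale_tag Reporting scale attached to each summary.
#' @return A list of [normal_summary()] objects, one per replicate, each
#'   carrying the configured `se`.
#' @export
simulate_estimates <- function(cfg, scale_tag = "identity") {
  stopifnot(inherits(cfg, "synthetic_study_config"))
  draws <- withr_seed(cfg$seed, function() {
    stats::rnorm(cfg$n_replicates, mean = cfg$true_beta, sd = cfg$se)
  })
  lapply(draws, normal_summary, se = cfg$se, scale_tag = scale_tag)
}

# run fn with a local RNG state; restores the caller's state afterwards
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Monte-Carlo posterior-credibility rate for a hypothetical replication
#'
#' Simulates replication estimates from `N(true_replication_beta, prior_s)`,
#' uses each as the prior mean (with SD `prior_s`) in a conjugate update
#' against the observed summary, and returns the fraction of updates whose
#' credible interval excludes the null in the direction of interest. When
#' `true_replication_beta` equals the tipping point, a replication estimate
#' is more extreme than the tipping point with probability 1/2, so the rate
#' crosses 0.5 there.
#'
#' @param obs A [normal_summary()] for the observed result.
#' @param prior_s Replication standard error / prior SD (positive).
#' @param true_replication_beta True effect generating the replication
#'   estimates, additive scale.
#' @param n_replicates Number of Monte-Carlo replications.
#' @param seed Integer seed.
#' @param direction Direction of interest (see [tipping_point()]); credible
#'   intervals excluding the null on the opposite side do not count.
#' @param cred_level Credible level, default 0.95.
#' @return The empirical credibility rate (a proportion in \[0, 1\]).
#' @export
replication_credibility_rate <- function(obs, prior_s, true_replication_beta,
                                         n_replicates = 10000L, seed = 1L,
                                         direction = c("less_than_null",
                                                       "greater_than_null"),
                                         cred_level = 0.95) {
  stopifnot(inherits(obs, "normal_summary"))
  direction <- match.arg(direction)
  check_level(cred_level, "cred_level")
  if (!is.numeric(prior_s) || prior_s <= 0) {
    stop("`prior_s` must be positive", call. = FALSE)
  }
  draws <- withr_seed(seed, function() {
    stats::rnorm(n_replicates, mean = true_replication_beta, sd = prior_s)
  })
  # the credible limit is linear in the prior mean, so vectorise directly
  z <- stats::qnorm(1 - (1 - cred_level) / 2)
  s_p2 <- 1 / (1 / obs$se^2 + 1 / prior_s^2)
  s_p <- sqrt(s_p2)
  mu_p <- s_p2 * (draws / prior_s^2 + obs$beta_hat / obs$se^2)
  credible <- if (direction == "less_than_null") {
    mu_p + z * s_p < 0
  } else {
    mu_p - z * s_p > 0
  }
  mean(credible)
}
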