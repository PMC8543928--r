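#' Construct a normal prior on the additive scale
#'
#' @param mu Prior mean on the additive (log) scale.
#' @param s Prior standard deviation (positive).
#' @return An object of class `"normal_prior"`.
#' @export
normal_prior <- function(mu, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("prior standard deviation `s` must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("prior mean `mu` must be a single finite number", call. = FALSE)
  }
  structure(list(mu = mu, s = s), class = "normal_prior")
}

#' Normal-normal conjugate posterior update
#'
#' Combines an observed additive-scale summary `beta_hat ~ N(beta_true, se)`
#' with a normal prior `beta_true ~ N(mu, s)`. By conjugacy the posterior is
#' normal with precision equal to the sum of the prior and observed
#' precisions:
#' \deqn{s_p^2 = (1/se^2 + 1/s^2)^{-1}, \quad
#'       \mu_p = s_p^2 (\mu/s^2 + \hat\beta/se^2)}
#' The credible interval is the central `cred_level` interval
#' `mu_p +/- z * s_p`.
#'
#' @param obs A [normal_summary()].
#' @param prior A [normal_prior()].
#' @param cred_level Credible level in (0, 1); default 0.95.
#' @return An object of class `"posterior_result"` with elements `mu_p`,
#'   `s_p`, `credible_lower`, `credible_upper`, `cred_level`, `scale_tag`.
#' @examples
#' obs <- normal_summary(log(0.42), 0.5544, "hazard_ratio")
#' posterior_update(obs, normal_prior(log(0.13), 0.4106))
#' @export
posterior_update <- function(obs, prior, cred_level = 0.95) {
  stopifnot(inherits(obs, "normal_summary"), inherits(prior, "normal_prior"))
  check_level(cred_level, "cred_level")
  s_p2 <- 1 / (1 / obs$se^2 + 1 / prior$s^2)
  s_p <- sqrt(s_p2)
  mu_p <- s_p2 * (prior$mu / prior$s^2 + obs$beta_hat / obs$se^2)
  z <- stats::qnorm(1 - (1 - cred_level) / 2)
  structure(
    list(mu_p = mu_p, s_p = s_p,
         credible_lower = mu_p - z * s_p,
         credible_upper = mu_p + z * s_p,
         cred_level = cred_level,
         scale_tag = obs$scale_tag),
    class = "posterior_result"
  )
}

#' Does the posterior credible interval exclude the null value?
#'
#' The null value is 0 on the additive scale (1 on ratio scales). An interval
#' whose limit equals 0 exactly is classified as NOT credible: the tipping
#' point itself is the boundary case, so strictly more extreme prior means
#' yield credibility and the boundary does not.
#'
#' @param post A [posterior_update()] result.
#' @return `TRUE`/`FALSE`; when credible the attribute `"direction"` is
#'   `"negative"` or `"positive"` (the sign of the posterior mean), otherwise
#'   `NA_character_`.
#' @export
is_credible <- function(post) {
  stopifnot(inherits(post, "posterior_result"))
  credible <- post$credible_upper < 0 || post$credible_lower > 0
  direction <- if (!credible) NA_character_
               else if (post$mu_p < 0) "negative" else "positive"
  structure(credible, direction = direction)
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("Posterior (additive scale): mean %.6g, SD %.6g\n",
              x$mu_p, x$s_p))
  cat(sprintf("  %d%% credible interval: (%.6g, %.6g)\n",
              round(100 * x$cred_level), x$credible_lower, x$credible_upper))
  if (is_ratio_scale(x$scale_tag)) {
    cat(sprintf("  on the %s scale: %.4g (%.4g, %.4g)\n",
                scale_label(x$scale_tag), exp(x$mu_p),
                exp(x$credible_lower), exp(x$credible_upper)))
  }
  cred <- is_credible(x)
  cat(if (cred) "  excludes the null value: credible evidence\n"
      else "  includes the null value: not credible\n")
  invisible(x)
}
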