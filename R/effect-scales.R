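#' @keywords internal
"_PACKAGE"

.scales <- c("hazard_ratio", "odds_ratio", "risk_ratio", "identity")
.ratio_scales <- c("hazard_ratio", "odds_ratio", "risk_ratio")

scale_label <- function(scale) {
  switch(scale,
    hazard_ratio = "hazard ratio",
    odds_ratio = "odds ratio",
    risk_ratio = "risk ratio",
    identity = "raw (identity) scale"
  )
}

is_ratio_scale <- function(scale) scale %in% .ratio_scales

#' Transform a reporting-scale value to the additive analysis scale
#'
#' Ratio scales (hazard, odds, risk ratio) are analysed on their natural
#' logarithm, where the estimator is approximately normal and the null value
#' is 0; the identity scale passes through unchanged.
#'
#' @param x Numeric value(s) on the reporting scale.
#' @param scale One of `"hazard_ratio"`, `"odds_ratio"`, `"risk_ratio"`,
#'   `"identity"`.
#' @return Numeric value(s) on the additive (log or raw) scale.
#' @seealso [from_additive()] for the inverse.
#' @export
to_additive_scale <- function(x, scale) {
  scale <- match.arg(scale, .scales)
  if (is_ratio_scale(scale)) {
    if (any(x <= 0)) {
      stop("values on a ", scale_label(scale), " scale must be positive",
           call. = FALSE)
    }
    log(x)
  } else {
    x
  }
}

#' Back-transform an additive-scale value to its reporting scale
#'
#' @param value Numeric value(s) on the additive (log or raw) scale.
#' @param scale Reporting scale tag (see [to_additive_scale()]).
#' @return `exp(value)` on ratio scales, `value` unchanged otherwise.
#' @export
from_additive <- function(value, scale) {
  scale <- match.arg(scale, .scales)
  if (is_ratio_scale(scale)) exp(value) else value
}

#' Recover a Wald standard error from a confidence interval
#'
#' Inverts a symmetric (on the additive scale) Wald interval:
#' `se = (t(upper) - t(lower)) / (2 z)` where `t` is the natural log on ratio
#' scales and the identity otherwise, and `z` is the standard-normal quantile
#' for `conf_level`.
#'
#' @param lower,upper Confidence limits on the reporting scale.
#' @param conf_level Two-sided confidence level in (0, 1). Default 0.95.
#' @param scale Reporting scale tag.
#' @return The standard error on the additive scale (positive scalar).
#' @examples
#' ci_to_se(0.14, 1.23, scale = "hazard_ratio")
#' @export
ci_to_se <- function(lower, upper, conf_level = 0.95, scale = "identity") {
  scale <- match.arg(scale, .scales)
  check_level(conf_level, "conf_level")
  if (is_ratio_scale(scale) && (lower <= 0 || upper <= 0)) {
    stop("confidence limits on a ", scale_label(scale),
         " scale must be positive", call. = FALSE)
  }
  if (lower >= upper) {
    stop("`lower` must be strictly less than `upper`", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  (to_additive_scale(upper, scale) - to_additive_scale(lower, scale)) / (2 * z)
}

#' Recover a Wald standard error from a two-sided p-value
#'
#' Uses `se = |t(point)| / z_p` with `z_p` the standard-normal quantile of the
#' two-sided p-value. Undefined when the point estimate sits exactly at the
#' null value (z = 0).
#'
#' @param point Point estimate on the reporting scale.
#' @param p_value Two-sided p-value in (0, 1).
#' @param scale Reporting scale tag.
#' @return The standard error on the additive scale (positive scalar).
#' @examples
#' pvalue_to_se(0.42, 0.11, scale = "hazard_ratio")
#' @export
pvalue_to_se <- function(point, p_value, scale = "identity") {
  scale <- match.arg(scale, .scales)
  if (!is.numeric(p_value) || p_value <= 0 || p_value >= 1) {
    stop("`p_value` must lie strictly between 0 and 1", call. = FALSE)
  }
  beta_hat <- to_additive_scale(point, scale)
  if (beta_hat == 0) {
    stop("the point estimate sits exactly at the null value; ",
         "its standard error cannot be recovered from a p-value",
         call. = FALSE)
  }
  abs(beta_hat) / stats::qnorm(1 - p_value / 2)
}

#' Construct a user-facing effect estimate
#'
#' Bundles a point estimate on its reporting scale with exactly one
#' uncertainty parameterisation: a two-sided confidence interval, a two-sided
#' p-value, or an explicit additive-scale standard error. If both a CI and a
#' p-value are supplied the CI wins (it carries more information) and a
#' warning is issued.
#'
#' @param point Point estimate (positive on ratio scales).
#' @param ci Optional length-2 numeric, `c(lower, upper)`, same scale as
#'   `point`.
#' @param p_value Optional two-sided p-value in (0, 1).
#' @param se Optional explicit standard error on the additive (log) scale.
#' @param conf_level Confidence level of `ci`, default 0.95.
#' @param scale Reporting scale tag.
#' @return An object of class `"effect_estimate"`.
#' @examples
#' effect_estimate(0.42, ci = c(0.14, 1.23), scale = "hazard_ratio")
#' @export
effect_estimate <- function(point, ci = NULL, p_value = NULL, se = NULL,
                            conf_level = 0.95,
                            scale = c("hazard_ratio", "odds_ratio",
                                      "risk_ratio", "identity")) {
  scale <- match.arg(scale)
  check_level(conf_level, "conf_level")
  if (!is.numeric(point) || length(point) != 1L || !is.finite(point)) {
    stop("`point` must be a single finite number", call. = FALSE)
  }
  if (is_ratio_scale(scale) && point <= 0) {
    stop("`point` must be positive on a ", scale_label(scale), " scale",
         call. = FALSE)
  }
  if (!is.null(ci) && !is.null(p_value)) {
    warning("both a confidence interval and a p-value were supplied; ",
            "the confidence interval is used", call. = FALSE)
    p_value <- NULL
  }
  n_unc <- (!is.null(ci)) + (!is.null(p_value)) + (!is.null(se))
  if (n_unc != 1L) {
    stop("supply exactly one of `ci`, `p_value` or `se`", call. = FALSE)
  }
  if (!is.null(ci)) {
    if (length(ci) != 2L || !is.numeric(ci)) {
      stop("`ci` must be a numeric vector c(lower, upper)", call. = FALSE)
    }
    if (!(ci[1] < point && point < ci[2])) {
      stop("`ci` must satisfy lower < point < upper", call. = FALSE)
    }
  }
  if (!is.null(se) && (!is.numeric(se) || se <= 0)) {
    stop("`se` must be a positive number", call. = FALSE)
  }
  structure(
    list(point = point, ci_lower = if (is.null(ci)) NA_real_ else ci[1],
         ci_upper = if (is.null(ci)) NA_real_ else ci[2],
         p_value = if (is.null(p_value)) NA_real_ else p_value,
         se = if (is.null(se)) NA_real_ else se,
         conf_level = conf_level, scale = scale),
    class = "effect_estimate"
  )
}

#' Construct an additive-scale normal summary
#'
#' The internal currency of the package: an estimate and standard error on
#' the additive (log) scale, where the estimator is modelled as
#' `beta_hat ~ N(beta_true, se)` with `se` the composite sigma/sqrt(n)
#' (plug-in convention).
#'
#' @param beta_hat Estimate on the additive scale.
#' @param se Positive standard error on the additive scale.
#' @param scale_tag Originating reporting scale (for back-transformation).
#' @return An object of class `"normal_summary"`.
#' @export
normal_summary <- function(beta_hat, se, scale_tag = "identity") {
  scale_tag <- match.arg(scale_tag, .scales)
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se <= 0) {
    stop("`se` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(beta_hat) || length(beta_hat) != 1L || !is.finite(beta_hat)) {
    stop("`beta_hat` must be a single finite number", call. = FALSE)
  }
  structure(list(beta_hat = beta_hat, se = se, scale_tag = scale_tag),
            class = "normal_summary")
}

#' Convert an effect estimate to its additive-scale normal summary
#'
#' The point estimate is log-transformed on ratio scales; the standard error
#' is recovered from whichever uncertainty parameterisation the estimate
#' carries (CI inversion, p-value inversion, or passed through).
#'
#' @param est An [effect_estimate()].
#' @return A [normal_summary()].
#' @examples
#' to_additive(effect_estimate(0.42, ci = c(0.14, 1.23),
#'                             scale = "hazard_ratio"))
#' @export
to_additive <- function(est) {
  stopifnot(inherits(est, "effect_estimate"))
  se <- if (!is.na(est$ci_lower)) {
    ci_to_se(est$ci_lower, est$ci_upper, est$conf_level, est$scale)
  } else if (!is.na(est$p_value)) {
    pvalue_to_se(est$point, est$p_value, est$scale)
  } else {
    est$se
  }
  normal_summary(to_additive_scale(est$point, est$scale), se, est$scale)
}

check_level <- function(level, name) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`", name, "` must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(level)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Effect estimate (%s): %.4g\n", scale_label(x$scale), x$point))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  %d%% CI: (%.4g, %.4g)\n", round(100 * x$conf_level),
                x$ci_lower, x$ci_upper))
  }
  if (!is.na(x$p_value)) cat(sprintf("  two-sided p-value: %.4g\n", x$p_value))
  if (!is.na(x$se)) cat(sprintf("  additive-scale SE: %.4g\n", x$se))
  invisible(x)
}

#' @export
print.normal_summary <- function(x, ...) {
  cat(sprintf("Normal summary (additive scale, from %s): estimate %.6g, SE %.6g\n",
              scale_label(x$scale_tag), x$beta_hat, x$se))
  invisible(x)
}
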