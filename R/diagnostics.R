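#' Closed-form parallel-trends violation profile
#'
#' Parallel trends concerns untreated potential outcomes: the group
#' difference in expected untreated outcomes at time \eqn{t} attributable to
#' the covariate is \eqn{g(t) = \lambda_t \{m_1(t) - m_0(t)\}}, where
#' \eqn{m_d(t)} is the covariate mean path of group \eqn{d} with any
#' treatment-induced covariate shift removed (treatment cannot affect
#' untreated potential outcomes). Parallel trends hold exactly when
#' \eqn{g} is constant over time: a constant group gap is absorbed by the
#' group intercept, while a time-varying gap biases the
#' difference-in-differences contrast.
#'
#' @param config A `did_scenario`.
#' @param tol Absolute range of `g` below which it is declared constant.
#'   All quantities are closed-form, so the default tolerates only
#'   floating-point noise.
#' @return A list of class `did_violation` with elements `g` (length-`T`
#'   vector), `is_parallel`, and `treatment_affects_covariate`.
#' @export
violation_profile <- function(config, tol = 1e-10) {
  validate_scenario(config)
  lam <- lambda_schedule(config)
  gap <- covariate_mean_path(config, 1) - covariate_mean_path(config, 0)
  g <- lam * gap
  structure(list(
    g = g,
    is_parallel = (max(g) - min(g)) < tol,
    treatment_affects_covariate = config$cov_process$delta != 0
  ), class = "did_violation")
}

#' @export
print.did_violation <- function(x, ...) {
  cat("<did_violation> parallel trends:", if (x$is_parallel) "hold" else "violated", "\n")
  cat("  g(t):", paste(signif(x$g, 4), collapse = " "), "\n")
  if (x$treatment_affects_covariate)
    cat("  treatment affects the covariate (mediation present)\n")
  invisible(x)
}

#' Classify the confounding structure of a data-generating process
#'
#' A covariate confounds a difference-in-differences comparison when it
#' induces a time-varying outcome difference between groups, i.e. when the
#' violation profile \eqn{g(t)} is not constant. A covariate that is itself
#' shifted by treatment additionally acts as a mediator, so the regression
#' interaction coefficient no longer targets the ATT even under correct
#' adjustment.
#'
#' @param config A `did_scenario`.
#' @return One of `"none"`, `"covariate_confounding"`,
#'   `"treatment_affected_covariate"`.
#' @export
classify_confounding <- function(config) {
  vp <- violation_profile(config)
  if (vp$treatment_affects_covariate) return("treatment_affected_covariate")
  if (!vp$is_parallel) return("covariate_confounding")
  "none"
}

#' Population average treatment effect on the treated
#'
#' Averaged over posttreatment times \eqn{t = t_0, \ldots, T}. Without a
#' treatment-affected covariate (\eqn{\delta = 0}) the ATT equals the
#' direct effect \eqn{\gamma} exactly. With \eqn{\delta \ne 0} the
#' treatment shifts the covariate by \eqn{\Delta x(t) = \delta (t - t_0 + 1)}
#' in the treated group, so each posttreatment time contributes a mediated
#' component \eqn{\lambda_t \Delta x(t)} on top of \eqn{\gamma}.
#'
#' @param config A `did_scenario`.
#' @return Scalar ATT in outcome units.
#' @export
true_att <- function(config) {
  validate_scenario(config)
  gamma <- config$gamma
  delta <- config$cov_process$delta
  if (delta == 0) return(gamma)
  post <- seq(config$t0, config$n_times)
  lam <- lambda_schedule(config)[post]
  gamma + mean(lam * delta * (post - config$t0 + 1))
}
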