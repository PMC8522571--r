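#' @title Regression estimators of the ATT
#' @description
#' Three two-way specifications share a common core: time fixed effects, a
#' treated-group indicator, and the treated-by-post interaction whose
#' coefficient is the difference-in-differences estimate of the treatment
#' effect. They differ only in how the covariate enters:
#' \describe{
#'   \item{simple}{covariate ignored}
#'   \item{ca}{covariate main effect (constant coefficient)}
#'   \item{tva}{covariate-by-time interactions (one coefficient per time
#'     point), accommodating a time-varying covariate effect}
#' }
#' Standard errors are CR1 cluster-robust, clustered on unit.
#' @name did_regressions
NULL

# Shared fitting engine. `extra` is "", "x", or "tva" and controls the
# covariate terms; weights are frequency weights (matched samples).
fit_did_lm <- function(panel, extra = c("none", "x", "tva"),
                       weights = NULL, estimator_name = "simple") {
  stopifnot(inherits(panel, "did_panel"))
  extra <- match.arg(extra)
  df <- as.data.frame(panel)
  if (length(unique(df$treated)) < 2) {
    stop("panel must contain both treated and control units", call. = FALSE)
  }
  if (!any(df$post == 1) || !any(df$post == 0)) {
    stop("panel must contain both pre and post periods", call. = FALSE)
  }
  df$time_f <- factor(df$time)
  df$did <- df$treated * df$post
  fml <- switch(extra,
                none = y ~ time_f + treated + did,
                x    = y ~ time_f + treated + x + did,
                tva  = y ~ time_f + treated + time_f:x + did)
  w <- if (is.null(weights)) rep(1, nrow(df)) else rep_len(weights, nrow(df))
  fit <- stats::lm(fml, data = df, weights = w)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("singular design: aliased coefficients in the ", estimator_name,
         " model (", paste(names(beta)[is.na(beta)], collapse = ", "), ")",
         call. = FALSE)
  }
  X <- stats::model.matrix(fit)
  se <- cluster_robust_se(X, stats::residuals(fit), w, df$unit)
  structure(list(
    estimator_name = estimator_name,
    gamma_hat = unname(beta[["did"]]),
    se_gamma = unname(se[["did"]]),
    n_units_used = length(unique(df$unit)),
    coefficients = beta,
    se = se
  ), class = "did_fit")
}

#' @export
print.did_fit <- function(x, ...) {
  cat(sprintf("<did_fit %s> gamma_hat = %.4f (cluster-robust SE %.4f), %d units\n",
              x$estimator_name, x$gamma_hat, x$se_gamma, x$n_units_used))
  invisible(x)
}

#' Simple difference-in-differences regression
#'
#' OLS of the outcome on time fixed effects, the treated indicator, and the
#' treated-by-post interaction; the covariate is ignored entirely.
#'
#' @param panel A `did_panel` (balanced; both groups; pre and post periods).
#' @return A `did_fit` with `gamma_hat`, cluster-robust `se_gamma`,
#'   `n_units_used`, and the full coefficient vector.
#' @export
fit_simple <- function(panel) fit_did_lm(panel, "none", estimator_name = "simple")

#' Covariate-adjusted (CA) regression
#'
#' Adds the covariate main effect — a constant coefficient — to the simple
#' model. This adjusts for a level difference in the covariate but not for
#' a time-varying covariate effect.
#'
#' @inheritParams fit_simple
#' @return A `did_fit`.
#' @export
fit_ca <- function(panel) fit_did_lm(panel, "x", estimator_name = "ca")

#' Time-varying-adjusted (TVA) regression
#'
#' Replaces the covariate main effect by covariate-by-time interactions: one
#' covariate coefficient per time point, so a time-varying covariate effect
#' is within the model span.
#'
#' @inheritParams fit_simple
#' @return A `did_fit`.
#' @export
fit_tva <- function(panel) fit_did_lm(panel, "tva", estimator_name = "tva")

#' Estimator registry
#'
#' @return Character vector of the six estimator names understood by
#'   [fit_estimator()] and [run_study()].
#' @export
did_estimators <- function() {
  c("simple", "ca", "tva", "match_level", "match_trend", "match_cov")
}

#' Apply one named estimator
#'
#' @param panel A `did_panel`.
#' @param estimator One of [did_estimators()].
#' @return A `did_fit`.
#' @export
fit_estimator <- function(panel, estimator) {
  estimator <- match.arg(estimator, did_estimators())
  switch(estimator,
         simple = fit_simple(panel),
         ca = fit_ca(panel),
         tva = fit_tva(panel),
         match_level = fit_matched(panel, "level"),
         match_trend = fit_matched(panel, "trend"),
         match_cov = fit_matched(panel, "cov"))
}
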