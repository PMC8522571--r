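#' @keywords internal
"_PACKAGE"

#' Canonical scenario identifiers
#'
#' The nine data-generating processes span the cross of covariate evolution
#' (time-invariant with equal or unequal group means; time-varying with
#' parallel, baseline-divergent, or posttreatment-divergent group paths) and
#' covariate effect schedule (constant or time-varying coefficient).
#'
#' @return Character vector of the nine scenario ids.
#' @export
scenario_ids <- function() {
  c("1", "2", "3", "4a", "4b", "5a", "5b", "6a", "6b")
}

# Structural template for each scenario: the covariate process family, the
# effect-schedule family, and the fields that are locked to zero because the
# scenario's definition requires it (e.g. no treatment effect on the
# covariate outside scenario 6).
scenario_registry <- function() {
  ti <- function(a1, effect) {
    list(covariate_kind = "time_invariant",
         effect_kind = effect,
         cov_process = list(a0 = 0, a1 = a1, b0 = 0, b1 = 0, delta = 0),
         locked_zero = c("b0", "b1", "delta"))
  }
  tv <- function(a1, b1, delta, effect, locked_zero) {
    list(covariate_kind = "time_varying",
         effect_kind = effect,
         cov_process = list(a0 = 0, a1 = a1, b0 = 0.2, b1 = b1, delta = delta),
         locked_zero = locked_zero)
  }
  list(
    "1"  = ti(a1 = 1, effect = "constant"),
    "2"  = ti(a1 = 1, effect = "linear"),
    "3"  = ti(a1 = 0, effect = "linear"),
    "4a" = tv(0.5, 0,   0,   "constant", c("b1", "delta")),
    "4b" = tv(0.5, 0,   0,   "linear",   c("b1", "delta")),
    "5a" = tv(0.5, 0.2, 0,   "constant", "delta"),
    "5b" = tv(0.5, 0.2, 0,   "linear",   "delta"),
    "6a" = tv(0,   0,   0.3, "constant", c("a1", "b1")),
    "6b" = tv(0,   0,   0.3, "linear",   c("a1", "b1"))
  )
}

default_effect <- function(kind) {
  switch(kind,
         constant = list(kind = "constant", lambda = 1),
         linear   = list(kind = "linear", a = 0.5, b = 0.2),
         stop("unknown effect kind: ", kind))
}

#' Build a fully resolved scenario configuration
#'
#' Resolves one of the nine canonical data-generating processes to a complete
#' parameter set. The outcome model is
#' \deqn{y_{it} = \alpha_0 + \alpha_1 d_i + \zeta_t + \lambda_t x_{it} +
#'       \gamma p_t d_i + \epsilon_{it},}
#' with time fixed effects \eqn{\zeta_t}, treated-group indicator \eqn{d_i},
#' posttreatment indicator \eqn{p_t} (1 for \eqn{t \ge t_0}) and additive
#' treatment effect \eqn{\gamma}. The covariate mean path is
#' \eqn{a_0 + a_1 d + (b_0 + b_1 d)\,t}, plus a treatment-induced shift
#' \eqn{\delta\,(t - t_0 + 1)} for treated units after \eqn{t_0}
#' (scenario 6 only).
#'
#' @param scenario_id One of `scenario_ids()`.
#' @param overrides Named list of parameter overrides. Recognized names:
#'   `n_units`, `n_times`, `t0`, `p_treat`, `alpha0`, `alpha1`, `zeta`,
#'   `gamma`, `sigma_x`, `sigma_y`, covariate-process parameters `a0`, `a1`,
#'   `b0`, `b1`, `delta` (aliases `mu0`/`mu1` for time-invariant group
#'   means), and effect-schedule parameters `lambda` (constant schedules),
#'   `lambda_a`/`lambda_b` (linear schedules \eqn{\lambda_t = a + b t}), or
#'   `lambda_values` (an explicit length-`n_times` vector, accepted for any
#'   scenario). Overrides that contradict the scenario's structure (a
#'   nonzero `delta` outside scenario 6, a linear-schedule parameter for a
#'   constant-effect scenario, ...) raise a structural-conflict error.
#' @return An object of class `did_scenario`.
#' @examples
#' cfg <- make_scenario("5a")
#' true_att(cfg)
#' make_scenario("4a", list(n_units = 50))$n_units
#' @export
make_scenario <- function(scenario_id, overrides = list()) {
  scenario_id <- as.character(scenario_id)
  reg <- scenario_registry()
  if (!scenario_id %in% names(reg)) {
    stop("unknown scenario id '", scenario_id, "'; valid ids: ",
         paste(scenario_ids(), collapse = ", "), call. = FALSE)
  }
  tmpl <- reg[[scenario_id]]
  if (!is.list(overrides)) stop("`overrides` must be a named list", call. = FALSE)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all overrides must be named", call. = FALSE)
  }

  # mu0/mu1 are aliases for the time-invariant mean parameterization
  if ("mu0" %in% names(overrides) || "mu1" %in% names(overrides)) {
    if (tmpl$covariate_kind != "time_invariant") {
      stop_structural(scenario_id, "mu0/mu1 apply only to time-invariant covariates")
    }
    mu0 <- overrides$mu0 %||% tmpl$cov_process$a0
    mu1 <- overrides$mu1 %||% (tmpl$cov_process$a0 + tmpl$cov_process$a1)
    overrides$a0 <- mu0
    overrides$a1 <- mu1 - mu0
    overrides$mu0 <- overrides$mu1 <- NULL
  }

  known <- c("n_units", "n_times", "t0", "p_treat", "alpha0", "alpha1",
             "zeta", "gamma", "sigma_x", "sigma_y",
             "a0", "a1", "b0", "b1", "delta",
             "lambda", "lambda_a", "lambda_b", "lambda_values")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown override field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  # structural locks: zero-constrained covariate-process fields
  for (f in tmpl$locked_zero) {
    if (!is.null(overrides[[f]]) && overrides[[f]] != 0) {
      stop_structural(scenario_id, paste0(f, " must be 0 in scenario ", scenario_id))
    }
  }
  # effect-schedule family locks (an explicit lambda_values vector is always
  # accepted as an escape hatch)
  if (tmpl$effect_kind == "constant" &&
      any(c("lambda_a", "lambda_b") %in% names(overrides))) {
    stop_structural(scenario_id, "scenario has a constant covariate effect; use `lambda`")
  }
  if (tmpl$effect_kind == "linear" && "lambda" %in% names(overrides)) {
    stop_structural(scenario_id, "scenario has a time-varying covariate effect; use `lambda_a`/`lambda_b`")
  }

  n_times <- as.integer(overrides$n_times %||% 10L)
  cov_process <- tmpl$cov_process
  for (f in c("a0", "a1", "b0", "b1", "delta")) {
    if (!is.null(overrides[[f]])) cov_process[[f]] <- as.numeric(overrides[[f]])
  }

  effect <- default_effect(tmpl$effect_kind)
  if (!is.null(overrides$lambda)) effect$lambda <- as.numeric(overrides$lambda)
  if (!is.null(overrides$lambda_a)) effect$a <- as.numeric(overrides$lambda_a)
  if (!is.null(overrides$lambda_b)) effect$b <- as.numeric(overrides$lambda_b)
  if (!is.null(overrides$lambda_values)) {
    effect <- list(kind = "custom", values = as.numeric(overrides$lambda_values))
  }

  config <- structure(list(
    scenario_id = scenario_id,
    n_units = as.integer(overrides$n_units %||% 800L),
    n_times = n_times,
    t0 = as.integer(overrides$t0 %||% 6L),
    p_treat = as.numeric(overrides$p_treat %||% 0.5),
    alpha0 = as.numeric(overrides$alpha0 %||% 1),
    alpha1 = as.numeric(overrides$alpha1 %||% 0.5),
    zeta = as.numeric(overrides$zeta %||% (0.1 * seq_len(n_times))),
    gamma = as.numeric(overrides$gamma %||% 1),
    covariate_kind = tmpl$covariate_kind,
    covariate_effect = effect,
    cov_process = cov_process,
    sigma_x = as.numeric(overrides$sigma_x %||% 0.5),
    sigma_y = as.numeric(overrides$sigma_y %||% 1)
  ), class = "did_scenario")
  validate_scenario(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_structural <- function(scenario_id, msg) {
  stop(structure(class = c("didconfound_structural_conflict", "error", "condition"),
                 list(message = paste0("structural conflict for scenario ",
                                       scenario_id, ": ", msg),
                      call = NULL)))
}

validate_scenario <- function(config) {
  stopifnot(inherits(config, "did_scenario"))
  with(config, {
    if (n_units < 2) stop("n_units must be >= 2", call. = FALSE)
    if (n_times < 1) stop("n_times must be >= 1", call. = FALSE)
    if (t0 < 1 || t0 > n_times) stop("t0 must lie in 1..n_times", call. = FALSE)
    if (p_treat < 0 || p_treat > 1) stop("p_treat must lie in [0, 1]", call. = FALSE)
    if (length(zeta) != n_times) stop("zeta must have length n_times", call. = FALSE)
    if (sigma_x < 0 || sigma_y < 0) stop("noise SDs must be nonnegative", call. = FALSE)
    if (!covariate_kind %in% c("time_invariant", "time_varying")) {
      stop("covariate_kind must be time_invariant or time_varying", call. = FALSE)
    }
    if (covariate_kind == "time_invariant" &&
        (cov_process$b0 != 0 || cov_process$b1 != 0 || cov_process$delta != 0)) {
      stop("time-invariant covariates require b0 = b1 = delta = 0", call. = FALSE)
    }
  })
  ls <- lambda_schedule(config)
  if (length(ls) != config$n_times || anyNA(ls)) {
    stop("covariate effect schedule must resolve to length n_times", call. = FALSE)
  }
  config
}

#' Covariate effect schedule
#'
#' Resolves the configured effect schedule to the vector
#' \eqn{(\lambda_1, \ldots, \lambda_T)}.
#'
#' @param config A `did_scenario`.
#' @return Numeric vector of length `n_times`.
#' @export
lambda_schedule <- function(config) {
  eff <- config$covariate_effect
  t <- seq_len(config$n_times)
  switch(eff$kind,
         constant = rep(eff$lambda, config$n_times),
         linear   = eff$a + eff$b * t,
         custom   = eff$values,
         stop("unknown effect kind"))
}

# Group mean path of the covariate at each time, excluding any
# treatment-induced shift: m_d(t) = a0 + a1 d + (b0 + b1 d) t.
covariate_mean_path <- function(config, d) {
  cp <- config$cov_process
  t <- seq_len(config$n_times)
  cp$a0 + cp$a1 * d + (cp$b0 + cp$b1 * d) * t
}

#' @export
print.did_scenario <- function(x, ...) {
  cat("<did_scenario", x$scenario_id, ">\n", sep = "")
  cat(sprintf("  panel: %d units x %d times, treatment from t0 = %d, P(treated) = %g\n",
              x$n_units, x$n_times, x$t0, x$p_treat))
  cat(sprintf("  covariate: %s; mean path a0=%g a1=%g b0=%g b1=%g delta=%g, sigma_x=%g\n",
              x$covariate_kind, x$cov_process$a0, x$cov_process$a1,
              x$cov_process$b0, x$cov_process$b1, x$cov_process$delta, x$sigma_x))
  eff <- x$covariate_effect
  sched <- switch(eff$kind,
                  constant = sprintf("constant lambda = %g", eff$lambda),
                  linear = sprintf("lambda_t = %g + %g t", eff$a, eff$b),
                  custom = paste("custom:", paste(signif(eff$values, 3), collapse = " ")))
  cat("  effect schedule:", sched, "\n")
  cat(sprintf("  outcome: alpha0=%g alpha1=%g gamma=%g sigma_y=%g\n",
              x$alpha0, x$alpha1, x$gamma, x$sigma_y))
  invisible(x)
}

#' Summarize the nine canonical scenarios
#'
#' Tabulates each canonical data-generating process with its covariate
#' evolution, effect schedule, computed confounding classification, and
#' population ATT under the default parameters. The confounded flag is
#' computed from [classify_confounding()], not stored.
#'
#' @return A data.frame with one row per scenario.
#' @export
scenario_table <- function() {
  rows <- lapply(scenario_ids(), function(id) {
    cfg <- make_scenario(id)
    cp <- cfg$cov_process
    evolution <-
      if (cfg$covariate_kind == "time_invariant") {
        if (cp$a1 == 0) "constant, equal means" else "constant, unequal means"
      } else if (cp$delta != 0) {
        "diverges in postperiod"
      } else if (cp$b1 != 0) {
        "diverges from baseline"
      } else {
        "parallel"
      }
    cls <- classify_confounding(cfg)
    data.frame(
      scenario = id,
      covariate_evolution = evolution,
      covariate_effect = if (cfg$covariate_effect$kind == "constant") "constant" else "time-varying",
      confounded = cls != "none",
      classification = cls,
      true_att = true_att(cfg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a scenario configuration to YAML or JSON
#'
#' Serializes the resolved configuration as a flat document whose keys
#' mirror the configuration fields. The format is chosen by file extension
#' (`.json` for JSON, anything else YAML).
#'
#' @param config A `did_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
scenario_write <- function(config, path) {
  validate_scenario(config)
  eff <- config$covariate_effect
  doc <- c(
    list(scenario_id = config$scenario_id),
    config[c("n_units", "n_times", "t0", "p_treat", "alpha0", "alpha1",
             "gamma", "sigma_x", "sigma_y", "covariate_kind")],
    list(zeta = config$zeta),
    config$cov_process,
    list(effect_kind = eff$kind),
    switch(eff$kind,
           constant = list(lambda = eff$lambda),
           linear   = list(lambda_a = eff$a, lambda_b = eff$b),
           custom   = list(lambda_values = eff$values))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path File written by [scenario_write()] (or hand-authored with the
#'   same keys). `scenario_id` selects the structural template; remaining
#'   keys are applied as overrides.
#' @return A validated `did_scenario`.
#' @export
scenario_read <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  id <- doc$scenario_id
  if (is.null(id)) stop("configuration document lacks a scenario_id", call. = FALSE)
  effect_kind <- doc$effect_kind %||% NULL
  doc[c("scenario_id", "covariate_kind", "effect_kind")] <- NULL
  doc <- Filter(Negate(is.null), doc)
  if (!is.null(doc$zeta)) doc$zeta <- as.numeric(unlist(doc$zeta))
  if (!is.null(doc$lambda_values)) doc$lambda_values <- as.numeric(unlist(doc$lambda_values))
  make_scenario(id, doc)
}
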