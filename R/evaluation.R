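#' Mean absolute percent bias
#'
#' Average the estimates, subtract the truth, take the absolute value, and
#' express it as a percentage of the true effect.
#'
#' @param estimates Numeric vector of Monte Carlo estimates.
#' @param truth True effect (nonzero; relative bias is undefined at zero).
#' @return Percent bias (nonnegative scalar).
#' @export
mean_abs_percent_bias <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  if (truth == 0) {
    stop("relative bias is undefined for a zero true effect; ",
         "use the absolute bias mean(estimates) - 0 instead", call. = FALSE)
  }
  abs(mean(estimates) - truth) / abs(truth) * 100
}

#' Mean standard error
#'
#' @param ses Vector of per-replicate standard error estimates (all >= 0).
#' @return Their arithmetic mean.
#' @export
mean_se <- function(ses) {
  stopifnot(length(ses) >= 1, all(ses >= 0))
  mean(ses)
}

#' Root mean squared error
#'
#' @param estimates Numeric vector of Monte Carlo estimates.
#' @param truth True effect.
#' @return `sqrt(mean((estimates - truth)^2))`.
#' @export
rmse <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  sqrt(mean((estimates - truth)^2))
}

#' Run a Monte Carlo study for one scenario
#'
#' Draws `n_reps` independent panels (replicate `k` on RNG stream `k` of
#' the master seed), applies the requested estimators to each, and
#' aggregates mean absolute percent bias, mean cluster-robust SE, RMSE and
#' the Monte Carlo SE of the mean estimate against the scenario's
#' population ATT. Replicate-level estimator failures are recorded and the
#' replicate excluded from that estimator's aggregate; more than 1%
#' exclusions for any estimator aborts the study.
#'
#' @param scenario_id One of [scenario_ids()].
#' @param n_reps Number of replicate panels.
#' @param overrides Passed to [make_scenario()].
#' @param seed Master seed.
#' @param estimators Subset of [did_estimators()].
#' @return A `did_study`: `summary` (one row per estimator), `estimates`
#'   (replicate-level long data.frame), `config`, `true_att`, `n_reps`,
#'   `seed`, `exclusions`.
#' @export
run_study <- function(scenario_id, n_reps = 400, overrides = list(),
                      seed = 1, estimators = did_estimators()) {
  estimators <- match.arg(estimators, did_estimators(), several.ok = TRUE)
  config <- make_scenario(scenario_id, overrides)
  truth <- true_att(config)

  res <- vector("list", n_reps)
  failures <- list()
  for (k in seq_len(n_reps)) {
    panel <- draw_panel(config, rng_spec(seed, k))
    fits <- lapply(estimators, function(est) {
      tryCatch(fit_estimator(panel, est), error = function(e) e)
    })
    names(fits) <- estimators
    ok <- !vapply(fits, inherits, logical(1), "error")
    for (est in estimators[!ok]) {
      failures[[length(failures) + 1]] <-
        data.frame(replicate = k, estimator = est,
                   message = conditionMessage(fits[[est]]))
    }
    if (any(ok)) {
      res[[k]] <- data.frame(
        replicate = k,
        estimator = estimators[ok],
        gamma_hat = vapply(fits[ok], `[[`, numeric(1), "gamma_hat"),
        se_gamma = vapply(fits[ok], `[[`, numeric(1), "se_gamma")
      )
    }
  }
  estimates <- do.call(rbind, res)
  rownames(estimates) <- NULL
  exclusions <- if (length(failures)) do.call(rbind, failures) else
    data.frame(replicate = integer(), estimator = character(), message = character())

  summary <- do.call(rbind, lapply(estimators, function(est) {
    sub <- estimates[estimates$estimator == est, ]
    n_excl <- sum(exclusions$estimator == est)
    if (n_excl > 0.01 * n_reps) {
      stop("estimator ", est, " failed on ", n_excl, " of ", n_reps,
           " replicates (> 1% exclusion cap)", call. = FALSE)
    }
    data.frame(
      scenario = config$scenario_id,
      estimator = est,
      n_reps = nrow(sub),
      mean_estimate = mean(sub$gamma_hat),
      mean_abs_pct_bias = if (truth != 0) mean_abs_percent_bias(sub$gamma_hat, truth) else NA_real_,
      mean_se = mean_se(sub$se_gamma),
      rmse = rmse(sub$gamma_hat, truth),
      mc_se_of_mean_estimate = stats::sd(sub$gamma_hat) / sqrt(nrow(sub)),
      true_att = truth,
      n_excluded = n_excl
    )
  }))
  rownames(summary) <- NULL

  structure(list(
    summary = summary,
    estimates = estimates,
    config = config,
    true_att = truth,
    n_reps = n_reps,
    seed = seed,
    exclusions = exclusions
  ), class = "did_study")
}

#' @export
print.did_study <- function(x, digits = 4, ...) {
  cat(sprintf("<did_study> scenario %s, %d replicates (seed %d), true ATT = %g\n",
              x$config$scenario_id, x$n_reps, x$seed, x$true_att))
  print(format(x$summary, digits = digits), ...)
  invisible(x)
}

#' Write study results as CSV plus a JSON manifest
#'
#' The CSV holds the per-estimator summary (one row per estimator); the
#' JSON document embeds the resolved configuration, seed, replicate count,
#' package version and timestamp — enough to regenerate the CSV exactly.
#'
#' @param study A `did_study`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of the paths written.
#' @export
study_write <- function(study, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(study, "did_study"))
  if (!is.null(csv_path)) {
    utils::write.csv(study$summary, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    cfg <- study$config
    doc <- list(
      scenario = cfg$scenario_id,
      n_reps = study$n_reps,
      seed = study$seed,
      true_att = study$true_att,
      config = unclass(cfg),
      summary = study$summary,
      n_excluded = nrow(study$exclusions),
      package_version = as.character(utils::packageVersion("didconfound")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(csv = csv_path, json = json_path))
}
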