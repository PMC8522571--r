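#' Reproducible RNG stream specification
#'
#' One master seed per study; replicate `stream` uses the `stream`-th
#' L'Ecuyer-CMRG substream, so each replicate is regenerable on its own
#' without storing panels, and distinct streams are statistically
#' independent.
#'
#' @param seed Master seed (integer).
#' @param stream Nonnegative replicate index; stream 0 is the master stream.
#' @return Object of class `rng_spec`.
#' @export
rng_spec <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stream), length(stream) == 1, stream >= 0)
  structure(list(seed = as.integer(seed), stream = as.integer(stream)),
            class = "rng_spec")
}

# Set .Random.seed to the requested substream. Restoring the caller's RNG
# state is the caller's concern (draw_* functions are the only entry points
# and are documented to own the RNG while they run).
activate_rng <- function(rng) {
  stopifnot(inherits(rng, "rng_spec"))
  suppressWarnings(set.seed(rng$seed, kind = "L'Ecuyer-CMRG"))
  if (rng$stream > 0) {
    s <- .Random.seed
    for (i in seq_len(rng$stream)) s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = globalenv())
  }
  invisible(NULL)
}

as_rng <- function(rng, stream = 0L) {
  if (inherits(rng, "rng_spec")) rng else rng_spec(rng, stream)
}

#' Assign units to the treatment group
#'
#' Independent Bernoulli(`p_treat`) draws. Degenerate assignments (all
#' treated or all control) are redrawn up to 100 times; persistent
#' degeneracy — only plausible for extreme `p_treat` — is an error.
#'
#' @param n_units Number of units (>= 2).
#' @param p_treat Treatment-group probability in `[0, 1]`.
#' @param rng An [rng_spec()] (or a bare seed).
#' @return Integer 0/1 vector of length `n_units`.
#' @export
assign_groups <- function(n_units, p_treat, rng) {
  stopifnot(n_units >= 2, p_treat >= 0, p_treat <= 1)
  activate_rng(as_rng(rng))
  for (attempt in seq_len(100)) {
    d <- stats::rbinom(n_units, 1L, p_treat)
    if (any(d == 1L) && any(d == 0L)) return(d)
  }
  stop("degenerate assignment: no mixed treated/control draw in 100 attempts ",
       "(p_treat = ", p_treat, ")", call. = FALSE)
}

# Covariate matrix (n_units x n_times) given the group vector. Time-invariant
# covariates draw one noise term per unit and replicate it across time;
# time-varying covariates follow the linear group mean path plus the
# treatment-induced post-divergence delta * (t - t0 + 1) for treated units,
# with independent noise per (unit, time).
draw_covariate_matrix <- function(config, d) {
  n <- length(d)
  T_ <- config$n_times
  cp <- config$cov_process
  if (config$covariate_kind == "time_invariant") {
    x_i <- cp$a0 + cp$a1 * d + stats::rnorm(n, 0, config$sigma_x)
    matrix(x_i, nrow = n, ncol = T_)
  } else {
    t_ <- seq_len(T_)
    mean_path <- outer(cp$a0 + cp$a1 * d, rep(1, T_)) +
      outer(cp$b0 + cp$b1 * d, t_)
    if (cp$delta != 0) {
      elapsed <- pmax(t_ - config$t0 + 1, 0)
      mean_path <- mean_path + cp$delta * outer(d, elapsed)
    }
    mean_path + matrix(stats::rnorm(n * T_, 0, config$sigma_x), n, T_)
  }
}

#' Draw the covariate process
#'
#' @param config A `did_scenario`.
#' @param d Group vector from [assign_groups()].
#' @param rng An [rng_spec()] (or a bare seed).
#' @return Numeric matrix, `n_units` rows by `n_times` columns.
#' @export
draw_covariates <- function(config, d, rng) {
  validate_scenario(config)
  stopifnot(length(d) == config$n_units, all(d %in% c(0, 1)))
  activate_rng(as_rng(rng))
  draw_covariate_matrix(config, d)
}

#' Simulate one balanced panel
#'
#' Draws group assignment, the covariate process, and outcomes
#' \eqn{y_{it} = \alpha_0 + \alpha_1 d_i + \zeta_t + \lambda_t x_{it} +
#' \gamma p_t d_i + \epsilon_{it}} with i.i.d. Gaussian noise. With
#' `gamma = 0` the panel carries the untreated potential outcomes of every
#' unit, which is what the parallel-trends diagnostics reason about.
#'
#' @param config A `did_scenario`.
#' @param rng An [rng_spec()] (or a bare seed). The same `(seed, stream)`
#'   reproduces the panel bit for bit.
#' @return A `did_panel`: long-format data.frame with columns `unit`,
#'   `time`, `treated`, `post`, `x`, `y` and attribute `t0`.
#' @export
draw_panel <- function(config, rng) {
  validate_scenario(config)
  rng <- as_rng(rng)
  activate_rng(rng)
  n <- config$n_units
  T_ <- config$n_times
  d <- NULL
  for (attempt in seq_len(100)) {
    d <- stats::rbinom(n, 1L, config$p_treat)
    if (any(d == 1L) && any(d == 0L)) break
    d <- NULL
  }
  if (is.null(d)) {
    stop("degenerate assignment: no mixed treated/control draw in 100 attempts",
         call. = FALSE)
  }
  x <- draw_covariate_matrix(config, d)
  t_ <- seq_len(T_)
  post <- as.integer(t_ >= config$t0)
  lam <- lambda_schedule(config)
  # row i, column t layout; flatten column-major so time is the slow index
  mu <- config$alpha0 + config$alpha1 * outer(d, rep(1, T_)) +
    outer(rep(1, n), config$zeta) +
    sweep(x, 2, lam, `*`) +
    config$gamma * outer(d, post)
  y <- mu + matrix(stats::rnorm(n * T_, 0, config$sigma_y), n, T_)
  panel <- data.frame(
    unit = rep(seq_len(n), times = T_),
    time = rep(t_, each = n),
    treated = rep(d, times = T_),
    post = rep(post, each = n),
    x = as.vector(x),
    y = as.vector(y)
  )
  panel <- panel[order(panel$unit, panel$time), , drop = FALSE]
  rownames(panel) <- NULL
  as_did_panel(panel, t0 = config$t0)
}

#' Construct / validate a panel object
#'
#' Checks balance (every unit at every time), constancy of `treated` within
#' unit, and agreement of `post` with `time >= t0`.
#'
#' @param panel data.frame with columns `unit`, `time`, `treated`, `post`,
#'   `x`, `y`.
#' @param t0 First posttreatment time.
#' @return The panel with class `did_panel` and attribute `t0`.
#' @export
as_did_panel <- function(panel, t0) {
  needed <- c("unit", "time", "treated", "post", "x", "y")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  times <- sort(unique(panel$time))
  units <- unique(panel$unit)
  if (nrow(panel) != length(times) * length(units)) {
    stop("panel is not balanced: expected one row per unit per time",
         call. = FALSE)
  }
  tab <- table(panel$unit, panel$time)
  if (any(tab != 1L)) stop("panel is not balanced", call. = FALSE)
  if (any(tapply(panel$treated, panel$unit, function(v) length(unique(v))) != 1L)) {
    stop("treated must be constant within unit", call. = FALSE)
  }
  if (!all(panel$post == as.integer(panel$time >= t0))) {
    stop("post must equal 1 exactly when time >= t0", call. = FALSE)
  }
  structure(panel, t0 = as.integer(t0),
            class = c("did_panel", "data.frame"))
}

#' @export
print.did_panel <- function(x, ...) {
  n <- length(unique(x$unit))
  T_ <- length(unique(x$time))
  cat(sprintf("<did_panel> %d units x %d times (t0 = %d), %d treated\n",
              n, T_, attr(x, "t0"), sum(x$treated[!duplicated(x$unit)])))
  NextMethod()
}

#' Write a panel as long-format CSV
#'
#' Columns `unit,time,treated,post,x,y`; `post` is derivable from `t0` but
#' included for convenience and cross-checked on re-import.
#'
#' @param panel A `did_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
panel_write <- function(panel, path) {
  stopifnot(inherits(panel, "did_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV panel
#'
#' @param path CSV written by [panel_write()] (or equivalent).
#' @param t0 First posttreatment time; if `NULL`, inferred as the earliest
#'   time with `post == 1`. The stored `post` column is re-derived from `t0`
#'   and any disagreement is an error.
#' @return A `did_panel`.
#' @export
panel_read <- function(path, t0 = NULL) {
  panel <- utils::read.csv(path)
  if (is.null(t0)) {
    if (!any(panel$post == 1)) {
      stop("cannot infer t0: no posttreatment rows; pass t0 explicitly",
           call. = FALSE)
    }
    t0 <- min(panel$time[panel$post == 1])
  }
  as_did_panel(panel, t0 = t0)
}
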