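#' Nearest-neighbor matching with replacement
#'
#' Pairs every treated unit with its nearest control by Euclidean distance
#' on a standardized matching vector, with replacement: a control can serve
#' several treated units and enters the matched sample with a multiplicity
#' weight. Matching variables:
#' \describe{
#'   \item{level}{pretreatment outcomes \eqn{(y_{i1}, \ldots, y_{i,t_0-1})}}
#'   \item{trend}{pretreatment outcome first differences}
#'   \item{cov}{the unit's covariate: its scalar value when time-invariant,
#'     else the vector of pretreatment values}
#' }
#' Each coordinate is centered and scaled by the pooled mean/SD across all
#' units before distances are computed. Distance ties break to the control
#' with the lowest unit id.
#'
#' @param panel A `did_panel`.
#' @param on One of `"level"`, `"trend"`, `"cov"`.
#' @return A list of class `did_matched`: `panel` (rows for retained
#'   units), `weights` (per retained unit: 1 for treated, multiplicity for
#'   controls), and `match_map` (data.frame treated -> control).
#' @export
match_units <- function(panel, on = c("level", "trend", "cov")) {
  stopifnot(inherits(panel, "did_panel"))
  on <- match.arg(on)
  t0 <- attr(panel, "t0")
  pre_times <- sort(unique(panel$time[panel$time < t0]))
  if (length(pre_times) < 1) stop("matching requires >= 1 pretreatment period", call. = FALSE)
  if (on == "trend" && length(pre_times) < 2) {
    stop("matching on trends requires >= 2 pretreatment periods", call. = FALSE)
  }

  df <- as.data.frame(panel)
  units <- sort(unique(df$unit))
  d <- df$treated[match(units, df$unit)]
  if (!any(d == 1) || !any(d == 0)) {
    stop("matching requires both treated and control units", call. = FALSE)
  }

  pre <- df[df$time %in% pre_times, ]
  pre <- pre[order(pre$unit, pre$time), ]
  wide <- function(v) matrix(v, nrow = length(units), byrow = TRUE,
                             dimnames = list(units, pre_times))
  M <- switch(on,
    level = wide(pre$y),
    trend = {
      ylev <- wide(pre$y)
      ylev[, -1, drop = FALSE] - ylev[, -ncol(ylev), drop = FALSE]
    },
    cov = {
      xs <- wide(pre$x)
      # time-invariant covariate: one column carries all the information
      if (all(xs == xs[, 1])) xs[, 1, drop = FALSE] else xs
    })

  # pooled standardization; constant coordinates are left unscaled
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  Z <- sweep(sweep(M, 2, ctr), 2, scl, `/`)

  treated_ids <- units[d == 1]
  control_ids <- units[d == 0]
  Zt <- Z[as.character(treated_ids), , drop = FALSE]
  Zc <- Z[as.character(control_ids), , drop = FALSE]
  # squared Euclidean distances, treated x control
  D2 <- outer(rowSums(Zt^2), rowSums(Zc^2), `+`) - 2 * tcrossprod(Zt, Zc)
  # control_ids ascend, so ties.method = "first" realizes lowest-id tie-break
  pick <- max.col(-D2, ties.method = "first")
  matched_controls <- control_ids[pick]

  match_map <- data.frame(treated = treated_ids, control = matched_controls)
  multiplicity <- table(matched_controls)
  kept_controls <- as.integer(names(multiplicity))
  keep <- c(treated_ids, kept_controls)
  weights <- c(rep(1, length(treated_ids)), as.integer(multiplicity))
  names(weights) <- keep

  out_panel <- df[df$unit %in% keep, ]
  out_panel <- out_panel[order(out_panel$unit, out_panel$time), ]
  rownames(out_panel) <- NULL
  structure(list(
    panel = as_did_panel(out_panel, t0 = t0),
    weights = weights,
    match_map = match_map,
    on = on,
    total_distance = sum(sqrt(pmax(D2[cbind(seq_along(pick), pick)], 0)))
  ), class = "did_matched")
}

#' @export
print.did_matched <- function(x, ...) {
  cat(sprintf("<did_matched on=%s> %d treated, %d distinct controls (total distance %.3f)\n",
              x$on, nrow(x$match_map), length(unique(x$match_map$control)),
              x$total_distance))
  invisible(x)
}

#' Matched difference-in-differences estimator
#'
#' Runs [match_units()], then fits the simple regression on the matched
#' sample with the control multiplicity weights as frequency weights — in
#' both the normal equations and the clustered sandwich. Clustering stays
#' on unit: a reused control is one cluster.
#'
#' @inheritParams match_units
#' @return A `did_fit` named `match_<on>`.
#' @export
fit_matched <- function(panel, on = c("level", "trend", "cov")) {
  on <- match.arg(on)
  m <- match_units(panel, on)
  w_row <- unname(m$weights[as.character(m$panel$unit)])
  fit_did_lm(m$panel, "none", weights = w_row,
             estimator_name = paste0("match_", on))
}
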