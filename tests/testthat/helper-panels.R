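# Shared fixtures, all generated in code.

# A scenario with all noise switched off (deterministic given the group draw).
noiseless <- function(id, ...) {
  make_scenario(id, list(sigma_x = 0, sigma_y = 0, ...))
}

# Outcome noise off, covariate noise kept: outcomes are then an exact linear
# function of the realized design, so correctly specified OLS recovers
# coefficients exactly.
exact_fit_config <- function(id, ...) {
  make_scenario(id, list(sigma_y = 0, ...))
}

# Hand-build a tiny balanced panel from per-unit outcome matrices.
toy_panel <- function(y, treated, t0, x = NULL) {
  n <- nrow(y); T_ <- ncol(y)
  if (is.null(x)) x <- matrix(0, n, T_)
  as_did_panel(data.frame(
    unit = rep(seq_len(n), each = T_),
    time = rep(seq_len(T_), times = n),
    treated = rep(treated, each = T_),
    post = rep(as.integer(seq_len(T_) >= t0), times = n),
    x = as.vector(t(x)),
    y = as.vector(t(y))
  ), t0 = t0)
}

# Independent normal-equations OLS on an explicitly constructed design.
manual_ols <- function(X, y) solve(crossprod(X), crossprod(X, y))

# Explicit simple-model design for a panel (intercept, time dummies 2..T,
# treated, treated*post), built without model.matrix.
simple_design <- function(panel) {
  times <- sort(unique(panel$time))
  X <- cbind(1, sapply(times[-1], function(t) as.numeric(panel$time == t)),
             panel$treated, panel$treated * panel$post)
  colnames(X) <- c("(Intercept)", paste0("time", times[-1]), "treated", "did")
  X
}
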