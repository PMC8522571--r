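#' Cluster-robust (CR1) standard errors
#'
#' Sandwich variance with clustering, allowing arbitrary error correlation
#' within cluster:
#' \deqn{(X'WX)^{-1} \Big[\sum_g X_g' W_g e_g e_g' W_g X_g\Big] (X'WX)^{-1}}
#' scaled by the CR1 finite-sample factor
#' \eqn{\frac{G}{G-1}\cdot\frac{N-1}{N-k}} with \eqn{G} clusters, \eqn{N}
#' rows and \eqn{k} columns. With every row its own cluster and unit
#' weights this reduces to HC1 heteroskedasticity-robust standard errors.
#'
#' @param design Model matrix (`N` x `k`), full rank.
#' @param residuals Residual vector of length `N`.
#' @param weights Observation weights (frequency weights for matched
#'   samples); recycled scalar 1 allowed.
#' @param clusters Cluster id per row (unit ids in panel use).
#' @return Named vector of per-coefficient standard errors.
#' @export
cluster_robust_se <- function(design, residuals, weights = 1, clusters) {
  X <- as.matrix(design)
  N <- nrow(X)
  k <- ncol(X)
  e <- as.numeric(residuals)
  w <- rep_len(as.numeric(weights), N)
  stopifnot(length(e) == N, length(clusters) == N)
  cl <- as.character(clusters)
  G <- length(unique(cl))
  if (G < 2) stop("cluster-robust variance requires >= 2 clusters", call. = FALSE)
  XtWX <- crossprod(X, w * X)
  R <- tryCatch(chol(XtWX), error = function(e) {
    stop("singular design: X'WX is not positive definite", call. = FALSE)
  })
  bread <- chol2inv(R)
  # cluster score sums: rows of S are sum_{i in g} w_i e_i x_i
  S <- rowsum(X * (w * e), group = cl)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((N - 1) / (N - k))
  V <- adj * bread %*% meat %*% bread
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- colnames(X)
  se
}
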