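#' Bifurcating autoregressive (BAR) model parameters
#'
#' A BAR model is a vector AR(1) process running down a binary lineage tree:
#' each cell carries a d-dimensional Gaussian latent state `x`, a daughter's
#' state has conditional mean `A x_mother` with unit intrinsic noise
#' covariance, and the intrinsic noise of the two sisters has
#' cross-covariance `gamma * I`. The observed cycle length is a monotone
#' function of the weighted sum `sum(alpha * x)`.
#'
#' @param A Inheritance matrix (d x d, d = 1 or 2, spectral radius < 1).
#' @param gamma Sister coupling in (-1, 1).
#' @param alpha Observation weights (nonnegative, normalised to sum to 1;
#'   default equal weights).
#' @return An object of class `bar_params`.
#' @export
bar_params <- function(A, gamma = 0, alpha = NULL) {
  A <- as.matrix(A)
  d <- nrow(A)
  if (ncol(A) != d || !d %in% 1:2) {
    stop_kc("kc_invalid_parameter", "A must be a 1x1 or 2x2 matrix")
  }
  if (spectral_radius(A) >= 1) {
    stop_kc("kc_stationarity",
            "inheritance matrix A has spectral radius >= 1 (non-stationary)")
  }
  if (!is.finite(gamma) || abs(gamma) >= 1) {
    stop_kc("kc_invalid_parameter", "gamma must lie in (-1, 1)")
  }
  if (is.null(alpha)) alpha <- rep(1 / d, d)
  if (length(alpha) != d || any(alpha < 0) || sum(alpha) <= 0) {
    stop_kc("kc_invalid_parameter", "alpha must be nonnegative with positive sum")
  }
  alpha <- alpha / sum(alpha)
  structure(list(d = d, A = A, gamma = gamma, alpha = alpha),
            class = "bar_params")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' @export
print.bar_params <- function(x, digits = 3, ...) {
  cat(sprintf("BAR parameters (d = %d)\nA =\n", x$d))
  print(round(x$A, digits))
  cat(sprintf("gamma = %.*f, alpha = (%s)\n", digits, x$gamma,
              paste(round(x$alpha, digits), collapse = ", ")))
  invisible(x)
}

#' Stationary covariance of the latent inheritance process
#'
#' Solves the discrete Lyapunov equation `C = A C A' + I` that the
#' stationary latent covariance satisfies under unit intrinsic noise.
#'
#' @param A Inheritance matrix with spectral radius < 1.
#' @return Symmetric positive-definite matrix `C`.
#' @export
stationary_cov <- function(A) {
  A <- as.matrix(A)
  if (spectral_radius(A) >= 1) {
    stop_kc("kc_stationarity", "spectral radius of A must be < 1")
  }
  d <- nrow(A)
  Id <- diag(d)
  vecC <- solve(diag(d * d) - A %x% A, as.vector(Id))
  C <- matrix(vecC, d, d)
  (C + t(C)) / 2
}

mat_pow <- function(A, n) {
  d <- nrow(A)
  P <- diag(d)
  for (i in seq_len(n)) P <- P %*% A
  P
}

#' Latent covariance between relatives of a given kinship
#'
#' For relatives at generation distances `(u, v)` from their MRCA, the
#' cross-covariance of the latent states is `A^u C (A^v)'` when one cell is
#' the other's ancestor (`u = 0`), and `A^(u-1) S (A^(v-1))'` otherwise,
#' where `S = A C A' + gamma I` is the sister covariance that carries the
#' extra sister coupling down both branches.
#'
#' @param params A [bar_params] object.
#' @param k A [kinship].
#' @param C Stationary covariance (computed from `params$A` if missing).
#' @return d x d covariance matrix.
#' @export
kin_cov <- function(params, k, C = stationary_cov(params$A)) {
  k <- as_kinship(k)
  A <- params$A
  u <- k[[1]]; v <- k[[2]]
  if (u == 0L) {
    mat_pow(A, v) %*% C
  } else {
    S <- A %*% C %*% t(A) + params$gamma * diag(params$d)
    mat_pow(A, u - 1L) %*% S %*% t(mat_pow(A, v - 1L))
  }
}

#' Predicted correlation between relatives under a BAR model
#'
#' Correlation of the observed (Gaussian-transformed) cycle-length scores
#' for each requested kinship: `alpha' M alpha / alpha' C alpha` with `M`
#' from [kin_cov]. For d = 1 this reproduces the classical single-variable
#' null in which first and second cousins correlate as `rho_ss * rho_md^2`
#' and `rho_ss * rho_md^4`.
#'
#' @param params A [bar_params] object.
#' @param k A [kinship], integer pair, or list of these.
#' @return Numeric vector of correlations, one per kinship.
#' @export
kin_corr <- function(params, k) {
  if (is.list(k) && !inherits(k, "kinship")) {
    return(vapply(k, function(ki) kin_corr(params, ki), numeric(1)))
  }
  k <- as_kinship(k)
  C <- stationary_cov(params$A)
  a <- params$alpha
  den <- drop(t(a) %*% C %*% a)
  # sister coupling must keep the sibling joint distribution valid
  S <- params$A %*% C %*% t(params$A) + params$gamma * diag(params$d)
  rho_ss <- drop(t(a) %*% S %*% a) / den
  if (abs(rho_ss) > 1 + 1e-12) {
    stop_kc("kc_invalid_parameter",
            sprintf("sister correlation %.4f outside [-1, 1]: invalid gamma/A",
                    rho_ss))
  }
  rho <- drop(t(a) %*% kin_cov(params, k, C) %*% a) / den
  unname(rho)
}

#' Rank-Gaussianize cycle lengths
#'
#' Maps cycle lengths to standard-normal scores via their average ranks:
#' `score_i = qnorm((rank_i - 0.5) / N)`. The map is monotone, so rank
#' correlations are preserved, and makes the Gaussian BAR likelihood
#' applicable regardless of the (approximately log-normal) marginal of the
#' raw cycle times. The returned map object supports forward (`tau -> y`)
#' and inverse (`y -> tau`) interpolation against the reference sample.
#'
#' @param taus Numeric vector of cycle lengths (>= 2 distinct values).
#' @return List with elements `scores` (per input value) and `map` (class
#'   `gauss_map`, a list of `forward` and `inverse` interpolators).
#' @export
gaussianize <- function(taus) {
  taus <- as.numeric(taus)
  n <- length(taus)
  if (n < 2L) stop_kc("kc_insufficient_data", "need at least 2 values")
  if (max(taus) == min(taus)) {
    stop_kc("kc_degenerate", "all cycle lengths identical; scores undefined")
  }
  r <- rank(taus, ties.method = "average")
  scores <- stats::qnorm((r - 0.5) / n)
  ord <- order(taus)
  ref_tau <- taus[ord]
  ref_score <- scores[ord]
  keep <- !duplicated(ref_tau)  # ties share a score; keep one knot each
  forward <- stats::approxfun(ref_tau[keep], ref_score[keep], rule = 2)
  inverse <- stats::approxfun(ref_score[keep], ref_tau[keep], rule = 2)
  map <- structure(list(forward = forward, inverse = inverse,
                        n = n, range = range(ref_tau)),
                   class = "gauss_map")
  list(scores = scores, map = map)
}

#' @export
print.gauss_map <- function(x, ...) {
  cat(sprintf("Rank-Gaussian map from %d reference cycle lengths (%.2f-%.2f h)\n",
              x$n, x$range[1], x$range[2]))
  invisible(x)
}
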