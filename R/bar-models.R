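#' The BAR model catalogue
#'
#' Nested family of inheritance structures compared by Bayesian evidence:
#' \describe{
#'   \item{II}{d = 1, single self-inheritance parameter `a`.}
#'   \item{III}{d = 2, independent inheritance (diagonal `A`).}
#'   \item{IV}{d = 2, unidirectional coupling: `a11`, `a22` free,
#'     `a12 < 0`, `a21 = 0`.}
#'   \item{V}{d = 2, unidirectional coupling with a single self-inheritance
#'     parameter `a11 = a22 > 0` and `a12 < 0`.}
#'   \item{VI}{d = 2, fully general `A` (bidirectional coupling).}
#'   \item{VII}{d = 2, pure cross-inheritance: only `a12 < 0` free.}
#' }
#' All models share the sister coupling `gamma` and, for d = 2, one free
#' observation weight `alpha1` (weights are normalised to sum to 1, so d - 1
#' weights are free; the full model has `d(d+1)` free parameters). Custom
#' structures can be built with [bar_model_custom].
#'
#' Parameter boxes double as the uniform evidence priors: self-inheritance
#' entries on (0, 1); sign-constrained cross entries `a12` on (-1, 0); free
#' cross entries (model VI) on (-1, 1); `gamma` on (-1, 1); `alpha1` on
#' (0, 1). Draws are truncated to the feasible region (spectral radius < 1
#' and a positive-definite whole-tree correlation).
#'
#' @param name One of `"II", "III", "IV", "V", "VI", "VII"`.
#' @return An object of class `bar_model`: parameter names, box bounds, and
#'   a builder mapping a parameter vector to [bar_params].
#' @export
bar_model <- function(name = c("II", "III", "IV", "V", "VI", "VII")) {
  name <- match.arg(name)
  eps <- 1e-9
  switch(name,
    II = bar_model_custom(
      name = "II", d = 1,
      par_names = c("a", "gamma"),
      lower = c(0 + eps, -1 + eps), upper = c(1 - eps, 1 - eps),
      build = function(th) bar_params(matrix(th[1], 1, 1), gamma = th[2])
    ),
    III = bar_model_custom(
      name = "III", d = 2,
      par_names = c("a11", "a22", "gamma", "alpha1"),
      lower = c(eps, eps, -1 + eps, eps),
      upper = c(1 - eps, 1 - eps, 1 - eps, 1 - eps),
      build = function(th) bar_params(diag(th[1:2]), gamma = th[3],
                                      alpha = c(th[4], 1 - th[4]))
    ),
    IV = bar_model_custom(
      name = "IV", d = 2,
      par_names = c("a11", "a22", "a12", "gamma", "alpha1"),
      lower = c(eps, eps, -1 + eps, -1 + eps, eps),
      upper = c(1 - eps, 1 - eps, -eps, 1 - eps, 1 - eps),
      build = function(th) bar_params(matrix(c(th[1], 0, th[3], th[2]), 2, 2),
                                      gamma = th[4],
                                      alpha = c(th[5], 1 - th[5]))
    ),
    V = bar_model_custom(
      name = "V", d = 2,
      par_names = c("a", "a12", "gamma", "alpha1"),
      lower = c(eps, -1 + eps, -1 + eps, eps),
      upper = c(1 - eps, -eps, 1 - eps, 1 - eps),
      build = function(th) bar_params(matrix(c(th[1], 0, th[2], th[1]), 2, 2),
                                      gamma = th[3],
                                      alpha = c(th[4], 1 - th[4]))
    ),
    VI = bar_model_custom(
      name = "VI", d = 2,
      par_names = c("a11", "a22", "a12", "a21", "gamma", "alpha1"),
      lower = c(eps, eps, -1 + eps, -1 + eps, -1 + eps, eps),
      upper = c(1 - eps, 1 - eps, 1 - eps, 1 - eps, 1 - eps, 1 - eps),
      build = function(th) bar_params(matrix(c(th[1], th[4], th[3], th[2]),
                                             2, 2),
                                      gamma = th[5],
                                      alpha = c(th[6], 1 - th[6]))
    ),
    VII = bar_model_custom(
      name = "VII", d = 2,
      par_names = c("a12", "gamma", "alpha1"),
      lower = c(-1 + eps, -1 + eps, eps),
      upper = c(-eps, 1 - eps, 1 - eps),
      build = function(th) bar_params(matrix(c(0, 0, th[1], 0), 2, 2),
                                      gamma = th[2],
                                      alpha = c(th[3], 1 - th[3]))
    )
  )
}

#' @rdname bar_model
#' @param d Number of latent variables.
#' @param par_names,lower,upper Free-parameter names and box bounds (the box
#'   is also the uniform evidence prior).
#' @param build Function mapping a parameter vector to [bar_params]. For a
#'   zero-parameter model pass empty `par_names` and a constant `build`.
#' @export
bar_model_custom <- function(name, d, par_names, lower, upper, build) {
  stopifnot(length(par_names) == length(lower),
            length(lower) == length(upper), is.function(build))
  structure(list(name = name, d = d, par_names = par_names,
                 n_par = length(par_names), lower = lower, upper = upper,
                 build = build),
            class = "bar_model")
}

#' @export
print.bar_model <- function(x, ...) {
  cat(sprintf("BAR model %s: d = %d, %d free parameter(s) (%s)\n",
              x$name, x$d, x$n_par, paste(x$par_names, collapse = ", ")))
  invisible(x)
}

# Build parameters and report feasibility instead of erroring; used by the
# prior-sampling evidence and ABC-style loops.
build_params_safely <- function(model, theta) {
  tryCatch(model$build(theta), kincycle_error = function(e) NULL)
}

# Uniform prior draw in the model's box.
draw_prior <- function(model, n) {
  m <- matrix(stats::runif(n * model$n_par), n, model$n_par, byrow = FALSE)
  sweep(sweep(m, 2, model$upper - model$lower, "*"), 2, model$lower, "+")
}
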