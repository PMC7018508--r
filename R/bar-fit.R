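#' Fit a BAR model to lineage trees by maximum likelihood
#'
#' Maximises the exact whole-tree Gaussian likelihood (see [tree_loglik])
#' over the model's free parameters. Optimisation runs on a logit-transform
#' of the box-constrained parameters with Nelder-Mead restarts from the
#' best of a set of prior draws.
#'
#' @param forest A (truncated) lineage forest.
#' @param model A [bar_model] or a catalogue name (`"II"` ... `"VII"`).
#' @param scores Optional per-row Gaussian scores; computed from the
#'   forest's divided cells by default.
#' @param n_starts Number of prior draws screened for starting points.
#' @param n_restarts Nelder-Mead restarts from the best draws.
#' @param seed Optional integer seed.
#' @return An object of class `bar_fit` with methods `print`, `summary`,
#'   `coef`, `logLik`, `predict` (kinship correlations) and `simulate`
#'   (forward-sampled forests through the fitted inverse rank-Gaussian
#'   map).
#' @export
fit_bar <- function(forest, model = "V", scores = NULL, n_starts = 64,
                    n_restarts = 3, seed = NULL) {
  if (is.character(model)) model <- bar_model(model)
  if (is.null(scores)) scores <- forest_scores(forest)
  map <- attr(scores, "map")
  ld <- bar_lik_data(forest, scores)

  negll <- function(z) {
    th <- box_from_z(z, model$lower, model$upper)
    p <- build_params_safely(model, th)
    if (is.null(p)) return(1e10)
    tryCatch(-bar_loglik_core(p, ld), kincycle_error = function(e) 1e10)
  }

  with_seed(seed, {
    starts <- draw_prior(model, n_starts)
    vals <- apply(starts, 1, function(th) {
      p <- build_params_safely(model, th)
      if (is.null(p)) return(-Inf)
      tryCatch(bar_loglik_core(p, ld), kincycle_error = function(e) -Inf)
    })
    ord <- order(vals, decreasing = TRUE)
    best <- NULL
    for (i in seq_len(min(n_restarts, sum(is.finite(vals))))) {
      z0 <- z_from_box(starts[ord[i], ], model$lower, model$upper)
      opt <- stats::optim(z0, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) {
      stop_kc("kc_invalid_parameter", "no feasible starting point found")
    }
    theta <- box_from_z(best$par, model$lower, model$upper)
    names(theta) <- model$par_names
    structure(list(model = model, theta = theta,
                   params = model$build(theta), loglik = -best$value,
                   n_obs = ld$n_obs, n_trees = length(ld$units),
                   map = map, scores = scores, lik_data = ld),
              class = "bar_fit")
  })
}

box_from_z <- function(z, lower, upper) lower + (upper - lower) * stats::plogis(z)
z_from_box <- function(th, lower, upper) {
  p <- pmin(pmax((th - lower) / (upper - lower), 1e-8), 1 - 1e-8)
  stats::qlogis(p)
}

#' @export
print.bar_fit <- function(x, digits = 3, ...) {
  cat(sprintf("BAR model %s fit: %d cells in %d trees, log-likelihood %.2f\n",
              x$model$name, x$n_obs, x$n_trees, x$loglik))
  cat("coefficients:\n")
  print(round(x$theta, digits))
  invisible(x)
}

#' @export
summary.bar_fit <- function(object, ...) {
  pred <- predict(object)
  out <- list(fit = object, pattern = pred)
  class(out) <- "summary.bar_fit"
  out
}

#' @export
print.summary.bar_fit <- function(x, ...) {
  print(x$fit)
  print(x$fit$params)
  cat("predicted kinship correlations:\n")
  print(format(x$pattern, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bar_fit <- function(object, ...) object$theta

#' @export
logLik.bar_fit <- function(object, ...) {
  structure(object$loglik, df = object$model$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' @describeIn fit_bar Predicted correlations for a set of kinships; if a
#'   credible band has been attached (see [credible_band]) its min/max per
#'   kinship are included.
#' @param object A `bar_fit`.
#' @param kinships List of kinships (default [default_kinships]).
#' @param ... Unused.
#' @export
predict.bar_fit <- function(object, kinships = default_kinships(), ...) {
  rho <- kin_corr(object$params, kinships)
  out <- data.frame(
    u = vapply(kinships, function(k) as_kinship(k)[[1]], integer(1)),
    v = vapply(kinships, function(k) as_kinship(k)[[2]], integer(1)),
    rho = rho
  )
  band <- object$band
  if (!is.null(band)) {
    m <- merge(out, band$band, by = c("u", "v"), all.x = TRUE, sort = FALSE)
    out <- m[order(match(paste(m$u, m$v), paste(out$u, out$v))), ]
    rownames(out) <- NULL
  }
  out
}

#' @describeIn fit_bar Forward-simulate lineage forests from the fitted
#'   parameters, converting latent scores to cycle times through the
#'   inverse rank-Gaussian map of the data the model was fitted to.
#' @param nsim Number of forests.
#' @param n_trees,n_gen Simulated design.
#' @export
simulate.bar_fit <- function(object, nsim = 1, seed = NULL, n_trees = 30,
                             n_gen = 7, ...) {
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(i) {
      bar_forward_sample(object$params, n_trees = n_trees, n_gen = n_gen,
                         tau_map = object$map$inverse)
    })
    if (nsim == 1L) out[[1]] else out
  })
}

#' Likelihood-ratio credible band for a fitted BAR model
#'
#' Collects all evaluated parameter sets whose likelihood is at least 15%
#' of the maximum (the Gaussian-approximate 95% credible region) and
#' reports per-kinship min/max predicted correlations over this set. The
#' boundary is inclusive. Candidate points are drawn from a Laplace
#' proposal around the maximum-likelihood point (numerical-Hessian
#' covariance, inflated twofold), mixed with draws from the box prior so
#' that flat likelihoods recover the whole searched region.
#'
#' @param fit A `bar_fit`.
#' @param n_draws Candidate parameter sets evaluated (default 4000).
#' @param threshold Likelihood ratio defining the band (default 0.15).
#' @param kinships Kinships to band (default [default_kinships]).
#' @param seed Optional integer seed.
#' @return The fit with a `band` component attached: `params` (matrix of
#'   retained parameter vectors, MLE first), `band` (per-kinship `lo`,
#'   `hi`), `threshold`, and `collapsed` (TRUE when only the MLE
#'   qualifies).
#' @export
credible_band <- function(fit, n_draws = 4000, threshold = 0.15,
                          kinships = default_kinships(), seed = NULL) {
  model <- fit$model
  ld <- bar_lik_data_from_fit(fit)
  with_seed(seed, {
    n_local <- round(0.75 * n_draws)
    theta <- rbind(
      laplace_proposal(fit, ld, n_local),
      draw_prior(model, n_draws - n_local)
    )
    ll <- apply(theta, 1, function(th) {
      p <- build_params_safely(model, th)
      if (is.null(p)) return(-Inf)
      tryCatch(bar_loglik_core(p, ld), kincycle_error = function(e) -Inf)
    })
    llmax <- max(fit$loglik, ll)
    keep <- which(ll >= llmax + log(threshold))
    params_kept <- rbind(fit$theta, theta[keep, , drop = FALSE])
    colnames(params_kept) <- model$par_names
    collapsed <- nrow(params_kept) == 1L
    if (collapsed) {
      warn_kc("kc_band_collapsed_warning",
              "credible band contains only the maximum-likelihood point")
    }
    rows <- lapply(kinships, function(k) {
      k <- as_kinship(k)
      r <- apply(params_kept, 1, function(th) {
        p <- build_params_safely(model, th)
        if (is.null(p)) return(NA_real_)
        tryCatch(kin_corr(p, k), kincycle_error = function(e) NA_real_)
      })
      data.frame(u = k[[1]], v = k[[2]], lo = min(r, na.rm = TRUE),
                 hi = max(r, na.rm = TRUE))
    })
    fit$band <- list(params = params_kept, band = do.call(rbind, rows),
                     threshold = threshold, collapsed = collapsed)
    fit
  })
}

# Gaussian candidates around the MLE with covariance 2 * H^-1 from a
# finite-difference Hessian of the log-likelihood, clipped to the box.
laplace_proposal <- function(fit, ld, n) {
  model <- fit$model
  th0 <- fit$theta
  p <- model$n_par
  f <- function(th) {
    pa <- build_params_safely(model, th)
    if (is.null(pa)) return(-Inf)
    tryCatch(bar_loglik_core(pa, ld), kincycle_error = function(e) -Inf)
  }
  h <- pmax(1e-4, 1e-3 * (model$upper - model$lower))
  H <- matrix(0, p, p)
  f0 <- f(th0)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(th0 + ei) - 2 * f0 + f(th0 - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(th0 + ei + ej) - f(th0 + ei - ej) -
             f(th0 - ei + ej) + f(th0 - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  Sig <- tryCatch(2 * solve(-H), error = function(e) NULL)
  R <- if (!is.null(Sig)) tryCatch(chol(Sig), error = function(e) NULL)
       else NULL
  if (is.null(R)) {
    # fall back to independent scales from the diagonal curvature
    sds <- sqrt(2 / pmax(-diag(H), 1e-2))
    draws <- matrix(stats::rnorm(n * p), n, p)
    draws <- sweep(draws, 2, sds, "*")
  } else {
    draws <- matrix(stats::rnorm(n * p), n, p) %*% R
  }
  draws <- sweep(draws, 2, th0, "+")
  lo <- matrix(model$lower, n, p, byrow = TRUE)
  hi <- matrix(model$upper, n, p, byrow = TRUE)
  pmin(pmax(draws, lo + 1e-9), hi - 1e-9)
}

bar_lik_data_from_fit <- function(fit) {
  if (!is.null(fit$lik_data)) return(fit$lik_data)
  stop_kc("kc_invalid_parameter",
          "fit carries no likelihood data; refit with fit_bar")
}
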