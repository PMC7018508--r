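#' Whole-tree log-likelihood of a BAR model
#'
#' Under a BAR model the Gaussian scores of all observed (divided) cells in
#' a tree are jointly multivariate normal with unit variances and pairwise
#' correlations determined solely by kinship. The log-likelihood of a forest
#' is the sum over trees of the corresponding multivariate-normal log
#' densities; cells without a usable score (lost, died, censored, truncated
#' away) are marginalised simply by omission.
#'
#' @param params A [bar_params] object.
#' @param forest A lineage forest.
#' @param scores Per-row Gaussian scores (`NA` for cells without a usable
#'   cycle length). Defaults to rank-Gaussianized cycle lengths of all
#'   divided cells, see [gaussianize].
#' @return Log-likelihood (scalar). A parameter combination whose implied
#'   correlation matrix is not positive definite raises an
#'   invalid-parameter error.
#' @export
tree_loglik <- function(params, forest, scores = NULL) {
  ld <- bar_lik_data(forest, scores)
  bar_loglik_core(params, ld)
}

# Correlations for a vector of kinship codes (u*64 + v), sharing one
# computation of the stationary covariance, sister covariance and powers of
# A; this is the inner loop of evidence integration.
kin_corr_codes <- function(params, codes) {
  A <- params$A
  d <- params$d
  a <- params$alpha
  C <- stationary_cov(A)
  den <- drop(t(a) %*% C %*% a)
  S <- A %*% C %*% t(A) + params$gamma * diag(d)
  rho_ss <- drop(t(a) %*% S %*% a) / den
  if (abs(rho_ss) > 1 + 1e-12) {
    stop_kc("kc_invalid_parameter",
            sprintf("sister correlation %.4f outside [-1, 1]: invalid gamma/A",
                    rho_ss))
  }
  u <- codes %/% 64L
  v <- codes %% 64L
  maxp <- max(v)
  Apow <- vector("list", maxp + 1L)
  Apow[[1]] <- diag(d)
  for (m in seq_len(maxp)) Apow[[m + 1L]] <- Apow[[m]] %*% A
  aC <- drop(C %*% a)
  vapply(seq_along(codes), function(i) {
    if (u[i] == 0L) {
      drop(t(a) %*% Apow[[v[i] + 1L]] %*% aC) / den
    } else {
      drop((t(a) %*% Apow[[u[i]]]) %*% S %*% t(Apow[[v[i]]]) %*% a) / den
    }
  }, numeric(1))
}

# Per-row default scores: rank-Gaussianized cycle lengths of divided cells.
forest_scores <- function(forest) {
  div <- which(forest$fate == "divided")
  taus <- forest$end_time_h[div] - forest$birth_time_h[div]
  g <- gaussianize(taus)
  scores <- rep(NA_real_, nrow(forest))
  scores[div] <- g$scores
  attr(scores, "map") <- g$map
  scores
}

# Precompute everything the likelihood needs that does not depend on the
# parameters: per-tree score vectors and kinship-code matrices, with trees
# of identical kinship structure grouped so the Cholesky factor is shared.
bar_lik_data <- function(forest, scores = NULL) {
  if (is.null(scores)) scores <- forest_scores(forest)
  stopifnot(length(scores) == nrow(forest))
  obs <- which(!is.na(scores) & forest$fate == "divided")
  if (!length(obs)) stop_kc("kc_insufficient_data", "no observed cells")
  pr <- forest_parent_row(forest)
  gen <- forest$generation

  trees <- split(obs, forest$tree_id[obs])
  units <- lapply(trees, function(rows) {
    n <- length(rows)
    g <- gen[rows]
    maxg <- max(g)
    # AG[i, h+1] = ancestor (global row) of cell i at absolute generation h
    AG <- matrix(NA_integer_, n, maxg + 1L)
    for (h in maxg:0) {
      self <- g == h
      AG[self, h + 1L] <- rows[self]
      deeper <- g > h
      if (h < maxg) AG[deeper, h + 1L] <- pr[AG[deeper, h + 2L]]
    }
    # mg[i, j] = generation of the MRCA of cells i and j
    mg <- matrix(-1L, n, n)
    for (h in 0:maxg) {
      col <- AG[, h + 1L]
      eq <- outer(col, col, "==")
      eq[is.na(eq)] <- FALSE
      mg[eq] <- h
    }
    umat <- matrix(g, n, n) - mg        # row cell's distance to MRCA
    vmat <- t(umat)
    code <- pmin(umat, vmat) * 64L + pmax(umat, vmat)
    diag(code) <- 0L
    list(y = scores[rows], code = code)
  })

  sig <- vapply(units, function(u) {
    paste(length(u$y), paste(u$code, collapse = ","), sep = ":")
  }, character(1))
  groups <- split(seq_along(units), sig)
  codes <- sort(unique(unlist(lapply(units, function(u) u$code))))
  codes <- setdiff(codes, 0L)
  list(units = units, groups = groups, codes = codes,
       n_obs = length(obs))
}

bar_loglik_core <- function(params, ld) {
  if (length(ld$codes)) {
    rho <- kin_corr_codes(params, ld$codes)
    lookup <- numeric(max(ld$codes) + 1L)
    lookup[ld$codes + 1L] <- rho
  } else {
    lookup <- numeric(1)
  }
  total <- 0
  for (grp in ld$groups) {
    u1 <- ld$units[[grp[1]]]
    n <- length(u1$y)
    Sigma <- matrix(lookup[u1$code + 1L], n, n)
    diag(Sigma) <- 1
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) {
      stop_kc("kc_invalid_parameter",
              "implied tree correlation matrix not positive definite")
    }
    Y <- vapply(grp, function(i) ld$units[[i]]$y, numeric(n))
    Y <- matrix(Y, nrow = n)
    Q <- backsolve(R, Y, transpose = TRUE)
    total <- total +
      length(grp) * (-0.5 * n * log(2 * pi) - sum(log(diag(R)))) -
      0.5 * sum(Q * Q)
  }
  total
}

#' Bayesian evidence of a BAR model by Monte-Carlo integration
#'
#' The evidence (marginal likelihood) is the prior-averaged likelihood,
#' estimated by plain Monte-Carlo: parameters are drawn uniformly from the
#' model's box prior, the whole-forest log-likelihood evaluated at each
#' draw, and the average computed with log-sum-exp stabilisation. Draws
#' outside the feasible region (non-stationary `A` or a non-positive-
#' definite implied correlation) contribute zero likelihood, which
#' implements truncation of the prior to the feasible region.
#'
#' @param model A [bar_model].
#' @param forest A lineage forest.
#' @param scores Optional per-row Gaussian scores (see [tree_loglik]).
#' @param n_mc Number of Monte-Carlo draws (default 1e5; at least 1e3
#'   except for zero-parameter models).
#' @param seed Optional integer seed.
#' @param lik_data Precomputed internal likelihood structure (as built for
#'   `forest`/`scores`), reused when comparing several models on one
#'   dataset.
#' @return Object of class `bar_evidence`: `log_evidence`, `mc_se`
#'   (Monte-Carlo standard error on the log scale), `n_draws`, `ess`
#'   (effective sample size), `model`. An effective sample size below 10
#'   attaches a warning flag.
#' @export
log_evidence <- function(model, forest, scores = NULL, n_mc = 1e5,
                         seed = NULL, lik_data = NULL) {
  ld <- if (is.null(lik_data)) bar_lik_data(forest, scores) else lik_data
  if (model$n_par == 0L) {
    ll <- bar_loglik_core(model$build(numeric(0)), ld)
    return(structure(list(log_evidence = ll, mc_se = 0, n_draws = 1L,
                          ess = 1, model = model$name, low_ess = FALSE),
                     class = "bar_evidence"))
  }
  if (n_mc < 1e3) {
    stop_kc("kc_invalid_parameter", "n_mc must be at least 1000")
  }
  with_seed(seed, {
    theta <- draw_prior(model, n_mc)
    ll <- rep(-Inf, n_mc)
    for (i in seq_len(n_mc)) {
      p <- build_params_safely(model, theta[i, ])
      if (is.null(p)) next
      ll[i] <- tryCatch(bar_loglik_core(p, ld),
                        kincycle_error = function(e) -Inf)
    }
    if (!any(is.finite(ll))) {
      stop_kc("kc_invalid_parameter",
              "no feasible prior draw produced a finite likelihood")
    }
    logz <- log_sum_exp(ll) - log(n_mc)
    w <- exp(ll - max(ll[is.finite(ll)]))
    mw <- mean(w)
    mc_se <- stats::sd(w) / (mw * sqrt(n_mc))
    ess <- sum(w)^2 / sum(w^2)
    res <- structure(list(log_evidence = logz, mc_se = mc_se,
                          n_draws = n_mc, ess = ess, model = model$name,
                          low_ess = ess < 10),
                     class = "bar_evidence")
    if (res$low_ess) {
      warn_kc("kc_low_ess_warning",
              sprintf("evidence for model %s: effective sample size %.1f < 10",
                      model$name, ess))
    }
    res
  })
}

#' @export
print.bar_evidence <- function(x, ...) {
  cat(sprintf("Model %s: log evidence %.3f (MC se %.3f, ESS %.0f, %d draws)%s\n",
              x$model, x$log_evidence, x$mc_se, x$ess, x$n_draws,
              if (isTRUE(x$low_ess)) " [low ESS]" else ""))
  invisible(x)
}

#' Relative evidences of a set of models
#'
#' Normalises evidences so the best-supported model scores 1 and the others
#' are reported as fractions of it (Occam-penalised model ranking).
#'
#' @param results List of `bar_evidence` objects, or a numeric vector of
#'   log evidences.
#' @return Named numeric vector of relative evidences in (0, 1].
#' @export
relative_evidence <- function(results) {
  if (is.numeric(results)) {
    lz <- results
    nm <- names(results)
  } else {
    lz <- vapply(results, function(r) r$log_evidence, numeric(1))
    nm <- vapply(results, function(r) r$model, character(1))
  }
  if (length(lz) < 2L) {
    stop_kc("kc_insufficient_data", "need at least 2 models to compare")
  }
  out <- exp(lz - max(lz))
  names(out) <- nm
  out
}

#' Compare the full BAR catalogue on one forest
#'
#' Convenience wrapper running [log_evidence] for several models on shared
#' scores and reporting relative evidences.
#'
#' @param forest A lineage forest.
#' @param models Character vector of catalogue model names.
#' @param n_mc,seed Passed to [log_evidence] (seeds are offset per model).
#' @param scores Optional shared scores.
#' @return Data.frame of class `bar_evidence_table` with one row per model.
#' @export
bar_evidence <- function(forest, models = c("II", "III", "IV", "V", "VI",
                                            "VII"),
                         n_mc = 1e4, seed = NULL, scores = NULL) {
  if (is.null(scores)) scores <- forest_scores(forest)
  ld <- bar_lik_data(forest, scores)
  res <- lapply(seq_along(models), function(i) {
    log_evidence(bar_model(models[i]), forest, n_mc = n_mc,
                 seed = if (is.null(seed)) NULL else seed + i - 1L,
                 lik_data = ld)
  })
  out <- data.frame(
    model = models,
    log_evidence = vapply(res, `[[`, numeric(1), "log_evidence"),
    mc_se = vapply(res, `[[`, numeric(1), "mc_se"),
    ess = vapply(res, `[[`, numeric(1), "ess")
  )
  out$relative_evidence <- unname(relative_evidence(out$log_evidence))
  class(out) <- c("bar_evidence_table", "data.frame")
  out
}

#' @export
print.bar_evidence_table <- function(x, digits = 3, ...) {
  cat("BAR model comparison (Monte-Carlo evidence)\n")
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}
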